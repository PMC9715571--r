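# Rigid-body geometry: transforms, Kabsch superposition, principal
# dimensions, helix-axis bend angles.

#' Construct a rigid transform
#'
#' A proper rigid motion x -> R x + t. The rotation must be orthonormal
#' with determinant +1 (tolerance 1e-8); reflections are rejected.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation has determinant != +1 (improper rotation)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation %.2f A\n",
              ang, sqrt(sum(x$translation^2))))
  invisible(x)
}

#' Rotation angle of a rotation matrix, in degrees
#' @param R 3x3 rotation matrix.
#' @return angle in [0, 180] degrees.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Compose two rigid transforms
#'
#' \code{compose_transform(a, b)} is the transform applying \code{b} first,
#' then \code{a}.
#' @param a,b \code{rigid_transform}s.
#' @return \code{rigid_transform}.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf \code{rigid_transform}.
#' @return \code{rigid_transform} undoing \code{tf}.
#' @export
invert_transform <- function(tf) {
  Rt <- t(tf$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% tf$translation))
}

#' Apply a rigid transform to coordinates or to model chains
#'
#' @param x an n x 3 coordinate matrix or an \code{xl_structure}.
#' @param tf \code{rigid_transform}.
#' @param chains for a model: chains to move (default all).
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, tf, chains = NULL) {
  if (inherits(x, "xl_structure")) {
    idx <- select_atoms(x, chains = chains)
    m <- as.matrix(x$atoms[idx, c("x", "y", "z")])
    m <- transform_coords(m, tf)
    x$atoms[idx, c("x", "y", "z")] <- m
    return(x)
  }
  transform_coords(x, tf)
}

transform_coords <- function(m, tf) {
  out <- m %*% t(tf$rotation)
  out[, 1] <- out[, 1] + tf$translation[1]
  out[, 2] <- out[, 2] + tf$translation[2]
  out[, 3] <- out[, 3] + tf$translation[3]
  out
}

#' Axis-angle rotation matrix
#' @param axis length-3 axis (normalised internally).
#' @param angle_deg rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Uniform random rotation (quaternion method)
#'
#' Draws a quaternion from four independent standard normals and
#' normalises; uses the current RNG state.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# ---- Kabsch superposition ------------------------------------------------

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform (rotation with det = +1, plus
#' translation) minimising the RMSD of \code{mobile} onto \code{ref} over
#' paired points, via SVD of the cross-covariance with sign correction to
#' exclude reflections. The RMSD is unweighted over the pairing; no
#' trimming or outlier rejection is applied.
#'
#' @param mobile,ref n x 3 coordinate matrices, same n >= 3.
#' @param pairing optional data.frame describing the matched residues
#'   (carried through to the result).
#' @return list of class \code{superposition}: \code{transform}
#'   (\code{rigid_transform} mapping mobile onto ref), \code{rmsd}
#'   (Angstrom), \code{n_atoms}, \code{pairing}.
#' @export
kabsch_superpose <- function(mobile, ref, pairing = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (nrow(mobile) != nrow(ref))
    stop("point sets differ in length: ", nrow(mobile), " vs ", nrow(ref))
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 paired points, got ", n)
  cm <- colMeans(mobile); cr <- colMeans(ref)
  P <- sweep(mobile, 2, cm); Q <- sweep(ref, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cr - as.numeric(R %*% cm)
  moved <- transform_coords(mobile, rigid_transform(R, t_vec))
  rmsd <- sqrt(mean(rowSums((moved - ref)^2)))
  structure(list(transform = rigid_transform(R, t_vec), rmsd = rmsd,
                 n_atoms = n, pairing = pairing),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d atoms\n",
              x$rmsd, x$n_atoms))
  invisible(x)
}

#' Pair common C-alpha atoms between two models
#'
#' Matches residues by author residue number present in both members of
#' each chain pair, requiring a CA atom on both sides, in deterministic
#' ascending (chain pair, resno) order.
#'
#' @param model_a,model_b \code{xl_structure}s.
#' @param chain_pairing named character vector: names are chains of
#'   \code{model_a}, values the corresponding chains of \code{model_b}.
#' @return list \code{coords_a}, \code{coords_b} (n x 3), \code{pairing}
#'   (data.frame chain_a, resno, chain_b).
#' @export
pair_common_ca <- function(model_a, model_b, chain_pairing) {
  stopifnot(length(chain_pairing) >= 1, !is.null(names(chain_pairing)))
  rows_a <- integer(); rows_b <- integer()
  pairing <- NULL
  for (ca in names(chain_pairing)) {
    cb <- chain_pairing[[ca]]
    ia <- select_atoms(model_a, chains = ca, elety = "CA")
    ib <- select_atoms(model_b, chains = cb, elety = "CA")
    ra <- model_a$atoms$resno[ia]; rb <- model_b$atoms$resno[ib]
    common <- sort(intersect(ra, rb))
    if (length(common) == 0L) next
    rows_a <- c(rows_a, ia[match(common, ra)])
    rows_b <- c(rows_b, ib[match(common, rb)])
    pairing <- rbind(pairing, data.frame(chain_a = ca, resno = common,
                                         chain_b = cb,
                                         stringsAsFactors = FALSE))
  }
  if (length(rows_a) == 0L)
    stop("no common CA residues under the supplied chain pairing")
  list(coords_a = as.matrix(model_a$atoms[rows_a, c("x", "y", "z")]),
       coords_b = as.matrix(model_b$atoms[rows_b, c("x", "y", "z")]),
       pairing = pairing)
}

#' Superpose two models over common C-alpha atoms
#'
#' For homodimers a crosslink-style chain correspondence is ambiguous:
#' with \code{try_swap = TRUE} and a two-chain pairing, both chain
#' assignments are evaluated and the lower-RMSD one kept (recorded in the
#' result as \code{swapped}).
#'
#' @param mobile,ref \code{xl_structure}s.
#' @param chain_pairing named character vector, chains of \code{mobile} to
#'   chains of \code{ref}.
#' @param try_swap evaluate the swapped assignment for 2-chain pairings.
#' @return \code{superposition} with elements \code{swapped} and
#'   \code{pairing}.
#' @export
superpose_models <- function(mobile, ref, chain_pairing, try_swap = TRUE) {
  cand <- list(chain_pairing)
  if (try_swap && length(chain_pairing) == 2L) {
    sw <- rev(unname(chain_pairing))
    names(sw) <- names(chain_pairing)
    cand <- c(cand, list(sw))
  }
  best <- NULL; best_sw <- FALSE
  for (k in seq_along(cand)) {
    p <- pair_common_ca(mobile, ref, cand[[k]])
    s <- kabsch_superpose(p$coords_a, p$coords_b, pairing = p$pairing)
    if (is.null(best) || s$rmsd < best$rmsd) {
      best <- s; best_sw <- (k == 2L)
    }
  }
  best$swapped <- best_sw
  best
}

#' RMSD between two coordinate sets without refitting
#' @param a,b n x 3 matrices.
#' @return root-mean-square deviation, Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# ---- principal dimensions ------------------------------------------------

#' Principal dimensions of a model or coordinate set
#'
#' Extents (max minus min coordinate) along the three principal axes of
#' the C-alpha coordinate covariance, sorted descending. For coplanar
#' input the smallest extent is ~0.
#'
#' @param x \code{xl_structure} (CA atoms are used) or an n x 3 matrix.
#' @param chains optional chain filter when \code{x} is a model.
#' @return numeric length-3, d1 >= d2 >= d3 (Angstrom).
#' @export
principal_dimensions <- function(x, chains = NULL) {
  m <- if (inherits(x, "xl_structure")) ca_coords(x, chains = chains)
       else as.matrix(x)
  if (nrow(m) < 3) stop("need >= 3 points")
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  proj <- sweep(m, 2, colMeans(m)) %*% ev$vectors
  sort(apply(proj, 2, function(v) diff(range(v))), decreasing = TRUE)
}

# ---- bend angle ----------------------------------------------------------

# Best-fit line direction of a CA window, oriented along increasing
# residue order. The trace is first smoothed with a one-turn (4-residue)
# moving average so the ~100 deg/residue helical wobble does not tilt
# the fitted axis; the line is then the principal axis of the smoothed
# points.
.window_axis <- function(m) {
  n <- nrow(m)
  k <- min(4L, n - 2L)
  if (k >= 2L) {
    sm <- vapply(seq_len(n - k + 1L), function(i)
      colMeans(m[i:(i + k - 1L), , drop = FALSE]), numeric(3))
    m <- t(sm)
  }
  ev <- eigen(stats::cov(m), symmetric = TRUE)
  axis <- ev$vectors[, 1]
  s <- sweep(m, 2, colMeans(m)) %*% axis
  if (stats::cor(as.numeric(s), seq_len(nrow(m))) < 0) axis <- -axis
  axis
}

#' Bend angle of a helical chain about a named hinge
#'
#' Measures the angle between the best-fit line directions (principal axis
#' of the C-alpha positions) of an N-side and a C-side residue window;
#' 0 degrees means straight. The hinge is an input: window choice follows
#' the residues flanking the kink of interest. Each window needs at least
#' 7 consecutive C-alpha atoms so the line direction approximates the
#' local helix axis.
#'
#' @param model \code{xl_structure}.
#' @param chain chain id.
#' @param window_n,window_c integer residue-number vectors (author
#'   numbering) for the windows on either side of the hinge.
#' @return bend angle in degrees.
#' @export
bend_angle <- function(model, chain, window_n, window_c) {
  get_win <- function(w) {
    idx <- select_atoms(model, chains = chain, resno = w, elety = "CA")
    if (length(idx) < 7)
      stop("window has ", length(idx), " CA atoms; need >= 7")
    a <- model$atoms[idx, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    as.matrix(a[, c("x", "y", "z")])
  }
  u <- .window_axis(get_win(window_n))
  v <- .window_axis(get_win(window_c))
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}
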
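# Solvent-accessible surface area (Shrake-Rupley), interface buried area,
# and distance-criterion polar-contact detection.

# Default van der Waals radii (Angstrom); elements outside the table fall
# back to the generic 1.80 A.
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
.vdw_fallback <- 1.80

#' Quasi-uniform points on the unit sphere (golden spiral)
#'
#' Deterministic golden-section spiral lattice; no RNG is involved, so
#' SASA values are bit-reproducible.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i          # golden angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.vdw_radii <- function(elements, radii = .default_vdw, strict = FALSE) {
  r <- unname(radii[toupper(elements)])
  unknown <- is.na(r)
  if (any(unknown) && strict)
    stop("unknown element(s) without fallback radius: ",
         paste(unique(elements[unknown]), collapse = ", "))
  r[unknown] <- .vdw_fallback
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points are placed on a sphere of radius
#' (vdW + probe) using the deterministic golden-spiral lattice; the
#' accessible fraction is the fraction of points not occluded by any
#' neighbouring atom's probe-expanded sphere, and the atom's area is that
#' fraction of 4 pi (r + probe)^2.
#'
#' @param model \code{xl_structure} or n x 3 coordinate matrix (in which
#'   case \code{elements} must be given).
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, a
#'   water molecule).
#' @param n_points sphere test points per atom (default 960).
#' @param radii named vdW radius table; unknown elements fall back to
#'   1.80 A unless \code{strict}.
#' @param elements element symbols when \code{model} is a bare matrix.
#' @param strict error on unknown elements.
#' @return list of class \code{sasa_result}: \code{per_atom} (Angstrom^2
#'   per atom, model order), \code{per_residue} (named vector keyed
#'   "chain resno"), \code{total}, \code{probe_radius},
#'   \code{n_sphere_points}.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960,
                 radii = .default_vdw, elements = NULL, strict = FALSE) {
  if (inherits(model, "xl_structure")) {
    xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
    elements <- model$atoms$elesy
    res_key <- paste(model$atoms$chain, model$atoms$resno)
  } else {
    xyz <- as.matrix(model)
    if (is.null(elements)) stop("elements required for bare coordinates")
    res_key <- as.character(seq_len(nrow(xyz)))
  }
  n <- nrow(xyz)
  r <- .vdw_radii(elements, radii, strict) + probe_radius
  sp <- sphere_points(n_points)
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r + r[i])^2 & d2 > 0)
    pts <- sp * r[i]
    pts[, 1] <- pts[, 1] + xyz[i, 1]
    pts[, 2] <- pts[, 2] + xyz[i, 2]
    pts[, 3] <- pts[, 3] + xyz[i, 3]
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= r[j]^2
    }
    per_atom[i] <- sum(acc) / n_points * 4 * pi * r[i]^2
  }
  per_residue <- tapply(per_atom, res_key, sum)
  structure(list(per_atom = per_atom,
                 per_residue = per_residue[unique(res_key)],
                 total = sum(per_atom), probe_radius = probe_radius,
                 n_sphere_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Interface buried area between two atom groups
#'
#' Buried surface area on complex formation:
#' delta = SASA(A alone) + SASA(B alone) - SASA(A and B together),
#' where each group "alone" is the group's atoms with everything else
#' removed. The primary value is the PISA-style interface area
#' delta / 2; the un-halved delta is also returned, as conventions differ
#' between tools.
#'
#' @param model \code{xl_structure}.
#' @param group_a,group_b disjoint integer atom-index vectors (rows of
#'   \code{model$atoms}, e.g. from \code{\link{select_atoms}}).
#' @param probe_radius,n_points,radii passed to \code{\link{sasa}}.
#' @return list: \code{bsa} (delta/2), \code{delta_sasa}, \code{sasa_a},
#'   \code{sasa_b}, \code{sasa_ab}.
#' @export
buried_area <- function(model, group_a, group_b, probe_radius = 1.4,
                        n_points = 960, radii = .default_vdw) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("interface groups must be non-empty")
  if (length(intersect(group_a, group_b)))
    stop("interface groups overlap")
  s_a <- sasa(subset_structure(model, group_a), probe_radius, n_points,
              radii)$total
  s_b <- sasa(subset_structure(model, group_b), probe_radius, n_points,
              radii)$total
  s_ab <- sasa(subset_structure(model, c(group_a, group_b)), probe_radius,
               n_points, radii)$total
  delta <- s_a + s_b - s_ab
  list(bsa = delta / 2, delta_sasa = delta,
       sasa_a = s_a, sasa_b = s_b, sasa_ab = s_ab)
}

.mainchain_atoms <- c("N", "CA", "C", "O", "OXT")

#' Detect hydrogen bonds between two groups (distance criterion)
#'
#' Heavy-atom criterion: every N/O ... N/O pair across the two groups
#' within \code{d_max} is reported, with side-chain vs main-chain role
#' annotated from the atom name. No hydrogen placement and no angle term:
#' maps at typical cryo-EM resolution carry no hydrogens, so the
#' distance-only criterion is the reproducible floor.
#'
#' @param model \code{xl_structure}.
#' @param group_a,group_b disjoint atom-index vectors.
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @return data.frame: one row per contact with both atom addresses,
#'   roles, and distance.
#' @export
detect_hbonds <- function(model, group_a, group_b, d_max = 3.5) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  a <- model$atoms
  polar <- toupper(a$elesy) %in% c("N", "O")
  ia <- group_a[polar[group_a]]
  ib <- group_b[polar[group_b]]
  .contact_pairs(a, ia, ib, d_max, role = TRUE)
}

.contact_pairs <- function(a, ia, ib, d_max, role = FALSE) {
  out <- data.frame(chain_a = character(), resno_a = integer(),
                    resid_a = character(), atom_a = character(),
                    chain_b = character(), resno_b = integer(),
                    resid_b = character(), atom_b = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (role) {
    out$role_a <- character(); out$role_b <- character()
  }
  if (length(ia) == 0L || length(ib) == 0L) return(out)
  xa <- as.matrix(a[ia, c("x", "y", "z")])
  xb <- as.matrix(a[ib, c("x", "y", "z")])
  for (p in seq_along(ia)) {
    d <- sqrt((xb[, 1] - xa[p, 1])^2 + (xb[, 2] - xa[p, 2])^2 +
              (xb[, 3] - xa[p, 3])^2)
    hit <- which(d <= d_max)
    for (q in hit) {
      row <- data.frame(
        chain_a = a$chain[ia[p]], resno_a = a$resno[ia[p]],
        resid_a = a$resid[ia[p]], atom_a = a$elety[ia[p]],
        chain_b = a$chain[ib[q]], resno_b = a$resno[ib[q]],
        resid_b = a$resid[ib[q]], atom_b = a$elety[ib[q]],
        distance = d[q], stringsAsFactors = FALSE)
      if (role) {
        row$role_a <- if (a$elety[ia[p]] %in% .mainchain_atoms)
          "main_chain" else "side_chain"
        row$role_b <- if (a$elety[ib[q]] %in% .mainchain_atoms)
          "main_chain" else "side_chain"
      }
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

# Charged-group atom names for salt-bridge detection.
.basic_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                     HIS = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.charged_idx <- function(a, idx, table) {
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    atoms <- table[[toupper(a$resid[i])]]
    keep[k] <- !is.null(atoms) && a$elety[i] %in% atoms
  }
  idx[keep]
}

#' Detect salt bridges between two groups
#'
#' Reports basic-to-acidic charged-group atom pairs (Lys NZ; Arg NH1,
#' NH2, NE; His ND1, NE2 against Asp OD1, OD2; Glu OE1, OE2) across the
#' groups with any atom-pair distance within \code{d_max}.
#'
#' @param model \code{xl_structure}.
#' @param group_a,group_b disjoint atom-index vectors.
#' @param d_max distance cutoff, Angstrom (default 4.0).
#' @return data.frame of contacts (atom-pair level), as in
#'   \code{\link{detect_hbonds}} without role columns.
#' @export
detect_salt_bridges <- function(model, group_a, group_b, d_max = 4.0) {
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  a <- model$atoms
  ba <- .charged_idx(a, group_a, .basic_atoms)
  aa <- .charged_idx(a, group_a, .acidic_atoms)
  bb <- .charged_idx(a, group_b, .basic_atoms)
  ab <- .charged_idx(a, group_b, .acidic_atoms)
  out <- rbind(.contact_pairs(a, ba, ab, d_max),
               .contact_pairs(a, aa, bb, d_max))
  rownames(out) <- NULL
  out
}

#' Full interface report for a declared interface
#'
#' @param model \code{xl_structure}.
#' @param interface_id label carried into the report.
#' @param group_a,group_b disjoint atom-index vectors.
#' @param probe_radius,n_points SASA parameters.
#' @param hbond_d_max,salt_d_max contact cutoffs, Angstrom.
#' @return list of class \code{interface_report}: \code{interface_id},
#'   \code{buried_area} (delta/2), \code{delta_sasa}, \code{hbonds},
#'   \code{salt_bridges}.
#' @export
interface_report <- function(model, interface_id, group_a, group_b,
                             probe_radius = 1.4, n_points = 960,
                             hbond_d_max = 3.5, salt_d_max = 4.0) {
  ba <- buried_area(model, group_a, group_b, probe_radius, n_points)
  structure(list(interface_id = interface_id, buried_area = ba$bsa,
                 delta_sasa = ba$delta_sasa,
                 hbonds = detect_hbonds(model, group_a, group_b,
                                        hbond_d_max),
                 salt_bridges = detect_salt_bridges(model, group_a,
                                                    group_b, salt_d_max)),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("<interface_report> %s: buried %.1f A^2 (delta %.1f), %d H-bond(s), %d salt bridge(s)\n",
              x$interface_id, x$buried_area, x$delta_sasa,
              nrow(x$hbonds), nrow(x$salt_bridges)))
  invisible(x)
}
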
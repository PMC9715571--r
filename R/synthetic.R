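# Seeded synthetic assemblies: parametric CA traces (helix, helix
# hairpin, solenoid), lysine-like anchor sites, simulated crosslink sets
# with decoys, and pose perturbation -- the ground-truth bench for the
# docking and characterisation stages.

# Ideal alpha-helix CA trace along +z: rise 1.5 A/residue, radius 2.3 A,
# 100 degrees/residue.
.helix_trace <- function(n, rise = 1.5, radius = 2.3, twist_deg = 100) {
  i <- seq_len(n) - 1
  th <- i * twist_deg * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

# Helix hairpin: two antiparallel helical arms joined by a short turn.
.hairpin_trace <- function(n) {
  n1 <- ceiling(n / 2); n2 <- n - n1
  arm1 <- .helix_trace(n1)
  arm2 <- .helix_trace(n2)
  arm2[, 3] <- -arm2[, 3]                      # run back down
  arm2[, 1] <- arm2[, 1] + 10                  # lateral offset of 10 A
  arm2[, 3] <- arm2[, 3] + max(arm1[, 3])
  rbind(arm1, arm2)
}

# Solenoid: helix of helices; the local helix axis follows a superhelical
# path of given radius and pitch. Defaults emulate an ARM-repeat
# alpha-solenoid superhelix (channel radius ~25 A, shallow pitch).
.solenoid_trace <- function(n, super_radius = 25, super_pitch = 30,
                            rise = 1.5, radius = 2.3, twist_deg = 100) {
  i <- seq_len(n) - 1
  s <- i * rise
  phi <- s * 2 * pi / sqrt((2 * pi * super_radius)^2 + super_pitch^2)
  centre <- cbind(super_radius * cos(phi), super_radius * sin(phi),
                  phi * super_pitch / (2 * pi))
  th <- i * twist_deg * pi / 180
  # local frame: tangent along the path, normal toward the superhelix axis
  tangent <- cbind(-super_radius * sin(phi), super_radius * cos(phi),
                   rep(super_pitch / (2 * pi), n))
  tangent <- tangent / sqrt(rowSums(tangent^2))
  normal <- cbind(-cos(phi), -sin(phi), rep(0, n))
  binorm <- cbind(tangent[, 2] * normal[, 3] - tangent[, 3] * normal[, 2],
                  tangent[, 3] * normal[, 1] - tangent[, 1] * normal[, 3],
                  tangent[, 1] * normal[, 2] - tangent[, 2] * normal[, 1])
  centre + radius * (cos(th) * normal + sin(th) * binorm)
}

#' Generate a synthetic multi-chain rigid assembly
#'
#' Builds CA-only chains from parametric backbone curves (ideal
#' alpha-helix, helix hairpin, or alpha-solenoid superhelix) and places
#' them side by side without CA clashes (all inter-chain CA distances
#' >= 4 A), with small seeded random tilts so chain poses are general.
#' Every \code{anchor_every}-th residue is a lysine-like crosslink anchor
#' (residue name LYS; the rest ALA). Chains are named A, B, C, ...;
#' residues are numbered from 1. Deterministic from \code{seed}.
#'
#' @param n_chains number of chains (>= 1).
#' @param chain_length residues per chain (>= 20); scalar or vector.
#' @param fold \code{"helix"}, \code{"helix_hairpin"}, or
#'   \code{"solenoid"}; scalar or vector per chain.
#' @param seed integer seed.
#' @param spacing nominal inter-chain offset, Angstrom.
#' @param anchor_every anchor site period in residues (default 7).
#' @param max_attempts placement attempts per chain before giving up.
#' @return \code{xl_structure} with attribute \code{anchors} (data.frame
#'   chain, resno) and \code{gen_params}.
#' @export
generate_assembly <- function(n_chains = 2, chain_length = 60,
                              fold = "helix", seed = 1, spacing = 10,
                              anchor_every = 7, max_attempts = 50) {
  stopifnot(n_chains >= 1, all(chain_length >= 20))
  chain_length <- rep_len(chain_length, n_chains)
  fold <- rep_len(fold, n_chains)
  set.seed(as.integer(seed))
  chains <- LETTERS[seq_len(n_chains)]
  placed <- list()
  for (k in seq_len(n_chains)) {
    trace <- switch(fold[k],
                    helix = .helix_trace(chain_length[k]),
                    helix_hairpin = .hairpin_trace(chain_length[k]),
                    solenoid = .solenoid_trace(chain_length[k]),
                    stop("unknown fold: ", fold[k]))
    trace <- sweep(trace, 2, colMeans(trace))
    if (k == 1L) {
      placed[[k]] <- trace
      next
    }
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      tilt <- rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 20))
      # bulky folds may not fit at the nominal spacing; push outward on
      # failed attempts so placement always terminates for sane inputs
      offset <- c((k - 1) * spacing + (attempt - 1) + stats::runif(1, 0, 2),
                  stats::runif(1, -2, 2), stats::runif(1, -2, 2))
      cand <- sweep(trace %*% t(tilt), 2, offset, "+")
      mind <- min(vapply(placed, function(p) {
        d2 <- outer(rowSums(p^2), rowSums(cand^2), "+") -
          2 * p %*% t(cand)
        min(d2)
      }, 1))
      if (mind >= 16) { placed[[k]] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not place chain ", chains[k],
                  " without CA clashes after ", max_attempts, " attempts")
  }
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k) {
    n <- chain_length[k]
    resno <- seq_len(n)
    data.frame(chain = chains[k], resno = resno, insert = "",
               resid = ifelse(resno %% anchor_every == 0, "LYS", "ALA"),
               elety = "CA", elesy = "C",
               x = placed[[k]][, 1], y = placed[[k]][, 2],
               z = placed[[k]][, 3], o = 1, b = 0,
               stringsAsFactors = FALSE)
  }))
  m <- structure_model(atoms, title = sprintf("synthetic %d-chain assembly",
                                              n_chains))
  a <- m$atoms
  attr(m, "anchors") <- data.frame(chain = a$chain[a$resid == "LYS"],
                                   resno = a$resno[a$resid == "LYS"],
                                   stringsAsFactors = FALSE)
  attr(m, "gen_params") <- list(n_chains = n_chains,
                                chain_length = chain_length, fold = fold,
                                seed = seed, spacing = spacing,
                                anchor_every = anchor_every)
  m
}

#' Anchor sites of a model
#'
#' Lysine-like crosslinkable residues: all residues named LYS with a CA
#' atom.
#' @param model \code{xl_structure}.
#' @return data.frame chain, resno.
#' @export
anchor_sites <- function(model) {
  a <- model$atoms
  keep <- a$resid == "LYS" & a$elety == "CA"
  data.frame(chain = a$chain[keep], resno = a$resno[keep],
             stringsAsFactors = FALSE)
}

#' Identity chain map for a synthetic assembly
#'
#' Protein names equal chain ids, offset 0, full residue range.
#' @param model \code{xl_structure}.
#' @return \code{xl_chainmap}.
#' @export
synthetic_chain_map <- function(model) {
  a <- model$atoms
  chain_map(do.call(rbind, lapply(unique(a$chain), function(ch)
    data.frame(protein = ch, chain = ch, offset = 0L,
               first = min(a$resno[a$chain == ch]),
               last = max(a$resno[a$chain == ch]),
               stringsAsFactors = FALSE))))
}

#' Simulate a crosslink set from a ground-truth assembly
#'
#' True links are sampled uniformly without replacement from anchor pairs
#' whose ground-truth CA-CA distance is at most \code{cutoff - margin};
#' decoys (emulating FDR-level false identifications) from pairs beyond
#' \code{cutoff + margin}. The number of decoys is binomial with mean
#' n_true * decoy_rate / (1 - decoy_rate), so decoys make up
#' \code{decoy_rate} of the set in expectation. Links carry only the
#' residue pair (no distances) plus a synthetic FDR: true links
#' U[0, 0.01], decoys U[0, 0.05]. With \code{noise_sd > 0} the selection
#' of true pairs uses jittered distances, admitting occasional mild
#' violators.
#'
#' @param model \code{xl_structure} with anchors (see
#'   \code{\link{anchor_sites}}).
#' @param n_true number of true links.
#' @param decoy_rate expected decoy fraction of the final set, in [0, 1).
#' @param noise_sd distance jitter, Angstrom (default 0).
#' @param cutoff,margin Angstrom; true links lie within cutoff - margin,
#'   decoys beyond cutoff + margin.
#' @param seed integer seed.
#' @param min_seq_sep minimum |i - j| for same-chain pairs, so trivial
#'   neighbours are not sampled.
#' @param pair_scope \code{"all"} anchor pairs, or restrict to
#'   \code{"inter"}- or \code{"intra"}-chain pairs (a docking benchmark
#'   uses inter-chain links, since only those constrain the relative
#'   pose).
#' @return \code{xl_set} with attribute \code{truth} (data.frame with
#'   \code{is_decoy} and \code{true_distance}).
#' @export
simulate_crosslinks <- function(model, n_true = 20, decoy_rate = 0,
                                noise_sd = 0, cutoff = 30, margin = 2,
                                seed = 1, min_seq_sep = 5,
                                pair_scope = c("all", "inter", "intra")) {
  pair_scope <- match.arg(pair_scope)
  stopifnot(decoy_rate >= 0, decoy_rate < 1, n_true >= 1)
  set.seed(as.integer(seed))
  anc <- anchor_sites(model)
  if (nrow(anc) < 2) stop("model has fewer than 2 anchor sites")
  ca <- ca_coords(model)
  addr <- attr(ca, "address")
  ai <- match(paste(anc$chain, anc$resno), paste(addr$chain, addr$resno))
  pos <- ca[ai, , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, nrow(anc), nrow(anc))), arr.ind = TRUE)
  same <- anc$chain[pairs[, 1]] == anc$chain[pairs[, 2]]
  sep <- abs(anc$resno[pairs[, 1]] - anc$resno[pairs[, 2]])
  keep <- !(same & sep < min_seq_sep)
  if (pair_scope == "inter") keep <- keep & !same
  if (pair_scope == "intra") keep <- keep & same
  pairs <- pairs[keep, , drop = FALSE]
  d <- sqrt(rowSums((pos[pairs[, 1], , drop = FALSE] -
                     pos[pairs[, 2], , drop = FALSE])^2))
  d_sel <- d + if (noise_sd > 0) stats::rnorm(length(d), 0, noise_sd) else 0
  true_pool <- which(d_sel <= cutoff - margin)
  decoy_pool <- which(d > cutoff + margin)
  if (length(true_pool) < n_true)
    stop("only ", length(true_pool), " candidate pairs within ",
         cutoff - margin, " A; need ", n_true)
  pick_true <- sample(true_pool, n_true)
  n_decoy <- if (decoy_rate > 0)
    stats::rbinom(1, n_true, decoy_rate / (1 - decoy_rate)) else 0L
  n_decoy <- min(n_decoy, length(decoy_pool))
  pick_decoy <- if (n_decoy > 0) sample(decoy_pool, n_decoy) else integer(0)
  sel <- c(pick_true, pick_decoy)
  is_decoy <- c(rep(FALSE, n_true), rep(TRUE, n_decoy))
  links <- data.frame(
    protein1 = anc$chain[pairs[sel, 1]],
    residue1 = anc$resno[pairs[sel, 1]],
    protein2 = anc$chain[pairs[sel, 2]],
    residue2 = anc$resno[pairs[sel, 2]],
    fdr = ifelse(is_decoy, stats::runif(length(sel), 0, 0.05),
                 stats::runif(length(sel), 0, 0.01)),
    spectra = 1L + stats::rbinom(length(sel), 5, 0.3),
    stringsAsFactors = FALSE)
  xl <- parse_crosslinks(links, fdr_threshold = 0.05)
  # parse_crosslinks keeps first-occurrence order, so truth rows align
  attr(xl, "truth") <- data.frame(is_decoy = is_decoy,
                                  true_distance = d[sel])
  xl$provenance <- sprintf(
    "simulated: n_true=%d decoy_rate=%g noise_sd=%g cutoff=%g margin=%g seed=%d scope=%s",
    n_true, decoy_rate, noise_sd, cutoff, margin, seed, pair_scope)
  xl
}

#' Apply a random rigid perturbation to named chains
#'
#' Draws a rotation of angle U[0, max_rot_deg] about a uniform random
#' axis through the moved chains' CA centroid, plus a translation
#' uniform in the ball of radius \code{max_trans}; applies it and
#' returns both the perturbed model and the transform (so the inverse
#' restores the input to numerical precision).
#'
#' @param model \code{xl_structure}.
#' @param chains chains to move.
#' @param max_rot_deg maximum rotation angle, degrees.
#' @param max_trans maximum translation, Angstrom.
#' @param seed integer seed.
#' @return list: \code{model} (perturbed), \code{transform}
#'   (\code{rigid_transform} that was applied, in absolute coordinates).
#' @export
perturb_pose <- function(model, chains, max_rot_deg = 180,
                         max_trans = 30, seed = 1) {
  missing_ch <- setdiff(chains, unique(model$atoms$chain))
  if (length(missing_ch))
    stop("unknown chain(s): ", paste(missing_ch, collapse = ", "))
  set.seed(as.integer(seed))
  cc <- colMeans(ca_coords(model, chains = chains))
  if (max_rot_deg > 0) {
    R <- rotation_about_axis(stats::rnorm(3),
                             stats::runif(1, 0, max_rot_deg))
  } else R <- diag(3)
  t_vec <- c(0, 0, 0)
  if (max_trans > 0) {
    repeat {
      t_vec <- stats::runif(3, -max_trans, max_trans)
      if (sum(t_vec^2) <= max_trans^2) break
    }
  }
  tf <- rigid_transform(R, cc - as.numeric(R %*% cc) + t_vec)
  list(model = apply_transform(model, tf, chains = chains),
       transform = tf)
}
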
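# Crosslink-restraint rigid-body docking: flat-bottom quadratic distance
# restraints plus a CA-CA clash penalty, optimised by simulated annealing
# with greedy coordinate-descent refinement over the 6 rigid degrees of
# freedom.

#' Restraint scoring parameters
#'
#' The score of a pose is
#' sum over links of max(0, d - cutoff)^2 * violation_weight
#' + n_clashes * clash_weight,
#' where d is the CA-CA distance of a crosslink and a clash is a CA pair
#' between the fixed and mobile bodies closer than \code{clash_distance}.
#' The flat bottom encodes that a crosslink constrains only an upper
#' distance bound.
#'
#' @param cutoff satisfaction cutoff, Angstrom (default 30, BS3 CA-CA).
#' @param violation_weight per-A^2 penalty above the cutoff.
#' @param clash_distance CA-CA clash threshold, Angstrom (default 3.0).
#' @param clash_weight penalty per clashing pair.
#' @param unmappable_policy \code{"count"} (report unmappable links) or
#'   \code{"ignore"}.
#' @return list of class \code{score_params}.
#' @export
score_params <- function(cutoff = 30.0, violation_weight = 1.0,
                         clash_distance = 3.0, clash_weight = 10.0,
                         unmappable_policy = c("count", "ignore")) {
  unmappable_policy <- match.arg(unmappable_policy)
  stopifnot(violation_weight >= 0, clash_weight >= 0,
            cutoff > clash_distance)
  structure(list(cutoff = cutoff, violation_weight = violation_weight,
                 clash_distance = clash_distance,
                 clash_weight = clash_weight,
                 unmappable_policy = unmappable_policy),
            class = "score_params")
}

# Precompute everything the inner scoring loop needs: CA matrices for both
# bodies and, per usable inter-body link, the candidate CA row indices on
# each side (several candidates when a homodimer leaves the chain copy
# ambiguous; the scorer takes the shortest combination per pose).
.dock_context <- function(fixed_model, mobile_model, xl, cmap, params) {
  fca <- ca_coords(fixed_model)
  mca <- ca_coords(mobile_model)
  fad <- attr(fca, "address"); mad <- attr(mca, "address")
  fkey <- paste(fad$chain, fad$resno)
  mkey <- paste(mad$chain, mad$resno)
  if (is.null(xl$links$kind)) {
    l <- xl$links
  } else l <- xl$links
  fidx <- list(); midx <- list()
  n_unmappable <- 0L
  for (i in seq_len(nrow(l))) {
    ma <- map_residue(cmap, l$protein_a[i], l$residue_a[i])
    mb <- map_residue(cmap, l$protein_b[i], l$residue_b[i])
    a_f <- match(paste(ma$chain, ma$resno), fkey)
    a_m <- match(paste(ma$chain, ma$resno), mkey)
    b_f <- match(paste(mb$chain, mb$resno), fkey)
    b_m <- match(paste(mb$chain, mb$resno), mkey)
    a_f <- a_f[!is.na(a_f)]; a_m <- a_m[!is.na(a_m)]
    b_f <- b_f[!is.na(b_f)]; b_m <- b_m[!is.na(b_m)]
    if (length(a_f) && length(b_m)) {
      fidx <- c(fidx, list(a_f)); midx <- c(midx, list(b_m))
    } else if (length(b_f) && length(a_m)) {
      fidx <- c(fidx, list(b_f)); midx <- c(midx, list(a_m))
    } else {
      n_unmappable <- n_unmappable + 1L
    }
  }
  if (length(fidx) == 0L)
    stop("no usable inter-unit links between the fixed and mobile bodies")
  simple <- vapply(fidx, length, 1L) == 1L &
    vapply(midx, length, 1L) == 1L
  list(fca = fca, mca = mca,
       fi = unlist(fidx[simple]), mi = unlist(midx[simple]),
       amb_f = fidx[!simple], amb_m = midx[!simple],
       n_links = length(fidx), n_unmappable = n_unmappable)
}

# Link distances and clash count for transformed mobile CA coordinates.
.ctx_eval <- function(ctx, M, params) {
  d <- numeric(0)
  if (length(ctx$fi)) {
    dx <- ctx$fca[ctx$fi, 1] - M[ctx$mi, 1]
    dy <- ctx$fca[ctx$fi, 2] - M[ctx$mi, 2]
    dz <- ctx$fca[ctx$fi, 3] - M[ctx$mi, 3]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  if (length(ctx$amb_f)) {
    for (k in seq_along(ctx$amb_f)) {
      F <- ctx$fca[ctx$amb_f[[k]], , drop = FALSE]
      Mm <- M[ctx$amb_m[[k]], , drop = FALSE]
      d2 <- outer(rowSums(F^2), rowSums(Mm^2), "+") - 2 * F %*% t(Mm)
      d <- c(d, sqrt(max(0, min(d2))))
    }
  }
  cross2 <- outer(rowSums(ctx$fca^2), rowSums(M^2), "+") -
    2 * ctx$fca %*% t(M)
  n_clash <- sum(cross2 < params$clash_distance^2)
  excess <- pmax(0, d - params$cutoff)
  list(score = sum(excess^2) * params$violation_weight +
         n_clash * params$clash_weight,
       d = d, n_clash = n_clash)
}

#' Score a rigid pose of a mobile body against a fixed scaffold
#'
#' @param fixed_model,mobile_model \code{xl_structure}s; crosslink ends
#'   are resolved to whichever body carries the mapped chain.
#' @param transform \code{rigid_transform} applied to the mobile body.
#' @param xl \code{xl_set}; at least one link must join the two bodies.
#' @param cmap \code{xl_chainmap}.
#' @param params \code{score_params}.
#' @return list: \code{score}, \code{n_satisfied}, \code{n_violated},
#'   \code{n_clashes}, \code{n_unmappable}.
#' @export
restraint_score <- function(fixed_model, mobile_model, transform, xl,
                            cmap, params = score_params()) {
  ctx <- .dock_context(fixed_model, mobile_model, xl, cmap, params)
  M <- transform_coords(ctx$mca, transform)
  ev <- .ctx_eval(ctx, M, params)
  list(score = ev$score,
       n_satisfied = sum(ev$d <= params$cutoff),
       n_violated = sum(ev$d > params$cutoff),
       n_clashes = ev$n_clash,
       n_unmappable = if (params$unmappable_policy == "count")
         ctx$n_unmappable else NA_integer_)
}

# One restart: random initial pose, simulated annealing, then greedy
# coordinate descent. Returns transform + evaluation.
.dock_one <- function(ctx, params, sa_steps, anchor_centre, shell_max) {
  R0 <- random_rotation()
  c0 <- colMeans(ctx$mca)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rad <- stats::runif(1, 0, shell_max)
  target <- anchor_centre + dir * rad
  t0 <- target - as.numeric(R0 %*% c0)
  tf <- rigid_transform(R0, t0)
  M <- transform_coords(ctx$mca, tf)
  ev <- .ctx_eval(ctx, M, params)

  T0 <- max(ev$score / 5, 10)
  Tend <- 0.01
  alpha <- (Tend / T0)^(1 / max(1, sa_steps))
  Temp <- T0
  rot0 <- 25; trans0 <- 10
  for (step in seq_len(sa_steps)) {
    s <- 0.05 + 0.95 * (1 - step / sa_steps)
    cc <- colMeans(M)
    Rp <- rotation_about_axis(stats::rnorm(3), stats::rnorm(1) * rot0 * s)
    dt <- stats::rnorm(3) * trans0 * s
    Mn <- sweep(M, 2, cc) %*% t(Rp)
    Mn[, 1] <- Mn[, 1] + cc[1] + dt[1]
    Mn[, 2] <- Mn[, 2] + cc[2] + dt[2]
    Mn[, 3] <- Mn[, 3] + cc[3] + dt[3]
    evn <- .ctx_eval(ctx, Mn, params)
    if (evn$score <= ev$score ||
        stats::runif(1) < exp((ev$score - evn$score) / Temp)) {
      step_tf <- rigid_transform(Rp, cc - as.numeric(Rp %*% cc) + dt)
      tf <- compose_transform(step_tf, tf)
      M <- Mn; ev <- evn
    }
    Temp <- Temp * alpha
  }

  # greedy coordinate descent to local convergence
  rot_step <- 4; trans_step <- 2
  axes <- diag(3)
  repeat {
    improved <- FALSE
    cc <- colMeans(M)
    for (k in 1:3) for (sg in c(1, -1)) {
      Rp <- rotation_about_axis(axes[, k], sg * rot_step)
      Mn <- sweep(M, 2, cc) %*% t(Rp)
      Mn <- sweep(Mn, 2, cc, "+")
      evn <- .ctx_eval(ctx, Mn, params)
      if (evn$score < ev$score - 1e-9) {
        tf <- compose_transform(
          rigid_transform(Rp, cc - as.numeric(Rp %*% cc)), tf)
        M <- Mn; ev <- evn; improved <- TRUE
      }
    }
    for (k in 1:3) for (sg in c(1, -1)) {
      dt <- axes[, k] * sg * trans_step
      Mn <- sweep(M, 2, dt, "+")
      evn <- .ctx_eval(ctx, Mn, params)
      if (evn$score < ev$score - 1e-9) {
        tf <- compose_transform(rigid_transform(diag(3), dt), tf)
        M <- Mn; ev <- evn; improved <- TRUE
      }
    }
    if (!improved) {
      rot_step <- rot_step / 2; trans_step <- trans_step / 2
      if (trans_step < 1e-3) break
    }
    if (ev$score < 1e-12 && !improved) break
  }
  list(tf = tf, ev = ev, M = M)
}

#' Rigid-body docking under crosslink restraints
#'
#' Multi-start stochastic search: each restart draws a uniform random
#' rotation (quaternion method) and places the mobile centroid uniformly
#' in a sphere around the centroid of the fixed body's crosslink anchors,
#' then refines by simulated annealing over the 6 rigid degrees of
#' freedom (geometric cooling) followed by greedy coordinate descent to
#' local convergence. Converged poses within 2 A pairwise CA RMSD are
#' merged (best kept) and the survivors ranked by score, ties by restart
#' seed. The whole procedure is reproducible from \code{seed}.
#'
#' @param fixed_model,mobile_model \code{xl_structure}s.
#' @param xl \code{xl_set} with at least one link joining the bodies.
#' @param cmap \code{xl_chainmap}.
#' @param params \code{score_params}.
#' @param n_restarts number of independent starts (>= 1).
#' @param seed integer master seed.
#' @param sa_steps annealing steps per restart.
#' @param shell_max radius of the initial-placement sphere, Angstrom;
#'   default 1.5 x cutoff.
#' @param dedup_rmsd pose-merge threshold, Angstrom CA RMSD.
#' @return object of class \code{dock_results}: \code{results}
#'   (data.frame rank, restart, seed, score, n_satisfied, n_violated,
#'   n_clashes), \code{transforms} (list of \code{rigid_transform}, one
#'   per row), \code{n_unmappable}.
#' @export
dock_rigid <- function(fixed_model, mobile_model, xl, cmap,
                       params = score_params(), n_restarts = 50,
                       seed = 1, sa_steps = 400, shell_max = NULL,
                       dedup_rmsd = 2.0) {
  stopifnot(n_restarts >= 1)
  ctx <- .dock_context(fixed_model, mobile_model, xl, cmap, params)
  anchor_rows <- unique(c(ctx$fi, unlist(ctx$amb_f)))
  anchor_centre <- colMeans(ctx$fca[anchor_rows, , drop = FALSE])
  if (is.null(shell_max)) shell_max <- 1.5 * params$cutoff

  fits <- vector("list", n_restarts)
  seeds <- integer(n_restarts)
  for (r in seq_len(n_restarts)) {
    rs <- (as.integer(seed) + r * 10007L) %% .Machine$integer.max
    seeds[r] <- rs
    set.seed(rs)
    fits[[r]] <- .dock_one(ctx, params, sa_steps, anchor_centre,
                           shell_max)
  }
  scores <- vapply(fits, function(f) f$ev$score, 1)

  # dedup: greedy by ascending (score, seed); a pose joins an earlier
  # cluster when within dedup_rmsd CA RMSD of its representative
  ord <- order(scores, seeds)
  keep <- integer(0)
  for (r in ord) {
    dup <- FALSE
    for (k in keep) {
      if (coord_rmsd(fits[[r]]$M, fits[[k]]$M) < dedup_rmsd) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep <- c(keep, r)
  }
  res <- data.frame(
    rank = seq_along(keep), restart = keep, seed = seeds[keep],
    score = scores[keep],
    n_satisfied = vapply(fits[keep], function(f)
      sum(f$ev$d <= params$cutoff), 1L),
    n_violated = vapply(fits[keep], function(f)
      sum(f$ev$d > params$cutoff), 1L),
    n_clashes = vapply(fits[keep], function(f) f$ev$n_clash, 1L))
  structure(list(results = res,
                 transforms = lapply(fits[keep], `[[`, "tf"),
                 n_unmappable = ctx$n_unmappable,
                 params = params, master_seed = seed),
            class = "dock_results")
}

#' @export
print.dock_results <- function(x, ...) {
  cat(sprintf("<dock_results> %d distinct pose(s); best score %.4g (%d/%d links satisfied, %d clashes)\n",
              nrow(x$results), x$results$score[1],
              x$results$n_satisfied[1],
              x$results$n_satisfied[1] + x$results$n_violated[1],
              x$results$n_clashes[1]))
  invisible(x)
}

#' Rank candidate assembly models by crosslink restraint score
#'
#' Scores each complete candidate model in place (identity transform):
#' flat-bottom violation penalties over all mappable links plus the
#' inter-chain clash penalty, sorted ascending (ties by input order).
#' A per-candidate violated-link report supports "all crosslinks
#' accounted for, except ..." style accounting.
#'
#' @param candidates named list of \code{xl_structure}s.
#' @param xl \code{xl_set}.
#' @param cmap \code{xl_chainmap}.
#' @param params \code{score_params}.
#' @return list of class \code{model_ranking}: \code{table} (data.frame
#'   rank, model, score, n_satisfied, n_violated, n_unmappable,
#'   n_clashes), \code{violated} (named list of violated-link
#'   data.frames).
#' @export
rank_models <- function(candidates, xl, cmap, params = score_params()) {
  stopifnot(length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model_", seq_along(candidates))
  rows <- NULL
  violated <- list()
  for (nm in names(candidates)) {
    m <- candidates[[nm]]
    ld <- link_distances(m, xl, cmap, cutoff = params$cutoff)
    if (!any(ld$mappable))
      stop("candidate '", nm, "' maps none of the linked chains")
    dd <- ld$distance[ld$mappable]
    n_clash <- .interchain_clashes(m, params$clash_distance)
    score <- sum(pmax(0, dd - params$cutoff)^2) *
      params$violation_weight + n_clash * params$clash_weight
    rows <- rbind(rows, data.frame(
      model = nm, score = score,
      n_satisfied = sum(ld$satisfied, na.rm = TRUE),
      n_violated = sum(!ld$satisfied, na.rm = TRUE),
      n_unmappable = sum(!ld$mappable), n_clashes = n_clash,
      stringsAsFactors = FALSE))
    violated[[nm]] <- ld[ld$mappable & !ld$satisfied, , drop = FALSE]
  }
  ord <- order(rows$score)
  rows <- rows[ord, , drop = FALSE]
  rows <- cbind(rank = seq_len(nrow(rows)), rows)
  rownames(rows) <- NULL
  structure(list(table = rows, violated = violated[rows$model]),
            class = "model_ranking")
}

.interchain_clashes <- function(model, clash_distance) {
  ca <- ca_coords(model)
  ch <- attr(ca, "address")$chain
  n_clash <- 0L
  chains <- unique(ch)
  if (length(chains) < 2) return(0L)
  for (i in seq_along(chains)[-length(chains)]) {
    A <- ca[ch == chains[i], , drop = FALSE]
    for (j in seq((i + 1), length(chains))) {
      B <- ca[ch == chains[j], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      n_clash <- n_clash + sum(d2 < clash_distance^2)
    }
  }
  n_clash
}

#' @export
print.model_ranking <- function(x, ...) {
  print(x$table)
  invisible(x)
}
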
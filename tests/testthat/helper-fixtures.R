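# Shared fixture builders: all inputs are generated in code at test time.

# One fixed-width PDB v3.3 ATOM line.
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z,
                     occ = 1, b = 0, elem = "C") {
  sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, if (nchar(name) >= 4) name else sprintf(" %-3s", name),
          alt, resn, chain, resno, x, y, z, occ, b, elem)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Minimal in-memory model from a compact spec: one row per atom.
toy_model <- function(chain, resno, elety = "CA", resid = "ALA",
                      x = 0, y = 0, z = 0, elesy = NULL) {
  structure_model(data.frame(chain = chain, resno = resno, insert = "",
                             resid = resid, elety = elety,
                             elesy = if (is.null(elesy))
                               substr(elety, 1, 1) else elesy,
                             x = x, y = y, z = z, o = 1, b = 0,
                             stringsAsFactors = FALSE))
}

# Identity chain map over all chains of a model (protein name = chain id).
toy_chain_map <- function(model) synthetic_chain_map(model)

# Brute-force minimum RMSD over a dense Euler-angle rotation grid
# (translation solved exactly by centroid matching per rotation).
grid_min_rmsd <- function(mobile, ref, step_deg = 10) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(ref, 2, colMeans(ref))
  best <- Inf
  ang <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  ang_b <- seq(0, 180, by = step_deg) * pi / 180
  for (a in ang) for (b in ang_b) for (g in ang) {
    Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
    Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
    R <- Rz2 %*% Ry %*% Rz1
    r <- sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
    if (r < best) best <- r
  }
  best
}

# Exposed area of two overlapping spheres (radii include the probe),
# by the spherical-cap formula.
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(c(4 * pi * R1^2, 4 * pi * R2^2))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  c(4 * pi * R1^2 - 2 * pi * R1 * max(0, h1),
    4 * pi * R2^2 - 2 * pi * R2 * max(0, h2))
}

# Benchmark assembly used across docking tests: compact mobile body at
# the channel of a solenoid scaffold (the package's study conditions).
benchmark_assembly <- function(seed) {
  generate_assembly(2, c(120, 30), fold = c("solenoid", "helix_hairpin"),
                    seed = seed, spacing = 0)
}

# One full recovery replicate; returns mobile-body CA RMSD of the
# best-ranked pose to ground truth, plus diagnostics.
recovery_replicate <- function(rep, n_true = 10, decoy_rate = 0,
                               n_restarts = 50) {
  m <- benchmark_assembly(1000 + rep)
  cmap <- synthetic_chain_map(m)
  xl <- simulate_crosslinks(m, n_true = n_true, decoy_rate = decoy_rate,
                            cutoff = 30, margin = 2, seed = 2000 + rep,
                            pair_scope = "inter")
  pert <- perturb_pose(m, "B", 180, 30, seed = 3000 + rep)
  fixed <- subset_structure(pert$model,
                            select_atoms(pert$model, chains = "A"))
  mobile <- subset_structure(pert$model,
                             select_atoms(pert$model, chains = "B"))
  dk <- dock_rigid(fixed, mobile, xl, cmap, n_restarts = n_restarts,
                   seed = 4000 + rep)
  best <- apply_transform(mobile, dk$transforms[[1]])
  list(rmsd = coord_rmsd(ca_coords(best), ca_coords(m, chains = "B")),
       score = dk$results$score[1],
       truth_transform = invert_transform(pert$transform),
       fixed = fixed, mobile = mobile, xl = xl, cmap = cmap,
       assembly = m, dock = dk)
}
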
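test_that("rigid transforms validate, compose, and invert", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")

  a <- rigid_transform(rotation_about_axis(c(1, 1, 0), 40), c(1, 2, 3))
  b <- rigid_transform(rotation_about_axis(c(0, 1, 2), -70), c(-4, 0, 9))
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(transform_coords(x, compose_transform(a, b)),
               transform_coords(transform_coords(x, b), a),
               tolerance = 1e-12)
  expect_equal(transform_coords(transform_coords(x, a),
                                invert_transform(a)), x,
               tolerance = 1e-12)
})

test_that("kabsch superposition recovers exact and known-transform cases", {
  set.seed(42)
  p <- matrix(rnorm(30, sd = 8), 10, 3)

  s0 <- kabsch_superpose(p, p)
  expect_equal(s0$rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(s0$n_atoms, 10)

  tf <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(3, -1, 7))
  q <- transform_coords(p, tf)
  s <- kabsch_superpose(p, q)       # recovers the applied transform
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$transform$rotation, tf$rotation, tolerance = 1e-9)
  expect_equal(s$transform$translation, tf$translation, tolerance = 1e-9)
  s_inv <- kabsch_superpose(q, p)   # and its inverse the other way
  expect_equal(s_inv$transform$rotation,
               invert_transform(tf)$rotation, tolerance = 1e-9)

  expect_error(kabsch_superpose(p[1:4, ], p), "length")
  expect_error(kabsch_superpose(p[1:2, ], p[1:2, ]), "at least 3")
})

test_that("kabsch equals the brute-force rotation-grid oracle on 4-point toys", {
  for (seed in c(1, 2)) {
    set.seed(seed)
    mobile <- matrix(rnorm(12, sd = 4), 4, 3)
    ref <- matrix(rnorm(12, sd = 4), 4, 3)
    kab <- kabsch_superpose(mobile, ref)$rmsd
    grid <- grid_min_rmsd(mobile, ref, step_deg = 10)
    expect_lte(kab, grid + 1e-9)
    # grid can miss the optimum by at most the grid resolution:
    # a <= ~9 degree rotation error over points of this size
    max_r <- max(sqrt(rowSums(sweep(mobile, 2, colMeans(mobile))^2)))
    expect_lte(grid - kab, 2 * sin(9 * pi / 360) * max_r)
  }
})

test_that("RMSD is symmetric and invariant under joint rigid motion", {
  for (seed in 1:3) {
    set.seed(seed)
    a <- matrix(rnorm(24, sd = 5), 8, 3)
    b <- a + matrix(rnorm(24, sd = 1), 8, 3)
    r_ab <- kabsch_superpose(a, b)$rmsd
    expect_equal(kabsch_superpose(b, a)$rmsd, r_ab, tolerance = 1e-9)
    g <- rigid_transform(rotation_about_axis(rnorm(3), 120), rnorm(3))
    expect_equal(kabsch_superpose(transform_coords(a, g),
                                  transform_coords(b, g))$rmsd,
                 r_ab, tolerance = 1e-9)
    # independent cross-check against bio3d's least-squares fit
    # (bio3d rounds its RMSD to 3 decimals)
    expect_equal(r_ab,
                 bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)),
                             fit = TRUE),
                 tolerance = 1e-3)
  }
})

test_that("common-CA pairing over shared construct ranges gives 2 x 67 = 134", {
  helix <- function(resno, chain, shift = 0) {
    toy_model(chain = rep(chain, length(resno)), resno = resno,
              x = 2.3 * cos(resno * 100 * pi / 180) + shift,
              y = 2.3 * sin(resno * 100 * pi / 180), z = 1.5 * resno)
  }
  two_chain <- function(lo, hi) {
    a <- helix(lo:hi, "A")
    b <- helix(lo:hi, "B", shift = 10)
    structure_model(rbind(a$atoms, b$atoms))
  }
  crystal <- two_chain(150, 241)
  cryoem <- two_chain(171, 237)
  p <- pair_common_ca(crystal, cryoem, c(A = "A", B = "B"))
  expect_equal(nrow(p$pairing), 134)
  expect_equal(nrow(p$coords_a), 134)
  expect_equal(as.vector(table(p$pairing$chain_a)), c(67L, 67L))

  expect_error(pair_common_ca(two_chain(1, 50), two_chain(60, 100),
                              c(A = "A", B = "B")), "no common")

  # deleting one CA shrinks the pairing by one
  drop1 <- subset_structure(crystal,
                            setdiff(seq_len(nrow(crystal$atoms)), 40))
  expect_equal(nrow(pair_common_ca(drop1, cryoem,
                                   c(A = "A", B = "B"))$pairing), 133)
})

test_that("homodimer superposition tries both chain assignments", {
  m <- generate_assembly(2, 30, seed = 5, spacing = 9)
  # a model with chains relabelled in swapped order
  sw <- m
  sw$atoms$chain <- ifelse(sw$atoms$chain == "A", "B", "A")
  sw$atoms <- sw$atoms[order(sw$atoms$chain, sw$atoms$resno), ]
  s <- superpose_models(sw, m, c(A = "A", B = "B"), try_swap = TRUE)
  expect_true(s$swapped)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  s_no <- superpose_models(sw, m, c(A = "A", B = "B"), try_swap = FALSE)
  expect_gt(s_no$rmsd, 1)
})

test_that("principal dimensions recover a cuboid under arbitrary rotation", {
  g <- as.matrix(expand.grid(x = seq(0, 10, 2), y = seq(0, 4, 2),
                             z = seq(0, 2, 2)))
  expect_equal(principal_dimensions(g), c(10, 4, 2), tolerance = 1e-9)

  set.seed(8)
  tf <- rigid_transform(rotation_about_axis(rnorm(3), 77), c(30, -4, 12))
  expect_equal(principal_dimensions(transform_coords(g, tf)),
               c(10, 4, 2), tolerance = 1e-6)

  # monotone non-decreasing when a point is added outside the extent
  g2 <- rbind(g, c(15, 2, 1))
  expect_true(all(principal_dimensions(g2) >=
                    principal_dimensions(g) - 1e-9))
})

test_that("bend angle reads ~0 for a straight helix and ~30 for a bent one", {
  m <- generate_assembly(1, 60, fold = "helix", seed = 2)
  # whole-turn windows (18 residues = 5 full turns at 100 deg/residue)
  # so the window principal axis coincides with the helix axis
  win_n <- 5:22
  win_c <- 39:56
  expect_lt(bend_angle(m, "A", win_n, win_c), 2)
  expect_lt(bend_angle(m, "A", win_n, win_n), 1e-3)

  # bend the C-terminal half by 30 degrees about the residue-30 CA
  bent <- m
  hinge <- as.numeric(m$atoms[m$atoms$resno == 30, c("x", "y", "z")])
  idx <- which(bent$atoms$resno > 30)
  R <- rotation_about_axis(c(1, 0, 0), 30)
  xyz <- as.matrix(bent$atoms[idx, c("x", "y", "z")])
  bent$atoms[idx, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, hinge) %*% t(R), 2, hinge, "+")
  ang <- bend_angle(bent, "A", win_n, win_c)
  expect_equal(ang, 30, tolerance = 3)

  expect_error(bend_angle(m, "A", 1:3, win_c), "need >= 7")
})
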
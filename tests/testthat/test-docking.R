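# Tiny two-body closed-form scenario: fixed anchors on chain A, one
# mobile anchor on chain B, distances controlled exactly.
closed_form_setup <- function(zb) {
  m <- toy_model(chain = c("A", "A", "B"), resno = c(7, 14, 7),
                 resid = "LYS", z = c(0, 5, zb))
  list(fixed = subset_structure(m, select_atoms(m, chains = "A")),
       mobile = subset_structure(m, select_atoms(m, chains = "B")),
       cmap = toy_chain_map(m),
       xl = parse_crosslinks(data.frame(
         protein1 = "A", residue1 = 7L, protein2 = "B", residue2 = 7L)))
}

test_that("restraint score matches the flat-bottom closed form", {
  s <- closed_form_setup(zb = 20)     # 20 A link, within cutoff
  r <- restraint_score(s$fixed, s$mobile, rigid_transform(), s$xl,
                       s$cmap, score_params(cutoff = 30))
  expect_equal(r$score, 0)
  expect_equal(r$n_satisfied, 1)

  s2 <- closed_form_setup(zb = 32)    # cutoff + 2, weight 1 -> penalty 4
  r2 <- restraint_score(s2$fixed, s2$mobile, rigid_transform(), s2$xl,
                        s2$cmap,
                        score_params(cutoff = 30, violation_weight = 1,
                                     clash_weight = 0))
  expect_equal(r2$score, 4.0, tolerance = 1e-9)
  expect_equal(r2$n_violated, 1)

  s3 <- closed_form_setup(zb = 2)     # within clash distance of A res 7
  r3 <- restraint_score(s3$fixed, s3$mobile, rigid_transform(), s3$xl,
                        s3$cmap,
                        score_params(clash_distance = 3,
                                     clash_weight = 10))
  expect_equal(r3$score, 10)
  expect_equal(r3$n_clashes, 1)

  # no usable inter-body link is an error
  bad <- parse_crosslinks(data.frame(protein1 = "A", residue1 = 7L,
                                     protein2 = "A", residue2 = 14L))
  expect_error(restraint_score(s$fixed, s$mobile, rigid_transform(),
                               bad, s$cmap), "inter-unit")
})

test_that("score parameters enforce their invariants", {
  expect_error(score_params(violation_weight = -1))
  expect_error(score_params(cutoff = 2, clash_distance = 3))
})

test_that("the score is frame independent", {
  rr <- recovery_replicate(1, n_restarts = 1)
  tf <- rr$truth_transform
  base <- restraint_score(rr$fixed, rr$mobile, tf, rr$xl, rr$cmap)

  g <- rigid_transform(rotation_about_axis(c(2, -1, 1), 133),
                       c(40, -7, 15))
  moved_fixed <- apply_transform(rr$fixed, g)
  r2 <- restraint_score(moved_fixed, rr$mobile, compose_transform(g, tf),
                        rr$xl, rr$cmap)
  expect_equal(r2$score, base$score, tolerance = 1e-9)
  expect_equal(r2$n_satisfied, base$n_satisfied)
  expect_equal(r2$n_clashes, base$n_clashes)
})

test_that("noiseless ground truth scores zero and degrades monotonically outward", {
  rr <- recovery_replicate(2, n_restarts = 1)
  truth <- restraint_score(rr$fixed, rr$mobile, rr$truth_transform,
                           rr$xl, rr$cmap)
  expect_identical(truth$score, 0)
  expect_equal(truth$n_violated, 0)

  # translating away along a ray: scores non-decreasing past the plateau
  set.seed(3)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  scores <- vapply(c(0, 20, 35, 50, 80), function(t) {
    shift <- rigid_transform(diag(3), u * t)
    restraint_score(rr$fixed, rr$mobile,
                    compose_transform(shift, rr$truth_transform),
                    rr$xl, rr$cmap,
                    score_params(clash_weight = 0))$score
  }, 1)
  expect_identical(scores[1], 0)
  expect_gt(scores[3], 0)            # 35 A off: beyond any slack
  expect_true(all(diff(scores[2:5]) >= 0))
})

test_that("docking is bit-reproducible from the seed", {
  rr <- recovery_replicate(3, n_restarts = 4)
  d1 <- dock_rigid(rr$fixed, rr$mobile, rr$xl, rr$cmap,
                   n_restarts = 4, seed = 99)
  d2 <- dock_rigid(rr$fixed, rr$mobile, rr$xl, rr$cmap,
                   n_restarts = 4, seed = 99)
  expect_identical(d1$results, d2$results)
  expect_identical(d1$transforms, d2$transforms)

  d3 <- dock_rigid(rr$fixed, rr$mobile, rr$xl, rr$cmap,
                   n_restarts = 4, seed = 100)
  expect_false(identical(d1$transforms, d3$transforms))

  # ranks are a permutation ordered by score
  expect_identical(d1$results$rank, seq_len(nrow(d1$results)))
  expect_true(!is.unsorted(d1$results$score))
})

test_that("a restart seeded at a feasible pose keeps score zero", {
  rr <- recovery_replicate(4, n_restarts = 1)
  # evaluate the converged pose: it must lie on the zero plateau
  expect_identical(rr$score, 0)
  got <- restraint_score(rr$fixed, rr$mobile, rr$dock$transforms[[1]],
                         rr$xl, rr$cmap)
  expect_identical(got$score, 0)
})

test_that("candidate ranking orders models by restraint satisfaction", {
  m <- benchmark_assembly(21)
  cmap <- synthetic_chain_map(m)
  xl <- simulate_crosslinks(m, n_true = 10, seed = 22,
                            pair_scope = "inter")

  solo <- rank_models(list(truth = m), xl, cmap)
  expect_equal(solo$table$rank, 1)
  expect_equal(solo$table$score, 0)

  # a decoy pose displaced far beyond any slack ranks below the truth
  decoy <- apply_transform(m, rigid_transform(diag(3), c(50, 0, 0)),
                           chains = "B")
  r <- rank_models(list(decoy = decoy, truth = m), xl, cmap)
  expect_equal(r$table$model[1], "truth")
  expect_equal(nrow(r$violated$truth), 0)
  expect_gt(r$table$score[r$table$model == "decoy"], 0)

  # with decoy links spiked in, the truth model's violated set is
  # exactly the decoys
  xl_spiked <- simulate_crosslinks(m, n_true = 10, decoy_rate = 0.3,
                                   seed = 23, pair_scope = "inter")
  truth_flag <- attr(xl_spiked, "truth")$is_decoy
  rs <- rank_models(list(truth = m), xl_spiked, cmap)
  expect_equal(nrow(rs$violated$truth), sum(truth_flag))
})
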
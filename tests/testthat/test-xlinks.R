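make_links_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("# simulated identifications",
               "protein1,residue1,protein2,residue2,fdr,spectra", rows),
             path)
  path
}

test_that("FDR filtering and unordered deduplication behave as specified", {
  path <- make_links_csv(c("P1,10,P2,20,0.01,3",
                           "P1,30,P2,40,0.08,1",
                           "P2,20,P1,10,0.002,5"))
  expect_message(xl <- parse_crosslinks(path, fdr_threshold = 0.05),
                 "dropped")
  expect_equal(nrow(xl$links), 1)        # one row filtered, two merged
  expect_equal(xl$n_dropped_fdr, 1)
  # merged pair keeps min fdr and max spectra, first-seen orientation
  expect_equal(xl$links$fdr, 0.002)
  expect_equal(xl$links$spectra, 5L)
  expect_equal(xl$links$protein_a, "P1")

  # inclusive boundary: fdr == threshold retained
  path2 <- make_links_csv("P1,1,P2,2,0.05,1")
  expect_equal(nrow(parse_crosslinks(path2, 0.05)$links), 1)

  incomplete <- tempfile(fileext = ".csv")
  writeLines(c("protein1,residue1,protein2", "P1,1,P2"), incomplete)
  expect_error(parse_crosslinks(incomplete), "missing columns")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("protein1,residue1,protein2,residue2", "P1,x,P2,2"), bad)
  expect_error(parse_crosslinks(bad), "non-integer")
})

test_that("deduplication is idempotent through a write/parse cycle", {
  path <- make_links_csv(c("P1,10,P2,20,0.01,3", "P2,20,P1,10,0.002,5",
                           "P1,7,P1,70,0.03,2"))
  xl <- parse_crosslinks(path)
  out <- tempfile(fileext = ".csv")
  write_crosslinks(xl, out)
  xl2 <- parse_crosslinks(out)
  expect_equal(xl2$links, xl$links)
})

test_that("classification assigns kind by protein and conserves link counts", {
  m <- toy_model(chain = c("A", "A", "B"), resno = c(155, 192, 10),
                 x = c(0, 5, 20))
  cmap <- chain_map(data.frame(
    protein = c("WTAP", "VIRMA", "METTL3"), chain = c("A", "B", "M"),
    offset = 0L, first = c(150L, 1L, 1L), last = c(237L, 100L, 580L)))
  tbl <- data.frame(protein1 = c("WTAP", "METTL3", "METTL3"),
                    residue1 = c(192L, 576L, 13L),
                    protein2 = c("WTAP", "VIRMA", "WTAP"),
                    residue2 = c(155L, 10L, 192L))
  xl <- classify_links(parse_crosslinks(tbl), cmap)
  expect_equal(xl$links$kind,
               c("intra_subunit", "inter_subunit", "inter_subunit"))
  # METTL3 maps to chain M which has no atoms -- but the chain map alone
  # decides mapping; link 3 is unmapped only if the map lacks the residue
  expect_equal(xl$links$status[1], "mapped")
  expect_equal(sum(xl$counts[c("n_inter", "n_intra")]) +
                 xl$counts[["n_unmapped"]], xl$counts[["n_total"]])

  # a residue outside every mapped range flags the link unmapped
  tbl2 <- data.frame(protein1 = "WTAP", residue1 = 400L,
                     protein2 = "WTAP", residue2 = 155L)
  xl2 <- classify_links(parse_crosslinks(tbl2), cmap)
  expect_equal(xl2$links$status, "unmapped")
  expect_equal(nrow(xl2$links), 1)  # flagged, never dropped
})

test_that("link distances are Euclidean CA-CA with inclusive cutoff", {
  m <- toy_model(chain = c("A", "B", "B"), resno = c(1, 1, 2),
                 x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 10, 30))
  cmap <- toy_chain_map(m)
  tbl <- data.frame(protein1 = c("A", "A"), residue1 = c(1L, 1L),
                    protein2 = c("B", "B"), residue2 = c(1L, 2L))
  ld <- link_distances(m, parse_crosslinks(tbl), cmap, cutoff = 30)
  expect_equal(ld$distance, c(10, 30))
  expect_true(all(ld$satisfied))        # boundary d == cutoff satisfied
  ld2 <- link_distances(m, parse_crosslinks(tbl), cmap, cutoff = 29.999)
  expect_equal(ld2$satisfied, c(TRUE, FALSE))
})

test_that("homodimer ambiguity resolves to the shorter distance", {
  # protein W maps to chains A and B; B's copy of residue 5 is closer
  m <- toy_model(chain = c("A", "B", "C"), resno = c(5, 5, 9),
                 x = c(50, 8, 0))
  cmap <- chain_map(data.frame(protein = c("W", "W", "C"),
                               chain = c("A", "B", "C"), offset = 0L,
                               first = 1L, last = 10L))
  tbl <- data.frame(protein1 = "W", residue1 = 5L,
                    protein2 = "C", residue2 = 9L)
  ld <- link_distances(m, parse_crosslinks(tbl), cmap)
  expect_equal(ld$chain_a, "B")
  expect_equal(ld$distance, 8)
})

test_that("residue mapped without a CA atom is unmappable, not an error", {
  m <- structure_model(data.frame(
    chain = c("A", "B"), resno = c(1, 1), insert = "",
    resid = "ALA", elety = c("CA", "N"), elesy = c("C", "N"),
    x = c(0, 5), y = 0, z = 0, o = 1, b = 0))
  cmap <- toy_chain_map(m)
  tbl <- data.frame(protein1 = "A", residue1 = 1L,
                    protein2 = "B", residue2 = 1L)
  ld <- link_distances(m, parse_crosslinks(tbl), cmap)
  expect_false(ld$mappable)
  expect_error(satisfaction_fraction(ld), "no mappable")
})

test_that("distances are invariant under joint rigid motion but not one-body motion", {
  m <- generate_assembly(2, c(40, 30), seed = 11, spacing = 8)
  cmap <- synthetic_chain_map(m)
  xl <- simulate_crosslinks(m, n_true = 12, seed = 5)
  d0 <- link_distances(m, xl, cmap)$distance

  tf <- rigid_transform(rotation_about_axis(c(1, 2, 3), 35), c(4, -7, 2))
  d_joint <- link_distances(apply_transform(m, tf), xl, cmap)$distance
  expect_equal(d_joint, d0, tolerance = 1e-9)

  d_one <- link_distances(apply_transform(m, tf, chains = "B"), xl,
                          cmap)$distance
  kinds <- link_distances(m, xl, cmap)$kind
  expect_equal(d_one[kinds == "intra_subunit"],
               d0[kinds == "intra_subunit"], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(d_one[kinds == "inter_subunit"],
                                d0[kinds == "inter_subunit"])))
})

test_that("satisfaction fraction counts and per-kind breakdown are correct", {
  z <- c(seq(2, 20, length.out = 8), 40, 50)      # 8 within 30, 2 beyond
  m <- toy_model(chain = c("A", rep("B", 10)), resno = c(1, 1:10),
                 z = c(0, z))
  cmap <- toy_chain_map(m)
  tbl <- data.frame(protein1 = "A", residue1 = 1L,
                    protein2 = "B", residue2 = 1:10)
  s <- satisfaction_fraction(link_distances(m, parse_crosslinks(tbl),
                                            cmap, cutoff = 30))
  expect_equal(s$fraction, 0.8)
  expect_equal(s$n_satisfied, 8)
  expect_equal(s$n_violated, 2)
  expect_equal(s$by_kind$kind, "inter_subunit")
})
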
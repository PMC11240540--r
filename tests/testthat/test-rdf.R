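test_that("annulus machinery matches the brute-force double loop", {
  set.seed(91)
  for (i in 1:6) {
    pat <- random_pattern(sample(3:12, 1), sample(20:80, 1))
    for (norm in c("csr", "pooled", "area")) {
      got <- rdf(pat, "pos", annulus_width = 10, r_max = 120,
                 normalization = norm)
      want <- rdf_oracle(pat, "pos", 10, 120, norm)
      expect_equal(got$g, as.numeric(want), tolerance = 1e-12)
    }
  }
})

test_that("hand-placed toy pattern gives hand-computed annulus ratios", {
  # 2 stroma pixels, 6 cells at engineered distances from the first pixel
  pat <- point_pattern(
    c(200, 200),
    data.frame(x_um = c(50, 150), y_um = c(50, 150)),
    data.frame(x_um = c(53, 58, 62, 70, 50, 150),
               y_um = c(50, 50, 50, 50, 62, 158),
               marker = c("pos", "neg", "pos", "pos", "neg", "pos")))
  got <- rdf(pat, "pos", annulus_width = 5, r_max = 30,
             normalization = "csr")
  want <- rdf_oracle(pat, "pos", 5, 30, "csr")
  expect_equal(got$g, as.numeric(want), tolerance = 1e-12)
  # distances from stroma 1: 3, 8, 12, 20, 12 -> annuli 1, 2, 3, 4, 3
  # stroma 2: cell 6 at distance 8 -> annulus 2 (marker pos)
  # annulus 1: pixel1 1/1 pos; pixel2 none -> mean ratio .5 * (6/4)
  expect_equal(got$g[1], 0.5 * 1 * 6 / 4)
  # annulus 2: pixel1 0/1; pixel2 1/1 -> mean .5 * 6/4
  expect_equal(got$g[2], 0.5 * 6 / 4)
})

test_that("all-positive labels give flat pooled curves and degenerate envelopes", {
  set.seed(92)
  pat <- random_pattern(10, 60, p_pos = 1.1)  # all pos
  expect_true(all(pat$cells$marker == "pos"))
  g <- rdf(pat, "pos", normalization = "pooled", r_max = 100)
  expect_true(all(g$g[!is.na(g$g)] == 1))
  env <- csr_envelope(pat, "pos", n_shuffles = 5, r_max = 100,
                      normalization = "pooled")
  ok <- !is.na(env$g)
  expect_equal(env$csr_lo[ok], env$csr_hi[ok])
  expect_true(all(abs(env$g[ok] - 1) < 1e-12))
})

test_that("label_shuffle preserves counts, positions, and is uniform", {
  set.seed(93)
  pat <- random_pattern(5, 40)
  sh <- label_shuffle(pat)
  expect_equal(sum(sh$cells$marker == "pos"), sum(pat$cells$marker == "pos"))
  expect_equal(sh$cells$x_um, pat$cells$x_um)
  expect_identical(sh$stroma, pat$stroma)
  # all-identical labels: shuffling is a no-op
  pat1 <- pat; pat1$cells$marker <- "neg"
  expect_identical(label_shuffle(pat1)$cells, pat1$cells)
  # 3 cells, one positive: the positive lands on each cell 1/3 of the time
  pat3 <- point_pattern(c(10, 10),
                        data.frame(x_um = 5, y_um = 5),
                        data.frame(x_um = 1:3, y_um = 1:3,
                                   marker = c("pos", "neg", "neg")))
  hits <- table(replicate(3000, which(label_shuffle(pat3)$cells$marker == "pos")))
  expect_gt(stats::chisq.test(hits)$p.value, 1e-4)
})

test_that("csr_envelope orders bounds and a single shuffle collapses them", {
  set.seed(94)
  pat <- random_pattern(15, 80)
  env <- csr_envelope(pat, "pos", n_shuffles = 19, r_max = 100)
  ok <- !is.na(env$csr_mean)
  expect_true(all(env$csr_lo[ok] <= env$csr_mean[ok] + 1e-12))
  expect_true(all(env$csr_mean[ok] <= env$csr_hi[ok] + 1e-12))
  env1 <- csr_envelope(pat, "pos", n_shuffles = 1, r_max = 100)
  expect_equal(env1$csr_lo, env1$csr_hi)
  expect_equal(env1$csr_lo, env1$csr_mean)
})

test_that("shuffled pooled curves average to 1 pointwise", {
  set.seed(95)
  pat <- random_pattern(20, 150)
  env <- csr_envelope(pat, "pos", n_shuffles = 500, r_max = 100,
                      normalization = "pooled")
  mid <- 5:20  # radii with stable counts
  expect_true(all(abs(env$csr_mean[mid] - 1) < 0.05))
})

test_that("gmax reads off the maximum with ties toward small radii", {
  res <- peristroma:::.new_rdf_result(c(1, 1, 1), 5, "pos", "csr")
  gm <- gmax(res)
  expect_equal(gm$g_max, 1)
  expect_equal(gm$r_at_max_um, 2.5)
  res2 <- peristroma:::.new_rdf_result(c(0.8, 2, 1.1), 5, "pos", "csr")
  gm2 <- gmax(res2)
  expect_equal(gm2$g_max, 2)
  expect_equal(gm2$r_at_max_um, 7.5)
  expect_equal(gm2$r_at_max_cells, 0.5)
})

test_that("rdf input contracts are enforced", {
  set.seed(96)
  pat <- random_pattern(5, 20)
  no_stroma <- point_pattern(pat$window, pat$stroma[0, ], pat$cells)
  expect_error(rdf(no_stroma, "pos"), "no stroma")
  allneg <- pat; allneg$cells$marker <- "neg"
  expect_error(rdf(allneg, "pos"), "no cells")
  expect_error(rdf(pat, "pos", annulus_width = 5, r_max = 2), "annulus width")
  empty_cells <- point_pattern(pat$window, pat$stroma, pat$cells[0, ])
  expect_error(label_shuffle(empty_cells), "no cells")
})

test_that("point patterns round-trip through the CSV exchange format", {
  set.seed(97)
  pat <- random_pattern(8, 25)
  f <- tempfile(fileext = ".csv")
  write_point_table(pat, f)
  pat2 <- read_point_table(f, window = pat$window)
  expect_equal(pat2$stroma$x_um, pat$stroma$x_um)
  expect_equal(pat2$cells$marker, pat$cells$marker)
  unlink(f)
})
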
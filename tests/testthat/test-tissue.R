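test_that("tissue_grid validates state codes and geometry", {
  expect_error(tissue_grid(matrix(7L, 3, 3)), "unknown state")
  expect_error(tissue_grid(matrix(0L, 2, 2), cell_size = 0), "positive")
  g <- tissue_grid(matrix(0L, 3, 4))
  expect_identical(dim(g), c(3L, 4L))
  expect_equal(g$cell_size, 15)
})

test_that("label masks round-trip through PNG and TIFF", {
  set.seed(71)
  st <- matrix(sample(0:3, 400, replace = TRUE, prob = c(.5, .3, .15, .05)),
               20, 20)
  g <- tissue_grid(st)
  for (ext in c("png", "tif")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_mask(g, f)
    g2 <- load_mask(f)
    expect_identical(g2$state, g$state)
    unlink(f)
  }
})

test_that("load_mask handles empty and single-pixel masks and bad codes", {
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 100, 100), f)
  g <- load_mask(f)
  expect_equal(sum(g$state != STATE[["empty"]]), 0)
  m <- matrix(0, 3, 3); m[2, 2] <- 2 / 255
  png::writePNG(m, f)
  g <- load_mask(f)
  expect_identical(which(g$state == STATE[["stroma"]]),
                   which(matrix(c(F, F, F, F, T, F, F, F, F), 3, 3)))
  png::writePNG(matrix(9 / 255, 2, 2), f)
  expect_error(load_mask(f), "unknown label code")
  unlink(f)
  expect_error(load_mask("no/such/file.png"), "not found")
})

test_that("synthetic masks reload identically from disk", {
  set.seed(72)
  g <- gen_stroma_topology(0.12, n_seeds = 10, side = 30)
  f <- tempfile(fileext = ".png")
  write_mask(g, f)
  expect_identical(load_mask(f)$state, g$state)
  unlink(f)
})

test_that("point-table masks place stroma and cells on the lattice", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    x_um = c(22.5, 7.5, 40), y_um = c(22.5, 7.5, 40),
    type = c("stroma", "cell", "cell"),
    marker = c(NA, "pos", "neg")), f, row.names = FALSE)
  g <- load_mask(f, window = c(45, 45))
  expect_equal(sum(g$state == STATE[["stroma"]]), 1)
  expect_equal(sum(g$state == STATE[["tumor"]]), 2)
  expect_equal(g$state[2, 2], STATE[["stroma"]])
  unlink(f)
})

test_that("pixelate_stroma matches brute-force tiling on random masks", {
  brute <- function(mask, px, tile, thr) {
    k <- tile / px
    out <- NULL
    for (ty in seq_len(nrow(mask) %/% k)) for (tx in seq_len(ncol(mask) %/% k)) {
      block <- mask[((ty - 1) * k + 1):(ty * k), ((tx - 1) * k + 1):(tx * k)]
      if (mean(block) >= thr)
        out <- rbind(out, c((tx - 0.5) * tile, (ty - 0.5) * tile))
    }
    out
  }
  set.seed(73)
  for (i in 1:5) {
    mask <- matrix(runif(45 * 60) < 0.4, 45, 60)
    got <- pixelate_stroma(mask, px_size_um = 5, tile_um = 15)
    want <- brute(mask, 5, 15, 0.5)
    expect_equal(nrow(got), NROW(want))
    if (NROW(want)) {
      got <- got[order(got$y_um, got$x_um), ]
      ord <- order(want[, 2], want[, 1])
      expect_equal(got$x_um, want[ord, 1])
      expect_equal(got$y_um, want[ord, 2])
    }
  }
})

test_that("pixelate_stroma trivial and error cases", {
  expect_equal(nrow(pixelate_stroma(matrix(FALSE, 30, 30))), 0)
  one <- matrix(FALSE, 15, 15); one[1:15, 1:15] <- TRUE
  got <- pixelate_stroma(one)
  expect_equal(unlist(got), c(x_um = 7.5, y_um = 7.5))
  expect_error(pixelate_stroma(matrix(TRUE, 4, 4), tile_um = 15),
               "tile larger")
})

test_that("niche map enumerates the chebyshev and euclidean neighborhoods", {
  st <- matrix(STATE[["empty"]], 9, 9); st[5, 5] <- STATE[["stroma"]]
  g <- tissue_grid(st)
  expect_equal(sum(compute_niche_map(g, 3, "chebyshev")$inside), 48)
  expect_equal(sum(compute_niche_map(g, 3, "euclidean")$inside), 28)
  expect_equal(sum(compute_niche_map(g, 0)$inside), 0)
  # clipping at borders
  st2 <- matrix(STATE[["empty"]], 4, 4); st2[1, 1] <- STATE[["stroma"]]
  expect_equal(sum(compute_niche_map(tissue_grid(st2), 3)$inside), 15)
})

test_that("niche grows monotonically with distance and ignores inactive stroma", {
  g <- fixture("topo_small")
  prev <- compute_niche_map(g, 0)$inside
  for (d in 1:4) {
    cur <- compute_niche_map(g, d)$inside
    expect_true(all(cur[prev]))
    prev <- cur
  }
  g2 <- deactivate_stroma(g, 1)
  expect_equal(sum(compute_niche_map(g2, 3)$inside), 0)
  empty <- tissue_grid(matrix(STATE[["empty"]], 5, 5))
  expect_equal(sum(compute_niche_map(empty, 3)$inside), 0)
})

test_that("extract_quadrant cuts aligned windows and preserves counts", {
  set.seed(74)
  st <- matrix(sample(c(0L, 2L), 200 * 100, TRUE, c(.9, .1)), 100, 200)
  g <- tissue_grid(st)
  full <- extract_quadrant(g, c(0, 0), 1500)
  expect_identical(full$state, st[, 1:100])
  right <- extract_quadrant(g, c(1500, 0), 1500)
  expect_identical(right$state, st[, 101:200])
  # counting oracle: abundance equals direct counts over the source window
  m <- stroma_metrics(right)
  expect_equal(m[["abundance"]], sum(st[, 101:200] == 2L) / 10000)
  expect_error(extract_quadrant(g, c(1515, 0), 1500), "outside")
  expect_error(extract_quadrant(g, c(10, 0), 1500), "align")
})

test_that("stroma_metrics matches hand-enumerated cases", {
  empty <- tissue_grid(matrix(STATE[["empty"]], 10, 10))
  expect_equal(stroma_metrics(empty), c(abundance = 0, dispersal = 0))
  one <- matrix(STATE[["empty"]], 100, 100); one[40, 40] <- STATE[["stroma"]]
  expect_equal(stroma_metrics(tissue_grid(one)),
               c(abundance = 1e-4, dispersal = 1))
  # solid 10x10 interior block: boundary = 36 perimeter sites of 100
  blk <- matrix(STATE[["empty"]], 30, 30)
  blk[11:20, 11:20] <- STATE[["stroma"]]
  expect_equal(stroma_metrics(tissue_grid(blk)),
               c(abundance = 100 / 900, dispersal = 36 / 100))
})

test_that("abundance is invariant under flips; excluded sites leave the denominator", {
  g <- fixture("topo_small")
  m <- stroma_metrics(g)
  flipped <- tissue_grid(g$state[nrow(g$state):1, ], g$cell_size)
  expect_equal(stroma_metrics(flipped), m)
  st <- g$state
  idx <- which(st == STATE[["empty"]])[1:50]
  st[idx] <- STATE[["excluded"]]
  m2 <- stroma_metrics(tissue_grid(st))
  n_str <- sum(st == STATE[["stroma"]])
  expect_equal(m2[["abundance"]], n_str / (length(st) - 50))
})
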
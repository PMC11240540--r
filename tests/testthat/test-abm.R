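empty_niche <- function(grid) compute_niche_map(grid, 0)

test_that("a tumor-free grid is a fixed point with zero events", {
  g <- tissue_grid(matrix(STATE[["empty"]], 10, 10))
  res <- abm_step(g, empty_niche(g), abm_params(), "baseline")
  expect_identical(res$grid$state, g$state)
  expect_equal(unname(res$events), c(0L, 0L, 0L))
})

test_that("certain death without division empties the grid in one step", {
  g <- single_cell_grid(5)
  p <- abm_params(p_div_base = 0, p_die_base = 1, p_move = 0)
  set.seed(101)
  res <- abm_step(g, empty_niche(g), p, "baseline")
  expect_equal(sum(res$grid$state == STATE[["tumor"]]), 0)
  expect_equal(res$events[["deaths"]], 1L)
})

test_that("a certain division places the daughter uniformly over the Moore neighborhood", {
  g <- single_cell_grid(5)
  p <- abm_params(p_div_base = 1, p_die_base = 0, p_move = 0)
  nm <- empty_niche(g)
  set.seed(102)
  landed <- replicate(2000, {
    st <- abm_step(g, nm, p, "baseline")$grid$state
    which(st == STATE[["tumor"]] & single_cell_grid(5)$state != STATE[["tumor"]])
  })
  expect_equal(length(unique(landed)), 8L)
  expect_gt(stats::chisq.test(table(landed))$p.value, 1e-4)
  # population exactly doubles
  set.seed(103)
  res <- abm_step(g, nm, p, "baseline")
  expect_equal(sum(res$grid$state == STATE[["tumor"]]), 2)
})

test_that("sparse populations follow the branching expectation N(1 + p - d)", {
  set.seed(104)
  st <- matrix(STATE[["empty"]], 25, 25)
  st[sample.int(625, 6)] <- STATE[["tumor"]]
  g <- tissue_grid(st)
  p <- abm_params(p_div_base = 0.2, p_die_base = 0.1, p_move = 0.3)
  nm <- empty_niche(g)
  n1 <- replicate(1000, sum(abm_step(g, nm, p, "baseline")$grid$state ==
                              STATE[["tumor"]]))
  expected <- 6 * (1 + 0.2 - 0.1)
  se <- sd(n1) / sqrt(length(n1))
  expect_lt(abs(mean(n1) - expected), 3 * se)
})

test_that("trajectories are deterministic given the seed and balance their books", {
  g <- fixture("topo_small")
  p <- abm_params(steps_baseline = 60, steps_therapy = 40, n_reps = 1)
  r1 <- run_abm(g, p, seed = 42)
  r2 <- run_abm(g, p, seed = 42)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_grid$state, r2$final_grid$state)
  tr <- r1$trajectory
  expect_equal(diff(tr$n_tumor), (tr$divisions - tr$deaths)[-1])
  expect_true(all(tr$n_tumor >= 0))
})

test_that("stroma and excluded sites are immutable under simulation", {
  set.seed(105)
  g <- fixture("topo_small")
  st <- g$state
  st[which(st == STATE[["empty"]])[1:20]] <- STATE[["excluded"]]
  g <- tissue_grid(st, g$cell_size)
  run <- run_abm(g, abm_params(steps_baseline = 80, steps_therapy = 60),
                 seed = 1)
  fixed <- st %in% c(STATE[["stroma"]], STATE[["stroma_inactive"]],
                     STATE[["excluded"]])
  expect_identical(run$final_grid$state[fixed], st[fixed])
})

test_that("baseline-only runs settle into a drift-free equilibrium", {
  g <- fixture("topo_small")
  p <- abm_params(steps_baseline = 250, steps_therapy = 0)
  run <- run_abm(g, p, seed = 7)
  late <- tail(run$trajectory$n_tumor, 50)
  drift <- abs(coef(lm(log(late) ~ seq_along(late)))[2])
  expect_lt(drift, 0.01)
  expect_equal(run$final_n, tail(run$trajectory$n_tumor, 1))
})

test_that("realized division rate approaches p_div when space is unconstrained", {
  set.seed(106)
  st <- matrix(STATE[["empty"]], 60, 60)
  st[sample.int(3600, 20)] <- STATE[["tumor"]]
  g <- tissue_grid(st)
  p <- abm_params(p_div_base = 0.1, p_die_base = 0.1, p_move = 0.2,
                  steps_baseline = 40, steps_therapy = 0,
                  seed_occupancy = NA)
  rates <- replicate(60, run_abm(g, p)$realized$baseline[["division"]])
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.1), 3 * se)
})

test_that("deactivate_stroma samples the requested fraction exactly", {
  st <- matrix(STATE[["empty"]], 10, 10)
  st[sample.int(100, 10)] <- STATE[["stroma"]]
  g <- tissue_grid(st)
  expect_identical(deactivate_stroma(g, 0)$state, g$state)
  g1 <- deactivate_stroma(g, 1)
  expect_equal(sum(g1$state == STATE[["stroma_inactive"]]), 10)
  expect_equal(sum(compute_niche_map(g1, 3)$inside), 0)
  set.seed(107)
  g5 <- deactivate_stroma(g, 0.5)
  expect_equal(sum(g5$state == STATE[["stroma_inactive"]]), 5)
  expect_equal(sum(g5$state == STATE[["stroma"]]), 5)
  expect_error(deactivate_stroma(g, 1.5), "\\[0, 1\\]")
})

test_that("abm_params validates probability and geometry ranges", {
  expect_error(abm_params(p_div_base = 1.2), "\\[0, 1\\]")
  expect_error(abm_params(niche_distance = -1), "non-negative")
  expect_error(abm_params(seed_occupancy = 2), "seed_occupancy")
})

test_that("calibration reproduces its targets on a fresh verification run", {
  g <- fixture("topo_small")
  set.seed(108)
  p <- calibrate_abm(g, p_move = 0.5, refine = FALSE, seed = 108)
  expect_equal(p$p_die_base, 0.62)
  expect_gt(p$p_div_base, 0.62)
  expect_equal(p$p_div_therapy_out, 0.026)
  expect_equal(p$p_die_therapy, 0.026 + 1 - exp(-0.113), tolerance = 1e-9)
  # realized baseline division rate at equilibrium matches the target
  pv <- abm_params(p_div_base = p$p_div_base, p_die_base = p$p_die_base,
                   p_move = 0.5, steps_baseline = 200, steps_therapy = 0)
  run <- run_abm(g, pv, seed = 9)
  tr <- run$trajectory
  rows <- which(tr$step >= 101)
  rate <- sum(tr$divisions[rows]) / sum(tr$n_tumor[rows - 1])
  expect_lt(abs(rate - 0.62), 0.05)
})
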
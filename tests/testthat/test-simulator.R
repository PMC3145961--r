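test_that("segregate keeps or replaces parental histones as specified", {
  f <- new_fiber(20)
  set.seed(1)
  expect_equal(as.logical(segregate(f, 1)$fiber), rep(TRUE, 20))
  expect_equal(segregate(f, 1)$retained, rep(TRUE, 20))
  expect_equal(as.logical(segregate(f, 0)$fiber), rep(FALSE, 20))

  set.seed(2)
  big <- segregate(new_fiber(10000), 0.5)
  # binomial: 5000 +/- 3 * sqrt(10000 * 0.25) = 5000 +/- 150
  expect_lt(abs(sum(as.logical(big$fiber)) - 5000), 150)
})

test_that("draw_stalls mixes random and fixed-site stalling", {
  p0 <- sim_params(n_nucleosomes = 100, p_stall_random = 0)
  set.seed(3)
  expect_length(draw_stalls(p0), 0L)

  pf <- sim_params(n_nucleosomes = 100, p_stall_random = 0,
                   fixed_site = 50, p_stall_fixed = 1)
  expect_equal(draw_stalls(pf), 50L)

  pr <- sim_params(n_nucleosomes = 10000, p_stall_random = 0.025)
  set.seed(4)
  # 250 +/- 3 * sqrt(10000 * 0.025 * 0.975) ~ 250 +/- 47
  expect_lt(abs(length(draw_stalls(pr)) - 250), 47)
})

test_that("apply_gaps clears deterministic tracts and truncates at ends", {
  f <- new_fiber(30)
  g5 <- gap_spec(5, 0)
  set.seed(5)
  res <- apply_gaps(f, 11L, g5, anchor = "downstream")
  expect_equal(which(!as.logical(res$fiber)), 11:15)
  expect_equal(unname(res$gap_intervals[1, ]), c(11L, 15L))

  res_c <- apply_gaps(f, 11L, g5, anchor = "center")
  expect_equal(which(!as.logical(res_c$fiber)), 9:13)

  # truncation: stall 2 positions from the end clears only what fits
  res_t <- apply_gaps(f, 29L, g5, anchor = "downstream")
  expect_equal(which(!as.logical(res_t$fiber)), 29:30)

  expect_equal(as.logical(apply_gaps(f, integer(0), g5)$fiber),
               rep(TRUE, 30))
  expect_error(apply_gaps(f, 31L, g5), "within the fiber")

  # overlapping gaps are unioned
  res_u <- apply_gaps(f, c(10L, 12L), g5, anchor = "downstream")
  expect_equal(which(!as.logical(res_u$fiber)), 10:16)
})

test_that("restore_marks follows the one/two-place copy rule synchronously", {
  f <- as_fiber(c(TRUE, FALSE, FALSE, FALSE, TRUE))
  set.seed(6)
  expect_equal(as.logical(restore_marks(f, 1, 0)),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(as.logical(restore_marks(as_fiber(c(TRUE, FALSE, FALSE)), 1, 1)),
               c(TRUE, TRUE, TRUE))
  expect_equal(as.logical(restore_marks(f, 0, 0)), as.logical(f))
})

test_that("restore_marks never removes a mark", {
  set.seed(7)
  for (i in 1:20) {
    states <- stats::runif(30) < 0.5
    out <- restore_marks(as_fiber(states), stats::runif(1), stats::runif(1))
    expect_true(all(as.logical(out)[states]))
  }
})

test_that("step_generation composes the update with its fixed points", {
  pars <- sim_params(n_nucleosomes = 50, p_retain = 1, p_stall_random = 0,
                     p_copy1 = 0.7, p_copy2 = 0.3)
  f <- new_fiber(50)
  set.seed(8)
  expect_equal(as.logical(step_generation(f, pars)$fiber), rep(TRUE, 50))

  det <- sim_params(n_nucleosomes = 50, p_retain = 1, p_stall_random = 0,
                    fixed_site = 25, p_stall_fixed = 1,
                    gap = gap_spec(5, 0), p_copy1 = 0, p_copy2 = 0)
  out <- step_generation(f, det)
  expect_equal(which(!as.logical(out$fiber)), 23:27)
  expect_equal(max_unmarked_run(out$fiber, 25), 5L)
  expect_equal(nrow(out$events$gap_intervals), 1L)
})

test_that("one-generation loss agrees with a naive reimplementation", {
  pars <- sim_params(n_nucleosomes = 100, p_stall_random = 0.025,
                     gap = gap_spec(5, 0), seed = 10)
  reps <- 200
  mine <- run_trajectory(sim_params(n_nucleosomes = 100,
                                    p_stall_random = 0.025,
                                    gap = gap_spec(5, 0),
                                    generations = 1, replicates = reps,
                                    seed = 10))
  loss_mine <- 1 - mine$frac_marked[, 1]
  loss_naive <- naive_final_loss(pars, reps, gens = 1, n = 100, seed = 77)
  se <- sqrt(stats::var(loss_mine) / reps + stats::var(loss_naive) / reps)
  expect_lt(abs(mean(loss_mine) - mean(loss_naive)), 3 * se)
})

test_that("multi-generation loss agrees with the naive oracle", {
  pars <- sim_params(n_nucleosomes = 100, p_stall_random = 0.01,
                     gap = gap_spec(6, 0))
  reps <- 200
  mine <- run_trajectory(sim_params(n_nucleosomes = 100,
                                    p_stall_random = 0.01,
                                    gap = gap_spec(6, 0),
                                    generations = 10, replicates = reps,
                                    seed = 21))
  loss_mine <- 1 - mine$frac_marked[, 10]
  loss_naive <- naive_final_loss(pars, reps, gens = 10, n = 100, seed = 42)
  se <- sqrt(stats::var(loss_mine) / reps + stats::var(loss_naive) / reps)
  expect_lt(abs(mean(loss_mine) - mean(loss_naive)), 3 * se)
})

test_that("trajectories replay bit-identically under a fixed seed", {
  pars <- sim_params(n_nucleosomes = 120, p_stall_random = 0.01,
                     fixed_site = 60, p_stall_fixed = 0.3,
                     replicates = 5, generations = 10, seed = 33)
  a <- run_trajectory(pars)
  b <- run_trajectory(pars)
  expect_identical(a$frac_marked, b$frac_marked)
  expect_identical(a$lost_tract, b$lost_tract)
  c <- run_trajectory(sim_params(n_nucleosomes = 120,
                                 p_stall_random = 0.01, fixed_site = 60,
                                 p_stall_fixed = 0.3, replicates = 5,
                                 generations = 10, seed = 34))
  expect_false(identical(a$frac_marked, c$frac_marked))
})

test_that("marks are maintained without stalling", {
  tr <- run_trajectory(sim_params(n_nucleosomes = 200, replicates = 10,
                                  generations = 30, seed = 5))
  expect_gt(mean(tr$frac_marked[, 30]), 0.9)
})

test_that("a deterministic recurrent stall keeps the tract at gap length", {
  pars <- sim_params(n_nucleosomes = 100, p_retain = 1, p_stall_random = 0,
                     fixed_site = 50, p_stall_fixed = 1,
                     gap = gap_spec(5, 0), p_copy1 = 0, p_copy2 = 0,
                     replicates = 1, generations = 10, seed = 2)
  tr <- run_trajectory(pars)
  expect_equal(as.vector(tr$lost_tract), rep(5, 10))
})

test_that("an isolated gap heals two nucleosomes per generation", {
  pars <- sim_params(n_nucleosomes = 60, p_retain = 1, p_stall_random = 0,
                     p_copy1 = 1, p_copy2 = 0)
  f <- as_fiber(c(rep(TRUE, 20), rep(FALSE, 10), rep(TRUE, 30)))
  set.seed(3)
  for (expected in c(8, 6, 4, 2, 0, 0)) {
    f <- step_generation(f, pars)$fiber
    expect_equal(max_unmarked_run(f, 25), expected)
  }
})

test_that("final loss increases with stall probability and gap length", {
  base <- function(p, g) sim_params(n_nucleosomes = 300,
                                    p_stall_random = p,
                                    gap = gap_spec(g, 0),
                                    replicates = 30, seed = 9)
  loss <- function(p, g) {
    tr <- run_trajectory(base(p, g))
    1 - mean(tr$frac_marked[, 30])
  }
  l_low <- loss(0.002, 10)
  l_mid <- loss(0.01, 10)
  l_high <- loss(0.05, 10)
  expect_lte(l_low, l_mid + 0.03)
  expect_lte(l_mid, l_high + 0.03)
  expect_lte(loss(0.01, 4), loss(0.01, 12) + 0.03)
})

test_that("stall_interval_kb converts probability to genomic interval", {
  expect_equal(stall_interval_kb(0.025, 200), 8.0)
  expect_equal(stall_interval_kb(1.0, 200), 0.2)
  expect_equal(stall_interval_kb(200 / 60000, 200), 60)
  expect_error(stall_interval_kb(0, 200), "\\(0, 1\\]")
})

test_that("the gap sweep returns the smallest qualifying mean gap", {
  base <- sim_params(n_nucleosomes = 200, replicates = 10, seed = 14)
  # an isolated one- or two-nucleosome gap heals within its own
  # generation (each cleared position keeps a marked distance-1
  # template across a flank), so only wider gaps sustain loss
  res <- sweep_gap_for_loss(8, 0.005, base, gap_cap = 10)
  expect_true(res$attained)
  expect_equal(res$min_gap, 3L)
  expect_lt(res$losses[1], 0.001)
  expect_equal(res$p_stall, 0.025)

  # unattainable targets are reported, not thrown
  res2 <- sweep_gap_for_loss(5000, 0.95, base, gap_cap = 3)
  expect_false(res2$attained)
  expect_true(is.na(res2$min_gap))
})

test_that("the fixed-site sweep hits its deterministic limits", {
  base <- sim_params(n_nucleosomes = 100, replicates = 5, generations = 10,
                     fixed_site = 50, seed = 15)
  tab0 <- sweep_fixed_stall(0, c(4L, 6L), base)
  expect_equal(unname(tab0[, 1]), c(0, 0))

  base_nc <- sim_params(n_nucleosomes = 100, replicates = 5,
                        generations = 10, fixed_site = 50,
                        p_copy1 = 0, p_copy2 = 0, p_retain = 1, seed = 15)
  tab1 <- sweep_fixed_stall(1, c(4L, 6L), base_nc)
  expect_equal(unname(tab1[, 1]), c(4, 6))
})
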
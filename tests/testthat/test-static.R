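test_that("branch activation requires the pulse to reach threshold from rest", {
  expect_true(check_branch_activation(1, 1.08, 0.04))
  expect_true(check_branch_activation(1, 1.04, 0.04))  # boundary: equality
  expect_false(check_branch_activation(1, 1.00, 0.04))
})

test_that("target-weight bounds form the half-open admissible interval", {
  b <- target_weight_bounds(0.04, 3)
  expect_equal(unname(b), c(1.04 / 3, 1.04 / 2))
  expect_equal(unname(target_weight_bounds(0, 3)), c(1 / 3, 1 / 2))
  expect_equal(unname(target_weight_bounds(0.04, 2)), c(0.52, 1.04))
  expect_error(target_weight_bounds(0.04, 1), ">= 2")
})

test_that("simultaneity offsets cancel the latency differences", {
  expect_equal(unname(simultaneity_offsets(c(1.08, 1.08, 1.08))), c(0, 0))
  off <- simultaneity_offsets(c(1.08, 1.1, 1.08))
  expect_equal(unname(off), c(12.5 - 10, 0))
  expect_error(simultaneity_offsets(c(1.08, 0.9, 1.2)), "exceed 1")
})

test_that("sequences built from the offsets reach the target synchronously and fire it", {
  w <- c(1.08, 1.13, 1.06)
  for (t0 in c(5, 8.7)) {
    fit <- mnsd(NULL, n_branches = 3, branch_weights = w)
    times <- t0 + c(0, simultaneity_offsets(w))
    res <- mnsd_detect(fit, times)
    expect_lt(diff(range(res$out_times)), 1e-6)
    expect_true(res$detected)
  }
})

test_that("the target fires on synchronous arrivals iff its weight is admissible", {
  w <- rep(1.08, 3)
  times <- c(5, 5, 5)
  b <- target_weight_bounds(0.04, 3)
  for (tw in c(b[["lower"]] + 1e-9, mean(b), b[["upper"]] - 1e-6)) {
    fit <- mnsd(NULL, n_branches = 3, branch_weights = w, target_weight = tw)
    expect_true(mnsd_detect(fit, times)$detected)
  }
  fit <- mnsd(NULL, n_branches = 3, branch_weights = w,
              target_weight = b[["lower"]] - 1e-3)
  expect_false(mnsd_detect(fit, times)$detected)
})

test_that("hypervolume axis evaluates the published closed form", {
  ax <- hypervolume_axis(rep(1.08, 3))
  expect_equal(ax$anchor, rep(12.5, 3))
  expect_equal(ax$direction, rep(1, 3) / sqrt(3))
  expect_equal(hypervolume_axis(c(1.1, 1.08, 1.05))$anchor, c(10, 12.5, 20))
  expect_error(hypervolume_axis(c(1, 1.08, 1.08)), "exceed 1")
})

test_that("distance to the axis is invariant under a common time shift", {
  ax <- hypervolume_axis(c(1.1, 1.08, 1.05))
  x <- matrix(c(11, 13, 19), 1)
  d0 <- mnsd:::.axis_distance(x, ax$anchor, ax$direction)
  d1 <- mnsd:::.axis_distance(x + 7.3, ax$anchor, ax$direction)
  expect_equal(d0, d1)
})

test_that("the tolerance condition accepts tuned inputs and rejects gross jitter", {
  w <- c(1.08, 1.1, 1.06)
  off <- simultaneity_offsets(w)
  expect_true(tolerance_condition(off[1], off[2], w, 0.04, 0.37))
  expect_false(tolerance_condition(off[1] + 100, off[2], w, 0.04, 0.37))
})

test_that("the analytic tolerance matches event-driven detection on a jitter grid", {
  # equal weights keep the input-offset signs aligned with the residual
  # signs; the bound is matched to the model's target weight, at which the
  # two routes should agree except on the measure-zero boundary
  d <- 0.04; L_d <- 0.37
  w <- rep(1.08, 3)
  tw <- mean(target_weight_bounds(d, 3))
  bound <- (3 * tw - 1 - d) / L_d
  fit <- mnsd(NULL, n_branches = 3, branch_weights = w, target_weight = tw,
              params = lifl_params(d = d, L_d = L_d))
  grid <- expand.grid(d12 = seq(-1.2, 1.2, by = 0.3),
                      d13 = seq(-1.2, 1.2, by = 0.3))
  agree <- vapply(seq_len(nrow(grid)), function(i) {
    analytic <- tolerance_condition(grid$d12[i], grid$d13[i], w, d, L_d,
                                    bound = bound)
    sim <- mnsd_detect(fit, c(10, 10 + grid$d12[i], 10 + grid$d13[i]))$detected
    identical(analytic, sim)
  }, logical(1))
  expect_equal(mean(agree), 1)
})
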
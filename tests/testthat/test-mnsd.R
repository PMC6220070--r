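test_that("construction validates weights and fills the default target weight", {
  fit <- mnsd(NULL, n_branches = 3)
  expect_s3_class(fit, "mnsd")
  expect_equal(fit$target_weight, mean(target_weight_bounds(0.04, 3)))
  expect_equal(fit$weights, rep(1.08, 3))
  expect_error(mnsd(NULL, n_branches = 1), ">= 2")
  expect_error(mnsd(NULL, n_branches = 3, branch_weights = 1.0),
               "w >= 1 \\+ d")
})

test_that("a tuned sequence is detected; shape mismatches are refused", {
  fit <- mnsd(NULL, n_branches = 3)
  expect_true(mnsd_detect(fit, c(5, 5, 5))$detected)
  expect_error(mnsd_detect(fit, c(5, 5)), "channel count")
  expect_error(predict(fit, matrix(1, 2, 4)), "channel count")
})

test_that("partial sequences never fire an admissible target but are predictable", {
  fit <- mnsd(NULL, n_branches = 3)  # default target weight inside bounds
  expect_false(mnsd_detect(fit, c(5, 5, NA))$detected)
  expect_false(mnsd_detect(fit, c(NA, NA, 7))$detected)
  det <- predict(fit, rbind(c(5, 5, 5), c(5, 5, NA)))
  expect_identical(det, c(TRUE, FALSE))
  # but learning requires complete sequences
  expect_error(mnsd_detect(fit, c(5, 5, NA), learn = TRUE), "partial")
})

test_that("detection is invariant under a global time translation", {
  set.seed(3)
  fit <- mnsd(NULL, n_branches = 3)
  for (k in 1:20) {
    base <- runif(3, 2, 10)
    shift <- runif(1, 0, 8)
    expect_identical(mnsd_detect(fit, base)$detected,
                     mnsd_detect(fit, base + shift)$detected)
  }
})

test_that("repeated presentation of one sequence synchronises the branch outputs", {
  pat <- matrix(rep(c(5, 12.5, 20), 100), ncol = 3, byrow = TRUE)
  fit <- mnsd(pat)
  desync <- residuals(fit)
  # the weights settle into a small limit cycle (the window does not vanish
  # at small lags), so judge the plateau by its mean, not one trial
  expect_lt(mean(utils::tail(desync, 10)), desync[1] / 5)
  # the synchronising offsets of the trained structure approach the
  # sequence's own inter-spike offsets (delay learning)
  off <- simultaneity_offsets(fit$weights)
  expect_lt(max(abs(off - c(7.5, 15))), 0.5)
  expect_equal(dim(fit$trajectory), c(101L, 3L))
})

test_that("training is inert with zero-length input or zero amplitudes", {
  fit0 <- mnsd(NULL, n_branches = 3)
  fit <- mnsd(matrix(numeric(0), 0, 3))
  expect_equal(fit$weights, fit0$weights)
  expect_equal(fit$n_trials, 0L)
  pat <- matrix(rep(c(5, 12.5, 20), 10), ncol = 3, byrow = TRUE)
  fit <- mnsd(pat, stdp = stdp_params(A_plus = 0, A_minus = 0))
  expect_equal(fit$weights, rep(1.08, 3))
  expect_true(all(fit$trajectory == 1.08))
})

test_that("training with the flipped convention desynchronises instead", {
  pat <- matrix(rep(c(8, 12.5, 17), 60), ncol = 3, byrow = TRUE)
  fit_sync <- mnsd(pat)
  fit_flip <- mnsd(pat, convention = "neighbor_minus_self")
  expect_lt(utils::tail(residuals(fit_sync), 1),
            utils::tail(residuals(fit_flip), 1))
})

test_that("weights stay inside the clipping bounds during long training", {
  set.seed(5)
  pat <- matrix(runif(300, 0, 25), ncol = 3)
  fit <- mnsd(pat, stdp = stdp_params(A_plus = 0.02, A_minus = -0.02))
  expect_true(all(fit$trajectory >= fit$w_min - 1e-12))
  expect_true(all(fit$trajectory <= fit$w_max + 1e-12))
})

test_that("a higher decay parameter makes detection more selective to jitter", {
  set.seed(9)
  base <- c(10, 10, 10)
  jit <- matrix(rnorm(3 * 200, 0, 0.4), ncol = 3)
  rate <- vapply(c(0.25, 0.55), function(L) {
    fit <- mnsd(NULL, n_branches = 3, params = lifl_params(L_d = L))
    mean(vapply(seq_len(nrow(jit)), function(i)
      mnsd_detect(fit, base + jit[i, ])$detected, logical(1)))
  }, numeric(1))
  expect_gt(rate[1], rate[2])
})

test_that("model serialisation round-trips bit-exactly and predicts identically", {
  pat <- matrix(rep(c(5, 12.5, 20), 25), ncol = 3, byrow = TRUE)
  fit <- mnsd(pat)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mnsd(fit, path)
  back <- read_mnsd(path)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$target_weight, fit$target_weight)
  expect_identical(back$params$d, fit$params$d)
  expect_identical(back$convention, fit$convention)
  set.seed(21)
  test <- matrix(runif(30, 0, 25), ncol = 3)
  expect_identical(predict(back, test), predict(fit, test))
  # a second write of the read model is byte-identical
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_mnsd(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("summary and coef expose the trained weights and offsets", {
  pat <- matrix(rep(c(5, 12.5, 20), 10), ncol = 3, byrow = TRUE)
  fit <- mnsd(pat)
  cf <- coef(fit)
  expect_length(cf, 4L)
  expect_equal(unname(cf[1:3]), fit$weights)
  s <- summary(fit)
  expect_equal(s$latencies, 1 / (fit$weights - 1))
  expect_output(print(s), "branch latencies")
})

test_that("simulated sequences from a trained model are mostly detected", {
  pat <- matrix(rep(c(9, 12.5, 16), 60), ncol = 3, byrow = TRUE)
  fit <- mnsd(pat)
  x <- simulate(fit, nsim = 40, seed = 4, sd = 0.15)
  expect_gt(mean(predict(fit, x)), 0.8)
})
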
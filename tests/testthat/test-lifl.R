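test_that("leakage term is linear in the interval and the decay parameter", {
  expect_identical(leakage_term(0.37, 0), 0)
  expect_equal(leakage_term(0.37, 1.0), 0.37)
  expect_identical(leakage_term(0, 100), 0)
  expect_error(leakage_term(0.37, -1), "non-negative")
})

test_that("firing equation gives the latency and its bound", {
  expect_equal(firing_equation(1.08), 12.5)
  expect_equal(firing_equation(2.0), 1.0)
  expect_equal(firing_equation(1.04), 25)
  expect_error(firing_equation(1), "S > 1")
  expect_error(firing_equation(0.5), "S > 1")

  expect_equal(max_latency(0.04), 25)
  expect_equal(max_latency(1), 1)
  expect_equal(max_latency(0.5), 2)
  expect_error(max_latency(0), "positive")
  # the bound is attained exactly at threshold
  expect_equal(max_latency(0.04), firing_equation(1 + 0.04))
})

test_that("rise term continues the latency countdown", {
  expect_identical(rise_term(1.08, 0), 0)
  # t_f(1.08) = 12.5; after 2 ms the remaining latency must be 10.5,
  # so the state must land on 1 + 1/10.5
  expect_equal(rise_term(1.08, 2.0), (1 + 1 / 10.5) - 1.08, tolerance = 1e-12)
  expect_equal(rise_term(1.5, 1.0), 0.5)
  expect_error(rise_term(1.5, 2.0), "already have fired")
  expect_error(rise_term(0.9, 1), "supra-threshold")
})

test_that("latency-countdown identity holds over random states and intervals", {
  set.seed(42)
  for (k in 1:1000) {
    S_p <- 1.04 + rexp(1, rate = 2)
    dt <- runif(1, 0, 0.999) * (1 / (S_p - 1))
    lhs <- firing_equation(S_p + rise_term(S_p, dt))
    rhs <- firing_equation(S_p) - dt
    expect_lt(abs(lhs - rhs), 1e-9)
  }
})

test_that("firing equation is strictly decreasing and bounded by the maximum latency", {
  S <- seq(1.0401, 3, length.out = 200)
  tf <- firing_equation(S)
  expect_true(all(diff(tf) < 0))
  expect_true(all(tf <= max_latency(0.04) + 1e-12))
})

test_that("passive input updates integrate decay, clamp at rest, and cross threshold", {
  p <- lifl_params(d = 0.04, L_d = 0.37)
  # rest + suprathreshold pulse: schedules a fire at the latency
  st <- lifl_apply_input(lifl_rest_state(), p, 0, 1, 1.08)
  expect_equal(st$S, 1.08)
  expect_identical(st$mode, "active")
  expect_equal(st$t_fire, 12.5)
  # subthreshold accumulation with decay over 1 ms
  st <- lifl_apply_input(lifl_rest_state(), p, 0, 1, 0.5)
  st <- lifl_apply_input(st, p, 1, 1, 0.2)
  expect_equal(st$S, 0.5 - 0.37 + 0.2)
  expect_identical(st$mode, "passive")
  # long gaps clamp at zero before the new pulse lands
  st <- lifl_apply_input(lifl_rest_state(), p, 0, 1, 0.5)
  st <- lifl_apply_input(st, p, 100, 1, 0.2)
  expect_equal(st$S, 0.2)
  # time regression is refused
  expect_error(lifl_apply_input(st, p, 50, 1, 0.1), "precedes")
})

test_that("state never goes negative under any passive event sequence", {
  set.seed(7)
  p <- lifl_params(d = 0.5, L_d = 0.5)  # high threshold: stays passive
  for (rep in 1:50) {
    st <- lifl_rest_state()
    t <- 0
    for (k in 1:20) {
      t <- t + rexp(1, 2)
      st <- lifl_apply_input(st, p, t, 1, runif(1, 0, 0.4))
      expect_gte(st$S, 0)
      if (st$mode == "active") break
    }
  }
})

test_that("larger pulse amplitude schedules an earlier fire", {
  p <- lifl_params()
  t1 <- lifl_apply_input(lifl_rest_state(), p, 0, 1, 1.08)$t_fire
  t2 <- lifl_apply_input(lifl_rest_state(), p, 0, 1.5, 1.08)$t_fire
  expect_lt(t2, t1)
})

test_that("firing resets the state and honours the refractory period", {
  p <- lifl_params(t_arp = 2)
  st <- lifl_apply_input(lifl_rest_state(), p, 0, 1, 1.08)
  fired <- lifl_fire(st, p, 12.5)
  expect_equal(fired$spike$time, 12.5)
  expect_equal(fired$spike$amplitude, 1)
  expect_equal(fired$state$S, 0)
  expect_identical(fired$state$mode, "refractory")
  # input inside the refractory window is discarded unchanged
  st2 <- lifl_apply_input(fired$state, p, 13, 1, 2)
  expect_equal(st2$S, 0)
  expect_identical(st2$mode, "refractory")
  # input after it is integrated again
  st3 <- lifl_apply_input(fired$state, p, 15, 1, 1.08)
  expect_identical(st3$mode, "active")
  # zero refractory period: passive immediately
  p0 <- lifl_params(t_arp = 0)
  st <- lifl_apply_input(lifl_rest_state(), p0, 0, 1, 1.08)
  expect_identical(lifl_fire(st, p0, 12.5)$state$mode, "passive")
  # firing a non-active neuron is a logic error
  expect_error(lifl_fire(lifl_rest_state(), p, 1), "non-active")
})
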
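dpy <- 365
mu_D <- oa_param_defaults()$mu_D

test_that("the UC-II indicator is 1 during on-phases and 0 off", {
  s <- make_schedule("uc2_6mo_cycle", 50, 60)
  expect_equal(h_u2(10, s), 1)     # day 10 of the first 6-month phase
  expect_equal(h_u2(200, s), 0)    # inside the 6-month break
  expect_equal(h_u2(364 + 10, s), 1)  # second cycle
  expect_equal(h_u2(c(0, 181.9, 182, 300), s), c(1, 1, 0, 0))
  expect_equal(h_u2(50, no_treatment()), 0)
  expect_equal(h_d(50, no_treatment()), 0)
})

test_that("fisetin impulses decay exponentially and superpose", {
  s <- dose_schedule("D", d_dose_days = c(100, 130), start_age = 50,
                     end_age = 52)
  expect_equal(h_d(100, s, mu_D), 1)                       # at the dose
  expect_equal(h_d(100 + log(2) / mu_D, s, mu_D), 0.5)     # one half-life
  t <- 135
  expect_equal(h_d(t, s, mu_D),
               exp(-mu_D * (t - 100)) + exp(-mu_D * (t - 130)))
  expect_equal(h_d(99.9, s, mu_D), 0)                      # before any dose
  expect_error(h_d(0, s, mu_D = 0), "mu_D")
})

test_that("between doses the input decays at exactly rate mu_D", {
  s <- dose_schedule("D", d_dose_days = c(0, 1, 30, 31), start_age = 50,
                     end_age = 51)
  t1 <- 5; t2 <- 20
  expect_equal(h_d(t2, s, mu_D) / h_d(t1, s, mu_D), exp(-mu_D * (t2 - t1)),
               tolerance = 1e-12)
})

test_that("adding dose days never lowers the fisetin input", {
  set.seed(3)
  base_days <- sort(sample(0:300, 10))
  super_days <- sort(union(base_days, sample(0:300, 10)))
  s1 <- dose_schedule("D", d_dose_days = base_days, start_age = 50,
                      end_age = 51)
  s2 <- dose_schedule("D", d_dose_days = super_days, start_age = 50,
                      end_age = 51)
  t <- seq(0, 350, by = 0.7)
  expect_true(all(h_d(t, s2, mu_D) >= h_d(t, s1, mu_D) - 1e-15))
})

test_that("named patterns produce the documented dose-day counts", {
  # first two days of each 30-day month over a 360-day year: 2 x 12
  s <- make_schedule("fisetin_monthly_2d", 50, 50 + 360 / dpy)
  expect_equal(length(s$d_dose_days), 24)
  # first two days of each week over 28 days: 2 x 4
  s <- make_schedule("fisetin_weekly_2d", 50, 50 + 28 / dpy)
  expect_equal(length(s$d_dose_days), 8)
  # 7 on / 7 off over 28 days: 14 days
  s <- make_schedule("fisetin_7on7off", 50, 50 + 28 / dpy)
  expect_equal(length(s$d_dose_days), 14)
  # phase-1 protocol: 2 days, 28-day break, 2 days
  s <- make_schedule("fisetin_trial_2d_28d", 60, 61)
  expect_equal(s$d_dose_days, (60 - 50) * dpy + c(0, 1, 30, 31))
  # clinical T1-T4 protocol: 90 consecutive UC-II days ending at end_age
  s <- make_schedule("t1_t4_daily_90d", 50, 63)
  expect_equal(unname(s$u2_intervals[1, ]), c(13 * dpy - 90, 13 * dpy))
  expect_equal(sum(h_u2(seq(0, 13 * dpy - 0.5, by = 1), s)), 90)
  expect_error(make_schedule("nope", 50, 60), "unknown pattern")
})

test_that("dosing outside the treatment window is rejected", {
  expect_error(dose_schedule("D", d_dose_days = c(-5), start_age = 50,
                             end_age = 60), "window")
  expect_error(dose_schedule("U2",
                             u2_intervals = matrix(c(0, 11 * dpy), ncol = 2),
                             start_age = 50, end_age = 60), "window")
})

test_that("zero dose density reproduces the no-drug trajectory bitwise", {
  g <- quick_grid()
  p <- oa_params("female")
  sched <- make_schedule("fisetin_monthly_2d", 50, 52, gamma_D = 0)
  sched$u2_intervals <- matrix(c(0, 300), ncol = 2)
  sched$gamma_U2 <- 0
  s_drug <- oa_simulate(p, sched, end_age = 52, grid = g,
                        record_every_days = 30)
  s_ctrl <- oa_simulate(p, NULL, end_age = 52, grid = g,
                        record_every_days = 30)
  expect_identical(s_drug$averages, s_ctrl$averages)
  expect_identical(s_drug$profiles, s_ctrl$profiles)
})
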
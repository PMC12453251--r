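p_m <- oa_params("male")
p_f <- oa_params("female")
dpy <- p_m$days_per_year

test_that("senescent-cell clearance drifts linearly with age", {
  expect_equal(mu_cs(0, p_m), 0.04)
  expect_equal(mu_cs(90 * dpy, p_m), 0.08)
  expect_equal(mu_cs(45 * dpy, p_m), 0.06)
  t <- seq(0, 40 * dpy, length.out = 50)
  expect_true(all(diff(mu_cs(t, p_m)) >= 0))
  expect_error(mu_cs(-1, p_m), ">= 0")
  # alternative reading: clearance declining with immune ageing
  p_dec <- oa_params(mu_cs_aging = "decreasing")
  expect_equal(mu_cs(90 * dpy, p_dec), 0.02)
  expect_true(all(diff(mu_cs(t, p_dec)) <= 0))
})

test_that("postmenopausal coefficients start at their amplitude and halve at T_w", {
  expect_equal(dp_menopause(0, "MP", p_f), 2.5)
  expect_equal(dp_menopause(0, "L2", p_f), 2.5e-4)
  expect_equal(dp_menopause(12 * dpy, "MP", p_f), 1.25)
  t <- seq(0, 40 * dpy, length.out = 50)
  expect_true(all(diff(dp_menopause(t, "MP", p_f)) < 0))
  expect_error(dp_menopause(0, "Cc", p_f), "MP")
  expect_error(dp_menopause(-5, "MP", p_f), ">= 0")
})

test_that("with zero state and no drugs only the chondrocyte source survives", {
  g <- quick_grid()
  st <- species_state(g$x, 0, 0, 0, 0, 0, 0, 0)
  rt <- reaction_terms(st, 0, p_m)
  expect_equal(rt$C, rep(1.41e-3, g$n_nodes))
  for (s in c("Cs", "Ch", "Cc", "MP", "L2", "D"))
    expect_equal(rt[[s]], rep(0, g$n_nodes), label = s)
})

test_that("the calibrated steady state balances the protein equations", {
  g <- grid_spec(n_nodes = 3)
  # collagen II balance at the estimation levels
  st <- species_state(g$x, C = 0.027, Cs = 4.05e-3, Ch = 0, Cc = 0,
                      MP = 16.17e-9, L2 = 2.83e-5, D = 0)
  rt <- reaction_terms(st, 0, p_m)
  l2_terms <- c(p_m$lambda_CL2 * 0.027, p_m$mu_MPL2 * 2.83e-5 * 16.17e-9,
                p_m$mu_L2 * 2.83e-5)
  # the table's 3-significant-figure rounding leaves ~1e-3 relative residual
  expect_lt(abs(rt$L2[1]), 2e-3 * max(l2_terms))
  # MMP13 balance at the senescent level the estimation used (Cs0 = 4.1e-3)
  st2 <- species_state(g$x, C = 0.027, Cs = 4.1e-3, Ch = 0, Cc = 0,
                       MP = 16.17e-9, L2 = 2.83e-5, D = 0)
  rt2 <- reaction_terms(st2, 0, p_m)
  mp_terms <- c(p_m$lambda_CsMP * 4.1e-3, p_m$mu_MP * 16.17e-9)
  expect_lt(abs(rt2$MP[1]), 1e-3 * max(mp_terms))
})

test_that("female and male rates differ exactly by the postmenopausal terms", {
  g <- quick_grid()
  for (seed in 1:5) {
    st <- random_state(g, seed)
    t <- seed * 500
    rm <- reaction_terms(st, t, p_m)
    rf <- reaction_terms(st, t, p_f)
    for (s in c("C", "Cs", "Ch", "Cc", "D"))
      expect_identical(rf[[s]], rm[[s]], label = s)
    expect_equal(rf$MP - rm$MP, dp_menopause(t, "MP", p_f) * st$MP)
    expect_equal(rf$L2 - rm$L2, -dp_menopause(t, "L2", p_f) * st$L2)
  }
})

test_that("fisetin action is monotone: more drug never boosts MMP13 or spares senescent cells", {
  g <- quick_grid()
  st0 <- random_state(g, 42)
  d_levels <- c(0, 1e-8, 1e-6, 1e-4)
  prev <- NULL
  for (d in d_levels) {
    st <- st0
    st$D <- rep(d, g$n_nodes)
    rt <- reaction_terms(st, 100, p_m)
    if (!is.null(prev)) {
      expect_true(all(rt$MP <= prev$MP + 1e-15))
      expect_true(all(rt$Cs <= prev$Cs + 1e-15))
    }
    prev <- rt
  }
})

test_that("MMP13 production saturates as 1/(alpha_D * D) at high drug levels", {
  g <- grid_spec(n_nodes = 3)
  d <- 1  # alpha_D * D = 2e6
  st <- species_state(g$x, C = 0, Cs = 4e-3, Ch = 0, Cc = 0, MP = 0, L2 = 0,
                      D = d)
  rt <- reaction_terms(st, 0, p_m)
  prod_limit <- p_m$lambda_CsMP * 4e-3 / (p_m$alpha_D * d)
  expect_equal(rt$MP[1], prod_limit, tolerance = 1e-6)
})

test_that("invalid states are rejected", {
  g <- quick_grid()
  st <- random_state(g, 1)
  st$MP[3] <- -1e-9
  expect_error(reaction_terms(st, 0, p_m), "negative")
  st2 <- random_state(g, 2)
  st2$C[1] <- NaN
  expect_error(reaction_terms(st2, 0, p_m), "NaN")
})

test_that("the algebraic-elimination variant divides the Ch rate by 1 + lambda_ChCc", {
  g <- quick_grid()
  st <- random_state(g, 7)
  rt_fast <- reaction_terms(st, 0, p_m)
  p_alg <- oa_params(ch_calcification_sink = "algebraic")
  rt_alg <- reaction_terms(st, 0, p_alg)
  expect_equal(rt_alg$Ch, rt_fast$Ch / (1 + p_m$lambda_ChCc))
  expect_equal(rt_alg$Cc, p_m$lambda_ChCc * rt_alg$Ch)
})
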
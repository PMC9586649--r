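test_that("total cost is the linear facet aggregation", {
  expect_equal(total_cost(cost_schedule(c(a = 1, b = 1, c = 1)),
                          c(a = 2, b = 3, c = 4)), 9)
  sched <- cost_schedule(c(s = 15896, f = 6677, st = 4843))
  expect_equal(total_cost(sched, c(s = 6, f = 4, st = 18)), 209258)
  expect_equal(total_cost(cost_schedule(c(a = 0, b = 0), fixed_cost = 100),
                          c(a = 3, b = 7)), 100)
  expect_error(total_cost(sched, c(s = 6, q = 1)), "lacks facet")
  # linearity: doubling sizes and halving unit costs preserves the total
  sched2 <- cost_schedule(c(s = 15896 / 2, f = 6677 / 2, st = 4843 / 2))
  expect_equal(total_cost(sched2, c(s = 12, f = 8, st = 36)), 209258)
})

test_that("ICER arithmetic reproduces signs and guards zero denominators", {
  expect_equal(icer(plan_economics("b", 10, 1), plan_economics("a", 0, 0)), 10)
  # cheaper, less effective intervention: positive ICER by sign cancellation
  expect_gt(icer(plan_economics("cut", 150, 0.70),
                 plan_economics("now", 200, 0.80)), 0)
  expect_error(icer(plan_economics("a", 10, 0.5), plan_economics("b", 20, 0.5)),
               "compare their costs directly")
})

test_that("ICER rescaling is exact and display rounding is half away from zero", {
  expect_equal(rescale_icer(1029150, 0.01), 10291.5)
  expect_equal(rescale_icer(123.4, 1), 123.4)
  expect_equal(rescale_icer(0), 0)
  expect_error(rescale_icer(1, unit = 0), "positive")
  expect_equal(currency_round(10291.5), 10292)
  expect_equal(currency_round(-10291.5), -10292)
  expect_equal(currency_round(2.49), 2)
  expect_equal(currency_round(0), 0)
})

test_that("degenerate CEAC is a step: certain below the ICER, zero above (cost-saving case)", {
  base <- plan_economics("current", 209240, 0.81)
  int <- plan_economics("proposal", 147491, 0.75)
  res <- ceac(int, base, wtp = seq(0, 30000, by = 500), n_draws = 50,
              seed = 4)
  # brute-force expectation: dC and dE both negative, so the net benefit
  # lambda*dE - dC is positive exactly when lambda < dC/dE (the ICER)
  expected <- as.numeric(res$wtp / res$rescale_unit < res$icer)
  expect_equal(res$ceac, expected)
  expect_equal(res$icer, (147491 - 209240) / (0.75 - 0.81))
  expect_equal(res$icer_rescaled, res$icer * 0.01)
  expect_true(all(res$ceac >= 0 & res$ceac <= 1))
})

test_that("a tie in net benefit counts as not cost-effective", {
  base <- plan_economics("a", 0, 0.5)
  int <- plan_economics("b", 100, 1.0) # ICER = 200 per 1.0 = 2 per 0.01
  res <- ceac(int, base, wtp = c(1, 2, 3), n_draws = 10, seed = 1)
  expect_equal(res$ceac, c(0, 0, 1)) # lambda = ICER gives zero net benefit
})

test_that("CEAC is reproducible under a seed and monotone over the grid", {
  base <- plan_economics("current", 209240, 0.81)
  int <- plan_economics("proposal", 147491, 0.75)
  unc_e <- list(dist = "normal", sd = 0.02)
  unc_c <- list(dist = "normal", cv = 0.15)
  r1 <- ceac(int, base, n_draws = 5000, seed = 10,
             eff_uncertainty = unc_e, cost_uncertainty = unc_c)
  r2 <- ceac(int, base, n_draws = 5000, seed = 10,
             eff_uncertainty = unc_e, cost_uncertainty = unc_c)
  expect_identical(r1$ceac, r2$ceac)
  r3 <- ceac(int, base, n_draws = 5000, seed = 11,
             eff_uncertainty = unc_e, cost_uncertainty = unc_c)
  band <- 3 * sqrt(pmax(r1$ceac * (1 - r1$ceac), 0.25 / 5000) / 5000)
  expect_true(all(abs(r3$ceac - r1$ceac) <= pmax(band, 0.03)))
  # dE < 0 for every draw here, so acceptance can only fall as lambda grows
  expect_true(all(diff(r1$ceac) <= 0))
})

test_that("large-draw CEAC converges to the closed-form normal-theory probability", {
  base <- plan_economics("current", 209240, 0.81)
  int <- plan_economics("proposal", 147491, 0.75)
  sd_e <- 0.01
  sd_c <- 5000
  res <- ceac(int, base, wtp = c(4000, 10291.5, 20000), n_draws = 1e5,
              seed = 12,
              eff_uncertainty = list(dist = "normal", sd = sd_e),
              cost_uncertainty = list(dist = "normal", sd = sd_c))
  lambda <- c(4000, 10291.5, 20000) / 0.01
  mu <- lambda * res$delta_effectiveness - res$delta_cost
  sdv <- sqrt(lambda^2 * sd_e^2 + sd_c^2)
  expect_lt(max(abs(res$ceac - pnorm(mu / sdv))), 0.01)
})

test_that("lognormal cost uncertainty is moment-matched per plan", {
  base <- plan_economics("a", 200000, 0.8)
  int <- plan_economics("b", 150000, 0.7)
  res <- ceac(int, base, wtp = c(1000), n_draws = 2e5, seed = 13,
              cost_uncertainty = list(dist = "lognormal", cv = 0.1))
  # reconstruct the draws to check their moments
  draws <- gcea:::with_seed(13, list(
    dE = gcea:::draw_delta_e(-0.1, list(dist = "degenerate"), 2e5),
    dC = gcea:::draw_delta_c(-50000, 150000, 200000,
                             list(dist = "lognormal", cv = 0.1), 2e5)))
  expect_lt(abs(mean(draws$dC) + 50000), 300)
  expect_lt(abs(sd(draws$dC) - sqrt((0.1 * 150000)^2 + (0.1 * 200000)^2)),
            300)
  expect_true(all(res$ceac >= 0 & res$ceac <= 1))
})

test_that("ceac validates its configuration", {
  base <- plan_economics("a", 0, 0.5)
  int <- plan_economics("b", 100, 1.0)
  expect_error(ceac(int, base, n_draws = 5000), "seed is required")
  expect_error(ceac(int, base, n_draws = 0, seed = 1), "n_draws")
  expect_error(ceac(int, base, wtp = numeric(0), seed = 1), "nonempty")
  expect_error(plan_economics("a", 10, 1.2), "\\[0, 1\\]")
})

test_that("coefficient uncertainty: pass-through, degenerate data, and method guards", {
  d <- parse_design("p x t x r")
  tab <- simulate_scores(d, c(p = 20, t = 4, r = 2),
                         c(p = 4, "p*t*r" = 1), seed = 30)
  vc <- estimate_components(tab, d)
  plan <- dstudy_plan(d, c(t = 4, r = 2))
  expect_equal(effectiveness_uncertainty(vc, plan, method = "user-supplied",
                                         se = 0.02), 0.02)
  const <- tab
  const$score <- 2
  vc0 <- estimate_components(const, d)
  expect_equal(effectiveness_uncertainty(vc0, plan, seed = 1), 0)
  vc_assumed <- as_variance_components(d, c(p = 1, "p*t*r" = 1))
  expect_error(effectiveness_uncertainty(vc_assumed, plan, seed = 1),
               "df and mean squares")
  expect_error(effectiveness_uncertainty(vc, plan,
                                         method = "parametric-bootstrap"),
               "seed")
})

test_that("parametric-bootstrap SE matches the sampling SD of the coefficient", {
  d <- parse_design("p x t x r")
  sizes <- c(p = 30, t = 4, r = 3)
  truth <- c(p = 4, "p*t" = 1, "p*r" = 1, "p*t*r" = 2)
  plan <- dstudy_plan(d, c(t = 4, r = 3))

  # sampling SD across independently simulated examinations
  n_data <- 500
  n_boot_sets <- 60
  set.seed(71)
  seeds <- sample.int(1e6, n_data + n_boot_sets)
  g_hat <- vapply(seeds[seq_len(n_data)], function(s) {
    vc <- estimate_components(simulate_scores(d, sizes, truth, seed = s), d)
    g_coefficient(vc, plan, "relative")$coefficient
  }, numeric(1))
  empirical <- sd(g_hat)

  # average bootstrap SE over datasets (a single dataset's SE is itself noisy)
  boots <- vapply(seeds[n_data + seq_len(n_boot_sets)], function(s) {
    vc <- estimate_components(simulate_scores(d, sizes, truth, seed = s), d)
    effectiveness_uncertainty(vc, plan, "relative", n_boot = 1000,
                              seed = s + 1)
  }, numeric(1))
  expect_lt(abs(mean(boots) - empirical) / empirical, 0.25)
})

test_that("jackknife SE is of the same order as the bootstrap SE", {
  d <- parse_design("p x t x r")
  tab <- simulate_scores(d, c(p = 40, t = 4, r = 3),
                         c(p = 4, "p*t" = 1, "p*r" = 1, "p*t*r" = 2),
                         seed = 55)
  vc <- estimate_components(tab, d)
  plan <- dstudy_plan(d, c(t = 4, r = 3))
  se_b <- effectiveness_uncertainty(vc, plan, "relative", seed = 56)
  se_j <- effectiveness_uncertainty(vc, plan, "relative",
                                    method = "jackknife")
  expect_gt(se_j, 0)
  expect_lt(abs(log(se_j / se_b)), log(2.5))
})
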
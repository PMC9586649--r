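make_crossed_data <- function(sizes, seed) {
  d <- parse_design("p x t x r")
  grid <- expand.grid(p = seq_len(sizes[1]), t = seq_len(sizes[2]),
                      r = seq_len(sizes[3]))
  set.seed(seed)
  grid$score <- rnorm(nrow(grid))
  list(design = d, data = grid)
}

test_that("hand-worked 2x2 table gives the classical sums of squares and components", {
  d <- parse_design("p x i")
  tab <- expand.grid(p = 1:2, i = 1:2)
  tab$score <- c(1, 3, 2, 4) # persons are rows: [[1,2],[3,4]]
  ss <- sums_of_squares(tab, d)
  expect_equal(ss$SS[ss$effect == "p"], 4)
  expect_equal(ss$SS[ss$effect == "i"], 1)
  expect_equal(ss$SS[ss$effect == "p*i"], 0)

  # hand-solved EMS system: sigma2_pi = MS_pi, sigma2_p = (MS_p - MS_pi)/n_i
  vc <- estimate_components(tab, d)
  expect_equal(vc$sigma2[vc$effect == "p"], (4 - 0) / 2)
  expect_equal(vc$sigma2[vc$effect == "i"], (1 - 0) / 2)
  expect_equal(vc$sigma2[vc$effect == "p*i"], 0)
  expect_false(any(vc$truncated))
})

test_that("constant scores give zero sums of squares and zero components", {
  d <- parse_design("p x t x r")
  grid <- expand.grid(p = 1:4, t = 1:3, r = 1:2)
  grid$score <- 5
  ss <- sums_of_squares(grid, d)
  expect_equal(ss$SS, rep(0, 7))
  vc <- estimate_components(grid, d)
  expect_equal(vc$sigma2, rep(0, 7))
})

test_that("sums of squares satisfy the ANOVA identity and match anova(lm()) term by term", {
  # crossed design
  cd <- make_crossed_data(c(5, 4, 3), seed = 11)
  ss <- sums_of_squares(cd$data, cd$design)
  expect_equal(sum(ss$SS), sum((cd$data$score - mean(cd$data$score))^2),
               tolerance = 1e-10)

  fdat <- data.frame(lapply(cd$data[c("p", "t", "r")], factor),
                     score = cd$data$score)
  # saturated model: residual df is 0, so silence the F-test warning
  lm_ss <- suppressWarnings(anova(lm(score ~ p * t * r, data = fdat)))
  for (eff in c("p", "t", "r", "p:t", "p:r", "t:r", "p:t:r")) {
    ours <- ss$SS[ss$effect == gsub(":", "*", eff, fixed = TRUE)]
    expect_equal(ours, lm_ss[eff, "Sum Sq"], tolerance = 1e-8)
  }

  # nested design: persons within sites, crossed with forms
  d <- parse_design("p:s x f")
  grid <- expand.grid(p = 1:4, s = 1:3, f = 1:5)
  set.seed(12)
  grid$score <- rnorm(nrow(grid), mean = 10)
  ss <- sums_of_squares(grid, d)
  expect_equal(sum(ss$SS), sum((grid$score - mean(grid$score))^2),
               tolerance = 1e-10)
  fdat <- data.frame(lapply(grid[c("p", "s", "f")], factor),
                     score = grid$score)
  lm_ss <- suppressWarnings(anova(lm(score ~ s * f + s:p + s:p:f,
                                     data = fdat)))
  map <- c(s = "s", f = "f", "s:f" = "s*f", "s:p" = "p:s", "s:f:p" = "p*f:s")
  for (eff in names(map)) {
    expect_equal(ss$SS[ss$effect == map[[eff]]], lm_ss[eff, "Sum Sq"],
                 tolerance = 1e-8)
  }
})

test_that("EMS coefficients follow the product-of-absent-sizes rule", {
  d <- parse_design("p x t x r")
  C <- ems_coefficients(d, c(p = 10, t = 3, r = 2))
  # E[MS_p] = n_t n_r sigma2_p + n_r sigma2_pt + n_t sigma2_pr + sigma2_ptr
  expect_equal(C["p", c("p", "p*t", "p*r", "p*t*r")],
               c(p = 6, "p*t" = 2, "p*r" = 3, "p*t*r" = 1))
  # residual component has coefficient 1 in every containing effect's EMS
  expect_equal(unname(C[, "p*t*r"]), rep(1, 7))
  # sizes all 1: the containment indicator matrix
  C1 <- ems_coefficients(d, c(p = 1, t = 1, r = 1))
  expect_true(all(C1 %in% c(0, 1)))
  expect_equal(C1["p", ], c(p = 1, t = 0, r = 0, "p*t" = 1, "p*r" = 1,
                            "t*r" = 0, "p*t*r" = 1))
  # triangular under the canonical order, hence invertible
  expect_gt(abs(det(C)), 0)
})

test_that("residual-only data recover residual ~ 1 and other components ~ 0", {
  d <- parse_design("p x t x r")
  tab <- simulate_scores(d, c(p = 60, t = 6, r = 4),
                         c("p*t*r" = 1), grand_mean = 3, seed = 101)
  vc <- estimate_components(tab, d)
  res <- vc$sigma2[vc$effect == "p*t*r"]
  # residual MS ~ chi^2 with df = 59*5*3: 3 sd band
  expect_lt(abs(res - 1), 3 * sqrt(2 / (59 * 5 * 3)))
  expect_true(all(vc$sigma2[vc$effect != "p*t*r"] < 0.15))
  # negative raw estimates are retained and flagged, sigma2 floored at 0
  expect_true(all(vc$sigma2 >= 0))
  expect_equal(vc$truncated, vc$raw_estimate < 0)
})

test_that("unbalanced or malformed tables are rejected with the offending cell named", {
  d <- parse_design("p x i")
  tab <- expand.grid(p = 1:3, i = 1:2)
  tab$score <- rnorm(6)
  expect_error(estimate_components(tab[-2, ], d),
               "missing index combination \\(p=2, i=1\\)")
  expect_error(estimate_components(rbind(tab, tab[1, ]), d), "duplicated")
  expect_error(estimate_components(tab[0, ], d), "empty")
  expect_error(estimate_components(tab[, c("p", "score")], d),
               "lacks column")
  tab1 <- expand.grid(p = 1:4, i = 1)
  tab1$score <- rnorm(4)
  expect_error(estimate_components(tab1, d), "need >= 2 levels of 'i'")
})

test_that("globally unique nested labels are re-indexed within parents", {
  d <- parse_design("p:s x f")
  tab <- simulate_scores(d, c(p = 6, s = 3, f = 4),
                         c("p:s" = 2, s = 0.5, f = 0.3, "p*f:s" = 1),
                         seed = 21)
  vc_within <- estimate_components(tab, d)
  tab_global <- tab
  tab_global$p <- sprintf("person%02d", (tab$s - 1) * 6 + tab$p)
  vc_global <- estimate_components(tab_global, d)
  expect_equal(vc_global$sigma2, vc_within$sigma2, tolerance = 1e-12)
})
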
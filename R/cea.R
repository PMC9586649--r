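#' Facet-linear cost schedule
#'
#' Assigns a unit cost (money per level) to each facet of an assessment
#' configuration, plus an optional fixed cost.  Total plan cost is the linear
#' aggregation \eqn{\sum_f c_f n_f + fixed}.
#'
#' @param unit_costs Named nonnegative numeric vector (money per level).
#' @param fixed_cost Nonnegative scalar, default 0.
#' @param currency Currency label for display, default `"GBP"`.
#' @return An object of class `cost_schedule`.
#' @examples
#' cost_schedule(c(s = 15896, f = 6677, st = 4843))
#' @export
cost_schedule <- function(unit_costs, fixed_cost = 0, currency = "GBP") {
  if (is.null(names(unit_costs)) || any(!nzchar(names(unit_costs)))) {
    stop("unit_costs must be named by facet", call. = FALSE)
  }
  if (any(unit_costs < 0) || fixed_cost < 0) {
    stop("costs must be nonnegative", call. = FALSE)
  }
  if (!nzchar(currency)) stop("currency label must be nonempty", call. = FALSE)
  structure(list(unit_costs = unit_costs,
                 fixed_cost = as.numeric(fixed_cost),
                 currency = currency),
            class = "cost_schedule")
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Cost schedule (", x$currency, "):\n", sep = "")
  for (f in names(x$unit_costs)) {
    cat(sprintf("  %s: %s per level\n", f,
                format(x$unit_costs[[f]], big.mark = ",")))
  }
  if (x$fixed_cost != 0) {
    cat("  fixed:", format(x$fixed_cost, big.mark = ","), "\n")
  }
  invisible(x)
}

#' Total cost of a D-study plan
#'
#' @param schedule A `cost_schedule` covering every facet of the plan.
#' @param plan A `gcea_plan` (or a named vector of facet sizes).
#' @return Numeric scalar (money).
#' @examples
#' sched <- cost_schedule(c(s = 15896, f = 6677, st = 4843))
#' total_cost(sched, c(s = 6, f = 4, st = 18))
#' @export
total_cost <- function(schedule, plan) {
  stopifnot(inherits(schedule, "cost_schedule"))
  sizes <- if (inherits(plan, "gcea_plan")) plan$sizes else plan
  if (is.null(names(sizes))) stop("plan sizes must be named", call. = FALSE)
  missing <- setdiff(names(sizes), names(schedule$unit_costs))
  if (length(missing)) {
    stop(sprintf("cost schedule lacks facet(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sum(schedule$unit_costs[names(sizes)] * sizes) + schedule$fixed_cost
}

#' Pair a plan with its cost and effectiveness
#'
#' @param plan A `gcea_plan`, or a character label for externally specified
#'   plans.
#' @param total_cost Money.
#' @param effectiveness Coefficient value in `[0, 1]`.
#' @return An object of class `plan_economics`.
#' @examples
#' plan_economics("current", 209240, 0.81)
#' @export
plan_economics <- function(plan, total_cost, effectiveness) {
  if (effectiveness < 0 || effectiveness > 1) {
    stop("effectiveness must lie in [0, 1]", call. = FALSE)
  }
  label <- if (inherits(plan, "gcea_plan")) plan$label else as.character(plan)
  structure(list(plan = plan, label = label,
                 total_cost = as.numeric(total_cost),
                 effectiveness = as.numeric(effectiveness)),
            class = "plan_economics")
}

#' Incremental cost-effectiveness ratio
#'
#' The ICER between an intervention plan and a base case is the cost
#' difference divided by the effectiveness difference,
#' \eqn{(C_{int} - C_{base}) / (E_{int} - E_{base})}, signs preserved: a
#' cheaper and less effective intervention yields a positive ICER by sign
#' cancellation.
#'
#' @param intervention,base `plan_economics` objects.
#' @return Money per 1.0 coefficient unit.
#' @examples
#' icer(plan_economics("proposal", 147491, 0.75),
#'      plan_economics("current", 209240, 0.81))
#' @export
icer <- function(intervention, base) {
  stopifnot(inherits(intervention, "plan_economics"),
            inherits(base, "plan_economics"))
  de <- intervention$effectiveness - base$effectiveness
  if (de == 0) {
    stop(paste("ICER undefined: the plans have equal effectiveness;",
               "compare their costs directly"), call. = FALSE)
  }
  (intervention$total_cost - base$total_cost) / de
}

#' Rescale an ICER to a smaller effectiveness increment
#'
#' Converts money per 1.0 coefficient unit to money per `unit` increment
#' (e.g. 0.01).  Computation is exact; [currency_round()] gives the
#' nearest-integer display value.
#'
#' @param icer_value Money per 1.0 coefficient unit.
#' @param unit Positive coefficient increment, default 0.01.
#' @return Money per `unit` increment.
#' @examples
#' rescale_icer(1029150)           # 10291.5 per 0.01
#' currency_round(rescale_icer(1029150))
#' @export
rescale_icer <- function(icer_value, unit = 0.01) {
  if (unit <= 0) stop("rescale unit must be positive", call. = FALSE)
  icer_value * unit
}

#' Round money for display (half away from zero)
#'
#' Values are first snapped to 12 significant digits so that binary
#' round-off in upstream arithmetic (e.g. differences of decimal
#' effectiveness values) cannot push an exact half below the tie point.
#'
#' @param x Numeric.
#' @return Nearest integer, ties away from zero (so 10291.5 displays 10292).
#' @export
currency_round <- function(x) {
  y <- signif(x, 12)
  sign(y) * floor(abs(y) + 0.5)
}

#' Monte-Carlo cost-effectiveness acceptability curve
#'
#' Draws incremental cost and effectiveness pairs from configured
#' distributions and, for each willingness-to-pay value \eqn{\lambda}
#' (expressed per `rescale_unit` of the coefficient), reports the fraction
#' of draws with positive incremental net benefit
#' \eqn{\lambda \Delta E - \Delta C > 0} (ties count as not cost-effective).
#'
#' Uncertainty specifications are lists with a `dist` field:
#' * `list(dist = "degenerate")` — the point estimate only;
#' * `list(dist = "normal", sd = )` — normal around the point estimate
#'   (effectiveness differences additionally truncated to `[-1, 1]`);
#' * costs only: `list(dist = "normal", cv = )` — sd as a coefficient of
#'   variation of the absolute cost difference;
#' * costs only: `list(dist = "lognormal", cv = )` — each plan's total cost
#'   drawn lognormally with the given coefficient of variation
#'   (moment-matched), differenced.
#'
#' @param intervention,base `plan_economics` objects.
#' @param wtp Numeric vector of willingness-to-pay thresholds per
#'   `rescale_unit`; default `NULL` spans 0 to 3 times the rescaled ICER in
#'   100 steps.
#' @param n_draws Number of Monte-Carlo draws (>= 1), default 10000.
#' @param seed Integer seed (mandatory).
#' @param rescale_unit Coefficient increment the WTP grid is expressed in,
#'   default 0.01.
#' @param eff_uncertainty,cost_uncertainty Uncertainty specifications (see
#'   Details); defaults are degenerate.
#' @return An object of class `cea_result` carrying the comparator pair, the
#'   deltas, the ICER (raw and rescaled), the WTP grid, the per-WTP
#'   acceptance probabilities, `n_draws` and `seed`.
#' @examples
#' res <- ceac(plan_economics("proposal", 147491, 0.75),
#'             plan_economics("current", 209240, 0.81),
#'             n_draws = 1000, seed = 1,
#'             eff_uncertainty = list(dist = "normal", sd = 0.01),
#'             cost_uncertainty = list(dist = "normal", cv = 0.1))
#' res
#' @export
ceac <- function(intervention, base, wtp = NULL, n_draws = 10000, seed,
                 rescale_unit = 0.01,
                 eff_uncertainty = list(dist = "degenerate"),
                 cost_uncertainty = list(dist = "degenerate")) {
  stopifnot(inherits(intervention, "plan_economics"),
            inherits(base, "plan_economics"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for the Monte-Carlo CEAC", call. = FALSE)
  }
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (rescale_unit <= 0) stop("rescale unit must be positive", call. = FALSE)

  dC <- intervention$total_cost - base$total_cost
  dE <- intervention$effectiveness - base$effectiveness
  icer_value <- icer(intervention, base)
  icer_rescaled <- rescale_icer(icer_value, rescale_unit)

  if (is.null(wtp)) {
    wtp <- seq(0, 3 * abs(icer_rescaled), length.out = 101L)
  }
  if (!length(wtp)) stop("WTP grid must be nonempty", call. = FALSE)

  draws <- with_seed(seed, list(
    dE = draw_delta_e(dE, eff_uncertainty, n_draws),
    dC = draw_delta_c(dC, intervention$total_cost, base$total_cost,
                      cost_uncertainty, n_draws)))

  lambda <- wtp / rescale_unit # per 1.0 coefficient unit
  prob <- vapply(lambda, function(l) {
    mean(l * draws$dE - draws$dC > 0)
  }, numeric(1))

  structure(list(comparator = base,
                 intervention = intervention,
                 delta_cost = dC,
                 delta_effectiveness = dE,
                 icer = icer_value,
                 icer_rescaled = icer_rescaled,
                 icer_display = currency_round(icer_rescaled),
                 rescale_unit = rescale_unit,
                 wtp = as.numeric(wtp),
                 ceac = prob,
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "cea_result")
}

draw_delta_e <- function(dE, spec, n) {
  dist <- spec$dist %||% "degenerate"
  switch(dist,
    degenerate = rep(dE, n),
    normal = {
      sd <- spec$sd %||% 0
      pmin(1, pmax(-1, stats::rnorm(n, dE, sd)))
    },
    stop(sprintf("unknown effectiveness distribution '%s'", dist),
         call. = FALSE))
}

draw_delta_c <- function(dC, cost_int, cost_base, spec, n) {
  dist <- spec$dist %||% "degenerate"
  switch(dist,
    degenerate = rep(dC, n),
    normal = {
      sd <- spec$sd %||% (abs(dC) * (spec$cv %||% 0))
      stats::rnorm(n, dC, sd)
    },
    lognormal = {
      cv <- spec$cv %||% 0
      if (cv <= 0) return(rep(dC, n))
      sdlog <- sqrt(log(1 + cv^2))
      draw1 <- function(m) {
        stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      }
      draw1(cost_int) - draw1(cost_base)
    },
    stop(sprintf("unknown cost distribution '%s'", dist), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cea_result <- function(x, ...) {
  cur <- "currency units"
  cat(sprintf("CEA: '%s' (intervention) vs '%s' (base case)\n",
              x$intervention$label, x$comparator$label))
  cat(sprintf("  delta cost = %s, delta effectiveness = %.4f\n",
              format(x$delta_cost, big.mark = ","), x$delta_effectiveness))
  cat(sprintf("  ICER = %s per 1.0 coefficient unit\n",
              format(x$icer, big.mark = ",")))
  cat(sprintf("  ICER = %s per %g coefficient unit (displayed: %s)\n",
              format(x$icer_rescaled, big.mark = ","), x$rescale_unit,
              format(x$icer_display, big.mark = ",")))
  cat(sprintf("  CEAC over %d WTP values (%d draws, seed %d)\n",
              length(x$wtp), x$n_draws, x$seed))
  invisible(x)
}

#' Standard error of a projected coefficient
#'
#' Quantifies sampling uncertainty in a D-study coefficient.  The parametric
#' bootstrap resamples each mean square as \eqn{MS \cdot \chi^2_{df} / df}
#' (the exact sampling law of balanced-design mean squares under normality),
#' re-solves the EMS system with truncation at zero, recomputes the
#' coefficient, and returns the standard deviation over replicates.  The
#' jackknife deletes one object-of-measurement level at a time (for nested
#' objects, the level within every parent combination, preserving balance).
#'
#' @param vc A `gcea_vc` produced by [estimate_components()] (resampling
#'   methods need its `df` and mean squares; the jackknife needs the score
#'   table it was estimated from).
#' @param plan A `gcea_plan`.
#' @param error_type `"relative"` or `"absolute"`.
#' @param method `"parametric-bootstrap"`, `"jackknife"` or
#'   `"user-supplied"`.
#' @param se User-supplied standard error (returned unchanged when
#'   `method = "user-supplied"`).
#' @param n_boot Bootstrap replicates, default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return Nonnegative scalar standard error.
#' @examples
#' d <- parse_design("p x t x r")
#' tab <- simulate_scores(d, c(p = 30, t = 4, r = 2),
#'                        c(p = 4, "p*t" = 1, "p*r" = 1, "p*t*r" = 2),
#'                        seed = 2)
#' vc <- estimate_components(tab, d)
#' effectiveness_uncertainty(vc, dstudy_plan(d, c(t = 4, r = 2)),
#'                           seed = 3, n_boot = 200)
#' @export
effectiveness_uncertainty <- function(vc, plan,
                                      error_type = c("relative", "absolute"),
                                      method = c("parametric-bootstrap",
                                                 "jackknife",
                                                 "user-supplied"),
                                      se = NULL, n_boot = 1000, seed = NULL) {
  error_type <- match.arg(error_type)
  method <- match.arg(method)
  design <- attr(vc, "design")
  check_plan(design, plan)

  if (method == "user-supplied") {
    if (is.null(se)) stop("method 'user-supplied' needs 'se'", call. = FALSE)
    return(as.numeric(se))
  }
  if (anyNA(vc$df) || anyNA(vc$mean_square)) {
    stop(paste("resampling methods need df and mean squares:",
               "use components estimated by estimate_components()"),
         call. = FALSE)
  }
  if (all(vc$sigma2 == 0)) return(0) # no variance anywhere: coefficient fixed

  if (method == "parametric-bootstrap") {
    if (is.null(seed)) stop("a seed is required for the bootstrap", call. = FALSE)
    C <- attr(vc, "ems")
    Cinv <- solve(C)
    ms_star <- with_seed(seed, {
      vapply(seq_len(nrow(vc)), function(i) {
        vc$mean_square[i] * stats::rchisq(n_boot, vc$df[i]) / vc$df[i]
      }, numeric(n_boot))
    })
    sig_star <- tcrossprod(Cinv, ms_star) # effects x n_boot
    sig_star[sig_star < 0] <- 0           # truncation, as in estimation
    rownames(sig_star) <- vc$effect
    coefs <- coefficient_from_sigma(design, sig_star, plan, error_type)
    return(stats::sd(coefs, na.rm = TRUE))
  }

  # jackknife over object-of-measurement levels
  tab <- attr(vc, "scores")
  if (is.null(tab)) {
    stop("jackknife needs the score table; re-estimate with estimate_components()",
         call. = FALSE)
  }
  obj <- design$object
  n_obj <- attr(vc, "sizes")[[obj]]
  if (n_obj < 3) stop("jackknife needs >= 3 object levels", call. = FALSE)
  theta <- vapply(seq_len(n_obj), function(i) {
    sub <- tab[tab[[obj]] != i, , drop = FALSE]
    sub[[obj]] <- ifelse(sub[[obj]] > i, sub[[obj]] - 1L, sub[[obj]])
    vc_i <- estimate_components(sub, design)
    g_coefficient(vc_i, plan, error_type)$coefficient
  }, numeric(1))
  sqrt((n_obj - 1) / n_obj * sum((theta - mean(theta))^2))
}

# vectorized coefficient over columns of a sigma2 matrix (effects x draws)
coefficient_from_sigma <- function(design, sig, plan, error_type) {
  obj <- design$object
  obj_eff <- object_effect(design)
  w <- vapply(design$effects, function(e) {
    if (e$name == obj_eff) return(0)
    if (obj %in% e$full) return(1 / prod(plan$sizes[setdiff(e$full, obj)]))
    if (error_type == "absolute") return(1 / prod(plan$sizes[e$full]))
    0
  }, numeric(1))
  err <- as.numeric(crossprod(w[rownames(sig)], sig))
  objv <- sig[obj_eff, ]
  out <- objv / (objv + err)
  out[objv + err == 0] <- NA_real_
  out
}
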
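#' Define a D-study plan
#'
#' A plan fixes a projected number of levels for every facet other than the
#' object of measurement (for nested designs this includes the nesting
#' parents, e.g. the number of sites).  Sizes must be positive integers:
#' they are counts of stations, forms, raters, sites.
#'
#' @param design A `gcea_design`.
#' @param sizes Named vector of positive integers, one per non-object facet.
#' @param label Plan name used in reports.
#' @return An object of class `gcea_plan`.
#' @examples
#' d <- parse_design("p x t x r")
#' dstudy_plan(d, c(t = 8, r = 2), label = "two raters")
#' @export
dstudy_plan <- function(design, sizes, label = "plan") {
  stopifnot(inherits(design, "gcea_design"))
  needed <- setdiff(design$facet_names, design$object)
  if (is.null(names(sizes))) {
    stop("plan sizes must be named by facet", call. = FALSE)
  }
  missing <- setdiff(needed, names(sizes))
  if (length(missing)) {
    stop(sprintf("plan lacks size for facet(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(sizes), needed)
  if (length(extra)) {
    stop(sprintf("plan names unknown or object facet(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  sz <- sizes[needed]
  if (any(sz < 1)) stop("plan sizes must be >= 1", call. = FALSE)
  if (any(sz != round(sz))) {
    stop("plan sizes must be integers (counts of levels)", call. = FALSE)
  }
  structure(list(sizes = stats::setNames(as.numeric(sz), needed),
                 label = as.character(label)[1L],
                 design_formula = render_design(design)),
            class = "gcea_plan")
}

#' @export
print.gcea_plan <- function(x, ...) {
  cat("D-study plan '", x$label, "': ",
      paste(sprintf("n_%s = %g", names(x$sizes), x$sizes), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Projected error variance under a D-study plan
#'
#' Relative error sums, over every effect that involves the object of
#' measurement except the object effect itself, the component divided by the
#' product of the plan sizes of the effect's non-object facets.  Absolute
#' error adds every effect not involving the object, divided by the product
#' of the plan sizes of all its facets.
#'
#' @param vc A `gcea_vc` (estimated or assumed components).
#' @param plan A `gcea_plan` for the same design.
#' @param error_type `"relative"` or `"absolute"`.
#' @return Nonnegative scalar.
#' @examples
#' d <- parse_design("p x t x r")
#' vc <- as_variance_components(d, c(p = 7, "p*t" = 4, "p*r" = 2, "p*t*r" = 6))
#' error_variance(vc, dstudy_plan(d, c(t = 2, r = 1)), "relative")
#' @export
error_variance <- function(vc, plan, error_type = c("relative", "absolute")) {
  error_type <- match.arg(error_type)
  design <- attr(vc, "design")
  check_plan(design, plan)
  obj <- design$object
  obj_eff <- object_effect(design)
  sig <- stats::setNames(vc$sigma2, vc$effect)

  total <- 0
  for (e in design$effects) {
    if (e$name == obj_eff) next
    in_obj <- obj %in% e$full
    if (in_obj) {
      div <- prod(plan$sizes[setdiff(e$full, obj)])
      total <- total + sig[[e$name]] / div
    } else if (error_type == "absolute") {
      total <- total + sig[[e$name]] / prod(plan$sizes[e$full])
    }
  }
  unname(total)
}

check_plan <- function(design, plan) {
  if (!inherits(plan, "gcea_plan")) {
    stop("'plan' must be a gcea_plan (see dstudy_plan())", call. = FALSE)
  }
  if (!identical(plan$design_formula, render_design(design))) {
    stop("plan and variance components refer to different designs",
         call. = FALSE)
  }
  if (any(plan$sizes < 1)) stop("plan sizes must be >= 1", call. = FALSE)
  invisible(plan)
}

#' Generalizability / dependability coefficient for a plan
#'
#' The coefficient is the ratio of universe-score (object) variance to the
#' sum of object variance and the projected error variance:
#' \eqn{G = \sigma^2_p / (\sigma^2_p + \sigma^2_{error})}.  With relative
#' error this is the generalizability coefficient; with absolute error the
#' dependability coefficient used for criterion-referenced decisions.  For a
#' nested object of measurement (e.g. persons within sites) the object
#' variance is the nested component (\eqn{\sigma^2_{p:s}}).
#'
#' @inheritParams error_variance
#' @return An object of class `gcea_coef` with fields `coefficient`,
#'   `error_type`, `error_variance`, `object_variance`, `plan`.
#' @examples
#' d <- parse_design("p x t x r")
#' vc <- as_variance_components(d, c(p = 7, "p*t" = 4, "p*r" = 2, "p*t*r" = 6))
#' g_coefficient(vc, dstudy_plan(d, c(t = 2, r = 1)), "relative")
#' @export
g_coefficient <- function(vc, plan, error_type = c("relative", "absolute")) {
  error_type <- match.arg(error_type)
  design <- attr(vc, "design")
  obj_var <- vc$sigma2[vc$effect == object_effect(design)]
  err <- error_variance(vc, plan, error_type)
  if (obj_var == 0 && err == 0) {
    stop("coefficient undefined: object variance and error variance are both zero",
         call. = FALSE)
  }
  structure(list(coefficient = obj_var / (obj_var + err),
                 error_type = error_type,
                 error_variance = err,
                 object_variance = obj_var,
                 plan = plan),
            class = "gcea_coef")
}

#' @export
print.gcea_coef <- function(x, ...) {
  lab <- if (x$error_type == "relative") "generalizability (relative-error)"
         else "dependability (absolute-error)"
  cat(sprintf("%s coefficient = %.4f  [plan '%s': %s]\n", lab, x$coefficient,
              x$plan$label,
              paste(sprintf("n_%s=%g", names(x$plan$sizes), x$plan$sizes),
                    collapse = ", ")))
  cat(sprintf("  object variance %.6g, error variance %.6g\n",
              x$object_variance, x$error_variance))
  invisible(x)
}

#' Project coefficients over a set of candidate plans (the D study)
#'
#' @param vc A `gcea_vc`.
#' @param plans A list of `gcea_plan` objects (names override plan labels).
#' @param error_type `"relative"` or `"absolute"`.
#' @return data.frame with one row per plan: `plan`, one `n_<facet>` column
#'   per facet, `error_variance`, `coefficient`.  Row order follows `plans`.
#' @examples
#' d <- parse_design("p x t x r")
#' vc <- as_variance_components(d, c(p = 7, "p*t" = 4, "p*r" = 2, "p*t*r" = 6))
#' plans <- list(one = dstudy_plan(d, c(t = 4, r = 1)),
#'               two = dstudy_plan(d, c(t = 4, r = 2)))
#' dstudy_grid(vc, plans)
#' @export
dstudy_grid <- function(vc, plans, error_type = c("relative", "absolute")) {
  error_type <- match.arg(error_type)
  if (inherits(plans, "gcea_plan")) plans <- list(plans)
  if (!length(plans)) stop("need at least one plan", call. = FALSE)
  rows <- lapply(seq_along(plans), function(i) {
    p <- plans[[i]]
    if (!is.null(names(plans)) && nzchar(names(plans)[i])) {
      p$label <- names(plans)[i]
    }
    res <- g_coefficient(vc, p, error_type)
    out <- data.frame(plan = p$label, stringsAsFactors = FALSE)
    for (f in names(p$sizes)) out[[paste0("n_", f)]] <- p$sizes[[f]]
    out$error_variance <- res$error_variance
    out$coefficient <- res$coefficient
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "error_type") <- error_type
  out
}
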
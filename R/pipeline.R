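#' Read a run configuration file
#'
#' Run configurations are human-editable YAML documents declaring the design
#' formula, the score source (a file path, a simulation spec, or externally
#' supplied variance components), the error type, the candidate plans, the
#' cost schedule and the CEA block (comparators, effectiveness or cost
#' overrides, uncertainty distributions, WTP grid, draws, seed).  See
#' `system.file("extdata", "demo_config.yaml", package = "gcea")` for a
#' complete example.
#'
#' @param path Path to a YAML configuration.
#' @return A validated configuration list (class `gcea_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  config <- yaml::read_yaml(path)
  config$.dir <- dirname(normalizePath(path))
  validate_config(config)
}

#' Validate a run configuration
#'
#' Checks the whole configuration before any computation: the design formula
#' parses, referenced paths exist, every plan covers every non-object facet,
#' the cost schedule covers the plan facets (unless totals are supplied
#' directly), comparators refer to declared plans, effectiveness overrides
#' lie in `[0, 1]`, and a seed is present wherever a stochastic step is
#' enabled.  All problems are reported together.
#'
#' @param config A configuration list (as from [yaml::read_yaml()]).
#' @return The config, invisibly classed `gcea_config`.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  note <- function(fmt, ...) errs <<- c(errs, sprintf(fmt, ...))

  design <- NULL
  if (is.null(config$design)) {
    note("config lacks 'design' (a design formula)")
  } else {
    design <- tryCatch(parse_design(config$design), error = function(e) {
      note("bad design formula: %s", conditionMessage(e)); NULL
    })
  }

  has_scores <- !is.null(config$scores)
  if (has_scores) {
    if (!is.null(config$scores$path)) {
      p <- resolve_path(config$scores$path, config$.dir)
      if (!file.exists(p)) note("score file does not exist: %s", p)
    } else if (!is.null(config$scores$simulate)) {
      sim <- config$scores$simulate
      if (is.null(sim$seed)) note("simulation spec lacks 'seed'")
      if (is.null(sim$sizes)) note("simulation spec lacks 'sizes'")
      if (is.null(sim$components)) note("simulation spec lacks 'components'")
    } else {
      note("'scores' must contain 'path' or 'simulate'")
    }
  }

  plans <- config$plans
  if (!is.null(plans) && !is.null(design)) {
    for (nm in names(plans)) {
      tryCatch(dstudy_plan(design, unlist(plans[[nm]]), label = nm),
               error = function(e) note("plan '%s': %s", nm,
                                        conditionMessage(e)))
    }
  }

  cea_cfg <- config$cea
  if (!is.null(cea_cfg)) {
    for (role in c("base", "intervention")) {
      ref <- cea_cfg[[role]]
      if (is.null(ref)) {
        note("cea block lacks '%s'", role)
      } else if (!is.null(plans) && !ref %in% names(plans)) {
        note("cea %s '%s' is not a declared plan", role, ref)
      }
    }
    if (is.null(cea_cfg$seed)) note("cea block lacks 'seed' (required for the Monte-Carlo CEAC)")
    n_draws <- cea_cfg$n_draws %||% 10000
    if (n_draws < 1) note("cea n_draws must be >= 1")
    for (nm in names(cea_cfg$effectiveness)) {
      v <- cea_cfg$effectiveness[[nm]]
      if (v < 0 || v > 1) note("effectiveness override for '%s' outside [0, 1]", nm)
    }
    eff_known <- function(nm) !is.null(cea_cfg$effectiveness[[nm]])
    cmp <- c(cea_cfg$base, cea_cfg$intervention)
    if (!has_scores && is.null(config$components) &&
        !all(vapply(cmp, eff_known, logical(1)))) {
      note("no scores and no components: cea effectiveness values must be supplied for both comparators")
    }
  }

  costs <- config$costs
  if (is.null(costs)) {
    if (!is.null(cea_cfg)) note("config lacks 'costs'")
  } else {
    totals <- costs$totals
    if (is.null(costs$unit_costs) && is.null(totals)) {
      note("costs block needs 'unit_costs' or per-plan 'totals'")
    }
    if (!is.null(costs$unit_costs) && !is.null(plans)) {
      covered <- names(costs$unit_costs)
      for (nm in names(plans)) {
        if (!is.null(totals[[nm]])) next
        miss <- setdiff(names(plans[[nm]]), covered)
        if (length(miss)) {
          note("cost schedule lacks facet(s) %s used by plan '%s'",
               paste(miss, collapse = ", "), nm)
        }
      }
    }
  }

  if (length(errs)) {
    stop(paste0("invalid configuration:\n",
                paste0("  - ", errs, collapse = "\n")), call. = FALSE)
  }
  invisible(structure(config, class = c("gcea_config", class(config))))
}

resolve_path <- function(path, dir) {
  if (is.null(dir) || grepl("^(/|[A-Za-z]:)", path)) return(path)
  file.path(dir, path)
}

#' Run the full four-step analysis pipeline
#'
#' Executes, in order: (1) the G study (estimated from scores, simulated
#' scores, or externally supplied components), (2) cost aggregation per
#' plan, (3) the D study and ICER, and (4) the Monte-Carlo CEAC.  Writes one
#' report per step (both a delimited table and JSON) plus a combined
#' `summary.json` when `output_dir` is given; re-running an identical
#' configuration reproduces every machine-readable output byte for byte.  On
#' a step failure all partial outputs are removed and the failing step is
#' named.
#'
#' @param config A configuration list, or a path to a YAML config file.
#' @param output_dir Directory for reports (created if needed); `NULL`
#'   (default `config$output_dir`) returns reports without writing.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of step reports: `gstudy` (a `gcea_vc` or
#'   `NULL`), `costs`, `dstudy`, `cea` (a `cea_result`), `summary`.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_config(config)
  output_dir <- output_dir %||% config$output_dir
  say <- function(...) if (!quiet) message(sprintf(...))

  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)
  emit <- function(report, stem) {
    if (is.null(output_dir)) return(invisible(NULL))
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    for (ext in c(".tsv", ".json")) {
      p <- file.path(output_dir, paste0(stem, ext))
      write_report(report, p)
      written <<- c(written, p)
    }
  }

  design <- parse_design(config$design)
  error_type <- config$error_type %||% "absolute"
  say("design: %s (object of measurement: %s)", render_design(design),
      design$object)

  step <- "G study"
  reports <- tryCatch({
    # -- step 1: variance components ------------------------------------
    vc <- NULL
    if (!is.null(config$scores$path)) {
      p <- resolve_path(config$scores$path, config$.dir)
      say("step 1 (G study): scores from %s [md5 %s]", p,
          unname(tools::md5sum(p)))
      vc <- estimate_components(read_scores(p), design)
    } else if (!is.null(config$scores$simulate)) {
      sim <- config$scores$simulate
      say("step 1 (G study): simulating scores (seed %d)",
          as.integer(sim$seed))
      tab <- simulate_scores(design, unlist(sim$sizes),
                             unlist(sim$components),
                             grand_mean = sim$grand_mean %||% 0,
                             seed = sim$seed)
      vc <- estimate_components(tab, design)
    } else if (!is.null(config$components)) {
      say("step 1 (G study): using externally supplied components")
      vc <- as_variance_components(design, unlist(config$components))
    } else {
      say("step 1 (G study): skipped (effectiveness supplied directly)")
    }
    if (!is.null(vc)) emit(vc, "step1_gstudy")

    # -- step 2: cost aggregation ---------------------------------------
    step <- "cost aggregation"
    plans <- lapply(names(config$plans), function(nm) {
      dstudy_plan(design, unlist(config$plans[[nm]]), label = nm)
    })
    names(plans) <- names(config$plans)
    sched <- NULL
    if (!is.null(config$costs$unit_costs)) {
      sched <- cost_schedule(unlist(config$costs$unit_costs),
                             fixed_cost = config$costs$fixed_cost %||% 0,
                             currency = config$costs$currency %||% "GBP")
    }
    totals <- vapply(names(plans), function(nm) {
      override <- config$costs$totals[[nm]]
      if (!is.null(override)) as.numeric(override)
      else total_cost(sched, plans[[nm]])
    }, numeric(1))
    cost_tab <- data.frame(plan = names(plans), total_cost = unname(totals),
                           stringsAsFactors = FALSE)
    say("step 2 (costs): %s",
        paste(sprintf("%s=%s", cost_tab$plan,
                      format(cost_tab$total_cost, big.mark = ",")),
              collapse = ", "))
    emit(cost_tab, "step2_costs")

    # -- step 3: D study + ICER -----------------------------------------
    step <- "D study"
    eff_override <- config$cea$effectiveness
    eff <- vapply(names(plans), function(nm) {
      if (!is.null(eff_override[[nm]])) return(as.numeric(eff_override[[nm]]))
      if (is.null(vc)) {
        stop(sprintf("no effectiveness available for plan '%s'", nm),
             call. = FALSE)
      }
      g_coefficient(vc, plans[[nm]], error_type)$coefficient
    }, numeric(1))
    dstudy_tab <- data.frame(plan = names(plans),
                             total_cost = unname(totals),
                             effectiveness = unname(eff),
                             error_type = error_type,
                             stringsAsFactors = FALSE)
    say("step 3 (D study): %s",
        paste(sprintf("%s: E=%.4f", dstudy_tab$plan,
                      dstudy_tab$effectiveness), collapse = ", "))
    emit(dstudy_tab, "step3_dstudy")

    # -- step 4: ICER + CEAC --------------------------------------------
    step <- "CEA"
    cea_cfg <- config$cea
    econ <- function(nm) plan_economics(plans[[nm]], totals[[nm]], eff[[nm]])
    unc <- cea_cfg$uncertainty %||% list()
    wtp <- NULL
    if (!is.null(cea_cfg$wtp)) {
      w <- cea_cfg$wtp
      wtp <- if (is.list(w)) {
        seq(w$from %||% 0, w$to, length.out = (w$steps %||% 100) + 1L)
      } else as.numeric(w)
    }
    res <- ceac(econ(cea_cfg$intervention), econ(cea_cfg$base),
                wtp = wtp,
                n_draws = cea_cfg$n_draws %||% 10000,
                seed = cea_cfg$seed,
                rescale_unit = cea_cfg$rescale_unit %||% 0.01,
                eff_uncertainty = unc$effectiveness %||% list(dist = "degenerate"),
                cost_uncertainty = unc$cost %||% list(dist = "degenerate"))
    say("step 4 (CEA): ICER = %s per 1.0; %s per %g (displayed %s); seed %d",
        format(res$icer, big.mark = ","),
        format(res$icer_rescaled, big.mark = ","), res$rescale_unit,
        format(res$icer_display, big.mark = ","), res$seed)
    emit(res, "step4_cea")

    summary <- list(
      design = render_design(design),
      error_type = error_type,
      plans = dstudy_tab,
      base = cea_cfg$base,
      intervention = cea_cfg$intervention,
      delta_cost = res$delta_cost,
      delta_effectiveness = res$delta_effectiveness,
      icer = res$icer,
      icer_rescaled = res$icer_rescaled,
      icer_display = res$icer_display,
      rescale_unit = res$rescale_unit,
      n_draws = res$n_draws,
      seed = res$seed)
    if (!is.null(output_dir)) {
      p <- file.path(output_dir, "summary.json")
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      written <- c(written, p)
    }
    list(gstudy = vc, costs = cost_tab, dstudy = dstudy_tab, cea = res,
         summary = summary)
  }, error = function(e) {
    stop(sprintf("pipeline failed at step '%s': %s", step,
                 conditionMessage(e)), call. = FALSE)
  })
  ok <- TRUE
  invisible(reports)
}
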
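#' Simulate balanced rating data from known variance components
#'
#' Generates scores from the additive random-effects decomposition of the
#' design: one independent zero-mean normal draw per level combination of
#' each effect, with variance equal to that effect's true component; the
#' score is the grand mean plus the sum of the draws for its cell.  The
#' resulting table is balanced and fully reproducible from the seed.
#'
#' @param design A `gcea_design`.
#' @param sizes Named per-facet level counts (nested facets: levels per
#'   parent combination).
#' @param components Named nonnegative variance per effect (missing effects
#'   default to 0); names as in [effect_names()].
#' @param grand_mean Numeric scalar added to every score.
#' @param seed Integer seed (mandatory; simulation is a reproducibility
#'   contract).
#' @return Long-format balanced score table (data.frame: one integer level
#'   column per facet, then `score`).
#' @examples
#' d <- parse_design("p x t x r")
#' tab <- simulate_scores(d, c(p = 20, t = 4, r = 2),
#'                        c(p = 4, "p*t*r" = 1), seed = 1)
#' estimate_components(tab, d)
#' @export
simulate_scores <- function(design, sizes, components, grand_mean = 0,
                            seed) {
  stopifnot(inherits(design, "gcea_design"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for simulation", call. = FALSE)
  }
  sizes <- check_sizes(design, sizes)
  sigma2 <- complete_components(design, components)

  fn <- design$facet_names
  grid <- do.call(expand.grid,
                  c(lapply(fn, function(f) seq_len(sizes[[f]])),
                    list(KEEP.OUT.ATTRS = FALSE)))
  names(grid) <- fn

  score <- rep(as.numeric(grand_mean), nrow(grid))
  with_seed(seed, {
    for (e in design$effects) { # canonical effect order: reproducible
      s2 <- sigma2[[e$name]]
      key <- linear_index(grid, e$full, sizes)
      ndist <- prod(sizes[e$full])
      z <- stats::rnorm(ndist, 0, sqrt(s2)) # sd 0 still advances the stream
      score <- score + z[key]
    }
  })
  grid$score <- score
  grid
}

# evaluate an expression with a temporary RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates data from known components and re-estimates them,
#' reporting mean bias and root-mean-square error per component.  Used to
#' validate the estimator and to size designs.
#'
#' @inheritParams simulate_scores
#' @param n_replicates Number of simulated datasets (>= 2).
#' @return data.frame: `effect`, `true`, `mean_estimate`, `bias`, `rmse`.
#' @examples
#' d <- parse_design("p x i")
#' recovery_experiment(d, c(p = 30, i = 6), c(p = 2, "p*i" = 1),
#'                     n_replicates = 20, seed = 7)
#' @export
recovery_experiment <- function(design, sizes, components, grand_mean = 0,
                                n_replicates, seed) {
  stopifnot(inherits(design, "gcea_design"))
  if (missing(seed) || is.null(seed)) {
    stop("a seed is required for simulation", call. = FALSE)
  }
  if (n_replicates < 2) stop("need n_replicates >= 2", call. = FALSE)
  sigma2 <- complete_components(design, components)
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max - 1L, n_replicates))
  est <- vapply(rep_seeds, function(s) {
    tab <- simulate_scores(design, sizes, components, grand_mean, seed = s)
    estimate_components(tab, design)$sigma2
  }, numeric(length(design$effects)))
  est <- matrix(est, nrow = length(design$effects))
  mean_est <- rowMeans(est)
  truth <- unname(sigma2)
  data.frame(effect = names(design$effects),
             true = truth,
             mean_estimate = mean_est,
             bias = mean_est - truth,
             rmse = sqrt(rowMeans((est - truth)^2)),
             row.names = NULL, stringsAsFactors = FALSE)
}
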
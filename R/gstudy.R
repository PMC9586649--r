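#' Validate and normalize a balanced score table
#'
#' A score table is long-format: one column per facet (level labels), a final
#' numeric `score` column, and exactly one row per admissible index
#' combination.  Labels of a nested facet may be given either globally unique
#' (each person label occurs in one site only) or as within-parent indices
#' (1..n per site); globally unique labels are re-indexed within their parent
#' combination.
#'
#' @param scores A data.frame with one column per facet plus `score`.
#' @param design A `gcea_design`.
#' @return A normalized data.frame with integer level columns (attribute
#'   `sizes` carries the per-facet level counts).
#' @keywords internal
check_scores <- function(scores, design) {
  stopifnot(inherits(design, "gcea_design"))
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    stop("no data: score table is empty", call. = FALSE)
  }
  fn <- design$facet_names
  missing <- setdiff(c(fn, "score"), names(scores))
  if (length(missing)) {
    stop(sprintf("score table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(scores$score)) {
    stop("'score' column must be numeric", call. = FALSE)
  }
  if (anyNA(scores$score)) {
    stop("missing scores are not allowed (balanced data required)",
         call. = FALSE)
  }

  out <- scores[c(fn, "score")]
  # code each facet as consecutive integers; nested facets within parents
  for (f in fn) {
    anc <- design$facets[[f]]$nested_within
    lev <- factor(out[[f]])
    if (length(anc)) {
      parent_key <- interaction(out[anc], drop = TRUE, lex.order = TRUE)
      tab <- table(lev, parent_key) > 0
      if (all(rowSums(tab) == 1L)) {
        # globally unique labels: re-index within each parent combination
        idx <- integer(nrow(out))
        for (pk in levels(parent_key)) {
          rows <- parent_key == pk
          idx[rows] <- as.integer(factor(as.character(lev[rows])))
        }
        out[[f]] <- idx
        next
      }
    }
    out[[f]] <- as.integer(lev)
  }

  sizes <- vapply(out[fn], max, numeric(1))
  names(sizes) <- fn
  key <- linear_index(out, fn, sizes)
  if (anyDuplicated(key)) {
    dup <- out[which(duplicated(key))[1L], fn, drop = FALSE]
    stop(sprintf("unbalanced table: duplicated index combination (%s)",
                 paste(sprintf("%s=%s", fn, unlist(dup)), collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(out) != prod(sizes)) {
    report_imbalance(out, fn, sizes)
  }
  attr(out, "sizes") <- sizes
  out
}

report_imbalance <- function(out, fn, sizes) {
  key <- linear_index(out, fn, sizes)
  missing_key <- setdiff(seq_len(prod(sizes)), key)
  if (length(missing_key)) {
    combo <- decode_index(missing_key[1L], fn, sizes)
    stop(sprintf("unbalanced table: missing index combination (%s)",
                 paste(sprintf("%s=%d", fn, combo), collapse = ", ")),
         call. = FALSE)
  }
  stop("unbalanced table: row count does not match the full crossing",
       call. = FALSE)
}

# mixed-radix linear index of each row over the full facet crossing
linear_index <- function(out, fn, sizes) {
  idx <- rep(1, nrow(out))
  mult <- 1
  for (f in fn) {
    idx <- idx + (out[[f]] - 1) * mult
    mult <- mult * sizes[[f]]
  }
  idx
}

decode_index <- function(i, fn, sizes) {
  i <- i - 1
  combo <- integer(length(fn))
  for (k in seq_along(fn)) {
    combo[k] <- i %% sizes[[fn[k]]] + 1
    i <- i %/% sizes[[fn[k]]]
  }
  combo
}

#' Sums of squares for every effect of a balanced design
#'
#' Uses the classical T-term method for balanced designs: for each effect the
#' squared cell totals over its full index set are summed and divided by the
#' cell size, and sums of squares are obtained by inclusion-exclusion over
#' contained effects.  The sums of squares add up to the total sum of squares
#' about the grand mean.
#'
#' @param scores Balanced long-format score table (see [check_scores()]).
#' @param design A `gcea_design`.
#' @return data.frame with columns `effect`, `df`, `SS`, `MS`.
#' @examples
#' d <- parse_design("p x i")
#' tab <- expand.grid(p = 1:2, i = 1:2)
#' tab$score <- c(1, 3, 2, 4)
#' sums_of_squares(tab, d)
#' @export
sums_of_squares <- function(scores, design) {
  tab <- check_scores(scores, design)
  sizes <- attr(tab, "sizes")
  x <- tab$score
  n_tot <- length(x)
  t_mu <- sum(x)^2 / n_tot

  effs <- design$effects
  tt <- vapply(effs, function(e) {
    key <- linear_index(tab, e$full, sizes)
    totals <- rowsum(x, key)
    cell <- n_tot / prod(sizes[e$full])
    sum(totals^2) / cell
  }, numeric(1))

  ss <- numeric(length(effs))
  names(ss) <- names(effs)
  for (i in seq_along(effs)) {
    inner <- vapply(effs[seq_len(i - 1L)], function(b) {
      all(b$full %in% effs[[i]]$full)
    }, logical(1))
    ss[i] <- tt[i] - t_mu - sum(ss[seq_len(i - 1L)][inner])
  }
  tol <- 1e-10 * max(1, sum(x^2))
  ss[ss < 0 & ss > -tol] <- 0 # round-off guard: SS is nonnegative by theory

  df <- degrees_of_freedom(design, sizes)
  data.frame(effect = names(effs), df = as.numeric(df), SS = unname(ss),
             MS = unname(ifelse(df > 0, ss / df, NA_real_)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected-mean-square coefficient matrix
#'
#' For a balanced fully random design, the expected mean square of effect
#' \eqn{\alpha} is a linear combination of variance components:
#' \eqn{E[MS_\alpha] = \sum_{\beta \supseteq \alpha} c_{\alpha\beta}
#' \sigma^2_\beta}, where \eqn{c_{\alpha\beta}} is the product of the sizes
#' of all facets absent from \eqn{\beta}.  The matrix is triangular in the
#' canonical effect order and always invertible.
#'
#' @param design A `gcea_design`.
#' @param sizes Named per-facet level counts.
#' @return Square numeric matrix, rows = mean squares, columns = variance
#'   components, dimnames = effect names.
#' @examples
#' ems_coefficients(parse_design("p x t x r"), c(p = 10, t = 3, r = 2))
#' @export
ems_coefficients <- function(design, sizes) {
  stopifnot(inherits(design, "gcea_design"))
  sizes <- check_sizes(design, sizes)
  effs <- design$effects
  k <- length(effs)
  C <- matrix(0, k, k, dimnames = list(names(effs), names(effs)))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (all(effs[[a]]$full %in% effs[[b]]$full)) {
        C[a, b] <- prod(sizes[setdiff(design$facet_names, effs[[b]]$full)])
      }
    }
  }
  C
}

#' Estimate variance components (the G study)
#'
#' ANOVA (expected-mean-squares) estimation for balanced, fully random
#' designs: mean squares are computed per effect and the triangular EMS
#' system is solved exactly; negative solutions are truncated to zero after
#' solving, with the raw value retained.
#'
#' @param scores Balanced long-format score table.
#' @param design A `gcea_design`.
#' @return An object of class `gcea_vc`: a data.frame with columns `effect`,
#'   `df`, `mean_square`, `raw_estimate`, `truncated`, `sigma2`, `percent`,
#'   carrying the design, the facet sizes and the EMS matrix as attributes.
#' @examples
#' d <- parse_design("p x i")
#' tab <- expand.grid(p = 1:2, i = 1:2)
#' tab$score <- c(1, 3, 2, 4)
#' estimate_components(tab, d)
#' @export
estimate_components <- function(scores, design) {
  tab <- check_scores(scores, design)
  sizes <- attr(tab, "sizes")
  need2 <- design$facet_names[sizes < 2]
  if (length(need2)) {
    stop(sprintf("need >= 2 levels of %s to estimate its variance component",
                 paste(sprintf("'%s'", need2), collapse = ", ")),
         call. = FALSE)
  }
  anova_tab <- sums_of_squares(tab, design)
  C <- ems_coefficients(design, sizes)
  ms <- anova_tab$MS
  raw <- as.numeric(solve(C, ms))
  sigma2 <- pmax(0, raw)
  new_vc(design, sizes,
         df = anova_tab$df, mean_square = ms,
         raw = raw, sigma2 = sigma2,
         scores = tab)
}

new_vc <- function(design, sizes, df, mean_square, raw, sigma2,
                   scores = NULL) {
  effs <- design$effects
  total <- sum(sigma2)
  vc <- data.frame(
    effect = names(effs),
    df = df,
    mean_square = mean_square,
    raw_estimate = raw,
    truncated = raw < 0,
    sigma2 = sigma2,
    percent = if (total > 0) 100 * sigma2 / total else rep(0, length(sigma2)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(vc,
            design = design,
            sizes = sizes,
            ems = ems_coefficients(design, sizes),
            scores = scores,
            class = c("gcea_vc", "data.frame"))
}

#' Build a variance-component set from assumed values
#'
#' Wraps user-specified (e.g. true or published) variance components in the
#' same container that [estimate_components()] returns, for use in D studies
#' and simulations.  Effects not named default to zero.
#'
#' @param design A `gcea_design`.
#' @param sigma2 Named numeric vector of nonnegative components, names as in
#'   [effect_names()].
#' @param sizes Optional named facet sizes (needed only for resampling-based
#'   uncertainty methods).
#' @return A `gcea_vc` object.
#' @examples
#' d <- parse_design("p x t x r")
#' as_variance_components(d, c(p = 4, "p*t" = 1, "p*r" = 1, "p*t*r" = 2))
#' @export
as_variance_components <- function(design, sigma2, sizes = NULL) {
  stopifnot(inherits(design, "gcea_design"))
  sigma2 <- complete_components(design, sigma2)
  if (!is.null(sizes)) sizes <- check_sizes(design, sizes) else {
    sizes <- stats::setNames(rep(1, length(design$facet_names)),
                             design$facet_names)
  }
  k <- length(design$effects)
  new_vc(design, sizes,
         df = rep(NA_real_, k), mean_square = rep(NA_real_, k),
         raw = unname(sigma2), sigma2 = unname(sigma2))
}

# fill in zeros for unnamed effects, validate names and signs
complete_components <- function(design, sigma2) {
  en <- names(design$effects)
  if (is.null(names(sigma2))) {
    stop("variance components must be a named vector (names = effects)",
         call. = FALSE)
  }
  unknown <- setdiff(names(sigma2), en)
  if (length(unknown)) {
    stop(sprintf("unknown effect name(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(en, collapse = ", ")), call. = FALSE)
  }
  if (any(sigma2 < 0)) stop("variance components must be nonnegative",
                            call. = FALSE)
  out <- stats::setNames(rep(0, length(en)), en)
  out[names(sigma2)] <- sigma2
  out
}

#' @export
print.gcea_vc <- function(x, digits = 4, ...) {
  design <- attr(x, "design")
  cat("G-study variance components:", render_design(design), "\n")
  tab <- as.data.frame(x)
  num <- c("mean_square", "raw_estimate", "sigma2", "percent")
  tab[num] <- lapply(tab[num], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}
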
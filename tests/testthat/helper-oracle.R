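# Independent oracles used across the suite.  These deliberately avoid the
# package's sums-of-squares / EMS code paths: keys, degrees of freedom and
# T terms are recomputed here from the effect index sets alone.

# mixed-radix key of each grid row over a subset of facets
oracle_key <- function(grid, facets, sizes) {
  idx <- rep(1, nrow(grid))
  mult <- 1
  for (f in facets) {
    idx <- idx + (grid[[f]] - 1) * mult
    mult <- mult * sizes[[f]]
  }
  idx
}

oracle_df <- function(e, sizes) {
  prod(sizes[e$primary] - 1) * prod(sizes[e$nesting])
}

# Monte-Carlo mean squares: simulates R balanced datasets at once from true
# components and returns the empirical mean and standard error of each
# effect's mean square.
mc_mean_squares <- function(design, sizes, sigma2, R, seed) {
  effs <- design$effects
  fn <- design$facet_names
  grid <- do.call(expand.grid, lapply(fn, function(f) seq_len(sizes[[f]])))
  names(grid) <- fn
  N <- nrow(grid)

  set.seed(seed)
  X <- matrix(0, N, R)
  for (e in effs) {
    key <- oracle_key(grid, e$full, sizes)
    nd <- prod(sizes[e$full])
    s2 <- if (e$name %in% names(sigma2)) sigma2[[e$name]] else 0
    Z <- matrix(stats::rnorm(nd * R, 0, sqrt(s2)), nd, R)
    X <- X + Z[key, , drop = FALSE]
  }

  t_mu <- colSums(X)^2 / N
  tt <- lapply(effs, function(e) {
    key <- oracle_key(grid, e$full, sizes)
    totals <- rowsum(X, key)
    colSums(totals^2) / (N / nrow(totals))
  })
  ss <- vector("list", length(effs))
  for (i in seq_along(effs)) {
    inner <- 0
    for (j in seq_len(i - 1L)) {
      if (all(effs[[j]]$full %in% effs[[i]]$full)) inner <- inner + ss[[j]]
    }
    ss[[i]] <- tt[[i]] - t_mu - inner
  }
  ms <- mapply(function(s, e) s / oracle_df(e, sizes), ss, effs,
               SIMPLIFY = FALSE)
  list(mean = vapply(ms, mean, numeric(1)),
       se = vapply(ms, function(m) stats::sd(m) / sqrt(R), numeric(1)),
       effects = names(effs))
}

# closed-form relative-error generalizability coefficient for the fully
# crossed person x task x rater design
closed_form_g_ptr <- function(sp, spt, spr, sptr, nt, nr) {
  sp / (sp + spt / nt + spr / nr + sptr / (nr * nt))
}
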
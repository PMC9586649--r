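#' Parse a measurement-design formula
#'
#' A design formula declares the object of measurement and the facets of a
#' balanced measurement design, using `x` (or `*`) for crossing and `:` for
#' nesting (left nested within right).  The first identifier is the object of
#' measurement.  Nesting parents may be declared implicitly: `"p:s x f x st"`
#' defines four facets, with persons `p` nested within sites `s`, and `s`,
#' `f`, `st` mutually crossed.
#'
#' @param formula Character scalar, e.g. `"p x t x r"` or `"p:s x f x st"`.
#' @return An object of class `gcea_design` with components `facets` (a list
#'   of facet records: `name`, `nested_within`, `is_object_of_measurement`),
#'   `object` (name of the object of measurement), `effects` (the admissible
#'   variance-component effects, see [enumerate_effects()]) and
#'   `formula_text`.
#' @examples
#' d <- parse_design("p x t x r")
#' effect_names(d)
#' parse_design("p:s x f x st")
#' @seealso [enumerate_effects()], [degrees_of_freedom()], [render_design()]
#' @export
parse_design <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("design formula must be a single character string", call. = FALSE)
  }
  txt <- trimws(formula)
  if (!nzchar(txt)) stop("design formula is empty", call. = FALSE)

  terms <- split_crossing(txt)
  if (!length(terms)) stop("design formula is empty", call. = FALSE)

  facet_order <- character(0)
  nested_in <- list() # direct+transitive parents, ordered nearest first

  add_facet <- function(name, parents) {
    check_identifier(name)
    if (name %in% names(nested_in)) {
      old <- nested_in[[name]]
      if (!identical(old, parents) && length(parents)) {
        if (length(old)) {
          stop(sprintf("facet '%s' declared with conflicting nesting", name),
               call. = FALSE)
        }
        nested_in[[name]] <<- parents
      }
      return(invisible(NULL))
    }
    facet_order <<- c(facet_order, name)
    nested_in[[name]] <<- parents
    invisible(NULL)
  }

  object <- NULL
  heads <- character(0)
  for (i in seq_along(terms)) {
    if (grepl("(^:|:$|::)", terms[[i]])) {
      stop(sprintf("malformed term '%s': empty identifier around ':'",
                   terms[[i]]), call. = FALSE)
    }
    chain <- strsplit(terms[[i]], ":", fixed = TRUE)[[1]]
    chain <- trimws(chain)
    if (any(!nzchar(chain))) {
      stop(sprintf("malformed term '%s': empty identifier around ':'",
                   terms[[i]]), call. = FALSE)
    }
    if (anyDuplicated(chain)) {
      stop(sprintf("facet repeated within term '%s'", terms[[i]]),
           call. = FALSE)
    }
    if (chain[1L] %in% heads) {
      stop(sprintf("duplicate facet name '%s' in design formula", chain[1L]),
           call. = FALSE)
    }
    heads <- c(heads, chain[1L])
    # a:b:c means a nested in b, b nested in c
    for (j in seq_along(chain)) {
      nm <- chain[j]
      parents <- if (j < length(chain)) chain[(j + 1L):length(chain)] else character(0)
      add_facet(nm, parents)
    }
    if (i == 1L) object <- chain[1L]
  }

  # cycle check on the nesting relation
  for (nm in facet_order) {
    seen <- character(0)
    stack <- nested_in[[nm]]
    while (length(stack)) {
      cur <- stack[1L]; stack <- stack[-1L]
      if (cur == nm) {
        stop(sprintf("cyclic nesting involving facet '%s'", nm), call. = FALSE)
      }
      if (cur %in% seen) next
      seen <- c(seen, cur)
      if (!cur %in% names(nested_in)) {
        stop(sprintf("facet '%s' nested within undeclared facet '%s'",
                     nm, cur), call. = FALSE)
      }
      stack <- c(stack, nested_in[[cur]])
    }
  }

  facets <- lapply(facet_order, function(nm) {
    list(name = nm,
         nested_within = ancestors_of(nm, nested_in),
         is_object_of_measurement = identical(nm, object))
  })
  names(facets) <- facet_order

  design <- structure(
    list(facets = facets,
         facet_names = facet_order,
         object = object,
         effects = NULL,
         formula_text = txt),
    class = "gcea_design")
  design$effects <- enumerate_effects(design)
  design
}

# split a formula on the crossing operator; `*` always splits, a bare `x`
# splits when it stands alone between whitespace, else (whitespace-free
# input) every `x` is treated as the operator
split_crossing <- function(txt) {
  txt2 <- gsub("*", " x ", txt, fixed = TRUE)
  parts <- strsplit(txt2, "(?i)\\s+x\\s+", perl = TRUE)[[1]]
  if (length(parts) == 1L && !grepl("\\s", txt2) && grepl("x", txt2, fixed = TRUE)) {
    parts <- strsplit(txt2, "x", fixed = TRUE)[[1]]
  }
  trimws(parts[nzchar(trimws(parts))])
}

check_identifier <- function(name) {
  if (!grepl("^[A-Za-z][A-Za-z0-9_]*$", name) || tolower(name) == "x") {
    stop(sprintf("invalid facet identifier '%s'", name), call. = FALSE)
  }
  invisible(NULL)
}

# full ordered ancestor chain (nearest parent first)
ancestors_of <- function(name, nested_in) {
  out <- character(0)
  stack <- nested_in[[name]]
  while (length(stack)) {
    cur <- stack[1L]; stack <- stack[-1L]
    if (!cur %in% out) {
      out <- c(out, cur)
      stack <- c(stack, nested_in[[cur]])
    }
  }
  out
}

#' Enumerate the admissible variance-component effects of a design
#'
#' Effects correspond to the ancestrally closed, nonempty subsets of facets:
#' any effect containing a nested facet absorbs that facet's nesting parents
#' into its nesting-index part, and effects whose mean squares would be
#' confounded in a balanced design are merged (they canonicalize to the same
#' closed subset).  A fully crossed design with `k` facets plus the object of
#' measurement yields `2^(k+1) - 1` effects; the unique maximal effect is the
#' residual.
#'
#' @param design A `gcea_design`.
#' @return A list of effects, each with `primary` and `nesting` index sets
#'   (disjoint character vectors), the canonical `name` (primary indices
#'   joined by `*`, nesting indices after a `:`), `full` (their union) and
#'   `is_residual`.  Ordered by effect size, residual last.
#' @examples
#' vapply(enumerate_effects(parse_design("p x t x r")), `[[`, "", "name")
#' @export
enumerate_effects <- function(design) {
  stopifnot(inherits(design, "gcea_design"))
  fn <- design$facet_names
  k <- length(fn)
  if (k > 8L) stop("designs with more than 8 facets are not supported", call. = FALSE)
  anc <- lapply(design$facets, `[[`, "nested_within")

  seen <- character(0)
  effects <- list()
  for (mask in seq_len(2L^k - 1L)) {
    s <- fn[bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    full <- sort_by_design(union(s, unlist(anc[s], use.names = FALSE)), fn)
    key <- paste(full, collapse = "\r")
    if (key %in% seen) next
    seen <- c(seen, key)
    nesting <- full[vapply(full, function(f) {
      any(vapply(full, function(g) f %in% anc[[g]], logical(1)))
    }, logical(1))]
    primary <- setdiff(full, nesting)
    effects[[length(effects) + 1L]] <- list(
      primary = primary,
      nesting = nesting,
      full = full,
      name = effect_label(primary, nesting),
      is_residual = length(full) == k)
  }
  ord <- order(vapply(effects, function(e) length(e$full), integer(1)),
               vapply(effects, function(e) {
                 sum(2^(match(e$full, fn) - 1L))
               }, numeric(1)))
  effects <- effects[ord]
  names(effects) <- vapply(effects, `[[`, "", "name")
  effects
}

sort_by_design <- function(x, facet_names) x[order(match(x, facet_names))]

effect_label <- function(primary, nesting) {
  lab <- paste(primary, collapse = "*")
  if (length(nesting)) lab <- paste0(lab, ":", paste(nesting, collapse = "*"))
  lab
}

#' Effect names of a design
#'
#' @param design A `gcea_design`.
#' @return Character vector of canonical effect names (e.g. `"p"`, `"p*t"`,
#'   `"p*f:s"`), ordered with the residual last.
#' @export
effect_names <- function(design) {
  stopifnot(inherits(design, "gcea_design"))
  names(design$effects)
}

#' Degrees of freedom of balanced-design effects
#'
#' For a balanced design, the degrees of freedom of an effect equal the
#' product of `n - 1` over its primary indices times the product of `n` over
#' its nesting indices.  Sizes of nested facets are counts per parent
#' combination (e.g. persons per site).
#'
#' @param design A `gcea_design`.
#' @param sizes Named vector of positive integer level counts, one per facet.
#' @param effect Optional effect name; if `NULL` (default) all effects.
#' @return Named integer-valued vector of degrees of freedom.
#' @examples
#' degrees_of_freedom(parse_design("p x t x r"), c(p = 10, t = 3, r = 2))
#' @export
degrees_of_freedom <- function(design, sizes, effect = NULL) {
  stopifnot(inherits(design, "gcea_design"))
  sizes <- check_sizes(design, sizes)
  effs <- design$effects
  if (!is.null(effect)) {
    if (!effect %in% names(effs)) {
      stop(sprintf("unknown effect '%s'; see effect_names()", effect),
           call. = FALSE)
    }
    effs <- effs[effect]
  }
  vapply(effs, function(e) {
    prod(sizes[e$primary] - 1) * prod(sizes[e$nesting])
  }, numeric(1))
}

check_sizes <- function(design, sizes) {
  if (is.null(names(sizes)) || any(!nzchar(names(sizes)))) {
    stop("sizes must be a named vector (one entry per facet)", call. = FALSE)
  }
  missing <- setdiff(design$facet_names, names(sizes))
  if (length(missing)) {
    stop(sprintf("missing size for facet(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(sizes), design$facet_names)
  if (length(extra)) {
    stop(sprintf("sizes given for unknown facet(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  sz <- sizes[design$facet_names]
  if (any(sz < 1) || any(sz != round(sz))) {
    stop("facet sizes must be positive integers", call. = FALSE)
  }
  storage.mode(sz) <- "double"
  sz
}

#' Render a design back to its formula
#'
#' Produces a formula string that [parse_design()] maps back to an identical
#' design (same facets, nesting and effect list).
#'
#' @param design A `gcea_design`.
#' @return Character scalar.
#' @export
render_design <- function(design) {
  stopifnot(inherits(design, "gcea_design"))
  anc <- lapply(design$facets, `[[`, "nested_within")
  is_parent <- vapply(design$facet_names, function(f) {
    any(vapply(design$facet_names, function(g) f %in% anc[[g]], logical(1)))
  }, logical(1))
  heads <- unique(c(design$object, design$facet_names[!is_parent]))
  terms <- vapply(heads, function(f) {
    paste(c(f, anc[[f]]), collapse = ":")
  }, character(1))
  paste(terms, collapse = " x ")
}

#' @export
print.gcea_design <- function(x, ...) {
  cat("Measurement design:", render_design(x), "\n")
  cat("  object of measurement:", x$object, "\n")
  for (f in x$facets) {
    if (f$name == x$object) next
    nest <- if (length(f$nested_within)) {
      paste0(" (nested within ", paste(f$nested_within, collapse = ":"), ")")
    } else ""
    cat("  facet:", f$name, nest, "\n", sep = "")
  }
  cat("  effects (", length(x$effects), "): ",
      paste(names(x$effects), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: the effect whose variance is the universe-score variance
object_effect <- function(design) {
  obj <- design$object
  for (e in design$effects) {
    if (obj %in% e$primary && length(e$primary) == 1L &&
        setequal(e$full, c(obj, design$facets[[obj]]$nested_within))) {
      return(e$name)
    }
  }
  stop("internal error: object effect not found") # nocov
}
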
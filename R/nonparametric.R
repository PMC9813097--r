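#' Wilcoxon signed-rank test for paired amplitudes
#'
#' Two-sided paired test. Zero differences are dropped; for up to
#' `exact_max` nonzero pairs the p-value is exact, computed by full
#' enumeration of the `2^n` sign assignments of the absolute-difference
#' ranks (average ranks under ties), otherwise the tie-corrected normal
#' approximation is used.
#'
#' @param x,y Paired numeric vectors (e.g. immediate and entrained
#'   amplitudes of the same animals).
#' @param exact_max Largest number of nonzero pairs for which the exact
#'   enumeration is used (default 12).
#' @return A one-row tibble: `statistic` (V, sum of positive-difference
#'   ranks), `p_value`, `method`, `exact`, `n` (nonzero pairs).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 2, 2, 3)) # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 12) {
  if (length(x) != length(y)) abort("`x` and `y` must be paired.")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero.")
  if (n < 5) abort("need at least 5 nonzero pairs.")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= exact_max
  if (exact) {
    # distribution of V over all 2^n sign assignments, built by
    # successive doubling
    w_all <- 0
    for (ri in r) w_all <- c(w_all, w_all + ri)
    p <- min(1, 2 * min(mean(w_all <= v), mean(w_all >= v)))
  } else {
    p <- suppressWarnings(
      wilcox.test(d, exact = FALSE, correct = TRUE)
    )$p.value
  }
  tibble::tibble(
    statistic = v,
    p_value = p,
    method = "wilcoxon",
    exact = exact,
    n = n
  )
}

#' Mann-Whitney U test for two independent samples
#'
#' Two-sided unpaired rank-sum test. Exact p-value by enumeration for
#' small tie-free samples (guaranteed for nx + ny <= 12), tie-corrected
#' normal approximation otherwise. The reported statistic is U for the
#' first sample; swapping samples maps U to `nx * ny - U` and leaves the
#' p-value unchanged.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest combined sample size for an exact p-value
#'   (tie-free samples only; default 12).
#' @return A one-row tibble: `statistic` (U), `p_value`, `method`,
#'   `exact`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && (length(x) + length(y)) <= exact_max
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)
  )
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    method = "mann_whitney",
    exact = exact,
    n_x = length(x),
    n_y = length(y)
  )
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise comparisons
#'
#' Tie-corrected Kruskal-Wallis H across >= 3 groups, followed by Dunn's
#' z-tests on all pairs with Bonferroni-adjusted two-sided p-values.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping factor/vector parallel to `values` (>= 3 levels,
#'   each with >= 2 observations). Alternatively pass a named list of
#'   numeric vectors as `values` and omit `groups`.
#' @return A list of class `okr_kruskal_dunn`: `omnibus` (one-row tibble
#'   with `statistic` H, `df`, `p_value`) and `pairwise` (tibble with
#'   `group1`, `group2`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values) %||% as.character(seq_along(values)),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 3) abort("need at least 3 groups.")
  if (any(table(groups) < 2)) abort("each group needs at least 2 values.")

  kw <- kruskal.test(values, groups)

  n_total <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  mean_rank <- tapply(r, groups, mean)
  n_g <- as.numeric(table(groups))
  lev <- levels(groups)
  pairs <- utils::combn(seq_along(lev), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n_total * (n_total + 1) / 12 -
                  tie_sum / (12 * (n_total - 1))) *
                 (1 / n_g[i] + 1 / n_g[j]))
    (mean_rank[i] - mean_rank[j]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  pairwise <- tibble::tibble(
    group1 = lev[pairs[1, ]],
    group2 = lev[pairs[2, ]],
    z = unname(z),
    p_value = p_raw,
    p_adjusted = pmin(1, p.adjust(p_raw, method = "bonferroni"))
  )
  structure(
    list(
      omnibus = tibble::tibble(
        statistic = unname(kw$statistic),
        df = unname(kw$parameter),
        p_value = kw$p.value,
        method = "kruskal_dunn"
      ),
      pairwise = pairwise
    ),
    class = "okr_kruskal_dunn"
  )
}

#' @export
print.okr_kruskal_dunn <- function(x, ...) {
  cat(sprintf("<okr_kruskal_dunn> H = %.3f, df = %d, p = %.4g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @describeIn kruskal_dunn Pairwise Dunn comparisons, one row per pair.
#' @param x An `okr_kruskal_dunn` object.
#' @param ... Unused.
#' @export
tidy.okr_kruskal_dunn <- function(x, ...) x$pairwise

#' @describeIn kruskal_dunn One-row omnibus summary.
#' @export
glance.okr_kruskal_dunn <- function(x, ...) x$omnibus
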
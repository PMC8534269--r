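sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare one scalar indicator between two groups of cells
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) or Welch unequal-variance t
#' test, with group means and SEMs.  Groups whose pooled values are all
#' identical are degenerate for the rank test and flagged (`p = NA`).
#'
#' @param values_a,values_b Per-cell values (n >= 2 each).
#' @param test `"mann_whitney"` or `"welch_t"`.
#' @param labels Length-2 character vector of group labels.
#' @return A list of class `group_comparison`: `indicator`, `test`,
#'   `p_value`, `mean_a`, `sem_a`, `n_a`, likewise for b, `degenerate`.
#' @export
compare_scalar <- function(values_a, values_b,
                           test = c("mann_whitney", "welch_t"),
                           labels = c("a", "b")) {
  test <- match.arg(test)
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  pooled <- c(values_a, values_b)
  degenerate <- length(unique(pooled)) == 1
  p <- if (degenerate) {
    if (test == "welch_t") 1 else NA_real_
  } else if (test == "mann_whitney") {
    suppressWarnings(stats::wilcox.test(values_a, values_b,
                                        alternative = "two.sided"))$p.value
  } else {
    welch_p(values_a, values_b)
  }
  structure(list(indicator = NA_character_, test = test, p_value = p,
                 labels = labels,
                 mean_a = mean(values_a), sem_a = sem(values_a),
                 n_a = length(values_a),
                 mean_b = mean(values_b), sem_b = sem(values_b),
                 n_b = length(values_b),
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s (%s): %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d), p = %s\n",
              x$labels[1], x$labels[2], x$test, x$mean_a, x$sem_a, x$n_a,
              x$mean_b, x$sem_b, x$n_b, format.pval(x$p_value, digits = 3)))
  invisible(x)
}

# Welch two-sided p; identical group means with zero variance give t = 0,
# p = 1, instead of t.test()'s "data are essentially constant" error.
welch_p <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (mean(a) == mean(b)) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Per-portion comparison of density profiles between two groups
#'
#' One two-sided Welch (unequal-variance) t test per portion on per-cell
#' density values, the test used for per-portion topology comparisons.  Raw
#' p-values are reported (the original analysis reports raw per-portion
#' significance); a Benjamini-Hochberg adjusted column is added on request.
#'
#' @param profiles_a,profiles_b Numeric matrices (cells x 10) of per-cell
#'   density profiles.
#' @param adjust Add a BH-adjusted `p_adjusted` column?
#' @return Data frame with one row per portion (0..9): `portion`, `p_value`,
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`, and optionally
#'   `p_adjusted`.  Portions with fewer than 2 cells per group get `NA`.
#' @export
compare_profiles <- function(profiles_a, profiles_b, adjust = FALSE) {
  profiles_a <- as.matrix(profiles_a); profiles_b <- as.matrix(profiles_b)
  stopifnot(ncol(profiles_a) == 10, ncol(profiles_b) == 10)
  out <- data.frame(portion = 0:9, p_value = NA_real_,
                    mean_a = NA_real_, sem_a = NA_real_,
                    mean_b = NA_real_, sem_b = NA_real_,
                    n_a = NA_integer_, n_b = NA_integer_)
  for (k in 1:10) {
    a <- profiles_a[, k]; b <- profiles_b[, k]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    out$n_a[k] <- length(a); out$n_b[k] <- length(b)
    if (length(a) >= 2) { out$mean_a[k] <- mean(a); out$sem_a[k] <- sem(a) }
    if (length(b) >= 2) { out$mean_b[k] <- mean(b); out$sem_b[k] <- sem(b) }
    if (length(a) >= 2 && length(b) >= 2)
      out$p_value[k] <- welch_p(a, b)
  }
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
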
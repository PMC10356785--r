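#' Correlation of a cell-type frequency with inflammation severity
#'
#' Spearman (default) or Pearson correlation with a 95% confidence interval
#' from the Fisher z-transform (the rank-based standard error
#' `sqrt((1 + r^2/2)/(n - 3))` for Spearman) and a two-sided p-value. For
#' small samples (`n <= exact_n`) the p-value comes from full enumeration of
#' the permutation null of the coefficient; otherwise from the asymptotic
#' t-approximation.
#'
#' @param freq frequency table with one row per biopsy, a `severity` column
#'   in `[0, 1]` and one column per cell type; or pass two vectors via `x`
#'   and `y` directly.
#' @param type cell-type column to correlate.
#' @param method `"spearman"` or `"pearson"`.
#' @param severity_col severity column name.
#' @param conf_level confidence level (default 0.95).
#' @param exact_n largest n for which the exact permutation p is enumerated.
#' @return tibble: type, method, n, estimate, conf_low, conf_high, p_value,
#'   evaluable.
#' @export
severity_correlation <- function(freq, type, method = c("spearman", "pearson"),
                                 severity_col = "severity", conf_level = 0.95,
                                 exact_n = 8) {
  method <- match.arg(method)
  x <- freq[[type]]
  y <- freq[[severity_col]]
  abort_if(is.null(x), paste0("no column ", type))
  abort_if(is.null(y), paste0("no column ", severity_col))
  abort_if(any(y < 0 | y > 1), "severity must lie in [0, 1]")
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0 || n < 4) {
    return(tibble::tibble(type = type, method = method, n = n,
                          estimate = NA_real_, conf_low = NA_real_,
                          conf_high = NA_real_, p_value = NA_real_,
                          evaluable = FALSE))
  }
  r <- cor(x, y, method = method)
  se <- if (method == "spearman") sqrt((1 + r^2 / 2) / (n - 3))
        else 1 / sqrt(n - 3)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(atanh(r) + c(-1, 1) * zc * se)
  p <- if (n <= exact_n) {
    perms <- all_permutations(n)
    ref <- apply(perms, 1, function(pp) cor(x, y[pp], method = method))
    mean(abs(ref) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(type = type, method = method, n = n, estimate = r,
                 conf_low = ci[1], conf_high = ci[2], p_value = p,
                 evaluable = TRUE)
}

## all n! permutations of 1..n as rows (n <= 9 expected)
all_permutations <- function(n) {
  abort_if(n > 9, "refusing to enumerate more than 9! permutations")
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise comparisons
#'
#' Omnibus Kruskal-Wallis H across diagnostic groups, followed by Dunn's
#' rank-based pairwise z tests with tie correction and multiplicity
#' adjustment (Benjamini-Hochberg by default). Groups of size one take part
#' in the omnibus test but are flagged in the pairwise table.
#'
#' @param values numeric outcome (e.g. a cell-type frequency).
#' @param groups group label per observation.
#' @param p_adjust multiplicity adjustment method (see [stats::p.adjust()]).
#' @return list with `omnibus` (tibble: statistic, df, p_value) and
#'   `pairwise` (tibble: group1, group2, z, p_value, p_adjusted, small_n).
#' @export
group_compare <- function(values, groups, p_adjust = "BH") {
  abort_if(length(values) != length(groups), "values and groups must align")
  groups <- as.character(groups)
  kw <- kruskal.test(values, factor(groups))
  n <- length(values)
  r <- rank(values)
  t <- table(values)
  tie_corr <- sum(t^3 - t) / (12 * (n - 1))
  gstats <- tapply(r, groups, mean)
  gn <- table(groups)
  gl <- names(gn)
  pairs <- utils::combn(gl, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    s2 <- (n * (n + 1) / 12 - tie_corr) * (1 / gn[[a]] + 1 / gn[[b]])
    z[k] <- (gstats[[a]] - gstats[[b]]) / sqrt(s2)
    p_raw[k] <- 2 * pnorm(-abs(z[k]))
  }
  list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p_value = kw$p.value),
    pairwise = tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ],
                              z = z, p_value = p_raw,
                              p_adjusted = p.adjust(p_raw, p_adjust),
                              small_n = gn[pairs[1, ]] < 2 | gn[pairs[2, ]] < 2)
  )
}
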
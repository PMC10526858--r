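check_group_data <- function(values, labels, min_per_group = 2L) {
  if (length(values) != length(labels))
    stop_contract("values and labels differ in length")
  if (any(!is.finite(values)))
    stop_contract("all observations must be finite")
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop_contract("need at least 2 groups, got %d", length(tab))
  if (any(tab < min_per_group))
    stop_contract("every group needs >= %d observations (smallest has %d)",
                  min_per_group, min(tab))
  labels
}

new_test_report <- function(method, statistic, p, pairwise = NULL,
                            note = NULL) {
  structure(list(method = method, statistic = statistic, p = p,
                 pairwise = pairwise, note = note),
            class = "test_report")
}

#' @export
print.test_report <- function(x, digits = 4, ...) {
  cat(sprintf("<test_report> %s\n  statistic = %.*g, p = %.*g\n",
              x$method, digits, x$statistic, digits, x$p))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  if (!is.null(x$pairwise)) {
    cat("  pairwise comparisons:\n")
    print(x$pairwise, digits = digits, row.names = FALSE)
  }
  invisible(x)
}

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS test of the observations against a normal distribution
#' with the sample mean and SD plugged in (Lilliefors-style), with the
#' p-value taken from the asymptotic KS distribution.  Because the
#' reference parameters are estimated from the same sample, the p-value is
#' conservative and is flagged approximate; it is intended as a screen for
#' gross non-normality before choosing nonparametric group tests.
#'
#' @param values numeric vector, n >= 5, non-degenerate.
#' @return A `test_report` with the KS D statistic.
#' @examples
#' ks_normality(rnorm(100))
#' @export
ks_normality <- function(values) {
  if (length(values) < 5L)
    stop_contract("need at least 5 observations, got %d", length(values))
  if (any(!is.finite(values)))
    stop_contract("all observations must be finite")
  if (sd(values) == 0)
    stop_contract("zero-variance sample: normality test undefined")
  res <- suppressWarnings(
    ks.test(values, "pnorm", mean(values), sd(values)))
  new_test_report(
    method = "Kolmogorov-Smirnov normality (plug-in parameters)",
    statistic = unname(res$statistic), p = res$p.value,
    note = "approximate: reference parameters estimated from the sample")
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison of two or more groups, with tie
#' correction; the H statistic is referred to a chi-square distribution
#' with k - 1 degrees of freedom.
#'
#' @param values numeric observations.
#' @param labels group label per observation (>= 2 groups, each with >= 2
#'   observations).
#' @return A `test_report` with the H statistic.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
#'                rep(c("a", "b", "c"), each = 3))
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- check_group_data(values, labels)
  res <- kruskal.test(values, factor(labels))
  new_test_report(method = "Kruskal-Wallis rank sum test",
                  statistic = unname(res$statistic),
                  p = res$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise mean-rank comparisons on the pooled ranks, with tie-corrected
#' standard errors:
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' where `T = sum(t^3 - t)` over tie groups.  Two-sided p-values are
#' adjusted for the number of pairs; Holm is the default (it dominates
#' Bonferroni at the same familywise guarantee), with `"bonferroni"`
#' available as the conservative variant.
#'
#' @param values numeric observations.
#' @param labels group label per observation.
#' @param adjust one of `"holm"`, `"bonferroni"`, `"none"`.
#' @return A `test_report` whose `pairwise` data frame has columns
#'   `group_a`, `group_b`, `z`, `p`, `p_adjusted`.
#' @examples
#' dunn_posthoc(c(1, 2, 3, 14, 15, 16, 7, 8, 9),
#'              rep(c("a", "b", "c"), each = 3))
#' @export
dunn_posthoc <- function(values, labels, adjust = "holm") {
  ok <- c("holm", "bonferroni", "none")
  if (!is.character(adjust) || length(adjust) != 1L || !(adjust %in% ok))
    stop_contract("unknown adjust '%s'; options: %s",
                  as.character(adjust)[1], paste(ok, collapse = ", "))
  labels <- check_group_data(values, labels)
  n <- length(values)
  r <- rank(values)
  groups <- sort(unique(labels))
  mean_ranks <- vapply(groups, function(g) mean(r[labels == g]), numeric(1))
  sizes <- vapply(groups, function(g) sum(labels == g), numeric(1))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  var_core <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  pairs <- utils::combn(seq_along(groups), 2L)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(var_core * (1 / sizes[i] + 1 / sizes[j]))
    z[k] <- (mean_ranks[i] - mean_ranks[j]) / se
  }
  p <- 2 * pnorm(-abs(z))
  pw <- data.frame(group_a = groups[pairs[1L, ]],
                   group_b = groups[pairs[2L, ]],
                   z = z, p = p,
                   p_adjusted = p.adjust(p, method = adjust),
                   stringsAsFactors = FALSE)
  new_test_report(
    method = sprintf("Dunn's multiple comparison test (%s adjustment)",
                     adjust),
    statistic = max(abs(z)), p = min(pw$p_adjusted), pairwise = pw)
}

#' Omnibus test plus post-hoc in one call
#'
#' Convenience wrapper reproducing the standard nonparametric comparison
#' chain: Kruskal-Wallis omnibus, then Dunn's pairwise comparisons with
#' multiplicity adjustment.
#'
#' @inheritParams dunn_posthoc
#' @return A `test_report` carrying the Kruskal-Wallis H and p plus the
#'   Dunn pairwise table.
#' @export
compare_groups <- function(values, labels, adjust = "holm") {
  kw <- kruskal_wallis(values, labels)
  dn <- dunn_posthoc(values, labels, adjust = adjust)
  new_test_report(
    method = sprintf("Kruskal-Wallis + Dunn (%s)", adjust),
    statistic = kw$statistic, p = kw$p, pairwise = dn$pairwise)
}
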
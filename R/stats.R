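#' @title Selection-pressure and concordance statistics
#' @name stats_module
#' @description Exact binomial lower-tail tests of the proportion of
#'   expression-decreasing candidate markers (familial-AD genes vs other
#'   hereditary-disease genes, and vs the genome-wide 2:1 ratio of
#'   affinity-reducing to affinity-increasing regulatory SNPs), and the
#'   predicted-vs-measured concordance suite (Pearson r, Spearman R,
#'   Kendall tau, Goodman-Kruskal gamma, chi-square and Fisher exact test
#'   on a median-split 2x2 table).
NULL

#' Exact binomial lower-tail probability
#'
#' P(X <= k) for X ~ Binomial(n, p), computed by explicit log-space
#' summation of the exact terms.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials.
#' @param p success probability, strictly inside (0, 1).
#' @return the exact lower-tail probability.
#' @export
binomial_lower_tail <- function(k, n, p) {
  stopifnot(k >= 0, k <= n, n >= 1)
  if (p <= 0 || p >= 1)
    stop("degenerate-parameter error: p must be strictly inside (0, 1)")
  i <- 0:k
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(lt)
  min(1, exp(m) * sum(exp(lt - m)))
}

#' Selection-pressure tests on a marker count summary
#'
#' Tests whether the familial-AD gene group shows a deficit of
#' expression-decreasing candidate markers, (a) against the proportion
#' observed in the other-hereditary-disease group treated as a fixed
#' binomial p, and (b) against the genome-wide 2:1 ratio (p = 2/3). Both
#' are one-sided lower tails (the directional claim is a deficit). A
#' Fisher exact 2x2 companion p-value for the group-vs-group comparison is
#' reported for transparency.
#'
#' @param summary a `counts_summary` from [summarize_markers()].
#' @return list with `p_vs_other`, `p_vs_genome`, `p_fisher`, and the
#'   echoed inputs.
#' @export
selection_pressure_tests <- function(summary) {
  s <- summary
  if (s$n_significant_other == 0 || s$n_candidates_familial == 0)
    stop("zero denominators in counts summary")
  p_other <- s$n_decrease_other / s$n_significant_other
  p_vs_other <- binomial_lower_tail(s$n_decrease_familial,
                                    s$n_candidates_familial, p_other)
  p_vs_genome <- binomial_lower_tail(s$n_decrease_familial,
                                     s$n_candidates_familial, 2 / 3)
  tab <- matrix(c(s$n_decrease_familial,
                  s$n_candidates_familial - s$n_decrease_familial,
                  s$n_decrease_other,
                  s$n_significant_other - s$n_decrease_other), 2,
                dimnames = list(c("down", "not_down"),
                                c("familial", "other")))
  p_fisher <- fisher.test(tab, alternative = "less")$p.value
  list(p_vs_other = p_vs_other, p_vs_genome = p_vs_genome,
       p_fisher = p_fisher, table = tab, p_reference_other = p_other)
}

# concordant/discordant pair counts by explicit enumeration
.pair_counts <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
  }
  c(concordant = conc, discordant = disc)
}

#' Predicted-vs-measured concordance suite
#'
#' @param predicted,measured numeric vectors of equal length (>= 3 pairs,
#'   finite; typically predicted and measured K_D values).
#' @return object of class `concordance_report` with Pearson `r`, Spearman
#'   `R`, Kendall `tau` (tau-b, handling ties), Goodman-Kruskal `gamma`,
#'   `chi2` and `p_chi2` (chi-square without continuity correction) plus
#'   `p_fisher` on the 2x2 table from per-axis median splits, and
#'   `n_pairs`.
#' @export
concordance_suite <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured), length(predicted) >= 3,
            all(is.finite(predicted)), all(is.finite(measured)))
  if (var(predicted) == 0) stop("correlation undefined: predicted axis has zero variance")
  if (var(measured) == 0) stop("correlation undefined: measured axis has zero variance")
  pc <- .pair_counts(predicted, measured)
  gamma <- unname((pc["concordant"] - pc["discordant"]) /
                  (pc["concordant"] + pc["discordant"]))
  hx <- predicted > median(predicted)
  hy <- measured > median(measured)
  tab <- table(factor(hx, c(FALSE, TRUE)), factor(hy, c(FALSE, TRUE)))
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  structure(list(
    r = cor(predicted, measured),
    R = cor(predicted, measured, method = "spearman"),
    tau = cor(predicted, measured, method = "kendall"),
    gamma = gamma,
    chi2 = unname(chi$statistic), p_chi2 = chi$p.value,
    p_fisher = fisher.test(tab)$p.value,
    n_pairs = length(predicted), split_table = tab),
    class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(paste0("<concordance_report n=%d> r=%.3f R=%.3f tau=%.3f ",
                     "gamma=%.3f chi2=%.2f (p=%.3g) Fisher p=%.3g\n"),
              x$n_pairs, x$r, x$R, x$tau, x$gamma, x$chi2, x$p_chi2,
              x$p_fisher))
  invisible(x)
}
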
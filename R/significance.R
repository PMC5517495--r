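#' @title Z-statistic significance layer
#' @name significance
#' @description Turns a pair of affinity estimates (ancestral vs minor
#'   allele) into the decision layer: Z statistic (ratio of the ln K_D
#'   difference to the root of the sum of squared standard deviations),
#'   two-sided normal-tail significance alpha, heuristic rank A (best) to
#'   E (insignificant), and the expression-direction call. TBP affinity
#'   correlates positively with expression, so a K_D increase in the minor
#'   allele is called underexpression.
NULL

RANK_THRESHOLDS <- c(A = 1e-6, B = 1e-3, C = 1e-2, D = 0.05)

#' Z statistic of two affinity estimates
#' @param est_wt,est_minor objects of class `affinity_estimate`.
#' @return non-negative Z; symmetric in its arguments.
#' @export
z_score <- function(est_wt, est_minor) {
  if (est_wt$sd <= 0 || est_minor$sd <= 0)
    stop("standard deviations must be positive")
  abs(est_minor$ln_kd - est_wt$ln_kd) / sqrt(est_wt$sd^2 + est_minor$sd^2)
}

#' Two-sided normal-tail significance of a Z statistic
#' @param z non-negative Z.
#' @return alpha = 2 * (1 - Phi(z)), in (0, 1]; monotone decreasing in z.
#' @export
alpha_from_z <- function(z) {
  if (any(z < 0)) stop("z must be non-negative")
  # floor at the smallest positive double: extreme z underflows the normal
  # tail to 0, which would violate the (0, 1] contract downstream
  pmax(2 * pnorm(z, lower.tail = FALSE), .Machine$double.xmin)
}

#' Significance rank from alpha
#' @param alpha significance in (0, 1].
#' @return factor-free character rank: "A" (alpha <= 1e-6), "B" (<= 1e-3),
#'   "C" (<= 1e-2), "D" (<= 0.05), else "E".
#' @export
rank_from_alpha <- function(alpha) {
  stopifnot(all(alpha > 0), all(alpha <= 1))
  vapply(alpha, function(a) {
    hit <- which(a <= RANK_THRESHOLDS)
    if (length(hit)) names(RANK_THRESHOLDS)[hit[1]] else "E"
  }, "")
}

#' Ranks compatible with an integer-rounded printed Z
#'
#' Printed Z values are rounded to integers; a printed Z of 3 may stand for
#' any true Z in [z - tol, z + tol]. This returns every rank reachable
#' within that band, used when auditing printed Z/rank pairs.
#'
#' @param z printed (rounded) Z.
#' @param tol rounding half-width (default 0.5).
#' @return character vector of compatible ranks.
#' @export
ranks_compatible_with_z <- function(z, tol = 0.5) {
  lo <- max(0, z - tol); hi <- z + tol
  alphas <- alpha_from_z(c(hi, lo))     # alpha decreasing in z
  r <- rank_from_alpha(alphas)
  all_ranks <- c("A", "B", "C", "D", "E")
  span <- seq(match(r[1], all_ranks), match(r[2], all_ranks))
  all_ranks[span]
}

#' Compare the ancestral and minor allele of a promoter sequence
#'
#' Composes [estimate_affinity()], [z_score()], [alpha_from_z()] and
#' [rank_from_alpha()]. The decision is `insignificant` iff the rank is E;
#' otherwise a K_D increase (delta ln K_D > 0) maps to `underexpression`
#' and a decrease to `overexpression`.
#'
#' @param seq_wt,seq_minor DNA strings (>= 15 nt).
#' @param model a `tbp_model`.
#' @return object of class `comparison_result` with fields `z`, `alpha`,
#'   `decision`, `rank`, `delta_ln_kd`, `kd_wt_nM`, `kd_mut_nM`.
#' @export
compare_alleles <- function(seq_wt, seq_minor, model = default_model()) {
  ew <- estimate_affinity(seq_wt, model)
  em <- estimate_affinity(seq_minor, model)
  z <- z_score(ew, em)
  alpha <- alpha_from_z(z)
  rank <- rank_from_alpha(alpha)
  delta <- em$ln_kd - ew$ln_kd
  decision <- if (rank == "E") "insignificant"
              else if (delta > 0) "underexpression" else "overexpression"
  structure(list(z = z, alpha = alpha, decision = decision, rank = rank,
                 delta_ln_kd = delta, kd_wt_nM = ew$kd_nM,
                 kd_mut_nM = em$kd_nM),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(paste0("<comparison_result> Kd %.3g -> %.3g nM, ",
                     "Z = %.2f, alpha = %.3g, rank %s, %s\n"),
              x$kd_wt_nM, x$kd_mut_nM, x$z, x$alpha, x$rank, x$decision))
  invisible(x)
}
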
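#' @title Three-component TBP-promoter affinity model
#' @name affinity_model
#' @description Estimates -ln K_D (K_D in nM) of the TBP-promoter complex
#'   from three components mirroring the steps of TBP binding: (i) TBP
#'   slides along the DNA (dinucleotide sliding-affinity profile), (ii) TBP
#'   stops at a TATA/TBP-binding site (position-weight-matrix log-odds of
#'   the best 15-bp window), and (iii) the complex is fixed by bending of
#'   the DNA helix (dinucleotide bending-propensity profile). The three
#'   scores enter a linear predictor whose coefficients are calibrated by
#'   ordinary least squares against published K_D anchors.
NULL

PWM_WIDTH <- 15L
CONTEXT_WIDTH <- 26L

#' Build the default TATA-box position weight matrix
#'
#' A 15-column log-odds matrix embedding the TATAWAWR consensus (W = A/T,
#' R = A/G) at columns 7-14, with a pseudocount against a uniform
#' background; the other columns are background-neutral (log-odds 0). The
#' asymmetric embedding (6 upstream, 1 downstream column) keeps the best
#' window of a TATA box at position -30 inside a [-70; -20] region.
#'
#' @param pseudocount pseudocount added per base (default 0.25).
#' @return 4 x 15 numeric matrix, rows named A, C, G, T.
#' @export
build_default_pwm <- function(pseudocount = 0.25) {
  bases <- c("A", "C", "G", "T")
  consensus <- c("T", "A", "T", "A", "W", "A", "W", "R")
  counts <- matrix(0, 4, PWM_WIDTH, dimnames = list(bases, NULL))
  for (j in seq_along(consensus)) {
    col <- 6L + j
    counts[, col] <- switch(consensus[j],
      W = c(A = 0.5, C = 0, G = 0, T = 0.5),
      R = c(A = 0.5, C = 0, G = 0.5, T = 0),
      setNames(as.numeric(bases == consensus[j]), bases))
  }
  tot <- colSums(counts)
  p <- sweep(counts + pseudocount, 2, tot + 4 * pseudocount, "/")
  log(p / 0.25)
}

# Dinucleotide sliding-affinity scale: nearest-neighbour duplex stability
# (unified NN free energies, kcal/mol); less stable steps ease sliding and
# local opening. Calibration absorbs affine rescaling, so only the relative
# profile matters.
default_slide_table <- function() {
  c(AA = -1.00, AC = -1.44, AG = -1.28, AT = -0.88,
    CA = -1.45, CC = -1.84, CG = -2.17, CT = -1.28,
    GA = -1.30, GC = -2.24, GG = -1.84, GT = -1.44,
    TA = -0.58, TC = -1.30, TG = -1.45, TT = -1.00)
}

# Dinucleotide bending-propensity scale: propeller-twist compilation
# (degrees); strongly negative values mark rigid A-tract-like steps whose
# deformation TBP exploits when bending the helix toward 90 degrees.
default_bend_table <- function() {
  c(AA = -18.66, AC = -13.10, AG = -14.00, AT = -15.01,
    CA = -9.45,  CC = -8.11,  CG = -10.03, CT = -14.00,
    GA = -13.48, GC = -11.08, GG = -8.11,  GT = -13.10,
    TA = -11.85, TC = -13.48, TG = -9.45,  TT = -18.66)
}

#' Default model tables (PWM + dinucleotide scales)
#' @param pseudocount PWM pseudocount.
#' @return list with elements `pwm`, `slide`, `bend`.
#' @export
default_model_tables <- function(pseudocount = 0.25) {
  list(pwm = build_default_pwm(pseudocount),
       slide = default_slide_table(),
       bend = default_bend_table())
}

#' Compute the three component scores of a sequence
#'
#' @param sequence DNA string, at least 15 nt.
#' @param tables model tables as from [default_model_tables()].
#' @return list of class `component_scores` with `pwm_max` (max log-odds
#'   over all 15-bp windows on the given strand), `slide_mean`, `bend_mean`
#'   (means of the dinucleotide tables over the full sequence), and
#'   `best_window_offset` (0-based offset of the best PWM window).
#' @export
component_scores <- function(sequence, tables = default_model_tables()) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n < PWM_WIDTH) stop("too short for site scan (need >= ", PWM_WIDTH,
                          " nt, got ", n, ")")
  if (grepl("[^ACGT]", s)) stop("non-ACGT character in sequence")
  ch <- strsplit(s, "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  nwin <- n - PWM_WIDTH + 1L
  win_scores <- vapply(seq_len(nwin), function(i) {
    sum(tables$pwm[cbind(idx[i:(i + PWM_WIDTH - 1L)], seq_len(PWM_WIDTH))])
  }, 0)
  best <- which.max(win_scores)
  din <- paste0(ch[-n], ch[-1])
  structure(list(pwm_max = win_scores[best],
                 slide_mean = mean(tables$slide[din]),
                 bend_mean = mean(tables$bend[din]),
                 best_window_offset = best - 1L),
            class = "component_scores")
}

# linear predictor for -ln K_D on a (sub)sequence
.predict_minus_ln_kd <- function(sequence, model) {
  cs <- component_scores(sequence, model$tables)
  model$a0 + model$a_pwm * cs$pwm_max + model$a_slide * cs$slide_mean +
    model$a_bend * cs$bend_mean
}

#' Estimate TBP binding affinity of a sequence
#'
#' For sequences longer than 26 nt the predictor is minimized over K_D
#' across all 26-bp subwindows (best binding site wins; leftmost on ties),
#' so extending a region can only keep or improve the reported affinity.
#'
#' @param sequence DNA string (>= 15 nt).
#' @param model a `tbp_model` as from [calibrate()] or [default_model()].
#' @return object of class `affinity_estimate`: `ln_kd` (ln nM), `sd`
#'   (homoscedastic per-allele standard deviation, ln-nM units), `kd_nM`,
#'   and `window_offset` (0-based offset of the chosen 26-bp subwindow).
#' @export
estimate_affinity <- function(sequence, model = default_model()) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n <= CONTEXT_WIDTH) {
    mlk <- .predict_minus_ln_kd(s, model)
    off <- 0L
  } else {
    offs <- 0:(n - CONTEXT_WIDTH)
    vals <- vapply(offs, function(o)
      .predict_minus_ln_kd(substr(s, o + 1L, o + CONTEXT_WIDTH), model), 0)
    k <- which.max(vals)           # max -ln K_D == min K_D; leftmost tie
    mlk <- vals[k]; off <- offs[k]
  }
  structure(list(ln_kd = -mlk, sd = model$sigma0, kd_nM = exp(-mlk),
                 window_offset = off),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("<affinity_estimate> K_D = %.3g nM (ln K_D = %.3f +/- %.3f)\n",
              x$kd_nM, x$ln_kd, x$sd))
  invisible(x)
}

#' Calibrate the affinity model on K_D anchors
#'
#' Fits the linear predictor of -ln K_D on the three component scores by
#' ordinary least squares, and sets the per-comparison noise scale `sigma0`
#' so that the Z statistic computed from a pair of estimates reproduces the
#' printed Z values in median ratio 1: with homoscedastic per-allele
#' standard deviation `sigma0`, Z = |delta ln K_D| / (sigma0 * sqrt(2)),
#' hence sigma0 * sqrt(2) is the median over `z_anchors` of
#' |delta ln K_D| / Z.
#'
#' @param anchors data.frame with columns `sequence` and `kd_nM` (>= 10
#'   rows spanning at least a 10-fold K_D range).
#' @param z_anchors data.frame with columns `delta_ln_kd` (absolute) and
#'   `z` (printed, > 0).
#' @param tables model tables.
#' @return object of class `tbp_model` with coefficients, `resid_sd`,
#'   `sigma0`, fit metrics, and `provenance = "calibrated"`.
#' @export
calibrate <- function(anchors, z_anchors, tables = default_model_tables()) {
  if (nrow(anchors) < 10L)
    stop("calibration requires at least 10 anchors, got ", nrow(anchors))
  if (max(anchors$kd_nM) / min(anchors$kd_nM) < 10)
    stop("anchors must span at least a 10-fold K_D range")
  cs <- lapply(anchors$sequence, component_scores, tables = tables)
  X <- cbind(1,
             pwm = vapply(cs, `[[`, 0, "pwm_max"),
             slide = vapply(cs, `[[`, 0, "slide_mean"),
             bend = vapply(cs, `[[`, 0, "bend_mean"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("calibration error: rank-deficient design; collinear component(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
  }
  y <- -log(anchors$kd_nM)
  beta <- qr.coef(qrX, y)
  resid <- y - X %*% beta
  resid_sd <- sqrt(sum(resid^2) / (nrow(X) - ncol(X)))
  ok <- z_anchors$z > 0 & is.finite(z_anchors$delta_ln_kd)
  sigma0 <- median(z_anchors$delta_ln_kd[ok] / z_anchors$z[ok]) / sqrt(2)
  stopifnot(sigma0 > 0, resid_sd > 0)
  model <- structure(list(
    tables = tables,
    a0 = unname(beta[1]), a_pwm = unname(beta[2]),
    a_slide = unname(beta[3]), a_bend = unname(beta[4]),
    resid_sd = resid_sd, sigma0 = sigma0,
    provenance = "calibrated", n_anchors = nrow(anchors)),
    class = "tbp_model")
  fitted <- as.vector(X %*% beta)
  model$fit_spearman <- cor(fitted, y, method = "spearman")
  model$fit_pearson <- cor(fitted, y)
  model
}

#' @export
print.tbp_model <- function(x, ...) {
  cat(sprintf(paste0("<tbp_model %s> -lnKd = %.3f + %.3f*pwm + %.3f*slide",
                     " + %.3f*bend  (resid_sd %.3f, sigma0 %.4f)\n"),
              x$provenance, x$a0, x$a_pwm, x$a_slide, x$a_bend,
              x$resid_sd, x$sigma0))
  invisible(x)
}

# ---- plain-text model config ------------------------------------------------

#' Write a model (tables + coefficients) to a plain-text config
#' @param model a `tbp_model`.
#' @param path output path.
#' @export
write_model_config <- function(model, path) {
  num <- function(x) format(x, digits = 17)
  lines <- c(
    "# TBP-promoter affinity model configuration (key = value).",
    "# PWM rows are log-odds vs a uniform background; dinucleotide tables",
    "# are the sliding (nearest-neighbour duplex stability, kcal/mol) and",
    "# bending (propeller-twist, degrees) profiles; coefficients are the",
    "# OLS calibration against the packaged K_D anchors.",
    paste("provenance =", model$provenance),
    paste("n_anchors =", model$n_anchors))
  for (b in rownames(model$tables$pwm))
    lines <- c(lines, paste0("pwm.", b, " = ",
                             paste(num(model$tables$pwm[b, ]), collapse = " ")))
  for (d in names(model$tables$slide))
    lines <- c(lines, paste0("slide.", d, " = ", num(model$tables$slide[[d]])))
  for (d in names(model$tables$bend))
    lines <- c(lines, paste0("bend.", d, " = ", num(model$tables$bend[[d]])))
  for (k in c("a0", "a_pwm", "a_slide", "a_bend", "resid_sd", "sigma0",
              "fit_spearman", "fit_pearson"))
    lines <- c(lines, paste(k, "=", num(model[[k]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model config written by [write_model_config()]
#' @param path config path.
#' @return a `tbp_model`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  getnum <- function(k) as.numeric(vals[keys == k])
  pwm <- t(vapply(c("A", "C", "G", "T"), function(b)
    as.numeric(strsplit(vals[keys == paste0("pwm.", b)], " +")[[1]]),
    numeric(PWM_WIDTH)))
  dins <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                          function(a, b) paste0(a, b)))
  dins <- sort(dins)
  slide <- setNames(vapply(dins, function(d) getnum(paste0("slide.", d)), 0),
                    dins)
  bend <- setNames(vapply(dins, function(d) getnum(paste0("bend.", d)), 0),
                   dins)
  structure(list(
    tables = list(pwm = pwm, slide = slide, bend = bend),
    a0 = getnum("a0"), a_pwm = getnum("a_pwm"),
    a_slide = getnum("a_slide"), a_bend = getnum("a_bend"),
    resid_sd = getnum("resid_sd"), sigma0 = getnum("sigma0"),
    fit_spearman = getnum("fit_spearman"), fit_pearson = getnum("fit_pearson"),
    provenance = vals[keys == "provenance"],
    n_anchors = as.integer(vals[keys == "n_anchors"])),
    class = "tbp_model")
}

#' Load the packaged frozen model
#' @return the `tbp_model` shipped with the package (calibrated provenance).
#' @export
default_model <- function() {
  path <- system.file("extdata", "model_config.txt", package = "tatasnp",
                      mustWork = TRUE)
  read_model_config(path)
}

#' MD5 hash of the packaged model config (for run headers)
#' @return character md5 string.
#' @export
model_config_hash <- function() {
  path <- system.file("extdata", "model_config.txt", package = "tatasnp",
                      mustWork = TRUE)
  unname(tools::md5sum(path))
}
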
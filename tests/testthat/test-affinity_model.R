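test_that("component_scores: exhaustive window oracle and determinism", {
  tab <- default_model_tables()
  odn <- "cgcggcgctctatataagtgggcagt"   # TATA-consensus-bearing 26-mer
  cs <- component_scores(odn, tab)

  # oracle: enumerate every 15-bp window score directly from the matrix
  ch <- strsplit(toupper(odn), "")[[1]]
  idx <- match(ch, c("A", "C", "G", "T"))
  win <- vapply(1:(length(ch) - 14L), function(i)
    sum(tab$pwm[cbind(idx[i:(i + 14L)], 1:15)]), 0)
  expect_equal(cs$pwm_max, max(win))
  expect_equal(cs$best_window_offset, which.max(win) - 1L)
  # the best window covers the TATATAA core (positions 11..17)
  expect_true(cs$best_window_offset + 1L <= 11L &&
              cs$best_window_offset + 15L >= 17L)
  # dinucleotide means against direct averaging
  din <- paste0(ch[-length(ch)], ch[-1])
  expect_equal(cs$slide_mean, mean(tab$slide[din]))
  expect_equal(cs$bend_mean, mean(tab$bend[din]))

  expect_identical(component_scores(odn, tab), cs)  # deterministic
  expect_error(component_scores("ACGTACGTACGTAC", tab), "too short")
})

test_that("a G/C-only sequence scores below the consensus window", {
  tab <- default_model_tables()
  gc26 <- paste(rep(c("g", "c"), 13), collapse = "")
  cs_gc <- component_scores(gc26, tab)
  cs_tata <- component_scores("cgcggcgctctatataagtgggcagt", tab)
  expect_lt(cs_gc$pwm_max, cs_tata$pwm_max)
})

test_that("estimate_affinity is positive and minimizes over subwindows", {
  m <- the_model()
  odn <- "cgcggcgctctatataagtgggcagt"
  e26 <- estimate_affinity(odn, m)
  expect_gt(e26$kd_nM, 0)
  expect_gt(e26$sd, 0)

  # embedding the 26-mer in a [-70;-20]-sized region can only keep or
  # lower the minimized K_D (more windows available)
  set.seed(3)
  for (i in 1:10) {
    region <- paste0(random_dna(12), odn, random_dna(13))
    expect_lte(estimate_affinity(region, m)$kd_nM, e26$kd_nM + 1e-12)
  }
})

test_that("refitting on the packaged anchors reproduces the frozen model", {
  rows <- the_fixture()
  ca <- calibration_anchors(rows)
  expect_gte(nrow(ca$anchors), 10L)
  expect_gte(max(ca$anchors$kd_nM) / min(ca$anchors$kd_nM), 10)
  refit <- calibrate(ca$anchors, ca$z_anchors)
  frozen <- the_model()
  for (k in c("a0", "a_pwm", "a_slide", "a_bend", "resid_sd", "sigma0"))
    expect_equal(refit[[k]], frozen[[k]], tolerance = 1e-12, label = k)

  # noise scale from printed (K_D pair, Z) rows: sigma0*sqrt(2) is the
  # median |delta ln K_D| / Z; e.g. the 5 -> 29 nM pair with Z = 34
  # contributes |ln(29/5)|/34 = 0.0517
  za <- ca$z_anchors
  expect_equal(abs(log(29 / 5)) / 34, 0.05170, tolerance = 1e-3)
  ok <- za$z > 0
  expect_equal(frozen$sigma0, median(za$delta_ln_kd[ok] / za$z[ok]) / sqrt(2),
               tolerance = 1e-12)
})

test_that("calibration rejects degenerate designs", {
  anchors <- data.frame(
    sequence = rep("cgcggcgctctatataagtgggcagt", 12),
    kd_nM = c(1, 2, 4, 8, 16, 32, 3, 5, 7, 9, 11, 13))
  za <- data.frame(delta_ln_kd = rep(0.5, 5), z = rep(10, 5))
  expect_error(calibrate(anchors, za), "rank-deficient")
  expect_error(calibrate(anchors[anchors$kd_nM <= 8, ], za),
               "at least")  # too few anchors
})

test_that("model config round-trips through the plain-text format", {
  m <- the_model()
  tf <- tempfile(fileext = ".txt")
  write_model_config(m, tf)
  m2 <- read_model_config(tf)
  expect_equal(m2$tables$pwm, m$tables$pwm, ignore_attr = TRUE)
  expect_equal(m2$tables$slide, m$tables$slide)
  expect_equal(m2$tables$bend, m$tables$bend)
  for (k in c("a0", "a_pwm", "a_slide", "a_bend", "resid_sd", "sigma0"))
    expect_equal(m2[[k]], m[[k]], label = k)
  expect_match(model_config_hash(), "^[0-9a-f]{32}$")
})

test_that("anchor fit quality matches the frozen regression values", {
  rows <- the_fixture()
  m <- the_model()
  expect_gt(m$a_pwm, 0)
  # Spearman correlation of model -lnKd vs printed -lnKd over all anchors,
  # pinned at freeze with +/- 0.02
  expect_equal(m$fit_spearman, 0.7100265, tolerance = 0.02)
  # direction-sign concordance over the significant wt/minor pairs with
  # printed sequence (83 of the 84; one deletion's wt is not printed):
  # pinned at freeze, zero flips allowed
  sig <- which(rows$tbp_site_effect == "significant" & rows$context_available)
  pred <- vapply(sig, function(i)
    estimate_affinity(rows$context_mut[i], m)$ln_kd -
      estimate_affinity(rows$context_wt[i], m)$ln_kd, 0)
  concordant <- ifelse(pred > 0, "down", "up") == rows$direction[sig]
  expect_length(concordant, 83L)
  expect_equal(sum(concordant), 68L)
})

test_that("destroying a planted consensus element never lowers K_D", {
  m <- the_model()
  set.seed(7)
  for (i in 1:50) {
    s <- random_dna(51, gc = 0.4)
    substr(s, 30, 37) <- "tataaaag"
    s2 <- s
    substr(s2, 30, 37) <- "gcgccccg"   # GC complement of the element
    expect_gte(estimate_affinity(s2, m)$kd_nM,
               estimate_affinity(s, m)$kd_nM - 1e-12)
  }
})
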
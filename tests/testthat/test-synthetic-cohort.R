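test_that("sinus generator hits its deterministic limit exactly", {
  b <- generate_sinus_ibis(300, mean_rr_ms = 1000, rsa_amp_ms = 0,
                           jitter_sd_ms = 0)
  expect_equal(nrow(b), 300)
  expect_true(all(b$ibi_ms == 1000))
  expect_equal(b$t_s, 1:300)
})

test_that("sinus IBI spread matches the closed-form SD of sinusoid plus noise", {
  # sd = sqrt(A^2/2 + sigma^2); Monte-Carlo over one hour of beats
  withr::with_seed(7, {
    b <- generate_sinus_ibis(3600, mean_rr_ms = 800, rsa_amp_ms = 30,
                             rsa_freq_hz = 0.25, jitter_sd_ms = 10)
  })
  expected <- sqrt(30^2 / 2 + 10^2)
  expect_equal(sd(b$ibi_ms), expected, tolerance = 0.1)
  # positive short-lag autocorrelation from the shared modulation phase
  expect_gt(cor(b$ibi_ms[-1], b$ibi_ms[-nrow(b)]), 0)
})

test_that("generators are deterministic under a fixed seed and tile the duration", {
  b1 <- withr::with_seed(11, generate_sinus_ibis(600))
  b2 <- withr::with_seed(11, generate_sinus_ibis(600))
  expect_identical(b1, b2)
  a1 <- withr::with_seed(11, generate_af_ibis(600))
  a2 <- withr::with_seed(11, generate_af_ibis(600))
  expect_identical(a1, a2)
  for (b in list(b1, a1)) {
    expect_true(all(diff(b$t_s) > 0))
    expect_lte(max(b$t_s), 600 + 1e-9)
    expect_gt(max(b$t_s), 600 - 2)  # beats reach the end of the recording
    expect_equal(diff(b$t_s), b$ibi_ms[-1] / 1000, tolerance = 1e-9)
  }
})

test_that("generators reject invalid parameters", {
  expect_error(generate_sinus_ibis(-10), "positive")
  expect_error(generate_sinus_ibis(100, mean_rr_ms = 300), "400")
  expect_error(generate_af_ibis(0), "positive")
  expect_error(generate_af_ibis(100, cv = -0.1), "cv")
  expect_error(generate_flutter_ibis(100, ratios = integer(0)), "non-empty")
})

test_that("AF generator matches the gamma renewal moments and is serially flat", {
  withr::with_seed(3, {
    a <- generate_af_ibis(3600, mean_rr_ms = 700, cv = 0.22)
  })
  cv_hat <- sd(a$ibi_ms) / mean(a$ibi_ms)
  expect_gt(cv_hat, 0.20)
  expect_lt(cv_hat, 0.24)
  expect_equal(mean(a$ibi_ms), 700, tolerance = 0.02)
  r1 <- cor(a$ibi_ms[-1], a$ibi_ms[-nrow(a)])
  expect_lt(abs(r1), 0.05)
  # degenerate limit: zero CV gives a constant train with zero nRMSSD
  const <- generate_af_ibis(60, mean_rr_ms = 700, cv = 0)
  expect_true(all(const$ibi_ms == 700))
  expect_equal(nrmssd(const$ibi_ms), 0)
})

test_that("flutter is conduction-ratio regular with Poisson switching", {
  f0 <- generate_flutter_ibis(600, atrial_cycle_ms = 250, ratios = 2L,
                              switch_rate_per_h = 0, jitter_sd_ms = 0)
  expect_true(all(f0$ibi_ms == 500))
  expect_equal(nrow(attr(f0, "ratio_segments")), 1L)

  # switch count over one hour within the Poisson 95% band of mean 6
  withr::with_seed(5, {
    counts <- replicate(40, {
      f <- generate_flutter_ibis(3600, switch_rate_per_h = 6)
      nrow(attr(f, "ratio_segments")) - 1L
    })
  })
  expect_gt(mean(counts), qpois(0.025, 6))
  expect_lt(mean(counts), qpois(0.975, 6))

  # within a fixed-ratio stretch, nRMSSD is below the sinus default's
  withr::with_seed(5, {
    f <- generate_flutter_ibis(1800, switch_rate_per_h = 0)
    s <- generate_sinus_ibis(1800)
  })
  expect_lt(nrmssd(f$ibi_ms), nrmssd(s$ibi_ms))
})

test_that("rhythm timelines are contiguous partitions with the right states", {
  tl <- generate_rhythm_timeline(86400, "sinus")
  expect_equal(nrow(tl), 1L)
  expect_equal(tl$end_s - tl$start_s, 86400)
  expect_equal(tl$rhythm, "SINUS")

  withr::with_seed(2, {
    tlp <- generate_rhythm_timeline(86400, "af_paroxysmal")
  })
  expect_equal(tlp$start_s[1], 0)
  expect_equal(tlp$end_s[nrow(tlp)], 86400)
  expect_equal(tlp$start_s[-1], tlp$end_s[-nrow(tlp)])  # contiguous
  expect_true(all(rle(tlp$rhythm)$lengths == 1))        # alternating
  expect_true(any(tlp$rhythm == "AF"))

  withr::with_seed(2, {
    tlf <- generate_rhythm_timeline(86400, "flutter")
  })
  expect_true(any(tlf$rhythm == "FLUTTER"))
  expect_false(any(tlf$rhythm == "AF"))
})

test_that("paroxysmal AF time fraction matches the renewal expectation", {
  # stationary alternating renewal: E[AF fraction] = 45 / (45 + 120)
  withr::with_seed(8, {
    fracs <- replicate(200, {
      tl <- generate_rhythm_timeline(86400, "af_paroxysmal")
      sum((tl$end_s - tl$start_s)[tl$rhythm == "AF"]) / 86400
    })
  })
  target <- 45 / (45 + 120)
  expect_equal(mean(fracs), target, tolerance = 0.1)
})

test_that("activity profile hits its marginal target on aligned blocks", {
  p0 <- generate_activity_profile(86400, activity_params(active_fraction = 0))
  expect_false(any(p0$active))
  withr::with_seed(4, {
    act <- unlist(lapply(1:102, function(i) {
      generate_activity_profile(86400)$active
    }))
  })
  expect_equal(mean(act), 0.161, tolerance = 0.02 / 0.161)  # within 2 points
  p <- generate_activity_profile(1000)
  expect_true(all(p$block_start_s %% 300 == 0))
})

test_that("quality model limits behave as documented", {
  beats <- flat_beats(200)[, c("t_s", "ibi_ms")]
  prof <- data.frame(block_start_s = c(0, 300), active = FALSE)
  clean <- quality_params(base_q0_prob = 0, dropout_rate_per_h = 0,
                          good_quality_probs = c(0, 0, 1),
                          active_miss_coef = 0, lock_block_prob = 0,
                          frailty_sdlog = 0)
  out <- apply_quality_model(beats, prof, clean, frailty = 1)
  expect_equal(out$t_s, beats$t_s)
  expect_equal(out$ibi_ms, beats$ibi_ms)
  expect_true(all(out$quality == 3L))

  allbad <- quality_params(base_q0_prob = 1, dropout_rate_per_h = 0,
                           active_miss_coef = 0, lock_block_prob = 0)
  out2 <- apply_quality_model(beats, prof, allbad, frailty = 1)
  expect_true(all(out2$quality == 0L))
  expect_error(quality_params(base_q0_prob = 1.2), "probability")
})

test_that("quality model preserves the time/IBI consistency invariant", {
  withr::with_seed(21, {
    beats <- generate_af_ibis(3600)
    prof <- generate_activity_profile(3600, activity_params(active_fraction = 0.5))
    out <- apply_quality_model(beats, prof, quality_params(dropout_rate_per_h = 0))
  })
  expect_true(all(diff(out$t_s) > 0))
  # every interval still equals the gap to the previous detected beat
  expect_equal(diff(out$t_s), out$ibi_ms[-1] / 1000, tolerance = 1e-9)
  expect_true(all(out$ibi_ms > 0))
})

test_that("cohort allocation follows largest-remainder rounding and is reproducible", {
  cfg <- small_config(seed = 9, n_patients = 102, duration_h = 0.2)
  coh <- generate_cohort(cfg)
  kinds <- vapply(coh, `[[`, "", "kind")
  expect_equal(sum(kinds == "sinus"), 43)
  expect_equal(sum(kinds %in% c("af_persistent", "af_paroxysmal")), 48)
  expect_equal(sum(kinds == "flutter"), 11)
  expect_equal(vapply(coh, `[[`, 0L, "recruitment_index"), 1:102)

  one <- generate_cohort(small_config(seed = 1, n_patients = 1))
  expect_length(one, 1L)
  expect_gte(one[[1]]$duration_s, max(one[[1]]$samples$t_s))

  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(generate_cohort(small_config(seed = 5, n_patients = 2,
                                            duration_h = 0.5)), d1)
  write_cohort(generate_cohort(small_config(seed = 5, n_patients = 2,
                                            duration_h = 0.5)), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("cohort serialization round-trips through CSV/JSON", {
  coh <- generate_cohort(small_config(seed = 3, n_patients = 2, duration_h = 0.5))
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_s3_class(back, "af_cohort")
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$patient_id, coh[[1]]$patient_id)
  expect_equal(back[[1]]$samples$ibi_ms, coh[[1]]$samples$ibi_ms,
               tolerance = 1e-12)
  expect_equal(back[[2]]$timeline$rhythm, coh[[2]]$timeline$rhythm)
})

test_that("AF and sinus rhythms separate in the Poincare lag-1 correlation", {
  withr::with_seed(6, {
    a <- generate_af_ibis(3600)
    s <- generate_sinus_ibis(3600)
  })
  r_af <- cor(a$ibi_ms[-1], a$ibi_ms[-nrow(a)])
  r_sr <- cor(s$ibi_ms[-1], s$ibi_ms[-nrow(s)])
  expect_lt(r_af, 0.2)
  expect_gt(r_sr, 0.5)
})

test_that("per-window nRMSSD separates AF from sinus under defaults", {
  # >= 500 windows per rhythm: median AF above the sinus 95th percentile
  withr::with_seed(10, {
    nr <- function(gen) {
      unlist(lapply(1:5, function(i) {
        b <- gen(9e4)
        w <- floor(b$t_s / 300)
        vapply(split(b$ibi_ms, w), nrmssd, 0)
      }))
    }
    nr_af <- nr(function(d) generate_af_ibis(d))
    nr_sr <- nr(function(d) generate_sinus_ibis(d))
  })
  expect_gte(length(nr_af), 500)
  expect_gte(length(nr_sr), 500)
  expect_gt(median(nr_af), quantile(nr_sr, 0.95))
})
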
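test_that("five-minute segmentation follows the half-open window convention", {
  p <- as_patient(flat_beats(86400), 86400)
  per <- segment_periods(p)
  expect_equal(nrow(per), 288)  # 86400 / 300

  short <- as_patient(flat_beats(299), 299)
  expect_equal(nrow(segment_periods(short)), 0)

  # a beat at exactly t = 300 belongs to window 1, not window 0
  b <- data.frame(t_s = c(299.0, 300.0), ibi_ms = 1000, quality = 3L,
                  activity = factor("RESTING", levels = ACTIVITY_LEVELS))
  per2 <- segment_periods(as_patient(b, 600))
  expect_equal(per2$n_beats, c(1L, 1L))
  expect_equal(per2$beats[[2]]$t_s, 300.0)
})

test_that("every early beat lands in exactly one period", {
  withr::with_seed(31, {
    beats <- generate_af_ibis(1000)
  })
  beats$quality <- 3L
  per <- segment_periods(as_patient(beats, 1000))
  assigned <- do.call(rbind, per$beats)
  cutoff <- 300 * floor(1000 / 300)
  expect_equal(sort(assigned$t_s), sort(beats$t_s[beats$t_s < cutoff]))
  expect_equal(nrow(assigned), sum(per$n_beats))
})

test_that("coverage is the valid-IBI time fraction, capped at one", {
  expect_equal(compute_coverage(flat_beats(300, 1000)), 1)
  half <- flat_beats(300, 1000)
  half$quality[seq(1, 300, by = 2)] <- 0L
  expect_equal(compute_coverage(half), 0.5)
  # 240 s of valid IBI time -> 0.8, exactly at the clinical gate
  expect_equal(compute_coverage(flat_beats(240, 1000)), 0.8)
  expect_equal(compute_coverage(flat_beats(400, 1000)), 1)  # capped
  expect_equal(compute_coverage(flat_beats(1)[0, ]), 0)
})

test_that("the quality gate is inclusive, order-preserving and monotone", {
  per <- data.frame(patient_id = "x", window_start_s = c(0, 300, 600),
                    coverage = c(0.79, 0.80, 1.0))
  kept <- filter_interpretable(per)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$coverage, c(0.80, 1.0))
  expect_equal(nrow(filter_interpretable(per[0, ])), 0)
  expect_equal(nrow(filter_interpretable(per, 0)), 3)
  # raising the gate never keeps more periods
  withr::with_seed(1, cov <- runif(200))
  per2 <- data.frame(coverage = cov)
  kept_n <- vapply(seq(0, 1, by = 0.1),
                   function(g) nrow(filter_interpretable(per2, g)), 0L)
  expect_true(all(diff(kept_n) <= 0))
})

test_that("interpretable time summarises kept periods against recording length", {
  s <- interpretable_time(86400, 288)
  expect_equal(s$fraction, 1)
  expect_true(s$meets_80)
  s0 <- interpretable_time(86400, 0)
  expect_equal(s0$fraction, 0)
  expect_false(s0$meets_80)
  # pooled cohort arithmetic: 1781 of 2306 hours -> 77.2%
  expect_equal(pct1(100 * 1781 / 2306), 77.2)
})

test_that("activity labelling uses the any-overlap rule", {
  prof <- data.frame(block_start_s = c(0, 300, 600),
                     active = c(FALSE, TRUE, FALSE))
  expect_equal(label_period_activity(c(0, 300, 600), prof),
               c(FALSE, TRUE, FALSE))
  allrest <- data.frame(block_start_s = c(0, 300), active = FALSE)
  expect_false(any(label_period_activity(c(0, 300), allrest)))
  # misaligned block overlapping two windows marks both active
  off <- data.frame(block_start_s = 150, active = TRUE)
  expect_equal(label_period_activity(c(0, 300), off), c(TRUE, TRUE))
})

test_that("rhythm labels follow majority-of-time with non-AF tie-break", {
  tl <- data.frame(start_s = c(0, 500), end_s = c(500, 1200),
                   rhythm = c("AF", "SINUS"))
  lab <- label_period_rhythm(c(0, 300, 600), tl)
  expect_equal(lab$rhythm_label, c("AF", "AF", "SINUS"))  # window 1: 200s AF/100s sinus
  expect_equal(lab$af_positive, c(TRUE, TRUE, FALSE))

  # 60/40 sinus-AF split -> majority sinus; exact 50/50 tie -> non-AF
  tl2 <- data.frame(start_s = c(0, 180), end_s = c(180, 600),
                    rhythm = c("SINUS", "AF"))
  expect_equal(label_period_rhythm(0, tl2)$rhythm_label, "SINUS")
  tie <- data.frame(start_s = c(0, 150), end_s = c(150, 300),
                    rhythm = c("AF", "SINUS"))
  expect_equal(label_period_rhythm(0, tie)$rhythm_label, "SINUS")

  # flutter policy switches between negative and excluded
  tlf <- data.frame(start_s = 0, end_s = 300, rhythm = "FLUTTER")
  expect_false(label_period_rhythm(0, tlf)$af_positive)
  expect_true(is.na(label_period_rhythm(0, tlf, "exclude")$af_positive))

  expect_error(label_period_rhythm(600, tlf), "outside")
})

test_that("majority labelling matches brute-force counts on toy timelines", {
  # enumerate 1-second occupancy directly and compare AF-labelled windows
  withr::with_seed(17, {
    for (rep in 1:20) {
      cuts <- sort(sample(1:1199, 3))
      tl <- data.frame(start_s = c(0, cuts), end_s = c(cuts, 1200),
                       rhythm = sample(c("AF", "SINUS"), 4, replace = TRUE))
      lab <- label_period_rhythm(c(0, 300, 600, 900), tl)
      sec_rhythm <- rep(tl$rhythm, times = tl$end_s - tl$start_s)
      brute <- vapply(c(0, 300, 600, 900), function(w) {
        af_s <- sum(sec_rhythm[(w + 1):(w + 300)] == "AF")
        af_s > 150  # majority; ties go non-AF
      }, TRUE)
      expect_equal(lab$af_positive, brute)
    }
  })
})

test_that("hourly activity index averages five-minute blocks per hour", {
  prof <- data.frame(block_start_s = (0:23) * 300,
                     active = rep(c(TRUE, FALSE), 12))
  h <- activity_index_hourly(prof)
  expect_equal(h$active_pct, c(50, 50))
  all_on <- data.frame(block_start_s = (0:11) * 300, active = TRUE)
  expect_true(all(activity_index_hourly(all_on)$active_pct == 100))
})

test_that("pooled hourly activity of the default simulator shows two peaks", {
  withr::with_seed(12, {
    prof <- do.call(rbind, lapply(1:60, function(i) {
      generate_activity_profile(86400)
    }))
  })
  h <- activity_index_hourly(prof)$active_pct
  sm <- stats::filter(h, rep(1 / 3, 3))  # light smoothing
  interior <- 2:(length(h) - 1)
  peaks <- interior[sm[interior] > sm[interior - 1] & sm[interior] >= sm[interior + 1]]
  expect_gte(length(peaks), 2)
  # the configured peak hours dominate their neighbourhoods
  expect_gt(h[3], h[13])   # morning peak (offset 2.5 h) above the trough
  expect_gt(h[9], h[24])   # afternoon peak (offset 8.5 h) above the tail
})

test_that("cohort period table agrees with the single-series operations", {
  coh <- generate_cohort(small_config(seed = 14, n_patients = 2, duration_h = 1))
  per <- cohort_periods(coh)
  p1 <- coh[[1]]
  seg <- segment_periods(p1)
  expect_equal(sum(per$patient_id == p1$patient_id), nrow(seg))
  cov_direct <- compute_coverage(seg)
  expect_equal(per$coverage[per$patient_id == p1$patient_id], cov_direct,
               tolerance = 1e-12)
  lab <- label_period_rhythm(seg$window_start_s, p1$timeline)
  expect_equal(per$rhythm_label[per$patient_id == p1$patient_id],
               lab$rhythm_label)
})
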
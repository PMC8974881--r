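test_that("identical config and seed give bit-identical cohorts", {
  cfg <- fast_cohort_config(n_subjects = 4, seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  for (i in seq_along(a$recordings)) {
    expect_identical(a$recordings[[i]], b$recordings[[i]])
  }
})

test_that("a subject's signals do not depend on cohort size", {
  big <- fast_cohort_config(n_subjects = 9, seed = 13)
  small <- fast_cohort_config(n_subjects = 3, seed = 13)
  tpl <- template_250()
  expect_identical(simulate_subject(big, 2, tpl),
                   simulate_subject(small, 2, tpl))
})

test_that("paired conditions share the responsiveness factor and subject id", {
  pair <- simulate_subject(fast_cohort_config(n_subjects = 2, seed = 5), 1)
  expect_identical(pair$noxious$responsiveness, pair$control$responsiveness)
  expect_identical(pair$noxious$subject_id, pair$control$subject_id)
  expect_identical(pair$noxious$ga_weeks, pair$control$ga_weeks)
})

test_that("generated recordings satisfy their structural invariants", {
  co <- small_cohort()
  for (rec in co$recordings) {
    if (!is.null(rec$beat_times)) {
      expect_true(all(diff(rec$beat_times) > 0))
      expect_lt(rec$beat_times[1], -20)
      expect_gt(rec$beat_times[length(rec$beat_times)], 30)
    }
    if (!is.null(rec$spo2)) {
      expect_true(all(rec$spo2$x >= 0 & rec$spo2$x <= 100))
    }
    if (!is.null(rec$facial)) {
      expect_true(all(rec$facial >= 0 & rec$facial <= 30))
    }
    if (!is.null(rec$eeg)) {
      # covers at least [-0.5, 1.0)
      expect_lte(rec$eeg$t0, -0.5)
      expect_gte(rec$eeg$t0 + length(rec$eeg$x) / rec$eeg$fs, 1.0)
    }
  }
})

test_that("noxious EMG burst lies in the first second, ipsi at least contra", {
  cfg <- fast_cohort_config(n_subjects = 6, seed = 31, emg_noise_sd = 0)
  for (i in 1:6) {
    pair <- simulate_subject(cfg, i)
    ips <- pair$noxious$emg_ipsi
    con <- pair$noxious$emg_contra
    tt <- ips$t0 + (seq_along(ips$x) - 1) / ips$fs
    first_active <- tt[which(abs(ips$x) > 0)[1]]
    expect_gte(first_active, 0)
    expect_lte(first_active, 1)
    expect_gte(max(abs(ips$x)), max(abs(con$x)))
    # control has no burst energy at zero noise
    expect_equal(max(abs(pair$control$emg_ipsi$x)), 0)
  }
})

test_that("null cohorts (all effects zero) are indistinguishable between conditions", {
  cfg <- fast_cohort_config(n_subjects = 120, seed = 909, eeg_amp_uV = 0,
                            emg_amp_uV = 0, hr_rise_bpm = 0,
                            spo2_dip_pct = 0, facial_mean_s = 0,
                            missingness = setNames(numeric(6), names(
                              cohort_config()$missingness)))
  feats <- extract_features(simulate_cohort(cfg))
  pos <- feats$condition == "noxious"
  for (m in c("NF", "hr_max_15", "sat_min_30", "EEGt", "RMSi")) {
    v <- feats[[m]]
    p <- suppressWarnings(ks.test(v[pos], v[!pos])$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("missingness injection matches its configured rate", {
  miss <- setNames(c(0, 0.2, 0, 0, 0, 0),
                   c("facial", "hr", "spo2", "eeg", "emg_ipsi", "emg_contra"))
  cfg <- fast_cohort_config(n_subjects = 400, seed = 55, missingness = miss)
  # availability flags only; skip signal generation cost by sampling the
  # manifest of a simulated cohort
  co <- simulate_cohort(cfg)
  frac_missing <- mean(!co$manifest$hr)
  se <- sqrt(0.2 * 0.8 / nrow(co$manifest))
  expect_lt(abs(frac_missing - 0.2), 3 * se)
  expect_true(all(co$manifest$facial))
  expect_true(all(co$manifest$eeg))
})

test_that("missingness one removes a modality everywhere", {
  miss <- setNames(c(0, 0, 0, 1, 0, 0),
                   c("facial", "hr", "spo2", "eeg", "emg_ipsi", "emg_contra"))
  co <- simulate_cohort(fast_cohort_config(n_subjects = 5, seed = 3,
                                           missingness = miss))
  expect_true(all(!co$manifest$eeg))
  expect_true(all(vapply(co$recordings, function(r) is.null(r$eeg),
                         logical(1))))
})

test_that("effect monotonicity: larger EEG amplitude does not lower EEG discrimination", {
  auc_of <- function(cfg) {
    feats <- extract_features(simulate_cohort(cfg))
    ok <- !is.na(feats$EEGt)
    oracle_auc(feats$EEGt[ok], (feats$condition == "noxious")[ok])
  }
  base <- auc_of(fast_cohort_config(n_subjects = 60, seed = 404,
                                    eeg_amp_uV = 4))
  boosted <- auc_of(fast_cohort_config(n_subjects = 60, seed = 404,
                                       eeg_amp_uV = 20))
  expect_gte(boosted, base)
})
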
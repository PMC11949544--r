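test_that("cross-correlation index: identity, sign flip, lag recovery, oracle", {
  set.seed(1)
  f <- rnorm(1000)
  expect_identical(xcorr_similarity(f, f), 1)
  # amplitude-scale invariance
  expect_equal(xcorr_similarity(f, 17 * f + 3), 1, tolerance = 1e-12)
  # sign flip: -1 exactly at the matched alignment; over all lags the
  # maximum equals the negated minimum of the autocorrelation
  expect_equal(xcorr_similarity(f, -f, max_lag = 0), -1, tolerance = 1e-12)
  full <- xcorr_similarity(f, -f)
  expect_gt(full, -1)
  expect_lte(full, 1)
  # delayed copy: index 1, recovered lag 50
  g <- c(rep(0, 50), f)[1:1000]
  r <- xcorr_similarity(f, g, details = TRUE)
  expect_gt(r$index, 0.97)
  expect_identical(r$lag, 50L)
  # brute-force oracle over all lags on short signals
  set.seed(2)
  for (rep in 1:3) {
    a <- rnorm(40 + 5 * rep)
    b <- rnorm(35 + 3 * rep)
    oracle <- xcorr_brute(a, b)
    got <- xcorr_similarity(a, b, details = TRUE)
    expect_equal(got$index, oracle$index, tolerance = 1e-10)
    expect_identical(got$lag, as.integer(oracle$lag))
  }
  expect_error(xcorr_similarity(rep(1, 10), f[1:10]), "constant")
  expect_error(xcorr_similarity(f, c(f[-1], NA)), "finite")
})

test_that("cross-correlation index stays in [-1,1] and is swap-symmetric", {
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(50 + i) * runif(1, 0.1, 10)
    b <- rnorm(60 - i) * runif(1, 0.1, 10)
    ra <- xcorr_similarity(a, b, details = TRUE)
    rb <- xcorr_similarity(b, a, details = TRUE)
    expect_gte(ra$index, -1)
    expect_lte(ra$index, 1)
    expect_equal(ra$index, rb$index, tolerance = 1e-10)
    expect_identical(ra$lag, -rb$lag)
  }
})

test_that("polarity labelling matches constructed templates, with sign symmetry", {
  fs <- 512
  for (pol in c("PP", "PN", "NP", "NN")) {
    tpl <- spike_wave_template(fs, spike_amp = 80, wave_amp = 40,
                               polarity = pol)
    expect_identical(label_polarity(as.numeric(tpl), fs), pol)
    # global sign flip maps PP<->NN and PN<->NP
    flipped <- chartr("PN", "NP", pol)
    expect_identical(label_polarity(-as.numeric(tpl), fs), flipped)
  }
})

test_that("detector round trip on generated spike trains: recall and precision", {
  mont <- montage_longitudinal()
  # noise-free train: 20 spike-waves at 2 Hz in 10 s on one derivation
  ref <- make_reference_eeg(list("F3-C3" = list(rate = 2, amplitude = 80)),
                            duration = 10, noise_sd = 0, seed = 1)
  ev <- detect_ies(ref$eeg, window = 10)
  expect_identical(nrow(ev), 20L)
  expect_true(all(ev$channel == "F3-C3"))
  # every ground-truth event recovered within 60 ms (recall = precision = 1)
  d <- vapply(ref$truth$time, function(t0) min(abs(ev$time - t0)), numeric(1))
  expect_lt(max(d), 0.06)
  # the same train below the amplitude floor: zero events
  lo <- make_reference_eeg(list("F3-C3" = list(rate = 2, amplitude = 20)),
                           duration = 10, noise_sd = 0, seed = 1)
  expect_identical(nrow(detect_ies(lo$eeg, window = 10)), 0L)
  # flat recording: zero events
  flat <- eeg_recording(matrix(0, 5120, 3,
                               dimnames = list(NULL, mont$name[1:3])) +
                          1e-9 * rnorm(5120 * 3), 512, "bipolar")
  expect_identical(nrow(detect_ies(flat, window = 10)), 0L)
  # noisy train at SNR 5: recall >= 0.9
  sd_bg <- 9
  noisy <- make_reference_eeg(list("F3-C3" = list(rate = 2, amplitude = 5 * sd_bg)),
                              duration = 40, noise_sd = sd_bg, seed = 4)
  evn <- detect_ies(noisy$eeg, window = 40)
  evn <- evn[evn$channel == "F3-C3", ]
  hits <- vapply(noisy$truth$time,
                 function(t0) any(abs(evn$time - t0) < 0.1), logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(detect_ies(noisy$eeg, window = 100), "window exceeds")
})

test_that("feature extraction recovers injected rates, polarities and phase inversion", {
  targets <- list(
    "Fp1-F3" = list(rate = 2.5, amplitude = 70, polarity = "PN"),
    "F3-C3" = list(rate = 2.5, amplitude = 90, polarity = "NP"),
    "C3-P3" = list(rate = 1, amplitude = 50, polarity = "NP")
  )
  ref <- make_reference_eeg(targets, duration = 40, noise_sd = 3, seed = 2)
  ft <- ies_features(ref$eeg, window = 40)
  per <- ft$per_derivation
  rownames(per) <- per$derivation
  expect_identical(ft$top_amplitude_derivation, "F3-C3")
  expect_identical(per["F3-C3", "dominant_polarity"], "NP")
  expect_identical(per["Fp1-F3", "dominant_polarity"], "PN")
  expect_equal(per["F3-C3", "rate"], 2.5, tolerance = 0.1)
  expect_equal(per["C3-P3", "rate"], 1, tolerance = 0.15)
  expect_false(any(per[setdiff(per$derivation, names(targets)), "present"]))
  # PN above NP sharing F3 -> phase-inversion electrode F3
  expect_identical(ft$phase_inversion, "F3")
})

test_that("EEG-IES scorer: perfection, total mismatch, bounds, monotonicity", {
  targets <- list(
    "Fp1-F3" = list(rate = 2.5, amplitude = 70, polarity = "PN"),
    "F3-C3" = list(rate = 2.5, amplitude = 90, polarity = "NP")
  )
  ref <- make_reference_eeg(targets, duration = 40, noise_sd = 3, seed = 2)
  ft <- ies_features(ref$eeg, window = 40)
  s_self <- eeg_ies_score(ft, ft)
  expect_identical(s_self$percentage, 100)
  expect_identical(s_self$maximum, 11 + 4 * nrow(ft$per_derivation))
  # a simulation with no events anywhere against a reference with events on
  # every derivation earns nothing: no per-channel agreement exists and no
  # per-EEG landmark can match
  all_on <- feat5(rates = rep(2, 5), pols = rep("NP", 5),
                  amps = c(90, 80, 70, 60, 50))
  all_off <- manual_features(
    data.frame(derivation = paste0("d", 1:5), n_events = 0L, rate = 0,
               mean_amplitude = 0, dominant_polarity = NA_character_,
               present = FALSE, stringsAsFactors = FALSE),
    top = NA_character_,
    ranks = list(chain1 = stats::setNames(rep(3, 5), paste0("d", 1:5))),
    phase = NA_character_)
  expect_identical(eeg_ies_score(all_on, all_off)$percentage, 0)
  # reference without spikes scores 0 by convention
  empty <- make_reference_eeg(list(), duration = 40, noise_sd = 3, seed = 5)
  ft0 <- ies_features(empty$eeg, window = 40)
  expect_identical(eeg_ies_score(ft0, ft)$percentage, 0)
  # monotonicity: degrading one matching derivation never raises the score
  base <- feat5(rates = c(2, 2, 1, 0, 0), pols = c("NP", "NP", "PN", NA, NA),
                amps = c(90, 70, 50, 0, 0))
  s_base <- eeg_ies_score(base, base)$percentage
  worse <- base
  worse$per_derivation$rate[2] <- 8 # outside +/-50%
  expect_lt(eeg_ies_score(base, worse)$percentage, s_base)
  worse2 <- base
  worse2$per_derivation$dominant_polarity[1] <- "PP"
  expect_lt(eeg_ies_score(base, worse2)$percentage, s_base)
  worse3 <- base
  worse3$per_derivation$present[3] <- FALSE
  worse3$per_derivation$rate[3] <- 0
  worse3$per_derivation$n_events[3] <- 0L
  expect_lt(eeg_ies_score(base, worse3)$percentage, s_base)
  expect_error(eeg_ies_score(base, ft), "different derivation sets")
})

test_that("Table-style tally: 6/31 worked example and the 5-point criteria", {
  # hand tally: only the highest-amplitude (1 pt) and phase-inversion
  # (5 pt) criteria match on a 5-derivation EEG
  tal <- ies_tally(c(1, 0, 0, 0, 0, 0, 5), n_derivations = 5)
  expect_identical(tal$maximum, 31)
  expect_equal(tal$percentage, 100 * 6 / 31, tolerance = 1e-12)
  expect_equal(tal$percentage, 19.35, tolerance = 0.01)
  # criteria 2 and 7 carry exactly 5 available points each in the scorer
  base <- feat5(rates = c(2, 2, 1, 1, 1), pols = c("NP", "NP", "PN", "PN", "NP"),
                amps = c(90, 70, 50, 40, 30))
  s <- eeg_ies_score(base, base)
  expect_identical(s$available[2], 5)
  expect_identical(s$available[7], 5)
  expect_identical(s$earned[2], 5)
  expect_identical(s$earned[7], 5)
  # criterion 3 boundary: +/-50% is relative to the reference rate
  half <- base
  half$per_derivation$rate <- base$per_derivation$rate * 1.49
  expect_identical(eeg_ies_score(base, half)$earned[3], 5)
  over <- base
  over$per_derivation$rate <- base$per_derivation$rate * 1.51
  expect_identical(eeg_ies_score(base, over)$earned[3], 0)
  expect_error(ies_tally(c(2, 0, 0, 0, 0, 0, 0), 5), "invalid")
})
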
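#' Maximum-cross-correlation similarity index for single-channel signals
#'
#' Computes the cross-correlation `R(l) = sum_n f(n) g(n + l)` between two
#' equally sampled signals after removing each signal's mean and scaling by
#' the product of their norms, and returns the maximum of `R` over all lags.
#' The normalisation confines the index to `[-1, 1]`: 1 means identical
#' signals (up to amplitude scale and a time shift), -1 a sign-flipped copy.
#' Taking the maximum over lags keeps the index high when matching events
#' (such as epileptic spikes) are not concomitant in both signals.
#'
#' Note that the maximum over unrestricted lags of `f` against `-f` is the
#' negated minimum of the autocorrelation of `f` (not -1): the index reaches
#' -1 only when the lag search is confined to the matched alignment, e.g.
#' `max_lag = 0` for concomitant events.
#'
#' @param f,g Numeric signals at the same sampling rate, length >= 2.
#'   Constant signals have no defined index and raise an error.
#' @param max_lag Largest absolute lag (samples) searched; `NULL` (default)
#'   searches all lags.
#' @param details If `TRUE`, return a list with the `index` and the `lag`
#'   (in samples, positive when `g` lags `f`) at which it is attained.
#' @return The similarity index in `[-1, 1]`, or a list when
#'   `details = TRUE`.
#' @export
xcorr_similarity <- function(f, g, max_lag = NULL, details = FALSE) {
  stopifnot(is.numeric(f), is.numeric(g), length(f) >= 2, length(g) >= 2)
  if (anyNA(f) || anyNA(g) || !all(is.finite(f)) || !all(is.finite(g))) {
    stop("signals must be finite")
  }
  f0 <- f - mean(f)
  g0 <- g - mean(g)
  nf <- sqrt(sum(f0^2))
  ng <- sqrt(sum(g0^2))
  if (nf == 0 || ng == 0) {
    stop("similarity index undefined for a constant signal")
  }
  # r[l] = sum_n f0[n] g0[n + l], l in [-(len(g)-1), len(f)-1]
  r <- rev(stats::convolve(g0, f0, conj = TRUE, type = "open")) / (nf * ng)
  lags <- seq.int(-(length(g) - 1L), length(f) - 1L)
  if (!is.null(max_lag)) {
    keep <- abs(-lags) <= max_lag
    r <- r[keep]
    lags <- lags[keep]
  }
  # the FFT evaluation carries ~1e-13 rounding error; recompute every
  # near-maximal lag with an exact dot product so that, e.g., the
  # self-similarity of a signal is exactly 1
  near <- which(r >= max(r) - 1e-9)
  exact <- vapply(near, function(i) {
    l <- -lags[i]
    n1 <- seq_along(f0)
    m <- n1 + l
    ok <- m >= 1 & m <= length(g0)
    sum(f0[n1[ok]] * g0[m[ok]]) / sqrt(sum(f0^2) * sum(g0^2))
  }, numeric(1))
  best <- near[which.max(exact)]
  idx <- min(max(max(exact), -1), 1)
  if (details) list(index = idx, lag = -lags[best]) else idx
}

# Zero-phase FFT band-pass with raised-cosine transition bands. Used by the
# spike detector; no IIR filter design dependency is available, and a
# frequency-domain filter is deterministic and phase-neutral.
.bandpass <- function(x, fs, lo, hi, transition = 1) {
  n <- length(x)
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x - mean(x), rep(0, nfft - n)))
  fr <- seq(0, fs, length.out = nfft + 1)[1:nfft]
  fr <- pmin(fr, fs - fr) # two-sided frequency axis
  H <- rep(1, nfft)
  H[fr < lo - transition / 2] <- 0
  H[fr > hi + transition / 2] <- 0
  ramp_lo <- fr >= lo - transition / 2 & fr < lo + transition / 2
  H[ramp_lo] <- 0.5 * (1 - cos(pi * (fr[ramp_lo] - lo + transition / 2) / transition))
  ramp_hi <- fr > hi - transition / 2 & fr <= hi + transition / 2
  H[ramp_hi] <- 0.5 * (1 + cos(pi * (fr[ramp_hi] - hi + transition / 2) / transition))
  Re(stats::fft(X * H, inverse = TRUE))[1:n] / nfft
}

#' Label the spike/slow-wave polarity of one event window
#'
#' The first letter is the sign of the spike's extremum, the second the sign
#' of the following slow wave's dominant deflection: `"PP"`, `"PN"`, `"NP"`
#' or `"NN"`. The spike is the largest absolute excursion in the first
#' `spike_search` seconds of the window; the wave sign is the sign of the
#' dominant deflection of the low-pass (< 8 Hz) component after the spike
#' (documented fallback when no clean wave is present).
#'
#' @param window Numeric samples containing one spike followed by its slow
#'   wave.
#' @param fs Sampling rate (Hz).
#' @param spike_search Seconds from window start searched for the spike peak
#'   (default 0.15).
#' @return One of `"PP"`, `"PN"`, `"NP"`, `"NN"`.
#' @export
label_polarity <- function(window, fs, spike_search = 0.15) {
  stopifnot(is.numeric(window), length(window) >= 4, fs > 0)
  x <- window - stats::median(window)
  n <- length(x)
  i_max <- min(n, max(2L, round(spike_search * fs)))
  spike_idx <- which.max(abs(x[seq_len(i_max)]))
  spike_sign <- sign(x[spike_idx])
  if (spike_sign == 0) spike_sign <- 1
  # wave: dominant slow deflection after the spike
  post <- seq.int(min(spike_idx + max(1L, round(0.05 * fs)), n), n)
  slow <- if (length(x) > 16) .bandpass(x, fs, 0.1, 8) else x
  wseg <- slow[post]
  wave_sign <- if (max(wseg) + min(wseg) >= 0) 1 else -1
  paste0(if (spike_sign > 0) "P" else "N", if (wave_sign > 0) "P" else "N")
}

#' Detect interictal epileptic spikes on every channel of a recording
#'
#' Parameter-light robust detector: each channel is band-passed to 1-40 Hz;
#' a spike-emphasis band (default 6-30 Hz, where spike energy concentrates
#' and background 1/f energy does not) provides the detection statistic;
#' samples whose absolute emphasis amplitude exceeds `k` scaled median
#' absolute deviations of the detection statistic, and whose broadband
#' amplitude exceeds `min_amplitude`, seed events; each event takes the
#' locally largest peak, a refractory period suppresses re-triggering, and
#' the event window is labelled with [label_polarity()]. Deterministic.
#'
#' The MAD reference is, by default, the median of the per-channel MADs over
#' the whole recording (`threshold_ref = "recording"`): a channel carrying a
#' continuous spike-wave discharge has no quiet baseline of its own, and is
#' judged against the recording's background the way a reader compares a
#' channel with its neighbours. `threshold_ref = "channel"` restores the
#' purely per-channel statistic; `k = 0` degrades to a plain absolute
#' threshold at `min_amplitude` (useful for source-level traces).
#'
#' @param eeg An [eeg_recording()] (any reference; channels analysed as-is)
#'   or a plain numeric vector/matrix with `fs` supplied.
#' @param window Analysis window length in seconds (default 40); detection
#'   runs on the first `window` seconds, which must not exceed the
#'   recording length.
#' @param fs Sampling rate when `eeg` is not an `eeg_recording`.
#' @param k Threshold in scaled-MAD units of the detection statistic
#'   (default 4).
#' @param min_amplitude Absolute broadband amplitude floor (same units as
#'   the recording; default 30, a clinical-style uV floor for scalp EEG;
#'   lower it for source-level traces).
#' @param refractory Minimum event separation (s), default 0.2.
#' @param event_window Window around the spike peak used for amplitude
#'   measurement and wave labelling (s), default 0.6.
#' @return Data frame of class `"ies_events"`: `channel`, `time` (s, peak),
#'   `amp_max`, `amp_min` (broadband, within the event window), `amplitude`
#'   (peak absolute excursion), `polarity`.
#' @export
detect_ies <- function(eeg, window = 40, fs = NULL, k = 4, min_amplitude = 30,
                       refractory = 0.2, event_window = 0.6,
                       emphasis_band = c(6, 30),
                       threshold_ref = c("recording", "channel")) {
  threshold_ref <- match.arg(threshold_ref)
  if (inherits(eeg, "eeg_recording")) {
    samples <- eeg$samples
    fs <- eeg$fs
  } else {
    samples <- as.matrix(eeg)
    if (is.null(colnames(samples))) {
      colnames(samples) <- paste0("ch", seq_len(ncol(samples)))
    }
    if (is.null(fs)) stop("fs required for plain numeric input")
  }
  if (nrow(samples) < 2) stop("empty recording")
  nwin <- min(nrow(samples), as.integer(round(window * fs)))
  if (window * fs > nrow(samples) + 0.5) {
    stop("analysis window exceeds the recording length")
  }
  broad_l <- emph_l <- list()
  for (ch in colnames(samples)) {
    x <- samples[seq_len(nwin), ch]
    broad_l[[ch]] <- .bandpass(x, fs, 1, 40)
    emph_l[[ch]] <- .bandpass(x, fs, emphasis_band[1], emphasis_band[2])
  }
  mads <- vapply(emph_l, stats::mad, numeric(1))
  sigma_rec <- stats::median(mads)
  out <- list()
  half <- as.integer(round(event_window / 2 * fs))
  for (ch in colnames(samples)) {
    broad <- broad_l[[ch]]
    emph <- emph_l[[ch]]
    sigma <- if (threshold_ref == "recording" && sigma_rec > 0) sigma_rec else
      mads[[ch]]
    thr <- k * sigma
    cand <- which(abs(emph) > thr & abs(broad) > min_amplitude)
    if (!length(cand)) next
    # collapse candidates into peaks separated by the refractory period
    ord <- cand[order(-abs(emph[cand]))]
    peaks <- integer(0)
    for (i in ord) {
      if (!length(peaks) || all(abs(peaks - i) > refractory * fs)) {
        peaks <- c(peaks, i)
      }
    }
    peaks <- sort(peaks)
    ev <- lapply(peaks, function(p) {
      lo <- max(1L, p - half)
      hi <- min(nwin, p + half)
      w <- broad[lo:hi]
      data.frame(channel = ch, time = (p - 1) / fs,
                 amp_max = max(w), amp_min = min(w),
                 amplitude = max(abs(w)),
                 polarity = label_polarity(broad[p:hi], fs),
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, ev)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(channel = character(0), time = numeric(0),
               amp_max = numeric(0), amp_min = numeric(0),
               amplitude = numeric(0), polarity = character(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "window") <- nwin / fs
  attr(res, "channels") <- colnames(samples)
  class(res) <- c("ies_events", "data.frame")
  res
}

.dominant_polarity <- function(labels) {
  if (!length(labels)) return(NA_character_)
  tab <- table(factor(labels, levels = c("PN", "NP", "PP", "NN")))
  names(tab)[which.max(tab)] # ties broken by the fixed class order
}

#' Extract the scalp spike feature set of a recording
#'
#' Per derivation: event count and rate over the analysis window, dominant
#' polarity class, mean absolute spike amplitude, presence flag. Per EEG:
#' the derivation with the highest mean spike amplitude, the rank order of
#' spike amplitudes along each anterior-to-posterior chain, and the common
#' electrode of the most prominent phase inversion (a pair of adjacent
#' derivations in one chain with dominant polarities PN above and NP below;
#' prominence is the summed mean spike amplitude of the pair, ties broken by
#' the more anterior electrode).
#'
#' @param eeg A bipolar [eeg_recording()], or an `"ies_events"` object from
#'   [detect_ies()].
#' @param montage The `"eeg_montage"` describing the derivations and chains.
#' @param window Analysis window (s), default 40.
#' @param ... Detector arguments passed to [detect_ies()] when `eeg` is a
#'   recording.
#' @return An object of class `"ies_features"`.
#' @export
ies_features <- function(eeg, montage = montage_longitudinal(), window = 40,
                         ...) {
  events <- if (inherits(eeg, "ies_events")) eeg else
    detect_ies(eeg, window = window, ...)
  window <- attr(events, "window")
  derivs <- montage$name
  per <- data.frame(derivation = derivs, stringsAsFactors = FALSE)
  per$n_events <- vapply(derivs, function(d) sum(events$channel == d), integer(1))
  per$rate <- per$n_events / window
  per$mean_amplitude <- vapply(derivs, function(d) {
    a <- events$amplitude[events$channel == d]
    if (length(a)) mean(a) else 0
  }, numeric(1))
  per$dominant_polarity <- vapply(derivs, function(d) {
    p <- .dominant_polarity(events$polarity[events$channel == d])
    if (is.na(p)) NA_character_ else p
  }, character(1))
  per$present <- per$n_events > 0
  rownames(per) <- NULL

  top <- if (any(per$present)) {
    per$derivation[which.max(per$mean_amplitude)]
  } else NA_character_

  chains <- split(seq_len(nrow(montage)), montage$chain)
  chain_ranks <- lapply(chains, function(ix) {
    a <- per$mean_amplitude[ix]
    stats::setNames(rank(a, ties.method = "average"), per$derivation[ix])
  })

  # phase inversion: adjacent pair PN above / NP below sharing an electrode
  best <- NULL
  for (ch in names(chains)) {
    ix <- chains[[ch]]
    if (length(ix) < 2) next
    for (j in seq_len(length(ix) - 1)) {
      up <- ix[j]; dn <- ix[j + 1]
      if (montage$cathode[up] != montage$anode[dn]) next
      pu <- per$dominant_polarity[up]; pd <- per$dominant_polarity[dn]
      if (identical(pu, "PN") && identical(pd, "NP")) {
        prom <- per$mean_amplitude[up] + per$mean_amplitude[dn]
        cand <- list(electrode = montage$cathode[up], prominence = prom,
                     y = NA)
        if (is.null(best) || prom > best$prominence) best <- cand
        # ties keep the earlier (more anterior) find
      }
    }
  }
  structure(list(
    per_derivation = per,
    window = window,
    top_amplitude_derivation = top,
    chain_ranks = chain_ranks,
    phase_inversion = if (is.null(best)) NA_character_ else best$electrode,
    montage = montage
  ), class = "ies_features")
}

#' @export
print.ies_features <- function(x, ...) {
  cat(sprintf("IES feature set over %g s: %d/%d derivations with spikes\n",
              x$window, sum(x$per_derivation$present), nrow(x$per_derivation)))
  cat("  highest amplitude:", x$top_amplitude_derivation,
      "| phase inversion:", x$phase_inversion, "\n")
  invisible(x)
}

#' Normalise a seven-criterion point tally to a percentage
#'
#' The theoretical maximum for a scalp EEG with `n_derivations` derivations
#' is `11 + 4 * n_derivations`: 1 point for the highest-amplitude
#' derivation, 5 for the anteroposterior amplitude gradient and 5 for the
#' phase-inversion electrode (per EEG), plus 1 point per derivation for each
#' of spike frequency, polarity, presence and absence.
#'
#' @param earned Numeric length-7 vector of points earned per criterion.
#' @param n_derivations Number of derivations scored.
#' @return List with `earned`, `available`, `maximum`, `percentage`.
#' @export
ies_tally <- function(earned, n_derivations) {
  stopifnot(length(earned) == 7, n_derivations >= 1)
  available <- c(1, 5, n_derivations, n_derivations, n_derivations,
                 n_derivations, 5)
  if (any(earned < 0 | earned > available)) stop("invalid point tally")
  maximum <- sum(available)
  list(earned = earned, available = available, maximum = maximum,
       percentage = 100 * sum(earned) / maximum)
}

#' Seven-criterion scalp EEG spike-similarity score
#'
#' Scores a simulated EEG's spike feature set against a reference (real)
#' one. Criteria and weights: (1) identical highest-amplitude derivation, 1
#' point per EEG; (2) identical anteroposterior amplitude ordering along
#' every chain, 5 points per EEG; (3) per derivation, simulated spike rate
#' within +/-50 percent of the reference rate (matching emptiness when the
#' reference rate is zero), 1 point each; (4) per derivation, identical
#' dominant polarity class (matching emptiness counts), 1 point each; (5)
#' and (6) per derivation, agreement of the spike presence/absence pattern,
#' 1 point each (the two Table rows judge the same channel set from the
#' presence and the absence side); (7) identical phase-inversion common
#' electrode, 5 points per EEG. The total is normalised by the theoretical
#' maximum `11 + 4 n` and expressed as a percentage; a reference EEG with no
#' spikes anywhere scores 0 by convention.
#'
#' @param real Reference [ies_features()].
#' @param sim Simulated [ies_features()].
#' @return Object of class `"eeg_ies_score"`: per-criterion earned and
#'   available points, `maximum` and `percentage`.
#' @export
eeg_ies_score <- function(real, sim) {
  stopifnot(inherits(real, "ies_features"), inherits(sim, "ies_features"))
  if (!identical(real$per_derivation$derivation, sim$per_derivation$derivation)) {
    stop("feature sets cover different derivation sets")
  }
  rp <- real$per_derivation
  sp <- sim$per_derivation
  n <- nrow(rp)

  if (!any(rp$present)) {
    tal <- ies_tally(rep(0, 7), n)
    return(structure(c(tal, list(note = "reference EEG contains no IES")),
                     class = "eeg_ies_score"))
  }

  c1 <- as.numeric(identical(real$top_amplitude_derivation,
                             sim$top_amplitude_derivation) &&
                     !is.na(real$top_amplitude_derivation))
  c2 <- 5 * as.numeric(identical(lapply(real$chain_ranks, unname),
                                 lapply(sim$chain_ranks, unname)))
  c3 <- sum(ifelse(rp$rate > 0,
                   abs(sp$rate - rp$rate) / rp$rate < 0.5,
                   sp$rate == 0))
  c4 <- sum(mapply(function(r, s) {
    if (is.na(r)) is.na(s) else identical(r, s)
  }, rp$dominant_polarity, sp$dominant_polarity))
  agree <- rp$present == sp$present
  c5 <- sum(agree)
  c6 <- sum(agree)
  c7 <- 5 * as.numeric(identical(real$phase_inversion, sim$phase_inversion))

  tal <- ies_tally(c(c1, c2, c3, c4, c5, c6, c7), n)
  structure(tal, class = "eeg_ies_score")
}

#' @export
print.eeg_ies_score <- function(x, ...) {
  crit <- c("highest-amplitude derivation", "amplitude gradient",
            "spike frequency", "spike polarity", "spike presence",
            "spike absence", "phase inversion")
  cat("EEG-IES similarity score\n")
  for (i in 1:7) {
    cat(sprintf("  %d) %-28s %g / %g\n", i, crit[i], x$earned[i],
                x$available[i]))
  }
  cat(sprintf("  total %g / %g = %.1f%%\n", sum(x$earned), x$maximum,
              x$percentage))
  invisible(x)
}
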
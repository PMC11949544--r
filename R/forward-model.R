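#' A current-dipole source
#'
#' A regional layer-V synaptic drive `y(t)` (mV) is converted into an axial
#' current `I(t) = eta * y(t)` (A) flowing over a distance `d_length` along
#' the dipole `orientation`. The scalp contribution of `M` summed point
#' contacts at distance `R` from the electrode is
#' `phi = (1/(4*sigma*pi)) * I * d_length * cos(theta) / R^2`,
#' where `theta` is the angle between the dipole orientation and the
#' source-to-electrode axis.
#'
#' @param position Numeric length-3 source position (mm, RAS).
#' @param orientation Numeric length-3 dipole orientation; normalised
#'   internally, must be non-zero.
#' @param y Numeric trace of the summed layer-V synaptic potential (mV).
#' @param d_length Distance travelled by the axial current (m), > 0.
#' @param eta PSP-to-current conversion factor (S), default `1e-3`.
#' @return An object of class `"dipole_source"`.
#' @export
dipole_source <- function(position, orientation, y, d_length = 1e-3,
                          eta = 1e-3) {
  stopifnot(length(position) == 3, all(is.finite(position)),
            length(orientation) == 3, all(is.finite(orientation)),
            is.numeric(y), d_length > 0, eta > 0)
  nrm <- sqrt(sum(orientation^2))
  if (nrm == 0) stop("dipole orientation must be non-zero")
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / nrm,
                 y = as.numeric(y), d_length = d_length, eta = eta),
            class = "dipole_source")
}

#' Forward-model physical parameters
#'
#' @param sigma Extracellular conductivity (S/m), default 0.33.
#' @param electrodes Data frame of electrode positions with columns `name`,
#'   `x`, `y`, `z` (mm, RAS; same frame as the atlas centroids).
#' @return An object of class `"forward_params"`.
#' @export
forward_params <- function(sigma = 0.33, electrodes = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0)
  if (!is.null(electrodes)) {
    stopifnot(is.data.frame(electrodes),
              all(c("name", "x", "y", "z") %in% names(electrodes)))
  }
  structure(list(sigma = sigma, electrodes = electrodes),
            class = "forward_params")
}

# Leadfield gain of one unit-drive dipole at one electrode (volts per mV of
# synaptic drive). Positions in mm are converted to metres here.
.dipole_gain <- function(position, orientation, electrode_pos, sigma,
                         d_length, eta) {
  rvec <- (electrode_pos - position) / 1000 # m
  R <- sqrt(sum(rvec^2))
  if (R <= 0) stop("coincident source and electrode")
  cth <- sum(orientation * rvec) / R
  (1 / (4 * sigma * pi)) * eta * d_length * cth / R^2
}

#' Scalp potential of a set of current dipoles
#'
#' Direct evaluation of the current-dipole approximation: the potential at
#' one electrode is the sum over sources of
#' `(1/(4*sigma*pi)) * I_k(t) * d_k * cos(theta_k) / R_k^2`, linear in each
#' axial current and decaying with the squared source-electrode distance.
#'
#' @param sources A list of [dipole_source()] objects (equal trace lengths).
#' @param electrode Numeric length-3 electrode position (mm).
#' @param fp A [forward_params()].
#' @return Numeric potential trace (V).
#' @export
dipole_potential <- function(sources, electrode, fp = forward_params()) {
  if (inherits(sources, "dipole_source")) sources <- list(sources)
  stopifnot(length(sources) >= 1, length(electrode) == 3,
            inherits(fp, "forward_params"))
  lens <- vapply(sources, function(s) length(s$y), integer(1))
  if (length(unique(lens)) != 1L) stop("source traces must share one length")
  out <- numeric(lens[1])
  for (s in sources) {
    g <- .dipole_gain(s$position, s$orientation, as.numeric(electrode),
                      fp$sigma, s$d_length, s$eta)
    out <- out + g * s$y
  }
  out
}

#' Build an analytic region-level leadfield
#'
#' Single-shell homogeneous-conductor leadfield computed directly from the
#' current-dipole formula: one normal-constrained dipole per cortical region
#' at its centroid, oriented radially outward, evaluated at every electrode.
#' The thalamus (a closed-field deep structure) is given a zero row when
#' present in the atlas.
#'
#' @param atlas A [brain_atlas()].
#' @param electrodes Electrode table (`name`, `x`, `y`, `z` in mm).
#' @param sigma Conductivity (S/m).
#' @param d_length,eta Dipole geometry and conversion factor, see
#'   [dipole_source()].
#' @return A regions x electrodes numeric matrix with dimnames, class
#'   `"leadfield"`, attribute `provenance = "analytic"`.
#' @export
make_leadfield <- function(atlas, electrodes, sigma = 0.33, d_length = 1e-3,
                           eta = 1e-3) {
  stopifnot(inherits(atlas, "brain_atlas"), is.data.frame(electrodes))
  epos <- as.matrix(electrodes[, c("x", "y", "z")])
  G <- matrix(0, nrow(atlas), nrow(electrodes),
              dimnames = list(atlas$name, electrodes$name))
  for (i in seq_len(nrow(atlas))) {
    if (atlas$name[i] == "Thalamus") next
    pos <- as.numeric(atlas[i, c("x", "y", "z")])
    ori <- pos / sqrt(sum(pos^2)) # radially outward
    for (e in seq_len(nrow(electrodes))) {
      G[i, e] <- .dipole_gain(pos, ori, epos[e, ], sigma, d_length, eta)
    }
  }
  structure(G, class = c("leadfield", class(G)), provenance = "analytic")
}

#' Aggregate a dipole-level leadfield to regions
#'
#' Sums the leadfield rows of all dipoles belonging to one atlas region,
#' turning a dipoles x electrodes matrix (e.g. 15000 x 32 from a BEM
#' computation) into a regions x electrodes matrix (66 x 32 for the default
#' cortical atlas). Dipoles mapped to `NA` (e.g. insular dipoles excluded
#' from the parcellation) are dropped before aggregation.
#'
#' @param dipole_leadfield Dipoles x electrodes numeric matrix.
#' @param dipole_to_region Character (or factor) vector, one region label
#'   per dipole; `NA` excludes the dipole.
#' @param regions Optional character vector fixing the output row order;
#'   defaults to the order of first appearance. Every non-`NA` label must be
#'   contained in it.
#' @return Regions x electrodes matrix, class `"leadfield"`, provenance
#'   `"aggregated"`.
#' @export
aggregate_leadfield <- function(dipole_leadfield, dipole_to_region,
                                regions = NULL) {
  dipole_leadfield <- as.matrix(dipole_leadfield)
  dipole_to_region <- as.character(dipole_to_region)
  if (length(dipole_to_region) != nrow(dipole_leadfield)) {
    stop("need exactly one region label per dipole")
  }
  keep <- !is.na(dipole_to_region)
  labs <- dipole_to_region[keep]
  if (is.null(regions)) regions <- unique(labs)
  if (!all(labs %in% regions)) {
    stop("dipole mapped to a region absent from 'regions': ",
         paste(setdiff(labs, regions)[1], collapse = ""))
  }
  f <- factor(labs, levels = regions)
  G <- rowsum(dipole_leadfield[keep, , drop = FALSE], f)
  G <- G[regions, , drop = FALSE]
  structure(as.matrix(G), class = c("leadfield", "matrix", "array"),
            provenance = "aggregated")
}

#' An EEG recording container
#'
#' @param samples Numeric matrix, time x channels, in microvolts; column
#'   names are channel names (10-20 electrode names for referential
#'   recordings, `"Fp1-F3"`-style derivation names for bipolar ones).
#' @param fs Sampling rate (Hz).
#' @param reference `"referential"` or `"bipolar"`.
#' @return Object of class `"eeg_recording"`.
#' @export
eeg_recording <- function(samples, fs, reference = c("referential", "bipolar")) {
  reference <- match.arg(reference)
  samples <- as.matrix(samples)
  stopifnot(is.numeric(samples), is.numeric(fs), fs > 0)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("EEG samples must be finite with no NaN")
  }
  if (is.null(colnames(samples))) stop("EEG channels must be named")
  structure(list(samples = samples, fs = fs, reference = reference,
                 channels = colnames(samples)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %.1f s @ %g Hz (%s)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, x$reference))
  invisible(x)
}

#' The standard longitudinal bipolar (double banana) montage
#'
#' Four anterior-to-posterior chains plus the midline, built from 10-20
#' electrode names. Each derivation is anode minus cathode.
#'
#' @return Data frame with columns `name` (e.g. `"Fp1-F3"`), `anode`,
#'   `cathode`, `chain`; class `"eeg_montage"`. Derivations within a chain
#'   are ordered anterior to posterior.
#' @export
montage_longitudinal <- function() {
  chains <- list(
    left_temporal  = c("Fp1", "F7", "T3", "T5", "O1"),
    left_parasag   = c("Fp1", "F3", "C3", "P3", "O1"),
    right_parasag  = c("Fp2", "F4", "C4", "P4", "O2"),
    right_temporal = c("Fp2", "F8", "T4", "T6", "O2"),
    midline        = c("Fz", "Cz", "Pz")
  )
  rows <- do.call(rbind, lapply(names(chains), function(ch) {
    e <- chains[[ch]]
    data.frame(name = paste0(e[-length(e)], "-", e[-1]),
               anode = e[-length(e)], cathode = e[-1],
               chain = ch, stringsAsFactors = FALSE)
  }))
  class(rows) <- c("eeg_montage", "data.frame")
  rows
}

#' Apply a bipolar montage to a referential recording
#'
#' @param eeg A referential [eeg_recording()].
#' @param montage An `"eeg_montage"` data frame.
#' @return A bipolar [eeg_recording()]; each derivation trace is
#'   anode minus cathode.
#' @export
apply_montage <- function(eeg, montage = montage_longitudinal()) {
  stopifnot(inherits(eeg, "eeg_recording"), eeg$reference == "referential",
            inherits(montage, "data.frame"))
  missing_el <- setdiff(unique(c(montage$anode, montage$cathode)), eeg$channels)
  if (length(missing_el)) {
    stop("montage references missing electrode(s): ",
         paste(missing_el, collapse = ", "))
  }
  out <- eeg$samples[, montage$anode, drop = FALSE] -
    eeg$samples[, montage$cathode, drop = FALSE]
  colnames(out) <- montage$name
  eeg_recording(out, eeg$fs, "bipolar")
}

#' Project regional source activity to scalp electrodes
#'
#' Referential electrode potentials are `traces %*% leadfield` per sample
#' (linear superposition of the regional dipole drives); an optional bipolar
#' montage is applied afterwards. A single global scale maps model units to
#' microvolts; the default was fixed once so that a background whole-brain
#' simulation spans roughly 10-50 uV peak to peak and is not claimed from
#' any empirical calibration.
#'
#' @param regional_traces A `"regional_traces"` matrix (time x regions) from
#'   [simulate_network()], or any matrix with region column names plus an
#'   `fs` argument.
#' @param leadfield Regions x electrodes `"leadfield"` matrix; rows must
#'   match the trace columns (order and names).
#' @param montage Optional `"eeg_montage"`; if supplied the returned
#'   recording is bipolar.
#' @param scale Model-to-microvolt output scale.
#' @param fs Sampling rate override when `regional_traces` carries none.
#' @param demean Subtract each region's mean drive before projecting
#'   (removes the static DC offset of the operating point).
#' @return An [eeg_recording()] in microvolts.
#' @export
project_to_scalp <- function(regional_traces, leadfield,
                             montage = montage_longitudinal(),
                             scale = scalp_scale_default(), fs = NULL, demean = TRUE) {
  X <- unclass(regional_traces)
  attrs <- attributes(regional_traces)
  if (is.null(fs)) fs <- attrs$fs
  if (is.null(fs)) stop("sampling rate unknown; pass fs")
  G <- unclass(leadfield)
  if (ncol(X) != nrow(G)) stop("trace count must equal leadfield rows")
  if (!is.null(colnames(X)) && !is.null(rownames(G)) &&
      !identical(colnames(X), rownames(G))) {
    stop("region names of traces and leadfield disagree")
  }
  if (demean) X <- sweep(X, 2, colMeans(X))
  ref <- (X %*% G) * scale
  colnames(ref) <- colnames(G)
  eeg <- eeg_recording(ref, fs, "referential")
  if (!is.null(montage)) eeg <- apply_montage(eeg, montage) else eeg
}

#' Downsample an EEG recording by an integer factor
#'
#' Anti-alias low-passes below the new Nyquist frequency, then decimates.
#' Used to export simulations (integrated at 2048 Hz) at the clinical
#' 512 Hz rate.
#'
#' @param eeg An [eeg_recording()].
#' @param fs_out Target rate; `fs/fs_out` must be a whole number.
#' @return The resampled [eeg_recording()].
#' @export
resample_eeg <- function(eeg, fs_out = 512) {
  stopifnot(inherits(eeg, "eeg_recording"), fs_out > 0)
  k <- eeg$fs / fs_out
  if (abs(k - round(k)) > 1e-9) stop("fs/fs_out must be an integer factor")
  k <- as.integer(round(k))
  if (k == 1L) return(eeg)
  idx <- seq(1L, nrow(eeg$samples), by = k)
  out <- apply(eeg$samples, 2, function(x)
    .bandpass(x, eeg$fs, 0.05, 0.45 * fs_out)[idx])
  colnames(out) <- eeg$channels
  eeg_recording(out, fs_out, eeg$reference)
}

#' Virtual resection: remove regions from the leadfield
#'
#' In-silico surgery removes the epileptic mass from the leadfield
#' calculation: the named rows are zeroed (dimensions are preserved so the
#' regional traces stay aligned) and the resected sources no longer reach
#' any electrode.
#'
#' @param leadfield A `"leadfield"` matrix with region rownames.
#' @param region_names Regions to resect; empty vector returns the input
#'   unchanged.
#' @return The modified leadfield.
#' @export
virtual_resection <- function(leadfield, region_names) {
  if (length(region_names) == 0) return(leadfield)
  unknown <- setdiff(region_names, rownames(leadfield))
  if (length(unknown)) stop("unknown region(s): ", paste(unknown, collapse = ", "))
  leadfield[region_names, ] <- 0
  leadfield
}
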
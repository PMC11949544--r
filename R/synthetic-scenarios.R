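# Everything in this file is synthetic stand-in generation: geometry,
# connectivity and reference recordings that emulate the statistical
# structure of the clinical inputs (which are not distributable) so that
# every pipeline stage runs self-contained. All generators are
# deterministic per seed.

.fib_sphere <- function(n, radius, upper_only = FALSE) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  if (upper_only) phi <- phi / 2 # squeeze into the upper hemisphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = radius * sin(phi) * cos(theta),
        y = radius * sin(phi) * sin(theta),
        z = radius * cos(phi))
}

#' The synthetic 66-region cortical atlas (plus thalamus)
#'
#' Desikan-Killiany region labels (insula excluded, 33 per hemisphere) with
#' approximate, hand-placed centroid coordinates on a template-like cortical
#' shell. The geometry is synthetic: anatomically plausible in laterality
#' and anteroposterior ordering, but not derived from any subject's MRI.
#'
#' @param include_thalamus Append the lumped `"Thalamus"` record.
#' @return A [brain_atlas()] with 66 cortical rows (+1 thalamic).
#' @export
synthetic_atlas <- function(include_thalamus = TRUE) {
  path <- system.file("extdata", "atlas_dk66_synthetic.tsv",
                      package = "spikewave", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!include_thalamus) df <- df[df$name != "Thalamus", ]
  brain_atlas(df)
}

.electrode_table <- function(head_radius = 92.5) {
  path <- system.file("extdata", "electrodes_1020_32.tsv",
                      package = "spikewave", mustWork = TRUE)
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  xyz <- as.matrix(el[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2)) * head_radius
  data.frame(name = el$name, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a synthetic head: atlas, electrodes and leadfield
#'
#' Region centroids on a cortical shell, electrodes on an outer scalp
#' shell, and a region-level leadfield computed from the current-dipole
#' formula with radially oriented normal-constrained dipoles
#' ([make_leadfield()]). With the defaults this reproduces the standard
#' configuration: 66 cortical regions, 32 scalp electrodes covering the
#' 10-20 set, and a 66 x 32 leadfield.
#'
#' @param n_regions Cortical region count; 66 selects the named
#'   [synthetic_atlas()], other values generate a generic spherical atlas.
#' @param n_electrodes Electrode count; 32 selects the 10-20-based fixture
#'   layout, other values generate a generic upper-shell layout.
#' @param seed Seed for the generic-geometry branches.
#' @param head_radius Scalp shell radius (mm).
#' @param cortex_radius Cortical shell radius (mm) for generic atlases.
#' @param sigma Conductivity (S/m).
#' @return List with `atlas`, `electrodes`, `leadfield` (cortical rows
#'   only).
#' @export
make_synthetic_head <- function(n_regions = 66, n_electrodes = 32, seed = 1,
                                head_radius = 92.5, cortex_radius = 72,
                                sigma = 0.33) {
  stopifnot(n_regions >= 2, n_electrodes >= 2)
  if (n_regions == 66) {
    atlas <- synthetic_atlas()
  } else {
    set.seed(seed)
    xyz <- .fib_sphere(n_regions, cortex_radius)
    # deterministic small jitter so no two atlases are degenerate
    xyz <- xyz + matrix(stats::rnorm(3 * n_regions, sd = 1), ncol = 3)
    df <- data.frame(
      name = sprintf("region_%02d", seq_len(n_regions)),
      hemisphere = ifelse(xyz[, 1] < 0, "lh", "rh"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      extent = 30, parent = NA_character_, stringsAsFactors = FALSE
    )
    df <- rbind(df, data.frame(name = "Thalamus", hemisphere = "both",
                               x = 0, y = -18, z = 10, extent = 20,
                               parent = NA_character_))
    atlas <- brain_atlas(df)
  }
  if (n_electrodes == 32) {
    electrodes <- .electrode_table(head_radius)
  } else {
    xyz <- .fib_sphere(n_electrodes, head_radius, upper_only = TRUE)
    electrodes <- data.frame(name = sprintf("E%02d", seq_len(n_electrodes)),
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             stringsAsFactors = FALSE)
  }
  ctx <- atlas[atlas$name != "Thalamus", ]
  G <- make_leadfield(brain_atlas(as.data.frame(ctx)), electrodes,
                      sigma = sigma)
  list(atlas = atlas, electrodes = electrodes, leadfield = G)
}

#' Generate synthetic structural connectivity
#'
#' Stands in for a DTI fibre-density matrix averaged over healthy subjects:
#' symmetric non-negative weights with exponential distance decay times a
#' random positive factor, thresholded so that only the strongest `density`
#' fraction of region pairs keeps a connection.
#'
#' @param atlas A [brain_atlas()]; only cortical regions are connected.
#' @param decay Distance-decay length (mm).
#' @param density Fraction of off-diagonal pairs with non-zero weight, in
#'   `[0, 1]`.
#' @param seed Seed.
#' @return Symmetric cortical connectivity matrix with zero diagonal and
#'   unit maximum (when non-empty).
#' @export
make_synthetic_connectivity <- function(atlas, decay = 45, density = 0.35,
                                        seed = 1) {
  stopifnot(inherits(atlas, "brain_atlas"), decay > 0,
            density >= 0, density <= 1)
  ctx <- atlas[atlas$name != "Thalamus", ]
  n <- nrow(ctx)
  d <- as.matrix(stats::dist(as.matrix(ctx[, c("x", "y", "z")])))
  set.seed(seed)
  fac <- matrix(stats::runif(n * n, 0.5, 1.5), n, n)
  fac[lower.tri(fac)] <- t(fac)[lower.tri(fac)]
  W <- exp(-d / decay) * fac
  diag(W) <- 0
  if (density < 1) {
    off <- W[upper.tri(W)]
    keep_n <- floor(density * length(off))
    thr <- if (keep_n == 0) Inf else sort(off, decreasing = TRUE)[keep_n]
    W[W < thr] <- 0
  }
  if (max(W) > 0) W <- W / max(W)
  dimnames(W) <- list(ctx$name, ctx$name)
  W
}

#' Spike-wave template for injection into synthetic reference EEGs
#'
#' A difference-of-Gaussians spike (default 70 ms) followed by a half-sine
#' slow wave (default 300 ms). Independent of the neural mass model, so
#' detector round-trip tests are not circular. The polarity code sets the
#' sign of the spike (first letter) and of the wave (second letter).
#'
#' @param fs Sampling rate (Hz).
#' @param spike_amp Spike peak amplitude (uV).
#' @param wave_amp Slow-wave peak amplitude (uV).
#' @param polarity `"PP"`, `"PN"`, `"NP"` or `"NN"`.
#' @param spike_ms,wave_ms Component durations (ms).
#' @return Numeric template; attribute `peak` holds the spike peak index.
#' @export
spike_wave_template <- function(fs, spike_amp = 80, wave_amp = 35,
                                polarity = "NP", spike_ms = 70,
                                wave_ms = 300) {
  stopifnot(polarity %in% c("PP", "PN", "NP", "NN"))
  sgn_s <- if (substr(polarity, 1, 1) == "P") 1 else -1
  sgn_w <- if (substr(polarity, 2, 2) == "P") 1 else -1
  sp_s <- spike_ms / 1000
  wv_s <- wave_ms / 1000
  t <- seq(0, sp_s + wv_s + 0.05, by = 1 / fs)
  t0 <- sp_s / 2
  sa <- sp_s / 6
  spike <- exp(-(t - t0)^2 / (2 * sa^2)) - 0.45 * exp(-(t - t0)^2 / (2 * (2 * sa)^2))
  spike <- spike / max(spike)
  wstart <- sp_s
  wave <- ifelse(t >= wstart & t <= wstart + wv_s,
                 sin(pi * (t - wstart) / wv_s), 0)
  out <- sgn_s * spike_amp * spike + sgn_w * wave_amp * wave
  attr(out, "peak") <- which.max(abs(sgn_s * spike_amp * spike))
  out
}

#' Generate a synthetic reference scalp EEG with implanted spike-waves
#'
#' Pink-noise background on every derivation plus spike-wave templates
#' injected at a controlled rate, amplitude and polarity on the requested
#' derivations. The ground-truth event list is returned for detector
#' validation. Stands in for a clinical interictal recording.
#'
#' @param targets Named list keyed by derivation name; each entry a list
#'   with `rate` (events/s), `amplitude` (spike uV), optional
#'   `wave_amplitude` (default 0.45 * amplitude) and `polarity` (default
#'   `"NP"`).
#' @param montage An `"eeg_montage"`.
#' @param duration Recording length (s), default 40.
#' @param fs Sampling rate (Hz), default 512.
#' @param noise_sd Background standard deviation (uV), default 5; 0 gives a
#'   noise-free recording.
#' @param jitter Relative jitter of the regular inter-event spacing
#'   (fraction of the period, default 0.15).
#' @param seed Seed.
#' @return List with `eeg` (bipolar [eeg_recording()]) and `truth` (data
#'   frame `channel`, `time`, `polarity`, `amplitude`).
#' @export
make_reference_eeg <- function(targets, montage = montage_longitudinal(),
                               duration = 40, fs = 512, noise_sd = 5,
                               jitter = 0.15, seed = 1) {
  stopifnot(is.list(targets), length(names(targets)) == length(targets))
  unknown <- setdiff(names(targets), montage$name)
  if (length(unknown)) stop("unknown derivation(s): ", paste(unknown, collapse = ", "))
  set.seed(seed)
  nsmp <- as.integer(round(duration * fs))
  nder <- nrow(montage)
  X <- matrix(0, nsmp, nder, dimnames = list(NULL, montage$name))
  if (noise_sd > 0) {
    for (j in seq_len(nder)) {
      w <- stats::rnorm(nsmp)
      # 1/f amplitude shaping between 0.5 and fs/2
      W <- stats::fft(w)
      fr <- seq(0, fs, length.out = nsmp + 1)[1:nsmp]
      fr <- pmin(fr, fs - fr)
      shape <- 1 / sqrt(pmax(fr, 0.5))
      pink <- Re(stats::fft(W * shape, inverse = TRUE)) / nsmp
      X[, j] <- pink / stats::sd(pink) * noise_sd
    }
  }
  truth <- list()
  for (d in names(targets)) {
    tg <- targets[[d]]
    stopifnot(!is.null(tg$rate), !is.null(tg$amplitude))
    pol <- if (is.null(tg$polarity)) "NP" else tg$polarity
    wamp <- if (is.null(tg$wave_amplitude)) 0.45 * tg$amplitude else tg$wave_amplitude
    n_ev <- floor(tg$rate * duration)
    if (n_ev < 1) next
    tpl <- spike_wave_template(fs, tg$amplitude, wamp, pol)
    # events live on a jittered regular grid inside [0.3, duration - 0.6]
    # so that no two events ever fall closer than (1 - 2*jitter) periods
    span <- duration - 0.9
    period <- span / n_ev
    base <- 0.3 + (seq_len(n_ev) - 0.5) * period
    times <- base + stats::runif(n_ev, -jitter, jitter) * period
    peak_off <- attr(tpl, "peak")
    for (tt in times) {
      start <- as.integer(round(tt * fs)) - peak_off + 1L
      idx <- seq_along(tpl) + start - 1L
      ok <- idx >= 1 & idx <= nsmp
      X[idx[ok], d] <- X[idx[ok], d] + tpl[ok]
    }
    truth[[d]] <- data.frame(channel = d, time = times, polarity = pol,
                             amplitude = tg$amplitude,
                             stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = character(0), time = numeric(0),
               polarity = character(0), amplitude = numeric(0))
  rownames(truth) <- NULL
  list(eeg = eeg_recording(X, fs, "bipolar"), truth = truth)
}

#' Named rhythm add-on presets
#'
#' Directional parameter changes generating the classical scalp rhythms in
#' the regions where they are physiologically expressed: alpha by
#' increasing the SST-mediated dendritic inhibition in occipital visual
#' areas, beta by increasing the PV-mediated somatic inhibition in the
#' frontal cortex, delta by slowing the PSP kinetics in the frontal pole.
#'
#' @return Named list; each entry holds `params` (a
#'   [cortical_column_params()]) and `regions` (default region list).
#' @export
rhythm_presets <- function() {
  list(
    alpha_boost = list(
      params = cortical_column_params("alpha_boost"),
      regions = c("lh_lateraloccipital", "rh_lateraloccipital",
                  "lh_lingual", "rh_lingual",
                  "lh_inferiortemporal", "rh_inferiortemporal")
    ),
    beta_boost = list(
      params = cortical_column_params("beta_boost"),
      regions = c("lh_rostralmiddlefrontal", "rh_rostralmiddlefrontal",
                  "lh_caudalmiddlefrontal", "rh_caudalmiddlefrontal")
    ),
    delta_boost = list(
      params = cortical_column_params("delta_boost"),
      regions = c("lh_frontalpole")
    )
  )
}

.project_cortical <- function(traces, leadfield, montage, scale) {
  keep <- intersect(colnames(traces), rownames(leadfield))
  project_to_scalp(traces[, rownames(leadfield), drop = FALSE],
                   leadfield, montage, scale = scale,
                   fs = attr(traces, "fs"))
}

#' Replay the epileptogenic-zone localisation workflow on synthetic data
#'
#' A parameter-recovery experiment mirroring the in-silico clinical
#' workflow: (1) build a synthetic head and connectome; (2) generate a
#' reference scalp EEG by simulating the whole-brain network with the
#' epileptic mass in a known region (optionally in a known sub-fraction of
#' it); (3) introduce the epileptic mass consecutively into each candidate
#' region, score every simulated EEG against the reference with the
#' seven-criterion spike-similarity index, and report the best-scoring
#' placement (ties broken by candidate order); (4) optionally fragment the
#' winning region and compare a full-region against a sub-fraction
#' epileptogenic zone; (5) resect the epileptogenic zone from the leadfield
#' and verify that the scalp spikes disappear.
#'
#' @param ez_region True epileptogenic region of the reference simulation.
#' @param candidates Candidate regions searched; default all cortical
#'   regions of the atlas.
#' @param fractions If non-`NULL`, fragmentation fractions for stage (4).
#' @param ez_child Index of the child holding the true EZ when the
#'   reference is built from a sub-fraction (default 3: the posterior
#'   part).
#' @param sub_fraction_reference If `TRUE`, the reference EEG is generated
#'   from the sub-fraction EZ (stage 4 compares full-region vs sub-fraction
#'   placements against it).
#' @param duration Simulated analysis window per EEG (s).
#' @param dt Integration step (s).
#' @param seed Master seed; the reference simulation uses `seed`, candidate
#'   simulations `seed + 1000`.
#' @param global_coupling,scale Network gain and scalp output scale
#'   forwarded to [build_network()] / [project_to_scalp()].
#' @param detector Optional list of [detect_ies()] arguments.
#' @param run_search,run_resection Switches for the expensive stages.
#' @return A bundle (list) with the reference EEG and features, the score
#'   table, `best_region`, the fragmentation comparison (if requested) and
#'   the pre-/post-resection spike counts.
#' @export
replay_fcd_scenario <- function(ez_region = "lh_rostralmiddlefrontal",
                                candidates = NULL,
                                fractions = NULL, ez_child = 3,
                                sub_fraction_reference = FALSE,
                                duration = 12, dt = 1 / 2048, seed = 1,
                                global_coupling = 15, scale = NULL,
                                detector = list(),
                                run_search = TRUE, run_resection = TRUE) {
  head <- make_synthetic_head()
  conn <- make_synthetic_connectivity(head$atlas, seed = seed)
  atlas <- head$atlas
  G <- head$leadfield
  montage <- montage_longitudinal()
  if (is.null(scale)) scale <- scalp_scale_default()

  frag_names <- NULL
  if (!is.null(fractions) || sub_fraction_reference) {
    if (is.null(fractions)) fractions <- rep(1 / 3, 3)
    fr <- fragment_region(atlas, conn, ez_region, fractions)
    atlas <- fr$atlas
    conn <- fr$connectivity
    frag_names <- paste0(ez_region, "_f", seq_along(fractions))
    ctx <- atlas[atlas$name != "Thalamus", ]
    G <- make_leadfield(brain_atlas(as.data.frame(ctx)), head$electrodes)
  }
  model <- build_network(atlas, conn, global_coupling = global_coupling)

  ref_ez <- if (sub_fraction_reference) frag_names[ez_child] else
    if (!is.null(frag_names)) frag_names else ez_region
  ref_traces <- simulate_network(model, duration = duration, dt = dt,
                                 seed = seed, ez_regions = ref_ez)
  ref_eeg <- .project_cortical(ref_traces, G, montage, scale)
  det_args <- utils::modifyList(list(window = duration), detector)
  ref_feat <- do.call(ies_features,
                      c(list(ref_eeg, montage = montage), det_args))

  out <- list(atlas = atlas, leadfield = G, reference_eeg = ref_eeg,
              reference_features = ref_feat, ez_region = ez_region,
              reference_ez = ref_ez)

  if (run_search) {
    if (is.null(candidates)) candidates <- cortical_regions(head$atlas)
    scores <- data.frame(region = candidates, score = NA_real_,
                         stringsAsFactors = FALSE)
    sims <- list()
    for (i in seq_along(candidates)) {
      cand <- candidates[i]
      cand_ez <- if (!is.null(frag_names) && cand == ez_region) frag_names else cand
      tr <- simulate_network(model, duration = duration, dt = dt,
                             seed = seed + 1000, ez_regions = cand_ez)
      eeg <- .project_cortical(tr, G, montage, scale)
      ft <- do.call(ies_features, c(list(eeg, montage = montage), det_args))
      scores$score[i] <- eeg_ies_score(ref_feat, ft)$percentage
      sims[[cand]] <- ft
    }
    # descending score, ties by candidate order
    best <- scores$region[order(-scores$score, seq_len(nrow(scores)))[1]]
    out$scores <- scores
    out$best_region <- best
    out$candidate_features <- sims
  }

  if (!is.null(frag_names)) {
    tr_full <- simulate_network(model, duration = duration, dt = dt,
                                seed = seed + 2000, ez_regions = frag_names)
    tr_sub <- simulate_network(model, duration = duration, dt = dt,
                               seed = seed + 2000,
                               ez_regions = frag_names[ez_child])
    s_full <- eeg_ies_score(ref_feat, do.call(ies_features, c(
      list(.project_cortical(tr_full, G, montage, scale), montage = montage),
      det_args)))
    s_sub <- eeg_ies_score(ref_feat, do.call(ies_features, c(
      list(.project_cortical(tr_sub, G, montage, scale), montage = montage),
      det_args)))
    out$fragmentation <- list(full_region_score = s_full$percentage,
                              sub_fraction_score = s_sub$percentage)
  }

  if (run_resection) {
    G_res <- virtual_resection(G, if (is.null(frag_names)) ez_region else ref_ez)
    res_eeg <- .project_cortical(ref_traces, G_res, montage, scale)
    pre <- do.call(detect_ies, c(list(ref_eeg), det_args))
    post <- do.call(detect_ies, c(list(res_eeg), det_args))
    out$resection <- list(pre_count = nrow(pre), post_count = nrow(post),
                          eeg = res_eeg)
  }
  class(out) <- "fcd_scenario"
  out
}

#' Default model-to-microvolt scalp output scale
#'
#' Fixed once so that an all-background whole-brain simulation projected
#' through the synthetic leadfield spans roughly 10-50 uV peak to peak on
#' the bipolar derivations, and then frozen. A package constant, not an
#' empirical claim.
#' @return Numeric scalar.
#' @export
scalp_scale_default <- function() 8.5e3
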
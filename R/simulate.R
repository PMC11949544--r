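# Per-region noise streams: region i under master seed s draws its standard
# normal sequence from set.seed(s + i). This makes a coupled network, the
# same network with coupling removed, and an isolated column (which is
# "region 1" of a one-mass network) reproducible and mutually comparable.
.noise_matrix <- function(seed, nsteps, n) {
  Z <- matrix(0, nsteps, n)
  for (i in seq_len(n)) {
    set.seed(as.integer(seed) + i)
    Z[, i] <- stats::rnorm(nsteps)
  }
  Z
}

.column_param_matrices <- function(params_list) {
  syn <- .cortical_synapse_table()$name
  n <- length(params_list)
  Wc <- TAUc <- Cc <- matrix(0, n, length(syn))
  SIGc <- matrix(0, n, 18)
  NOISEc <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    p <- params_list[[i]]
    stopifnot(inherits(p, "cortical_column_params"))
    for (k in seq_along(syn)) {
      s <- p$synapses[[syn[k]]]
      Wc[i, k] <- s$W
      TAUc[i, k] <- s$tau_w
      Cc[i, k] <- s$C
    }
    for (q in seq_along(CORTICAL_POPS)) {
      sg <- p$sigmoid[[CORTICAL_POPS[q]]]
      SIGc[i, (q - 1) * 3 + 1:3] <- c(sg$e0, sg$r, sg$v0)
    }
    NOISEc[i, ] <- c(p$noise$mean, p$noise$sd)
  }
  list(W = Wc, TAU = TAUc, C = Cc, SIG = SIGc, NOISE = NOISEc)
}

.thalamus_param_vectors <- function(p) {
  syn <- .thalamic_synapse_table()$name
  W <- TAU <- C <- numeric(length(syn))
  for (k in seq_along(syn)) {
    s <- p$synapses[[syn[k]]]
    W[k] <- s$W
    TAU[k] <- s$tau_w
    C[k] <- s$C
  }
  SIG <- numeric(9)
  for (q in seq_along(THALAMIC_POPS)) {
    sg <- p$sigmoid[[THALAMIC_POPS[q]]]
    SIG[(q - 1) * 3 + 1:3] <- c(sg$e0, sg$r, sg$v0)
  }
  list(W = W, TAU = TAU, C = C, SIG = SIG,
       NOISE = c(p$noise$mean, p$noise$sd))
}

.check_dt <- function(dt, params_list) {
  taus <- unlist(lapply(params_list, function(p)
    vapply(p$synapses, function(s) s$tau_w, numeric(1))))
  if (dt > min(taus) / 10) {
    stop(sprintf("dt = %g too coarse for fastest synapse tau_w = %g (need dt <= tau_w/10)",
                 dt, min(taus)))
  }
}

#' Simulate one isolated neocortical column
#'
#' Integrates the six-subpopulation column with a fixed-step stochastic Heun
#' scheme. The Gaussian white rate noise enters PYR; a fixed seed fixes the
#' noise stream, so identical seed and parameters give identical output.
#' The first `burn_in` seconds are discarded from the returned traces.
#'
#' @param params A [cortical_column_params()] object.
#' @param duration Analysis duration in seconds (after burn-in).
#' @param dt Integration step (s), default 1/2048. Must satisfy
#'   `dt <= min(tau_w)/10`.
#' @param seed Integer seed for the noise stream.
#' @param external_inputs Optional matrix of per-subpopulation afferent rate
#'   traces (spikes/s), `round((duration + burn_in)/dt)` rows and 6 columns
#'   named after `CORTICAL_POPS`; they enter through the long-range
#'   glutamatergic synapses. PYR2 receives no external afferent and its
#'   column must be zero.
#' @param burn_in Seconds of initial transient to discard (default 2).
#' @param record_pops Record per-subpopulation membrane potentials.
#' @return An object of class `"column_sim"`: list with `time` (s), `lfp`
#'   (the layer-V dipole drive, mV), `pops` (matrix time x 6, mV), `fs`,
#'   `dt`, `seed`, `params`.
#' @export
simulate_column <- function(params = cortical_column_params(), duration = 10,
                            dt = 1 / 2048, seed = 1, external_inputs = NULL,
                            burn_in = 2, record_pops = TRUE) {
  stopifnot(inherits(params, "cortical_column_params"),
            duration > 0, dt > 0, burn_in >= 0)
  .check_dt(dt, list(params))
  nsteps <- as.integer(round((duration + burn_in) / dt))
  ext <- matrix(numeric(0), 0, 0)
  if (!is.null(external_inputs)) {
    external_inputs <- as.matrix(external_inputs)
    if (nrow(external_inputs) != nsteps || ncol(external_inputs) != 6) {
      stop("external_inputs must be a ", nsteps, " x 6 matrix (burn-in included)")
    }
    if (any(external_inputs[, 2] != 0)) {
      stop("PYR2 receives no external afferent; column 2 must be zero")
    }
    if (!all(is.finite(external_inputs))) stop("non-finite external input")
    ext <- external_inputs
  }
  pm <- .column_param_matrices(list(params))
  Z <- .noise_matrix(seed, nsteps, 1)
  res <- .engine_simulate(
    1L, pm$W, pm$TAU, pm$C, pm$SIG, pm$NOISE,
    FALSE, numeric(8), rep(1, 8), numeric(8), numeric(9), numeric(2),
    matrix(0, 1, 1), matrix(0L, 1, 1), Z,
    nsteps, dt, ext, record_pops
  )
  keep <- seq.int(as.integer(round(burn_in / dt)) + 1L, nsteps)
  pops <- NULL
  if (record_pops) {
    pops <- res$pops[keep, , drop = FALSE]
    colnames(pops) <- CORTICAL_POPS
  }
  structure(list(
    time = (keep - 1L) * dt - burn_in,
    lfp = res$lfp[keep, 1L],
    pops = pops,
    fs = 1 / dt, dt = dt, seed = seed, params = params, burn_in = burn_in
  ), class = "column_sim")
}

#' Simulate the isolated thalamic mass
#'
#' @param params A [thalamus_params()] object.
#' @param cortical_drive Optional afferent rate trace (spikes/s) of length
#'   `round((duration + burn_in)/dt)` entering TC, RN1 and RN2 through the
#'   corticothalamic synapses, or a single number recycled.
#' @param duration,dt,seed,burn_in,record_pops As in [simulate_column()].
#' @return An object of class `"thalamus_sim"` with `time`, `rate` (the TC
#'   output firing rate, spikes/s), `lfp` (TC membrane potential, mV) and
#'   `pops` (TC, RN1, RN2 potentials).
#' @export
simulate_thalamus <- function(params = thalamus_params(), cortical_drive = NULL,
                              duration = 10, dt = 1 / 2048, seed = 1,
                              burn_in = 2, record_pops = TRUE) {
  stopifnot(inherits(params, "thalamus_params"), duration > 0, dt > 0)
  taus <- vapply(params$synapses, function(s) s$tau_w, numeric(1))
  if (dt > min(taus) / 10) stop("dt too coarse for fastest thalamic synapse")
  nsteps <- as.integer(round((duration + burn_in) / dt))
  ext <- matrix(numeric(0), 0, 0)
  if (!is.null(cortical_drive)) {
    drive <- if (length(cortical_drive) == 1L) rep(cortical_drive, nsteps) else cortical_drive
    if (length(drive) != nsteps) {
      stop("cortical_drive must have length ", nsteps, " (burn-in included)")
    }
    if (!all(is.finite(drive)) || any(drive < 0)) stop("invalid cortical drive")
    ext <- matrix(0, nsteps, 6)
    ext[, 1] <- drive
  }
  tp <- .thalamus_param_vectors(params)
  Z <- .noise_matrix(seed, nsteps, 1)
  res <- .engine_simulate(
    0L, matrix(0, 0, 17), matrix(1, 0, 17), matrix(0, 0, 17),
    matrix(0, 0, 18), matrix(0, 0, 2),
    TRUE, tp$W, tp$TAU, tp$C, tp$SIG, tp$NOISE,
    matrix(0, 1, 1), matrix(0L, 1, 1), Z,
    nsteps, dt, ext, record_pops
  )
  keep <- seq.int(as.integer(round(burn_in / dt)) + 1L, nsteps)
  pops <- NULL
  if (record_pops) {
    pops <- res$pops[keep, , drop = FALSE]
    colnames(pops) <- THALAMIC_POPS
  }
  e0 <- params$sigmoid$TC
  structure(list(
    time = (keep - 1L) * dt - burn_in,
    lfp = res$lfp[keep, 1L],
    rate = sigmoid(res$lfp[keep, 1L], e0),
    pops = pops,
    fs = 1 / dt, dt = dt, seed = seed, params = params, burn_in = burn_in
  ), class = "thalamus_sim")
}
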
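#' Sigmoid firing-rate parameters
#'
#' The wave-to-pulse sigmoid of a neural mass converts the net membrane
#' potential of a subpopulation into its mean firing rate,
#' \deqn{S(v) = 2 e_0 / (1 + e^{r (v_0 - v)}),}
#' so `2*e0` is the maximum firing rate, `r` the stiffness of the transition
#' and `v0` the potential at which the rate equals `e0`.
#'
#' @param e0 Half of the maximum firing rate (spikes/s). Must be positive.
#' @param r Sigmoid stiffness (1/mV). Must be positive.
#' @param v0 Membrane potential at half-maximum rate (mV).
#' @return An object of class `"sigmoid_params"`.
#' @examples
#' p <- sigmoid_params()
#' sigmoid(p$v0, p) # equals e0
#' @export
sigmoid_params <- function(e0 = 2.5, r = 0.56, v0 = 6) {
  stopifnot(is.numeric(e0), length(e0) == 1L, is.finite(e0), e0 > 0,
            is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
            is.numeric(v0), length(v0) == 1L, is.finite(v0))
  structure(list(e0 = e0, r = r, v0 = v0), class = "sigmoid_params")
}

#' Wave-to-pulse sigmoid
#'
#' @param v Membrane potential(s) in mV. May be a vector.
#' @param p A [sigmoid_params()] object.
#' @return Firing rate(s) in spikes/s, strictly inside `(0, 2*e0)` for
#'   finite `v`, monotonically increasing in `v`.
#' @export
sigmoid <- function(v, p = sigmoid_params()) {
  stopifnot(inherits(p, "sigmoid_params"), is.numeric(v))
  2 * p$e0 / (1 + exp(p$r * (p$v0 - v)))
}

#' Alpha-function synapse kernel
#'
#' A synapse converts a presynaptic firing rate into an average postsynaptic
#' potential through the critically damped second-order system
#' \deqn{\ddot y = (W/\tau_w)\,u(t) - (2/\tau_w)\,\dot y - y/\tau_w^2,}
#' whose impulse response is the alpha function
#' `h(t) = (W / tau_w) * t * exp(-t / tau_w)` (peak `W / e` at `t = tau_w`).
#' `W` sets the PSP amplitude (mV) and `tau_w` its rise/decay kinetics (s).
#' The `sign` records whether the PSP adds (excitatory) or subtracts
#' (inhibitory) in the membrane summation of the target subpopulation.
#'
#' @param W Average synaptic gain (mV).
#' @param tau_w Kinetic time constant (s). Must be positive.
#' @param sign `"excitatory"` or `"inhibitory"`.
#' @return An object of class `"synapse_kernel"`.
#' @export
synapse_kernel <- function(W, tau_w, sign = c("excitatory", "inhibitory")) {
  sign <- match.arg(sign)
  stopifnot(is.numeric(W), length(W) == 1L, is.finite(W),
            is.numeric(tau_w), length(tau_w) == 1L, is.finite(tau_w), tau_w > 0)
  structure(list(W = W, tau_w = tau_w, sign = sign), class = "synapse_kernel")
}

#' Synapse state: PSP and its derivative
#'
#' @param y Postsynaptic potential (mV).
#' @param y_dot First derivative of the PSP (mV/s).
#' @return An object of class `"synapse_state"`.
#' @export
synapse_state <- function(y = 0, y_dot = 0) {
  stopifnot(is.numeric(y), length(y) == 1L, is.finite(y),
            is.numeric(y_dot), length(y_dot) == 1L, is.finite(y_dot))
  structure(list(y = y, y_dot = y_dot), class = "synapse_state")
}

#' Advance one synapse by one time step
#'
#' One explicit Heun (trapezoidal predictor-corrector) step of the
#' second-order synaptic ODE with the input rate held constant over the step.
#' For a constant input `u` the discrete fixed point is exactly the
#' continuous equilibrium `y = W * tau_w * u`.
#'
#' @param s A [synapse_state()].
#' @param input_rate Presynaptic firing rate over the step (spikes/s).
#' @param k A [synapse_kernel()].
#' @param dt Time step (s); must satisfy `dt <= tau_w / 10`.
#' @return The updated [synapse_state()].
#' @export
synapse_step <- function(s, input_rate, k, dt) {
  stopifnot(inherits(s, "synapse_state"), inherits(k, "synapse_kernel"),
            is.numeric(dt), length(dt) == 1L, dt > 0)
  if (!is.finite(input_rate)) stop("non-finite synaptic input rate")
  if (dt > k$tau_w / 10) {
    stop(sprintf("dt = %g too coarse for tau_w = %g (need dt <= tau_w/10)",
                 dt, k$tau_w))
  }
  tau <- k$tau_w
  f <- function(y, z) c(z, (k$W / tau) * input_rate - (2 / tau) * z - y / tau^2)
  d1 <- f(s$y, s$y_dot)
  yp <- s$y + dt * d1[1L]
  zp <- s$y_dot + dt * d1[2L]
  d2 <- f(yp, zp)
  synapse_state(s$y + dt / 2 * (d1[1L] + d2[1L]),
                s$y_dot + dt / 2 * (d1[2L] + d2[2L]))
}

# Subpopulation labels of the neocortical column, in canonical order.
# PYR: layer-V pyramidal cells; PYR2: the collateral-excitation pyramidal
# pool; PV/SST/VIP/NGFC: the four GABAergic interneuron classes.
CORTICAL_POPS <- c("PYR", "PYR2", "PV", "SST", "VIP", "NGFC")
THALAMIC_POPS <- c("TC", "RN1", "RN2")

# Canonical intra-column synapse table. Order matters: it is the state
# layout of the compiled integrator. "LR" marks the long-range glutamatergic
# afferent bundle (network/thalamic input); "noise" the stochastic drive.
.cortical_synapse_table <- function() {
  data.frame(
    name = c("pyr_pyr2", "pyr2_pyr", "pyr_pv", "pyr_sst", "pv_pyr",
             "sst_pyr_apical", "sst_pyr_basal", "sst_pv", "vip_sst",
             "ngfc_pyr", "pyr_ngfc", "noise_pyr",
             "lr_pyr", "lr_pv", "lr_sst", "lr_vip", "lr_ngfc"),
    source = c("PYR", "PYR2", "PYR", "PYR", "PV",
               "SST", "SST", "SST", "VIP",
               "NGFC", "PYR", "noise",
               "LR", "LR", "LR", "LR", "LR"),
    target = c("PYR2", "PYR", "PV", "SST", "PYR",
               "PYR", "PYR", "PV", "SST",
               "PYR", "NGFC", "PYR",
               "PYR", "PV", "SST", "VIP", "NGFC"),
    transmitter = c("glutamatergic", "glutamatergic", "glutamatergic",
                    "glutamatergic", "GABAergic-fast",
                    "GABAergic-slow", "GABAergic-slow", "GABAergic",
                    "GABAergic", "GABAergic-very-slow", "glutamatergic",
                    "external", "glutamatergic", "glutamatergic",
                    "glutamatergic", "glutamatergic", "glutamatergic"),
    stringsAsFactors = FALSE
  )
}

.thalamic_synapse_table <- function() {
  data.frame(
    name = c("ctx_tc", "ctx_rn1", "ctx_rn2", "tc_rn1", "tc_rn2",
             "rn1_tc", "rn2_tc", "noise_tc"),
    source = c("LR", "LR", "LR", "TC", "TC", "RN1", "RN2", "noise"),
    target = c("TC", "RN1", "RN2", "RN1", "RN2", "TC", "TC", "TC"),
    transmitter = c("glutamatergic", "glutamatergic", "glutamatergic",
                    "glutamatergic", "glutamatergic",
                    "GABAergic-slow", "GABAergic-fast", "external"),
    stringsAsFactors = FALSE
  )
}

#' The intra-column connection motif
#'
#' Directed connection list of the six-subpopulation neocortical column:
#' reciprocal PYR/PYR2 collateral excitation, feed-forward excitation of PV
#' and SST interneurons by PYR, fast somatic PV inhibition of PYR, slow
#' dendritic SST inhibition of PYR through two kernels (slower apical, faster
#' basal), SST inhibition of PV, VIP disinhibition through SST, very slow
#' NGFC volume inhibition of PYR with weak reciprocal excitation, and the
#' external noise drive onto PYR. Long-range afferent entries (`source ==
#' "LR"`) mark where network and thalamic glutamatergic input is received
#' (PYR, PV, SST, VIP and NGFC).
#'
#' @param include_external If `FALSE`, drop the noise and long-range rows and
#'   return only the intra-column synapses.
#' @return A data frame with columns `name`, `source`, `target`,
#'   `transmitter`.
#' @export
column_motif <- function(include_external = TRUE) {
  tab <- .cortical_synapse_table()
  if (!include_external) tab <- tab[!(tab$source %in% c("noise", "LR")), ]
  rownames(tab) <- NULL
  tab
}

.presets_file <- function() {
  system.file("extdata", "presets.json", package = "spikewave", mustWork = TRUE)
}

.load_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- jsonlite::read_json(.presets_file(), simplifyVector = FALSE)
    }
    cache
  }
})

#' Available column parameter presets
#'
#' @return Character vector of preset names defined in the package's
#'   parameter configuration file.
#' @export
column_presets <- function() {
  names(.load_presets()$cortical)
}

.apply_deltas <- function(params, deltas) {
  for (conn in names(deltas)) {
    d <- deltas[[conn]]
    if (!conn %in% names(params$synapses)) {
      stop("unknown connection in preset delta: ", conn)
    }
    for (field in names(d)) {
      if (!field %in% c("W", "tau_w", "C")) {
        stop("preset deltas may only scale W, tau_w or C, got: ", field)
      }
      params$synapses[[conn]][[field]] <-
        params$synapses[[conn]][[field]] * d[[field]]
    }
  }
  params
}

.parse_column_json <- function(cfg) {
  syn_tab <- .cortical_synapse_table()
  synapses <- list()
  for (i in seq_len(nrow(syn_tab))) {
    nm <- syn_tab$name[i]
    entry <- cfg$synapses[[nm]]
    if (is.null(entry)) stop("preset is missing synapse: ", nm)
    synapses[[nm]] <- list(
      W = entry$W, tau_w = entry$tau_w, C = entry$C,
      sign = if (grepl("GABA", syn_tab$transmitter[i])) "inhibitory" else "excitatory"
    )
  }
  sig <- lapply(cfg$sigmoid, function(s) sigmoid_params(s$e0, s$r, s$v0))
  list(sigmoid = sig, synapses = synapses,
       noise = list(mean = cfg$noise$mean, sd = cfg$noise$sd))
}

#' Parameters of one neocortical column
#'
#' Builds the full parameter set of a single cortical neural mass: sigmoid
#' parameters per subpopulation, one synapse kernel (gain `W` in mV, time
#' constant `tau_w` in s) and one dimensionless coupling coefficient `C` per
#' directed connection of [column_motif()], and the mean/SD of the Gaussian
#' white rate noise driving PYR. Named presets are read from the package's
#' configuration file; the epileptic regimes are expressed there as
#' multiplicative deviations from `"background"` (raised glutamatergic and
#' PV-somatic gain, lowered SST dendritic gain for `"fcd_spikewave"`).
#'
#' @param preset One of [column_presets()]: `"background"`,
#'   `"fcd_spikewave"`, `"alpha_boost"`, `"beta_boost"` or `"delta_boost"`.
#' @param overrides Optional named list `list(connection = list(W=, tau_w=,
#'   C=))` of absolute parameter overrides applied after the preset.
#' @return An object of class `"cortical_column_params"`.
#' @export
cortical_column_params <- function(preset = "background", overrides = NULL) {
  cfgs <- .load_presets()
  if (!preset %in% names(cfgs$cortical)) {
    stop("unknown preset '", preset, "'; available: ",
         paste(names(cfgs$cortical), collapse = ", "))
  }
  params <- .parse_column_json(cfgs$cortical$background)
  cfg <- cfgs$cortical[[preset]]
  if (!is.null(cfg$deltas)) params <- .apply_deltas(params, cfg$deltas)
  if (!is.null(cfg$noise)) {
    params$noise <- list(mean = cfg$noise$mean, sd = cfg$noise$sd)
  }
  if (!is.null(overrides)) {
    for (conn in names(overrides)) {
      if (!conn %in% names(params$synapses)) stop("unknown connection: ", conn)
      for (f in names(overrides[[conn]])) {
        stopifnot(f %in% c("W", "tau_w", "C"))
        params$synapses[[conn]][[f]] <- overrides[[conn]][[f]]
      }
    }
  }
  for (s in params$synapses) {
    stopifnot(s$tau_w > 0, s$C >= 0)
  }
  params$preset <- preset
  class(params) <- "cortical_column_params"
  params
}

#' Parameters of the lumped thalamic mass
#'
#' Three subpopulations: glutamatergic thalamocortical relay cells (TC) and
#' two GABAergic reticular-nucleus pools, RN1 (slow kinetics) and RN2 (fast
#' kinetics), both inhibiting TC. Cortical afferents excite all three pools;
#' TC excites both RN pools.
#'
#' @param overrides Optional named list of absolute synapse overrides as in
#'   [cortical_column_params()].
#' @return An object of class `"thalamus_params"`.
#' @export
thalamus_params <- function(overrides = NULL) {
  cfg <- .load_presets()$thalamus
  syn_tab <- .thalamic_synapse_table()
  synapses <- list()
  for (i in seq_len(nrow(syn_tab))) {
    nm <- syn_tab$name[i]
    entry <- cfg$synapses[[nm]]
    if (is.null(entry)) stop("thalamus config missing synapse: ", nm)
    synapses[[nm]] <- list(
      W = entry$W, tau_w = entry$tau_w, C = entry$C,
      sign = if (grepl("GABA", syn_tab$transmitter[i])) "inhibitory" else "excitatory"
    )
  }
  params <- list(
    sigmoid = lapply(cfg$sigmoid, function(s) sigmoid_params(s$e0, s$r, s$v0)),
    synapses = synapses,
    noise = list(mean = cfg$noise$mean, sd = cfg$noise$sd)
  )
  if (!is.null(overrides)) {
    for (conn in names(overrides)) {
      if (!conn %in% names(params$synapses)) stop("unknown connection: ", conn)
      for (f in names(overrides[[conn]])) {
        stopifnot(f %in% c("W", "tau_w", "C"))
        params$synapses[[conn]][[f]] <- overrides[[conn]][[f]]
      }
    }
  }
  stopifnot(params$synapses$rn1_tc$sign == "inhibitory",
            params$synapses$rn2_tc$sign == "inhibitory")
  class(params) <- "thalamus_params"
  params
}
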
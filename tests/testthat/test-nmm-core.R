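test_that("sigmoid is bounded, monotone and exact at its landmarks", {
  p <- sigmoid_params()
  expect_identical(sigmoid(p$v0, p), p$e0)
  expect_equal(sigmoid(1e4, p), 2 * p$e0, tolerance = 1e-12)
  expect_lt(sigmoid(-1e3, p), 1e-12)
  v <- seq(-30, 30, by = 0.25)
  s <- sigmoid(v, p)
  expect_true(all(s > 0 & s < 2 * p$e0))
  expect_true(all(diff(s) > 0))
  # custom parameters keep the half-max landmark
  q <- sigmoid_params(e0 = 4, r = 0.3, v0 = -2)
  expect_identical(sigmoid(-2, q), 4)
  expect_error(sigmoid_params(e0 = -1), "e0")
})

test_that("synapse_step tracks the closed-form impulse response and equilibrium", {
  k <- synapse_kernel(3.25, 0.01, "excitatory")
  dt <- 1 / 8192
  y <- run_impulse(k, dt, 0.06)
  tt <- seq_along(y) * dt
  h <- alpha_impulse(tt, k$W, k$tau_w)
  expect_lt(max(abs(y - h)) / max(h), 1e-4)
  # peak value W/e at t = tau_w
  expect_equal(max(y), k$W / exp(1), tolerance = 1e-4)
  expect_lt(abs(tt[which.max(y)] - k$tau_w), 2 * dt)
  # constant input equilibrium y = W * tau_w * u (exact fixed point)
  s <- synapse_state()
  for (i in 1:20000) s <- synapse_step(s, 10, k, dt)
  expect_equal(s$y, k$W * k$tau_w * 10, tolerance = 1e-9)
  # zero input, zero state is a fixed point
  s0 <- synapse_step(synapse_state(), 0, k, dt)
  expect_identical(c(s0$y, s0$y_dot), c(0, 0))
  expect_error(synapse_step(synapse_state(), Inf, k, dt), "non-finite")
  expect_error(synapse_step(synapse_state(), 1, k, k$tau_w), "coarse")
})

test_that("synapse response is linear and converges at first order or better", {
  k <- synapse_kernel(5, 0.02, "inhibitory")
  dt <- 1 / 4096
  set.seed(3)
  u1 <- rnorm(300, 10, 3)
  u2 <- rnorm(300, 5, 2)
  run_u <- function(u) {
    s <- synapse_state()
    vapply(u, function(ui) {
      s <<- synapse_step(s, ui, k, dt)
      s$y
    }, numeric(1))
  }
  y1 <- run_u(u1)
  y2 <- run_u(u2)
  y12 <- run_u(u1 + u2)
  ya <- run_u(2.5 * u1)
  expect_equal(y12, y1 + y2, tolerance = 1e-8)
  expect_equal(ya, 2.5 * y1, tolerance = 1e-8)
  # empirical convergence order by halving dt: error must shrink at least ~2x
  err_at <- function(dt) {
    y <- run_impulse(k, dt, 0.08)
    tt <- seq_along(y) * dt
    max(abs(y - alpha_impulse(tt, k$W, k$tau_w)))
  }
  e1 <- err_at(1 / 2048)
  e2 <- err_at(1 / 4096)
  expect_lt(e2, e1 / 1.9)
})

test_that("column motif matches the declared circuit", {
  m <- column_motif()
  has <- function(src, tgt) any(m$source == src & m$target == tgt)
  expect_true(has("SST", "PV"))
  expect_false(has("PV", "SST"))
  expect_true(has("PYR", "PYR2") && has("PYR2", "PYR"))
  expect_true(has("VIP", "SST"))
  expect_true(has("NGFC", "PYR"))
  expect_true(has("noise", "PYR"))
  # two SST -> PYR kernels, apical slower than basal
  sp <- m$name[m$source == "SST" & m$target == "PYR"]
  expect_length(sp, 2L)
  p <- cortical_column_params()
  expect_gt(p$synapses$sst_pyr_apical$tau_w, p$synapses$sst_pyr_basal$tau_w)
  # glutamatergic intra-column connections: PYR<->PYR2, PYR->PV, PYR->SST
  # (weak PYR->NGFC excitation is configurable on top of the canonical four)
  intra <- column_motif(include_external = FALSE)
  glut <- intra[intra$transmitter == "glutamatergic", ]
  expect_true(all(c("pyr_pyr2", "pyr2_pyr", "pyr_pv", "pyr_sst") %in% glut$name))
  expect_equal(nrow(glut), 5L) # the four canonical + pyr_ngfc
  # long-range afferents reach PYR, PV, SST, VIP, NGFC
  lr <- m[m$source == "LR", "target"]
  expect_setequal(lr, c("PYR", "PV", "SST", "VIP", "NGFC"))
})

test_that("presets load and respect the declared deviation directions", {
  expect_setequal(column_presets(),
                  c("background", "fcd_spikewave", "alpha_boost",
                    "beta_boost", "delta_boost"))
  bg <- cortical_column_params("background")
  ep <- cortical_column_params("fcd_spikewave")
  # epileptic: more glutamatergic and PV gain, less SST dendritic gain
  expect_gt(ep$synapses$pyr_pyr2$W, bg$synapses$pyr_pyr2$W)
  expect_gt(ep$synapses$pv_pyr$W, bg$synapses$pv_pyr$W)
  expect_lt(ep$synapses$sst_pyr_apical$W, bg$synapses$sst_pyr_apical$W)
  expect_lt(ep$synapses$sst_pyr_basal$W, bg$synapses$sst_pyr_basal$W)
  al <- cortical_column_params("alpha_boost")
  expect_gt(al$synapses$sst_pyr_apical$W, bg$synapses$sst_pyr_apical$W)
  be <- cortical_column_params("beta_boost")
  expect_gt(be$synapses$pv_pyr$W, bg$synapses$pv_pyr$W)
  de <- cortical_column_params("delta_boost")
  expect_gt(de$synapses$pyr_pyr2$tau_w, bg$synapses$pyr_pyr2$tau_w)
  # overrides are absolute and validated
  ov <- cortical_column_params(overrides = list(pv_pyr = list(W = 1)))
  expect_identical(ov$synapses$pv_pyr$W, 1)
  expect_error(cortical_column_params("nope"), "unknown preset")
  expect_error(cortical_column_params(overrides = list(bad = list(W = 1))),
               "unknown connection")
})

test_that("simulate_column is deterministic, bounded for background, silent at zero gain", {
  p <- cortical_column_params()
  a <- simulate_column(p, duration = 4, seed = 9)
  b <- simulate_column(p, duration = 4, seed = 9)
  expect_identical(a$lfp, b$lfp)
  c2 <- simulate_column(p, duration = 4, seed = 10)
  expect_false(identical(a$lfp, c2$lfp))
  # background: stationary fluctuation, no transient beyond 5 sd
  x <- simulate_column(p, duration = 20, seed = 5)$lfp
  expect_lt(max(abs(x - mean(x))), 5 * sd(x))
  # all gains zero -> flat zero output
  z <- p
  for (nm in names(z$synapses)) z$synapses[[nm]]$W <- 0
  z <- cortical_column_params(overrides = lapply(z$synapses, function(s) list(W = 0)))
  z$noise$sd <- 0
  z$noise$mean <- 0
  xz <- simulate_column(z, duration = 2, seed = 1)
  expect_identical(max(abs(xz$lfp)), 0)
  expect_identical(max(abs(xz$pops)), 0)
})

test_that("epileptic preset yields 2-3 Hz spike-wave transients, spike before wave", {
  sim <- simulate_column(cortical_column_params("fcd_spikewave"),
                         duration = 30, seed = 5)
  fs <- sim$fs
  n <- count_complexes(sim$lfp, fs)
  rate <- n / 30
  expect_gte(rate, 2)
  expect_lte(rate, 3)
  expect_gt(diff(range(sim$lfp)), 30) # large-amplitude complexes (mV)
  # temporal order: sharp spike precedes the slow wave within each complex.
  # Source-level detection with an absolute threshold (continuous discharge
  # has no quiet own-channel baseline).
  ev <- detect_ies(matrix(sim$lfp, ncol = 1, dimnames = list(NULL, "lfp")),
                   window = 30, fs = fs, k = 0, min_amplitude = 15)
  expect_gt(nrow(ev), 30)
  # temporal order on the average complex: align epochs on the detected
  # spike peaks; in the grand average the sharp (6-30 Hz) component must
  # peak before the slow-wave (0.5-4 Hz) component
  x0 <- sim$lfp - median(sim$lfp)
  pre <- round(0.05 * fs)
  post <- round(0.35 * fs)
  idx <- round(ev$time * fs) + 1L
  idx <- idx[idx > pre & idx + post <= length(x0)]
  epoch <- rowMeans(vapply(idx, function(i) x0[(i - pre):(i + post)],
                           numeric(pre + post + 1L)))
  t_spike <- which.max(epoch)  # sharp positive spike
  t_wave <- which.min(epoch)   # following negative slow wave
  expect_lt(t_spike, t_wave)
  # the wave trough lags the spike by the order of the wave duration
  expect_gt((t_wave - t_spike) / fs, 0.05)
  # and the average complex carries both components at full amplitude
  expect_gt(epoch[t_spike], 15)
  expect_lt(epoch[t_wave], -5)
})

test_that("background preset produces no spike-wave transients", {
  sim <- simulate_column(cortical_column_params(), duration = 30, seed = 7)
  expect_identical(count_complexes(sim$lfp, sim$fs), 0L)
})

test_that("simulate_thalamus rests, tracks drive, and RN gain lowers TC rate", {
  # zero drive, zero noise -> constant resting output after the transient
  p0 <- thalamus_params()
  p0$noise$mean <- 0
  p0$noise$sd <- 0
  r0 <- simulate_thalamus(p0, duration = 4, seed = 1)
  tail_rate <- r0$rate[r0$time > 2]
  expect_lt(diff(range(tail_rate)), 1e-8)
  # step increase in cortical drive -> higher equilibrium TC rate
  nst <- round(6 / (1 / 2048))
  r_lo <- simulate_thalamus(p0, cortical_drive = 0.5, duration = 4, seed = 1)
  r_hi <- simulate_thalamus(p0, cortical_drive = 3, duration = 4, seed = 1)
  expect_gt(mean(r_hi$rate[r_hi$time > 2]), mean(r_lo$rate[r_lo$time > 2]))
  expect_gt(mean(r_hi$rate[r_hi$time > 2]), mean(tail_rate))
  # stronger reticular inhibition -> equilibrium TC rate decreases
  p_strong <- thalamus_params(overrides = list(rn1_tc = list(C = 40),
                                               rn2_tc = list(C = 40)))
  p_strong$noise$mean <- 0
  p_strong$noise$sd <- 0
  r_strong <- simulate_thalamus(p_strong, cortical_drive = 3, duration = 4,
                                seed = 1)
  expect_lt(mean(r_strong$rate[r_strong$time > 2]),
            mean(r_hi$rate[r_hi$time > 2]))
})

test_that("rhythm presets place their spectral peaks in the named bands", {
  al <- simulate_column(cortical_column_params("alpha_boost"),
                        duration = 16, seed = 3)$lfp
  f_al <- dominant_freq(al)
  expect_gte(f_al, 8)
  expect_lte(f_al, 12)
  be <- simulate_column(cortical_column_params("beta_boost"),
                        duration = 16, seed = 3)$lfp
  f_be <- dominant_freq(be)
  expect_gte(f_be, 13)
  expect_lte(f_be, 30)
  # background: 1/f-like, dominated by low frequencies, no narrowband
  # dominance above 8 Hz
  bg <- simulate_column(cortical_column_params(), duration = 16, seed = 3)$lfp
  expect_lt(dominant_freq(bg), 8)
})
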
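#' Construct a brain atlas table
#'
#' An atlas is an ordered table of region records. Cortical regions carry a
#' Desikan-Killiany style name, a hemisphere, a centroid in millimetres
#' (right-handed RAS, shared with the electrode frame), an approximate
#' anteroposterior extent used when fragmenting, and an optional parent name
#' for fragmented children. The subcortical thalamus record (if present) is
#' named `"Thalamus"` with hemisphere `"both"`.
#'
#' @param df Data frame with columns `name`, `hemisphere`, `x`, `y`, `z`,
#'   and optionally `extent` (mm, default 30) and `parent` (NA for top-level
#'   regions).
#' @return The validated data frame with class `"brain_atlas"`.
#' @export
brain_atlas <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("name", "hemisphere", "x", "y", "z") %in% names(df)))
  if (is.null(df$extent)) df$extent <- 30
  if (is.null(df$parent)) df$parent <- NA_character_
  df$name <- as.character(df$name)
  df$parent <- as.character(df$parent)
  if (anyDuplicated(df$name)) stop("atlas region names must be unique")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")])))) {
    stop("atlas centroids must be finite")
  }
  rownames(df) <- NULL
  class(df) <- c("brain_atlas", "data.frame")
  df
}

#' Cortical region names of an atlas
#' @param atlas A [brain_atlas()].
#' @return Character vector of region names excluding the thalamus record.
#' @export
cortical_regions <- function(atlas) {
  atlas$name[atlas$name != "Thalamus"]
}

#' Conduction-delay matrix from region centroids
#'
#' Delays are the pairwise Euclidean centroid distances divided by a mean
#' axonal conduction velocity (default 7.5 m/s), giving a symmetric matrix
#' with zero diagonal. Centroids are in mm, the velocity in m/s, delays in
#' seconds.
#'
#' @param atlas A [brain_atlas()].
#' @param velocity Mean propagation velocity in m/s (> 0), default 7.5.
#' @return Square numeric matrix (s), dimnames = region names.
#' @export
build_delay_matrix <- function(atlas, velocity = 7.5) {
  stopifnot(inherits(atlas, "brain_atlas"))
  if (!is.numeric(velocity) || length(velocity) != 1L || !is.finite(velocity) ||
      velocity <= 0) {
    stop("velocity must be a positive finite scalar (m/s)")
  }
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  d_mm <- as.matrix(stats::dist(xyz))
  delay <- (d_mm / 1000) / velocity
  dimnames(delay) <- list(atlas$name, atlas$name)
  delay
}

.check_connectivity <- function(connectivity, regions) {
  connectivity <- as.matrix(connectivity)
  if (nrow(connectivity) != ncol(connectivity)) stop("connectivity must be square")
  if (is.null(rownames(connectivity))) {
    if (nrow(connectivity) != length(regions)) {
      stop("connectivity dimensions do not match the atlas")
    }
    dimnames(connectivity) <- list(regions, regions)
  }
  if (!setequal(rownames(connectivity), regions) ||
      nrow(connectivity) != length(regions)) {
    stop("connectivity region names do not match the atlas")
  }
  connectivity <- connectivity[regions, regions]
  if (any(!is.finite(connectivity)) || any(connectivity < 0)) {
    stop("connectivity weights must be finite and non-negative")
  }
  diag(connectivity) <- 0
  connectivity
}

#' Couple regional masses into the whole-brain delayed network
#'
#' One neural mass per atlas region: a six-subpopulation neocortical column
#' for every cortical region and, when the atlas carries a `"Thalamus"`
#' record, a three-subpopulation thalamic mass. Long-range connections are
#' glutamatergic, originate from PYR of the source region and reach the
#' PYR, PV, SST, VIP and NGFC subpopulations of the target column; the
#' thalamic TC output reaches the same five classes of every cortical
#' column, and every cortical PYR pool projects onto TC, RN1 and RN2.
#' Cortico-cortical weights are the connectivity matrix normalised to unit
#' maximum and scaled by `global_coupling`; thalamocortical and
#' corticothalamic weights are single shared scalars.
#'
#' @param atlas A [brain_atlas()] (66 cortical regions + thalamus for the
#'   default whole-brain model).
#' @param connectivity Square non-negative cortical connectivity matrix
#'   (regions x regions, fibre-density scale); dimensions must match the
#'   cortical regions of the atlas.
#' @param params A single [cortical_column_params()] applied to every
#'   cortical region, or a named list keyed by region name.
#' @param thalamus A [thalamus_params()] (ignored when the atlas has no
#'   thalamus record).
#' @param global_coupling Scalar gain on the normalised cortico-cortical
#'   weights.
#' @param w_thalamocortical Weight of the TC afferent onto each cortical
#'   column.
#' @param w_corticothalamic Weight of each cortical PYR afferent onto the
#'   thalamus.
#' @param velocity Conduction velocity (m/s) for [build_delay_matrix()].
#' @return An object of class `"network_model"`.
#' @export
build_network <- function(atlas, connectivity,
                          params = cortical_column_params(),
                          thalamus = thalamus_params(),
                          global_coupling = 15,
                          w_thalamocortical = 2,
                          w_corticothalamic = 0.05,
                          velocity = 7.5) {
  stopifnot(inherits(atlas, "brain_atlas"))
  ctx <- cortical_regions(atlas)
  has_tha <- "Thalamus" %in% atlas$name
  # keep cortical regions first, thalamus last
  ord <- c(ctx, if (has_tha) "Thalamus")
  atlas <- brain_atlas(atlas[match(ord, atlas$name), ])
  connectivity <- .check_connectivity(connectivity, ctx)
  if (inherits(params, "cortical_column_params")) {
    params <- stats::setNames(rep(list(params), length(ctx)), ctx)
  } else {
    stopifnot(is.list(params), setequal(names(params), ctx))
    params <- params[ctx]
  }
  delay <- build_delay_matrix(atlas, velocity)
  structure(list(
    atlas = atlas,
    regions = ctx,
    params = params,
    thalamus = if (has_tha) thalamus else NULL,
    connectivity = connectivity,
    delay = delay,
    global_coupling = global_coupling,
    w_thalamocortical = w_thalamocortical,
    w_corticothalamic = w_corticothalamic,
    velocity = velocity
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat("Whole-brain neural mass network\n")
  cat("  cortical masses:", length(x$regions), "\n")
  cat("  thalamus:", if (is.null(x$thalamus)) "absent" else "present (lumped)", "\n")
  cat("  velocity:", x$velocity, "m/s; global coupling:", x$global_coupling, "\n")
  invisible(x)
}

#' Number of masses in a network model
#' @param model A `"network_model"`.
#' @return Integer count of regional masses (cortical + thalamic).
#' @export
n_masses <- function(model) {
  stopifnot(inherits(model, "network_model"))
  length(model$regions) + as.integer(!is.null(model$thalamus))
}

#' Assign parameter sets to named regions
#'
#' @param model A `"network_model"`.
#' @param regions Character vector of cortical region names.
#' @param params A [cortical_column_params()] applied to all named regions.
#' @return The modified model.
#' @export
set_region_params <- function(model, regions, params) {
  stopifnot(inherits(model, "network_model"),
            inherits(params, "cortical_column_params"))
  unknown <- setdiff(regions, model$regions)
  if (length(unknown)) stop("unknown region(s): ", paste(unknown, collapse = ", "))
  for (r in regions) model$params[[r]] <- params
  model
}

#' Fragment an atlas region into children that keep the parent connectivity
#'
#' Replaces one region by `length(parts)` child regions. Each child's
#' connectivity row and column is a copy of the parent's (the fibre bundle of
#' the parental area is guarded, not split), all other entries are left
#' untouched. Child centroids are placed along the parent's anteroposterior
#' axis at fraction-weighted positions within the parent's extent; child
#' extents are the corresponding fractions of the parent extent.
#'
#' @param atlas A [brain_atlas()].
#' @param connectivity Cortical connectivity matrix matching the atlas.
#' @param region_name Region to fragment.
#' @param parts Numeric vector of positive surface fractions summing to 1.
#' @return List with elements `atlas` and `connectivity`.
#' @export
fragment_region <- function(atlas, connectivity, region_name, parts) {
  stopifnot(inherits(atlas, "brain_atlas"), is.numeric(parts), length(parts) >= 1)
  if (!region_name %in% atlas$name) stop("unknown region: ", region_name)
  if (region_name == "Thalamus") stop("the thalamus cannot be fragmented")
  if (any(parts <= 0) || abs(sum(parts) - 1) > 1e-8) {
    stop("parts must be positive fractions summing to 1")
  }
  ctx <- cortical_regions(atlas)
  connectivity <- .check_connectivity(connectivity, ctx)
  i <- match(region_name, atlas$name)
  parent <- atlas[i, ]
  k <- length(parts)
  child_names <- if (k == 1L) paste0(region_name, "_f1") else
    paste0(region_name, "_f", seq_len(k))
  # anteroposterior axis through the parent centroid; children ordered
  # anterior (largest y) to posterior
  ends <- cumsum(parts)
  starts <- c(0, ends[-k])
  centre_frac <- (starts + ends) / 2          # 0 = anterior edge, 1 = posterior
  offs <- (0.5 - centre_frac) * parent$extent # mm along +y (anterior)
  children <- parent[rep(1L, k), ]
  children$name <- child_names
  children$y <- parent$y + offs
  # keep the children on the parent's cortical shell (same depth)
  r_parent <- sqrt(parent$x^2 + parent$y^2 + parent$z^2)
  if (r_parent > 0) {
    r_child <- sqrt(children$x^2 + children$y^2 + children$z^2)
    children$x <- children$x / r_child * r_parent
    children$y <- children$y / r_child * r_parent
    children$z <- children$z / r_child * r_parent
  }
  children$extent <- parts * parent$extent
  children$parent <- region_name
  new_atlas <- rbind(atlas[seq_len(i - 1L), , drop = FALSE], children,
                     atlas[seq.int(i + 1L, length.out = nrow(atlas) - i), , drop = FALSE])
  new_atlas <- brain_atlas(as.data.frame(new_atlas))

  # expand connectivity: each child copies the parent's row/column
  ci <- match(region_name, rownames(connectivity))
  idx <- c(rep(ci, k), seq_len(nrow(connectivity))[-ci])
  expanded <- connectivity[idx, idx, drop = FALSE]
  nm <- c(child_names, rownames(connectivity)[-ci])
  dimnames(expanded) <- list(nm, nm)
  diag(expanded) <- 0
  # children do not interconnect through the parental self-weight (diag was 0)
  expanded[seq_len(k), seq_len(k)] <- 0
  new_ctx <- cortical_regions(new_atlas)
  expanded <- expanded[new_ctx, new_ctx]
  list(atlas = new_atlas, connectivity = expanded)
}

#' Annul all connections of a region (post-surgical disconnection)
#'
#' Sets every weight to and from the named region to zero, leaving the rest
#' of the matrix untouched. This models the annulled connectivity of a
#' previously resected cortical area.
#'
#' @param connectivity Square named connectivity matrix.
#' @param region_name Region whose row and column are zeroed.
#' @return The modified matrix.
#' @export
annul_region_connections <- function(connectivity, region_name) {
  connectivity <- as.matrix(connectivity)
  if (is.null(rownames(connectivity))) stop("connectivity must carry region names")
  for (r in region_name) {
    if (!r %in% rownames(connectivity)) stop("unknown region: ", r)
    connectivity[r, ] <- 0
    connectivity[, r] <- 0
  }
  connectivity
}

#' Simulate the whole-brain delayed network
#'
#' Every region's PYR (or TC) output rate, lagged by the delay matrix
#' (rounded to the nearest integration step) and scaled by the coupling
#' weights, is summed into the long-range afferent bundle of each target
#' mass. Regions listed in `ez_regions` run with the epileptic parameter set,
#' the rest with their background parameters. Deterministic under a fixed
#' seed; the first `burn_in` seconds are discarded.
#'
#' @param model A `"network_model"`.
#' @param duration Analysis duration (s).
#' @param dt Integration step (s).
#' @param seed Master seed; region i uses noise stream `seed + i`.
#' @param ez_regions Cortical region names simulated with `ez_params`.
#' @param ez_params Parameter set for the epileptogenic-zone masses.
#' @param burn_in Seconds discarded before returning (default 2).
#' @param record_pops Also return per-subpopulation potentials (memory-heavy
#'   for large networks).
#' @return An object of class `"regional_traces"`: matrix `duration*fs` rows
#'   x n regions of layer-V dipole-drive potentials (mV), with attributes
#'   `fs`, `dt`, `seed`, `regions`, `ez_regions`.
#' @export
simulate_network <- function(model, duration = 30, dt = 1 / 2048, seed = 1,
                             ez_regions = character(),
                             ez_params = cortical_column_params("fcd_spikewave"),
                             burn_in = 2, record_pops = FALSE) {
  stopifnot(inherits(model, "network_model"), duration > 0, dt > 0)
  unknown <- setdiff(ez_regions, model$regions)
  if (length(unknown)) stop("unknown EZ region(s): ", paste(unknown, collapse = ", "))
  params <- model$params
  for (r in ez_regions) params[[r]] <- ez_params
  .check_dt(dt, params)
  n_ctx <- length(model$regions)
  has_tha <- !is.null(model$thalamus)
  n <- n_ctx + as.integer(has_tha)
  nsteps <- as.integer(round((duration + burn_in) / dt))

  K <- matrix(0, n, n)
  cmax <- max(model$connectivity)
  if (cmax > 0) {
    K[seq_len(n_ctx), seq_len(n_ctx)] <-
      model$global_coupling * model$connectivity / cmax
  }
  if (has_tha) {
    K[seq_len(n_ctx), n] <- model$w_thalamocortical
    K[n, seq_len(n_ctx)] <- model$w_corticothalamic
  }
  diag(K) <- 0
  Dsteps <- matrix(0L, n, n)
  ord <- c(model$regions, if (has_tha) "Thalamus")
  Dsteps[] <- as.integer(round(model$delay[ord, ord] / dt))

  pm <- .column_param_matrices(params)
  tp <- if (has_tha) .thalamus_param_vectors(model$thalamus) else
    list(W = numeric(8), TAU = rep(1, 8), C = numeric(8), SIG = numeric(9),
         NOISE = numeric(2))
  Z <- .noise_matrix(seed, nsteps, n)
  res <- .engine_simulate(
    n_ctx, pm$W, pm$TAU, pm$C, pm$SIG, pm$NOISE,
    has_tha, tp$W, tp$TAU, tp$C, tp$SIG, tp$NOISE,
    K, Dsteps, Z, nsteps, dt, matrix(numeric(0), 0, 0), record_pops
  )
  keep <- seq.int(as.integer(round(burn_in / dt)) + 1L, nsteps)
  lfp <- res$lfp[keep, , drop = FALSE]
  colnames(lfp) <- ord
  structure(lfp, class = c("regional_traces", class(lfp)),
            fs = 1 / dt, dt = dt, seed = seed, regions = ord,
            ez_regions = ez_regions,
            pops = if (record_pops) res$pops[keep, , drop = FALSE])
}
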
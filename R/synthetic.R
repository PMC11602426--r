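#' Parameters for the neuromast image phantom
#'
#' The phantom emulates a lateral-line neuromast rosette: `n_cells`
#' pear-shaped hair cells approximated as axis-aligned ellipsoids arranged
#' in a ring, each containing a negative-binomial number of endolysosomal
#' vesicles, imaged in two channels (structural reporter; labeled
#' aminoglycoside). The drug channel splits its signal between punctate
#' vesicles and a diffuse cytoplasmic pool: `diffuse_fraction` 0 gives a
#' purely punctate (G418-like) distribution, larger values a mixed
#' diffuse + punctate (neomycin-like) one. Noise is Poisson shot noise
#' plus additive Gaussian read noise; `snr` is the ratio of
#' (mean in-structure reporter signal - background) to the read-noise SD,
#' `Inf` for noise-free phantoms.
#'
#' @param n_cells hair cells in the rosette (default 10; rosettes hold
#'   roughly 8-14).
#' @param cell_radius_um lateral cell semi-axis (default 3.5; the axial
#'   semi-axis is 1.4x this, cells being taller than wide).
#' @param vesicles_per_cell `c(mean, dispersion)` of the per-cell
#'   negative-binomial vesicle count (dispersion = NB `size`; large =
#'   near-Poisson).
#' @param vesicle_radius_um `c(min, max)` vesicle radius, uniform.
#' @param cell_gap_um width of the unlabeled (membrane) gap between
#'   neighbouring cells (default 0.25), the dark boundary a cytoplasmic
#'   reporter leaves between touching cells.
#' @param diffuse_fraction fraction of each cell's drug signal placed in
#'   the cytoplasm rather than vesicles, in `[0, 1]`.
#' @param ag_total_per_cell optional fixed drug-signal budget per cell
#'   (intensity-sum units). When set, vesicles keep their fixed per-voxel
#'   amplitude and the cytoplasm absorbs the remainder of the budget —
#'   the lysosome-disruption (GPN-like) regime where vesicle number drops
#'   but total signal is conserved. When `NULL` (default) the cytoplasm
#'   receives `diffuse_fraction / (1 - diffuse_fraction)` of the realized
#'   vesicle signal, so `diffuse_fraction = 0` puts all signal in
#'   vesicles exactly.
#' @param snr signal-to-read-noise ratio; `Inf` disables noise.
#' @param voxel_size_um `(z, y, x)` voxel size (default `c(1, 0.2, 0.2)`:
#'   z sections at 1 um intervals, high-zoom lateral sampling).
#' @param shape_px `(z, y, x)` array extent (default `c(20, 192, 192)`).
#' @param drift_px_per_frame `(dy, dx)` per-frame drift for
#'   [gen_timelapse()].
#' @param seed RNG seed; identical seeds give bit-identical phantoms.
#' @return A validated `stack_phantom_params` list.
#' @export
stack_phantom_params <- function(n_cells = 10L,
                                 cell_radius_um = 3.5,
                                 vesicles_per_cell = c(mean = 5, dispersion = 20),
                                 vesicle_radius_um = c(0.4, 0.8),
                                 cell_gap_um = 0.25,
                                 diffuse_fraction = 0.15,
                                 ag_total_per_cell = NULL,
                                 snr = 20,
                                 voxel_size_um = c(1, 0.2, 0.2),
                                 shape_px = c(20L, 192L, 192L),
                                 drift_px_per_frame = c(0, 0),
                                 seed = 1L) {
  stopifnot(n_cells >= 1, cell_radius_um > 0,
            vesicles_per_cell[1] >= 0, vesicles_per_cell[2] > 0,
            length(vesicle_radius_um) == 2, all(vesicle_radius_um > 0),
            cell_gap_um >= 0,
            diffuse_fraction >= 0, diffuse_fraction <= 1,
            snr > 0, length(voxel_size_um) == 3, all(voxel_size_um > 0),
            length(shape_px) == 3, all(shape_px >= 4),
            length(drift_px_per_frame) == 2)
  p <- list(n_cells = as.integer(n_cells), cell_radius_um = cell_radius_um,
            vesicles_per_cell = unname(vesicles_per_cell),
            vesicle_radius_um = vesicle_radius_um,
            cell_gap_um = cell_gap_um,
            diffuse_fraction = diffuse_fraction,
            ag_total_per_cell = ag_total_per_cell,
            snr = snr, voxel_size_um = as.numeric(voxel_size_um),
            shape_px = as.integer(shape_px),
            drift_px_per_frame = as.numeric(drift_px_per_frame),
            seed = as.integer(seed))
  geom <- rosette_geometry(p)
  lat_need <- 2 * (geom$ring_radius_um + cell_radius_um) + 2
  if (lat_need > p$shape_px[2] * p$voxel_size_um[2] ||
      lat_need > p$shape_px[3] * p$voxel_size_um[3] ||
      2 * 1.4 * cell_radius_um + 2 > p$shape_px[1] * p$voxel_size_um[1])
    stop("shape too small for ", n_cells, " cells of radius ",
         cell_radius_um, " um")
  structure(p, class = "stack_phantom_params")
}

rosette_geometry <- function(p) {
  # ring radius giving neighbouring centres ~1.1 lateral radii apart
  # (cells wedge together like a rosette), floored for very few cells
  rr <- max(p$cell_radius_um,
            1.1 * p$cell_radius_um * p$n_cells / (2 * pi))
  ang <- 2 * pi * (seq_len(p$n_cells) - 1) / p$n_cells
  list(ring_radius_um = rr, angles = ang)
}

# constants of the phantom's intensity model (normalized [0,1] scale)
PHANTOM_BG <- 0.02
PHANTOM_CELL_INT <- 0.45
PHANTOM_VESICLE_AMP <- 0.8
PHANTOM_PHOTONS <- 400

#' Generate a two-channel neuromast phantom with ground truth
#'
#' Builds the rosette described by [stack_phantom_params()] and returns
#' the noisy two-channel stack (`reporter`, `ag`) together with the exact
#' ground truth every downstream stage can be scored against: the
#' neuromast mask (union of cell ellipsoids), per-cell labels (each voxel
#' owned by its nearest cell), per-vesicle labels, and a vesicle table
#' with centroid, volume and total drug signal.
#'
#' @param params a [stack_phantom_params()].
#' @return List: `stack` (`voxel_stack`), `neuromast`, `cells`, `vesicles`
#'   (`label_volume`s), `vesicle_truth` (data.frame: vesicle_id, cell_id,
#'   centroid_z/y/x, volume_voxels, total_ag), `clean` (noise-free
#'   two-channel array), `params`.
#' @export
gen_neuromast_stack <- function(params = stack_phantom_params()) {
  stopifnot(inherits(params, "stack_phantom_params"))
  set.seed(params$seed)
  d <- params$shape_px
  vox <- params$voxel_size_um
  geom <- rosette_geometry(params)

  # physical coordinates of voxel centres
  zc <- (seq_len(d[1]) - 0.5) * vox[1]
  yc <- (seq_len(d[2]) - 0.5) * vox[2]
  xc <- (seq_len(d[3]) - 0.5) * vox[3]
  cz <- mean(range(zc)); cy <- mean(range(yc)); cx <- mean(range(xc))

  centers <- cbind(z = rep(cz, params$n_cells),
                   y = cy + geom$ring_radius_um * sin(geom$angles),
                   x = cx + geom$ring_radius_um * cos(geom$angles))
  semi <- c(z = 1.4 * params$cell_radius_um,
            y = params$cell_radius_um, x = params$cell_radius_um)

  # normalized squared ellipsoid distance of every voxel to every cell
  Z <- array(rep(zc, times = d[2] * d[3]), d)
  Y <- array(rep(rep(yc, each = d[1]), times = d[3]), d)
  X <- array(rep(xc, each = d[1] * d[2]), d)
  cells <- array(0L, d)
  bestd <- array(Inf, d)
  bestd2 <- array(Inf, d)
  for (i in seq_len(params$n_cells)) {
    # superellipsoid: quadratic laterally, quartic in z — columnar cells
    # with blunt apical/basal ends rather than pointed ellipsoid tips
    nd <- ((Z - centers[i, 1]) / semi[1])^4 +
          ((Y - centers[i, 2]) / semi[2])^2 +
          ((X - centers[i, 3]) / semi[3])^2
    better <- nd < bestd
    bestd2[better] <- bestd[better]
    second <- !better & nd < bestd2
    bestd2[second] <- nd[second]
    inside <- nd <= 1 & better
    cells[inside] <- i
    bestd[nd < bestd] <- nd[nd < bestd]
  }
  # membrane gap: voxels too close to the bisector between two cells are
  # interstitial, leaving the dark boundary a cytoplasmic reporter shows
  if (params$cell_gap_um > 0) {
    gap_nd <- 2 * params$cell_gap_um / params$cell_radius_um
    cells[bestd2 - bestd < gap_nd & cells > 0L] <- 0L
  }
  if (!any(cells > 0L)) stop("degenerate phantom: no cell voxels")
  # the neuromast is the solid rosette: cells plus the membrane gaps and
  # the interstitial core (slice-wise closing over the gap width, then
  # hole filling)
  gap_px <- max(1L, as.integer(ceiling(params$cell_gap_um / vox[2])) + 1L)
  nm_mask <- cells > 0L
  brush <- EBImage::makeBrush(2L * gap_px + 1L, shape = "disc")
  for (z in seq_len(d[1]))
    nm_mask[z, , ] <- EBImage::closing(nm_mask[z, , ] * 1, brush) > 0
  nm_mask <- fill_holes_slicewise(nm_mask)

  # --- vesicles -----------------------------------------------------------
  n_ves_per_cell <- rnbinom(params$n_cells,
                            size = params$vesicles_per_cell[2],
                            mu = params$vesicles_per_cell[1])
  vesicles <- array(0L, d)
  truth <- list()
  ves_id <- 0L
  min_sep_um <- 2 * params$vesicle_radius_um[2] + 0.4
  placed <- matrix(numeric(0), 0, 3)
  for (i in seq_len(params$n_cells)) {
    # candidate centres: well inside the cell so the vesicle fits
    cand <- which(cells == i & bestd < 0.6)
    if (length(cand) == 0) cand <- which(cells == i)
    for (v in seq_len(n_ves_per_cell[i])) {
      r_um <- runif(1, params$vesicle_radius_um[1], params$vesicle_radius_um[2])
      pos <- NULL
      for (try in 1:50) {
        j <- cand[sample.int(length(cand), 1)]
        pj <- c(Z[j], Y[j], X[j])
        if (nrow(placed) == 0 ||
            min(sqrt(colSums((t(placed) - pj)^2))) >= min_sep_um) {
          pos <- pj; break
        }
        if (try == 50) pos <- pj   # dense cell: accept a close placement
      }
      placed <- rbind(placed, pos)
      ves_id <- ves_id + 1L
      nd <- ((Z - pos[1]) / max(r_um, vox[1] / 2))^2 +
            ((Y - pos[2]) / r_um)^2 + ((X - pos[3]) / r_um)^2
      vox_in <- which(nd <= 1 & cells == i & vesicles == 0L)
      if (length(vox_in) == 0)   # radius below grid: claim the centre voxel
        vox_in <- which.min(nd + ifelse(cells == i & vesicles == 0L, 0, Inf))
      vesicles[vox_in] <- ves_id
      truth[[ves_id]] <- data.frame(
        vesicle_id = ves_id, cell_id = i,
        centroid_z = mean(Z[vox_in]) / vox[1] + 0.5,
        centroid_y = mean(Y[vox_in]) / vox[2] + 0.5,
        centroid_x = mean(X[vox_in]) / vox[3] + 0.5,
        volume_voxels = length(vox_in),
        total_ag = length(vox_in) * PHANTOM_VESICLE_AMP)
    }
  }
  vesicle_truth <- if (ves_id > 0) do.call(rbind, truth) else
    data.frame(vesicle_id = integer(0), cell_id = integer(0),
               centroid_z = numeric(0), centroid_y = numeric(0),
               centroid_x = numeric(0), volume_voxels = integer(0),
               total_ag = numeric(0))

  # --- intensity model ----------------------------------------------------
  reporter <- array(PHANTOM_BG, d)
  reporter[cells > 0L] <- PHANTOM_CELL_INT
  ag <- array(0, d)
  ag[vesicles > 0L] <- PHANTOM_VESICLE_AMP
  for (i in seq_len(params$n_cells)) {
    cyto_i <- cells == i & vesicles == 0L
    n_cyto <- sum(cyto_i)
    if (n_cyto == 0) next
    ves_signal <- sum(vesicle_truth$total_ag[vesicle_truth$cell_id == i])
    diffuse <- if (!is.null(params$ag_total_per_cell)) {
      max(params$ag_total_per_cell - ves_signal, 0)
    } else if (params$diffuse_fraction >= 1) {
      # all-diffuse limit: reuse the expected punctate budget
      params$vesicles_per_cell[1] * PHANTOM_VESICLE_AMP * 8
    } else {
      ves_signal * params$diffuse_fraction / (1 - params$diffuse_fraction)
    }
    ag[cyto_i] <- ag[cyto_i] + diffuse / n_cyto
  }
  ag <- ag + PHANTOM_BG / 2

  clean <- array(0, c(2, d))
  clean[1, , , ] <- reporter
  clean[2, , , ] <- ag
  noisy <- add_camera_noise(clean, params$snr, nm_mask)

  list(stack = voxel_stack(noisy, c("reporter", "ag"), vox),
       neuromast = label_volume(nm_mask, "neuromast"),
       cells = label_volume(cells, "cells"),
       vesicles = label_volume(vesicles, "vesicles"),
       vesicle_truth = vesicle_truth,
       clean = clean,
       params = params)
}

# Poisson shot noise + Gaussian read noise on a (c, z, y, x) array.
# read-noise SD = (mean in-structure reporter signal - background) / snr.
add_camera_noise <- function(clean, snr, structure_mask) {
  if (!is.finite(snr)) return(clean)
  sig <- mean(clean[1, , , ][structure_mask]) - PHANTOM_BG
  read_sd <- sig / snr
  noisy <- array(rpois(length(clean), clean * PHANTOM_PHOTONS) /
                   PHANTOM_PHOTONS,
                 dim(clean))
  noisy <- noisy + rnorm(length(clean), sd = read_sd)
  noisy[noisy < 0] <- 0
  noisy
}

#' Generate a drifting two-channel time lapse
#'
#' Frame 1 is the clean phantom; frame t is frame 1 rigidly displaced by
#' the cumulative drift `(t - 1) * drift_px_per_frame` (bilinear warp),
#' with fresh camera noise per frame. The true per-frame cumulative drift
#' is returned for registration scoring.
#'
#' @param params a [stack_phantom_params()] (its `drift_px_per_frame` and
#'   `snr` apply).
#' @param n_frames number of frames (>= 2).
#' @param time_interval_s frame interval (default 30 s).
#' @return List: `stack` (time-lapse `voxel_stack`), `drift` (data.frame:
#'   frame, dy, dx cumulative true drift), `phantom` (the underlying
#'   [gen_neuromast_stack()] output).
#' @export
gen_timelapse <- function(params = stack_phantom_params(), n_frames,
                          time_interval_s = 30) {
  stopifnot(n_frames >= 2)
  dr <- params$drift_px_per_frame
  d <- params$shape_px
  max_shift <- (n_frames - 1) * abs(dr)
  if (max_shift[1] >= d[2] / 2 || max_shift[2] >= d[3] / 2)
    stop("cumulative drift (", paste(round(max_shift, 1), collapse = ", "),
         " px) exceeds half the field; phantom would leave the image")
  ph <- gen_neuromast_stack(params)
  set.seed(params$seed + 1L)
  clean <- ph$clean
  nm_mask <- as_mask(ph$neuromast)
  data <- array(0, c(n_frames, 2, d))
  drift <- data.frame(frame = seq_len(n_frames),
                      dy = (seq_len(n_frames) - 1) * dr[1],
                      dx = (seq_len(n_frames) - 1) * dr[2])
  for (t in seq_len(n_frames)) {
    ft <- clean
    if (drift$dy[t] != 0 || drift$dx[t] != 0) {
      for (ci in 1:2) for (z in seq_len(d[1])) {
        w <- warp_rigid(clean[ci, z, , ], 0, drift$dy[t], drift$dx[t])
        attr(w, "valid") <- NULL
        ft[ci, z, , ] <- w
      }
    }
    data[t, , , , ] <- add_camera_noise(ft, params$snr, nm_mask)
  }
  list(stack = voxel_stack(data, c("reporter", "ag"), params$voxel_size_um,
                           time_interval_s = time_interval_s),
       drift = drift, phantom = ph)
}

#' Parameters for synthetic calcium traces
#'
#' Emulates single-cell calcium recordings: a pre-exposure baseline
#' (default 5 frames at 30 s, i.e. 2.5 min), then the exposure period.
#' Dying responder cells carry one calcium transient — a Gaussian bump on
#' the F/F0 scale peaking `peak_lag_frames` before the fragmentation
#' frame, with peak amplitude drawn from
#' `Normal(peak_mean, peak_sd)` and floored at baseline + 6 `noise_sd`
#' so the two-SD rule is met by construction even after baseline noise.
#' Dying non-responders stay flat (their noiseless trace never leaves
#' baseline). Dying traces end at their fragmentation frame.
#'
#' @param n_dying,n_living cell counts.
#' @param frame_interval_s frame interval (default 30).
#' @param baseline_frames baseline length (default 5).
#' @param n_frames total frames including baseline (default 125, one hour
#'   of exposure at 30 s).
#' @param peak_mean,peak_sd peak F/F0 distribution of responders.
#' @param responder_fraction fraction of dying cells that respond.
#' @param noise_sd additive noise SD on the F/F0 scale.
#' @param frag_frame_range `c(min, max)` uniform fragmentation frame for
#'   dying cells (after the baseline).
#' @param peak_lag_frames frames between transient peak and fragmentation
#'   (default 3).
#' @param transient_width_frames Gaussian width of the transient
#'   (default 4).
#' @param f0 raw baseline intensity (default 100).
#' @param seed RNG seed.
#' @return A validated `trace_phantom_params` list.
#' @export
trace_phantom_params <- function(n_dying = 16L, n_living = 8L,
                                 frame_interval_s = 30,
                                 baseline_frames = 5L, n_frames = 125L,
                                 peak_mean = 2.2, peak_sd = 0.46,
                                 responder_fraction = 1,
                                 noise_sd = 0.05,
                                 frag_frame_range = c(20L, 120L),
                                 peak_lag_frames = 3L,
                                 transient_width_frames = 4,
                                 f0 = 100, seed = 1L) {
  stopifnot(n_dying >= 0, n_living >= 0, baseline_frames >= 2,
            n_frames > baseline_frames,
            responder_fraction >= 0, responder_fraction <= 1,
            noise_sd >= 0, f0 > 0,
            frag_frame_range[1] > baseline_frames,
            frag_frame_range[2] <= n_frames,
            frag_frame_range[1] <= frag_frame_range[2])
  structure(list(n_dying = as.integer(n_dying),
                 n_living = as.integer(n_living),
                 frame_interval_s = frame_interval_s,
                 baseline_frames = as.integer(baseline_frames),
                 n_frames = as.integer(n_frames),
                 peak_mean = peak_mean, peak_sd = peak_sd,
                 responder_fraction = responder_fraction,
                 noise_sd = noise_sd,
                 frag_frame_range = as.integer(frag_frame_range),
                 peak_lag_frames = as.integer(peak_lag_frames),
                 transient_width_frames = transient_width_frames,
                 f0 = f0, seed = as.integer(seed)),
            class = "trace_phantom_params")
}

#' Generate synthetic calcium traces with ground truth
#'
#' @param params a [trace_phantom_params()].
#' @param condition condition label stamped on every trace.
#' @return List: `traces` (list of [calcium_trace()]s) and `truth`
#'   (data.frame: cell, fate, responder, frag_frame, peak_true — the
#'   realized noiseless peak F/F0, `NA` for non-responders/living).
#' @export
gen_calcium_traces <- function(params = trace_phantom_params(),
                               condition = NA) {
  stopifnot(inherits(params, "trace_phantom_params"))
  set.seed(params$seed)
  traces <- list()
  truth <- list()
  n_tot <- params$n_dying + params$n_living
  responder <- c(runif(params$n_dying) < params$responder_fraction,
                 rep(FALSE, params$n_living))
  fate <- rep(c("dying", "living"), c(params$n_dying, params$n_living))
  floor_peak <- 1 + max(6 * params$noise_sd, 0.02)
  for (i in seq_len(n_tot)) {
    if (fate[i] == "dying") {
      frag <- sample(params$frag_frame_range[1]:params$frag_frame_range[2], 1)
      n <- frag
    } else {
      frag <- NA_integer_
      n <- params$n_frames
    }
    t_idx <- seq_len(n)
    ff0 <- rep(1, n)
    peak_true <- NA_real_
    if (responder[i]) {
      peak_true <- max(rnorm(1, params$peak_mean, params$peak_sd), floor_peak)
      t_pk <- frag - params$peak_lag_frames
      bump <- (peak_true - 1) *
        exp(-(t_idx - t_pk)^2 / (2 * params$transient_width_frames^2))
      bump[t_idx <= params$baseline_frames] <- 0
      ff0 <- ff0 + bump
    }
    noisy_ff0 <- ff0 + rnorm(n, sd = params$noise_sd)
    if (fate[i] == "dying" && !responder[i]) {
      # non-responders stay within the 2-SD rule by construction: clamp
      # post-baseline excursions below the threshold the realized
      # baseline implies
      bl <- noisy_ff0[seq_len(params$baseline_frames)]
      cap <- mean(bl) + 2 * sd(bl) - 1e-6
      post <- (params$baseline_frames + 1L):n
      noisy_ff0[post] <- pmin(noisy_ff0[post], cap)
    }
    intens <- params$f0 * noisy_ff0
    intens[intens <= 0] <- params$f0 * 1e-3
    traces[[i]] <- calcium_trace(intens, cell_id = i, condition = condition,
                                 fate = fate[i],
                                 frame_interval_s = params$frame_interval_s,
                                 baseline_frames = params$baseline_frames,
                                 frag_frame = frag)
    truth[[i]] <- data.frame(cell = i, fate = fate[i],
                             responder = responder[i], frag_frame = frag,
                             peak_true = peak_true)
  }
  list(traces = traces, truth = do.call(rbind, truth))
}

#' Parameters for synthetic dose-response count tables
#'
#' Per-fish summed hair-cell counts (4 neuromasts per fish) under a Hill
#' survival law: expected survival at dose d is
#' `1 / (1 + (d / HC50)^slope)` of the control mean. Each fish's capacity
#' is Poisson around `control_mean_per_fish` and its realized survival
#' probability is beta-distributed around the Hill value with
#' intra-class correlation `dispersion`, giving fish-to-fish
#' overdispersion beyond Poisson.
#'
#' @param true_hc50_um generating HC50 (> 0).
#' @param hill_slope Hill coefficient (default 2).
#' @param control_mean_per_fish mean control count, 4 neuromasts summed
#'   (default 60).
#' @param doses_um dose ladder, must include 0 (controls).
#' @param n_fish_per_dose fish per dose (default 10, matching the 9-13
#'   per condition of the counting design).
#' @param dispersion beta intra-class correlation in `[0, 1)`; 0 =
#'   binomial thinning only (default 0.06).
#' @param drug,paradigm labels stamped on the records.
#' @param seed RNG seed.
#' @return A validated `count_phantom_params` list.
#' @export
count_phantom_params <- function(true_hc50_um, hill_slope = 2,
                                 control_mean_per_fish = 60,
                                 doses_um = c(0, 6.25, 12.5, 25, 50,
                                              100, 200, 400),
                                 n_fish_per_dose = 10L,
                                 dispersion = 0.06,
                                 drug = "neomycin", paradigm = "acute_1h",
                                 seed = 1L) {
  stopifnot(true_hc50_um > 0, hill_slope > 0, control_mean_per_fish > 0,
            n_fish_per_dose >= 1, dispersion >= 0, dispersion < 1)
  if (!0 %in% doses_um) stop("doses must include 0 (controls)")
  structure(list(true_hc50_um = true_hc50_um, hill_slope = hill_slope,
                 control_mean_per_fish = control_mean_per_fish,
                 doses_um = sort(doses_um),
                 n_fish_per_dose = as.integer(n_fish_per_dose),
                 dispersion = dispersion, drug = drug, paradigm = paradigm,
                 seed = as.integer(seed)),
            class = "count_phantom_params")
}

#' Generate a synthetic per-fish count table
#'
#' @param params a [count_phantom_params()].
#' @return data.frame with one row per fish: `fish_id`, `drug`, `dose_um`,
#'   `paradigm`, `count`, `batch`.
#' @export
gen_doseresponse_counts <- function(params) {
  stopifnot(inherits(params, "count_phantom_params"))
  set.seed(params$seed)
  n <- params$n_fish_per_dose
  rows <- lapply(params$doses_um, function(d) {
    p_hill <- 1 / (1 + (d / params$true_hc50_um)^params$hill_slope)
    capacity <- rpois(n, params$control_mean_per_fish)
    p_fish <- if (params$dispersion > 0 && p_hill < 1 && p_hill > 0) {
      theta <- (1 - params$dispersion) / params$dispersion
      rbeta(n, p_hill * theta, (1 - p_hill) * theta)
    } else rep(p_hill, n)
    data.frame(drug = params$drug, dose_um = d, paradigm = params$paradigm,
               count = rbinom(n, capacity, p_fish), batch = 1L)
  })
  out <- do.call(rbind, rows)
  out$fish_id <- seq_len(nrow(out))
  out[, c("fish_id", "drug", "dose_um", "paradigm", "count", "batch")]
}
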
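#' Segmentation parameter set
#'
#' Collects every tunable of the segmentation stages with the pipeline's
#' defaults: strong Gaussian blur (sigma 6 px) + triangle threshold for
#' the neuromast mask; 5-class multi-Otsu background with replacement
#' value 1e-7; Sauvola window 45 px, k = 0.2 for the hair-cell foreground;
#' per-structure `(scale, cutoff)` detector pairs for vesicles.
#'
#' @param neuromast_gaussian_sigma Gaussian sigma in pixels (default 6).
#' @param multiotsu_classes multi-Otsu class count (default 5).
#' @param background_classes lowest classes regarded as background
#'   (default 1).
#' @param background_replacement intensity written into background voxels
#'   before local thresholding (default 1e-7).
#' @param sauvola_window_px odd Sauvola window (default 45).
#' @param sauvola_k Sauvola sensitivity (default 0.2).
#' @param dot_pairs,filament_pairs lists of `c(scale, cutoff)` pairs for
#'   the spot and filament detectors.
#' @param min_object_voxels components smaller than this are treated as
#'   artifacts and removed (default 4).
#' @param fill_holes fill enclosed holes slice-wise (default TRUE).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(neuromast_gaussian_sigma = 6,
                                multiotsu_classes = 5L,
                                background_classes = 1L,
                                background_replacement = 1e-7,
                                sauvola_window_px = 45L,
                                sauvola_k = 0.2,
                                dot_pairs = list(c(4, 0.5), c(2, 0.08)),
                                filament_pairs = list(c(2, 1), c(1, 0.9)),
                                min_object_voxels = 4L,
                                fill_holes = TRUE) {
  if (sauvola_window_px %% 2L != 1L || sauvola_window_px < 3L)
    stop("`sauvola_window_px` must be odd and >= 3")
  check_pairs(dot_pairs); check_pairs(filament_pairs)
  stopifnot(neuromast_gaussian_sigma > 0, multiotsu_classes >= 2,
            min_object_voxels >= 0)
  structure(list(neuromast_gaussian_sigma = neuromast_gaussian_sigma,
                 multiotsu_classes = as.integer(multiotsu_classes),
                 background_classes = as.integer(background_classes),
                 background_replacement = background_replacement,
                 sauvola_window_px = as.integer(sauvola_window_px),
                 sauvola_k = sauvola_k,
                 dot_pairs = dot_pairs,
                 filament_pairs = filament_pairs,
                 min_object_voxels = as.integer(min_object_voxels),
                 fill_holes = isTRUE(fill_holes)),
            class = "segmentation_params")
}

#' Shipped detector presets
#'
#' Loads the `(scale, cutoff)` detector pairs for the two vesicle targets
#' the pipeline was tuned on — `"rab7"` (endolysosomal reporter vesicles)
#' and `"g418"` (labeled-aminoglycoside puncta) — from the YAML presets
#' shipped with the package, merged into a full [segmentation_params()].
#'
#' @param name `"rab7"` or `"g418"`.
#' @return A `segmentation_params` object.
#' @export
vesicle_preset <- function(name = c("rab7", "g418")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_vesicles.yaml"),
                      package = "lateralline", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  segmentation_params(
    dot_pairs = lapply(y$dot_pairs, function(p) c(p$scale, p$cutoff)),
    filament_pairs = lapply(y$filament_pairs, function(p) c(p$scale, p$cutoff)))
}

#' Labelled segmentation volume
#'
#' A thin container pairing an integer label array (0 = background) with
#' the compartment kind it describes.
#'
#' @param labels integer (or logical) 3-D `(z, y, x)` array.
#' @param kind one of `"neuromast"`, `"cells"`, `"vesicles"`,
#'   `"cytoplasm"`.
#' @return A `label_volume` object with elements `labels` and `kind`.
#' @export
label_volume <- function(labels, kind = c("neuromast", "cells", "vesicles",
                                          "cytoplasm")) {
  kind <- match.arg(kind)
  if (is.logical(labels)) {
    lab <- array(0L, dim(labels)); lab[labels] <- 1L; labels <- lab
  }
  stopifnot(length(dim(labels)) == 3L, min(labels) >= 0)
  structure(list(labels = labels, kind = kind), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> kind=", x$kind, ", ",
      paste(dim(x$labels), collapse = " x "), " (z,y,x), ",
      max(x$labels), " label(s)\n", sep = "")
  invisible(x)
}

as_mask <- function(x) {
  if (inherits(x, "label_volume")) x$labels > 0 else x > 0
}

# separable 3-D Gaussian blur; sigma in lateral pixels, sigma_z in slices
gauss_blur3d <- function(x, sigma, sigma_z = sigma) {
  d <- dim(x)
  for (z in seq_len(d[1])) x[z, , ] <- gauss_blur2d(x[z, , ], sigma)
  if (d[1] > 1 && sigma_z > 0) {
    Gz <- gauss_matrix(d[1], sigma_z)
    dim(x) <- c(d[1], d[2] * d[3])
    x <- Gz %*% x
    dim(x) <- d
  }
  x
}

fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    m <- EBImage::fillHull(mask[z, , ] * 1)
    mask[z, , ] <- m > 0
  }
  mask
}

remove_small_components <- function(mask, min_voxels, connectivity = 26L) {
  if (min_voxels <= 1 || !any(mask)) return(mask)
  lab <- ll_label3d(mask, dim(mask), connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep, dim(mask))
}

#' Segment the whole-neuromast mask
#'
#' Strong Gaussian blur (sigma `neuromast_gaussian_sigma`) followed by a
#' triangle-method global threshold, slice-wise hole filling, removal of
#' sub-`min_object_voxels` artifacts, and reduction to the largest
#' connected component.
#'
#' @param reporter normalized 3-D `(z, y, x)` reporter channel.
#' @param params a [segmentation_params()].
#' @param voxel_size_um optional `(z, y, x)` voxel size; when given, the
#'   blur is kept isotropic in physical units (the pixel sigma applies
#'   laterally and is rescaled for the z spacing).
#' @param max_foreground_fraction foreground fraction above which
#'   detection is rejected as structureless (default 0.5).
#' @return A binary `label_volume` of kind `"neuromast"`.
#' @export
segment_neuromast <- function(reporter, params = segmentation_params(),
                              voxel_size_um = NULL,
                              max_foreground_fraction = 0.5) {
  stopifnot(length(dim(reporter)) == 3L)
  sg <- params$neuromast_gaussian_sigma
  sgz <- if (is.null(voxel_size_um)) sg
         else sg * voxel_size_um[2] / voxel_size_um[1]
  sm <- gauss_blur3d(reporter, sg, sgz)
  thr <- triangle_threshold(sm)
  mask <- sm > thr
  # a neuromast is a compact object; a threshold that marks most of the
  # stack means there is no structure to detect (e.g. pure noise)
  if (mean(mask) > max_foreground_fraction)
    stop("no neuromast detected: threshold marks ",
         round(100 * mean(mask)), "% of the stack")
  # and it must stand out from the background: a foreground whose mean
  # barely exceeds the background's is smoothed noise, not structure
  contrast <- mean(sm[mask]) - mean(sm[!mask])
  if (contrast < 0.1 * diff(range(reporter)))
    stop("no neuromast detected: foreground/background contrast too low")
  if (params$fill_holes) mask <- fill_holes_slicewise(mask)
  mask <- remove_small_components(mask, params$min_object_voxels)
  if (!any(mask)) stop("no neuromast detected")
  lab <- ll_label3d(mask, dim(mask), 26L)
  biggest <- which.max(tabulate(lab[lab > 0]))
  label_volume(array(lab == biggest, dim(mask)), "neuromast")
}

#' Multi-Otsu background mask
#'
#' Splits the intensity histogram into `n_classes` classes by exact
#' multi-level Otsu and returns the lowest class (voxels below the first
#' threshold) as the background. For the endolysosomal-reporter route the
#' inverted neuromast mask plays the same role; this operator serves the
#' structural-reporter route.
#'
#' @param reporter 3-D `(z, y, x)` channel.
#' @param n_classes class count (default 5).
#' @param background_classes how many of the lowest classes form the
#'   background (default 1; raise when the background mode is broad
#'   enough to straddle several classes).
#' @return Logical `(z, y, x)` background mask.
#' @export
background_mask_multiotsu <- function(reporter, n_classes = 5L,
                                      background_classes = 1L) {
  stopifnot(background_classes >= 1, background_classes < n_classes)
  thr <- multiotsu_thresholds(reporter, n_classes = n_classes)
  reporter < thr[background_classes]
}

#' Seed set for hair-cell watershed
#'
#' @param points data.frame with integer columns `z`, `y`, `x` (1-based
#'   voxel coordinates), one row per cell.
#' @param path alternatively, a CSV file with those columns.
#' @return A `seed_set` data.frame.
#' @export
seed_set <- function(points = NULL, path = NULL) {
  if (is.null(points)) points <- read.csv(path)
  stopifnot(all(c("z", "y", "x") %in% names(points)))
  if (anyDuplicated(points[, c("z", "y", "x")]))
    stop("duplicate seeds at identical voxel coordinates: rows ",
         paste(which(duplicated(points[, c("z", "y", "x")])), collapse = ", "))
  structure(points[, c("z", "y", "x")], class = c("seed_set", "data.frame"))
}

#' Segment individual hair cells by seeded watershed
#'
#' Background voxels (from the multi-Otsu background mask) are replaced
#' with `background_replacement`, a slice-wise Sauvola local threshold
#' (window 45 px, k 0.2) yields the cell foreground, holes are filled and
#' artifacts removed, and a seeded watershed on the negated Euclidean
#' distance transform assigns one label per seed (label i = seed row i).
#' Seeds falling outside the foreground are flagged with a warning and
#' yield no label.
#'
#' @param reporter normalized 3-D `(z, y, x)` structural channel.
#' @param seeds a [seed_set()], one seed per cell.
#' @param params a [segmentation_params()].
#' @param background logical background mask; computed by
#'   [background_mask_multiotsu()] when omitted.
#' @param voxel_size_um `(z, y, x)` spacing for the distance transform;
#'   isotropic pixels by default.
#' @param edits optional data.frame of label corrections applied last,
#'   columns `op` (`"merge"`, `"delete"`), `from`, `to`.
#' @return A `label_volume` of kind `"cells"`.
#' @export
segment_hair_cells <- function(reporter, seeds,
                               params = segmentation_params(),
                               background = NULL,
                               voxel_size_um = c(1, 1, 1),
                               edits = NULL) {
  stopifnot(length(dim(reporter)) == 3L)
  d <- dim(reporter)
  if (is.null(background))
    background <- background_mask_multiotsu(reporter, params$multiotsu_classes,
                                            params$background_classes)
  work <- reporter
  work[background] <- params$background_replacement
  fg <- sauvola_mask(work, params$sauvola_window_px, params$sauvola_k)
  fg <- fg & !background
  if (params$fill_holes) fg <- fill_holes_slicewise(fg)
  fg <- remove_small_components(fg, params$min_object_voxels)

  if (nrow(seeds) == 0) {
    warning("no seeds given: returning empty cell labels")
    return(label_volume(array(0L, d), "cells"))
  }
  seed_arr <- array(0L, d)
  dropped <- integer(0)
  for (i in seq_len(nrow(seeds))) {
    zyx <- as.integer(seeds[i, c("z", "y", "x")])
    if (any(zyx < 1L) || any(zyx > d)) { dropped <- c(dropped, i); next }
    if (!fg[zyx[1], zyx[2], zyx[3]]) { dropped <- c(dropped, i); next }
    seed_arr[zyx[1], zyx[2], zyx[3]] <- i
  }
  if (length(dropped))
    warning("seed(s) outside the cell foreground, omitted: ",
            paste(dropped, collapse = ", "))
  dist <- ll_edt3d(fg, d, as.numeric(voxel_size_um))
  lab <- ll_watershed3d(-dist, seed_arr, fg, d)
  if (!is.null(edits)) lab <- apply_label_edits(lab, edits)
  label_volume(lab, "cells")
}

# Scriptable replay of manual label corrections.
apply_label_edits <- function(lab, edits) {
  stopifnot(all(c("op", "from", "to") %in% names(edits)))
  for (i in seq_len(nrow(edits))) {
    op <- edits$op[i]
    if (op == "merge") lab[lab == edits$from[i]] <- edits$to[i]
    else if (op == "delete") lab[lab == edits$from[i]] <- 0L
    else stop("unknown edit op '", op, "'")
  }
  lab
}

#' Segment vesicles by fused spot + filament detection
#'
#' The two slice-wise detector masks are fused (union), holes filled,
#' artifacts below `min_object_voxels` removed, and the result labelled by
#' 26-connected components in 3-D. Touching vesicles may share a label
#' (no splitting is attempted). Labels with no voxel inside the neuromast
#' mask are discarded; by default partially-overlapping labels are kept
#' and clipped to the mask (`outside = "clip"`), or dropped entirely with
#' `outside = "strict"`.
#'
#' @param channel normalized 3-D `(z, y, x)` vesicle channel (labeled
#'   aminoglycoside or endolysosomal reporter).
#' @param params a [segmentation_params()] carrying the detector pairs.
#' @param neuromast binary `label_volume` (or logical array) restricting
#'   the segmentation.
#' @param outside `"clip"` (default) or `"strict"`.
#' @return A `label_volume` of kind `"vesicles"` with consecutive labels.
#' @export
segment_vesicles <- function(channel, params, neuromast,
                             outside = c("clip", "strict")) {
  outside <- match.arg(outside)
  nm <- as_mask(neuromast)
  stopifnot(identical(dim(channel), dim(nm)))
  fused <- detect_dots_2d(channel, params$dot_pairs) |
           detect_filaments_2d(channel, params$filament_pairs)
  if (params$fill_holes) fused <- fill_holes_slicewise(fused)
  fused <- remove_small_components(fused, params$min_object_voxels)
  lab <- ll_label3d(fused, dim(fused), 26L)
  if (max(lab) > 0) {
    n_lab <- max(lab)
    inside <- tabulate(lab[nm], n_lab)
    total <- tabulate(lab[lab > 0], n_lab)
    keep <- if (outside == "clip") which(inside > 0)
            else which(inside == total & total > 0)
    relab <- integer(n_lab)
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
    lab[!nm] <- 0L   # clip to the neuromast mask
  }
  label_volume(lab, "vesicles")
}

#' Cytoplasm mask as neuromast minus vesicles
#'
#' @param neuromast binary `label_volume` (kind `"neuromast"`).
#' @param vesicles `label_volume` of vesicle labels on the same grid.
#' @return Binary `label_volume` of kind `"cytoplasm"`. The partition
#'   invariant (cytoplasm and vesicles disjoint, union = neuromast) holds
#'   exactly and is asserted.
#' @export
make_cytoplasm_mask <- function(neuromast, vesicles) {
  nm <- as_mask(neuromast); ves <- as_mask(vesicles)
  if (!identical(dim(nm), dim(ves)))
    stop("neuromast and vesicle grids disagree: ",
         paste(dim(nm), collapse = "x"), " vs ", paste(dim(ves), collapse = "x"))
  if (any(ves & !nm))
    stop("vesicle voxels outside the neuromast mask: partition impossible")
  cyto <- nm & !ves
  stopifnot(!any(cyto & ves), identical(cyto | ves, nm))
  label_volume(cyto, "cytoplasm")
}
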
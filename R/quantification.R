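#' Per-vesicle property table
#'
#' One row per vesicle label with voxel and physical volume, centroid, and
#' mean/total intensity in every channel of the stack. When a cell label
#' volume is supplied, each vesicle is assigned to the cell holding the
#' majority of its voxels (`cell_id = NA` when no cell overlaps).
#'
#' @param vesicles `label_volume` of kind `"vesicles"`.
#' @param stack the `voxel_stack` the labels were derived from.
#' @param cells optional `label_volume` of kind `"cells"`.
#' @param frame time frame for time-lapse stacks.
#' @return data.frame with columns `vesicle_id`, `cell_id`,
#'   `volume_voxels`, `volume_um3`, `centroid_z/y/x`, and
#'   `mean_<channel>`, `total_<channel>` per channel. Empty labels give an
#'   empty table.
#' @export
vesicle_table <- function(vesicles, stack, cells = NULL, frame = 1L) {
  lab <- vesicles$labels
  stopifnot(length(dim(lab)) == 3L)
  n_lab <- max(lab)
  chans <- stack$channel_names
  cols <- c("vesicle_id", "cell_id", "volume_voxels", "volume_um3",
            "centroid_z", "centroid_y", "centroid_x",
            paste0("mean_", chans), paste0("total_", chans))
  if (n_lab == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  pos <- which(lab > 0)
  ids <- lab[pos]
  d <- dim(lab)
  z <- (pos - 1) %% d[1] + 1
  y <- ((pos - 1) %/% d[1]) %% d[2] + 1
  x <- (pos - 1) %/% (d[1] * d[2]) + 1
  vol <- tabulate(ids, n_lab)
  vox_um3 <- prod(stack$voxel_size_um)
  out <- data.frame(
    vesicle_id = seq_len(n_lab),
    cell_id = NA_integer_,
    volume_voxels = vol,
    volume_um3 = vol * vox_um3,
    centroid_z = as.numeric(tapply(z, ids, mean)),
    centroid_y = as.numeric(tapply(y, ids, mean)),
    centroid_x = as.numeric(tapply(x, ids, mean)))
  for (ch in chans) {
    v <- get_channel(stack, ch, frame = frame)[pos]
    tot <- as.numeric(tapply(v, ids, sum))
    out[[paste0("mean_", ch)]] <- tot / vol
    out[[paste0("total_", ch)]] <- tot
  }
  if (!is.null(cells)) {
    cl <- cells$labels[pos]
    for (i in seq_len(n_lab)) {
      ci <- cl[ids == i]
      ci <- ci[ci > 0]
      if (length(ci))
        out$cell_id[i] <- as.integer(names(which.max(table(ci))))
    }
  }
  out[, cols]
}

#' Per-neuromast summary statistics
#'
#' Aggregates a vesicle table over one neuromast: vesicles per hair cell
#' (vesicle count / cell count), mean vesicle volume and fluorescence, the
#' total signal in the measured channel over the whole neuromast mask, and
#' the vesicle-to-cytoplasm intensity ratio when the masks are supplied.
#'
#' @param records a [vesicle_table()] data.frame.
#' @param cells `label_volume` of kind `"cells"` (>= 1 cell required).
#' @param channel name of the measured (drug) channel in the table.
#' @param stack,neuromast optional; when both given, the total channel
#'   signal inside the neuromast mask is reported.
#' @return One-row data.frame: `n_cells`, `n_vesicles`,
#'   `vesicles_per_cell_mean`, `vesicle_volume_mean_um3`,
#'   `vesicle_fluorescence_mean`, `total_fluorescence` (`NA` without
#'   stack + neuromast). With no vesicles the per-vesicle means are `NA`.
#' @export
per_neuromast_stats <- function(records, cells, channel,
                                stack = NULL, neuromast = NULL) {
  n_cells <- length(setdiff(unique(as.vector(cells$labels)), 0L))
  if (n_cells == 0) stop("zero cells: per-cell statistics undefined")
  n_ves <- nrow(records)
  mean_col <- paste0("mean_", channel)
  total <- NA_real_
  if (!is.null(stack) && !is.null(neuromast))
    total <- sum(get_channel(stack, channel)[as_mask(neuromast)])
  data.frame(
    n_cells = n_cells,
    n_vesicles = n_ves,
    vesicles_per_cell_mean = n_ves / n_cells,
    vesicle_volume_mean_um3 = if (n_ves) mean(records$volume_um3) else NA_real_,
    vesicle_fluorescence_mean = if (n_ves) mean(records[[mean_col]])
                                else NA_real_,
    total_fluorescence = total)
}

#' Vesicle-to-cytoplasm accumulation ratio
#'
#' Mean drug-channel intensity over the vesicle compartment divided by the
#' mean over the cytoplasm compartment. Using means (a concentration-style
#' comparison) keeps the ratio free of compartment-volume confounding; set
#' `statistic = "total"` for the total/total variant.
#'
#' @param channel 3-D `(z, y, x)` drug-channel intensities.
#' @param vesicles,cytoplasm masks (`label_volume` or logical arrays);
#'   both must be non-empty.
#' @param statistic `"mean"` (default) or `"total"`.
#' @return The ratio (dimensionless).
#' @export
compartment_ratio <- function(channel, vesicles, cytoplasm,
                              statistic = c("mean", "total")) {
  statistic <- match.arg(statistic)
  vm <- as_mask(vesicles); cm <- as_mask(cytoplasm)
  stopifnot(identical(dim(channel), dim(vm)), identical(dim(channel), dim(cm)))
  if (!any(vm)) stop("empty vesicle compartment")
  if (!any(cm)) stop("empty cytoplasm compartment")
  f <- if (statistic == "mean") mean else sum
  f(channel[vm]) / f(channel[cm])
}

#' Two-group comparison
#'
#' Mann-Whitney (exact null for groups of at most 12 without ties, normal
#' approximation otherwise), Student's t, or paired t test; all two-sided.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param test `"mann_whitney"`, `"t_test"` or `"paired_t"`.
#' @return List with `statistic`, `p_value`, `test`.
#' @export
group_compare <- function(a, b, test = c("mann_whitney", "t_test", "paired_t")) {
  test <- match.arg(test)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (test == "mann_whitney") {
    exact <- length(a) <= 12 && length(b) <= 12 &&
      !anyDuplicated(c(a, b))
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = "mann_whitney")
  } else {
    ht <- t.test(a, b, paired = test == "paired_t", var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value, test = test)
  }
}
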
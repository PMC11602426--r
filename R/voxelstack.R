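#' Multichannel voxel stack
#'
#' `voxel_stack()` wraps an intensity array together with the acquisition
#' metadata the downstream analysis needs: channel names, physical voxel
#' size and (for time lapses) the frame interval. Axes follow the fixed
#' order `(t, c, z, y, x)`; the time axis is present only for time lapses,
#' so the array is 4-D `(c, z, y, x)` for a single-timepoint stack and 5-D
#' for a time lapse.
#'
#' @param data numeric array, `(c, z, y, x)` or `(t, c, z, y, x)`.
#' @param channel_names character vector naming the channel axis.
#' @param voxel_size_um numeric length-3 `(z, y, x)` voxel edge lengths in
#'   micrometres.
#' @param time_interval_s frame interval in seconds; required (non-`NULL`)
#'   when `data` has a time axis.
#' @return A `voxel_stack` object.
#' @examples
#' a <- array(runif(2 * 4 * 8 * 8), c(2, 4, 8, 8))
#' vs <- voxel_stack(a, c("reporter", "ag"), voxel_size_um = c(1, 0.2, 0.2))
#' dim(get_channel(vs, "ag"))
#' @export
voxel_stack <- function(data, channel_names, voxel_size_um,
                        time_interval_s = NULL) {
  nd <- length(dim(data))
  if (!nd %in% c(4L, 5L))
    stop("`data` must be a 4-D (c,z,y,x) or 5-D (t,c,z,y,x) array")
  has_t <- nd == 5L
  c_ax <- if (has_t) 2L else 1L
  if (length(channel_names) != dim(data)[c_ax])
    stop("length(channel_names) must equal the channel-axis extent (",
         dim(data)[c_ax], ")")
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be three positive lengths (z, y, x)")
  if (has_t && is.null(time_interval_s))
    stop("time-lapse stacks need `time_interval_s`")
  structure(
    list(data = data,
         channel_names = as.character(channel_names),
         voxel_size_um = as.numeric(voxel_size_um),
         time_interval_s = if (is.null(time_interval_s)) NULL
                           else as.numeric(time_interval_s)),
    class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$data)
  ax <- if (has_time(x)) "(t,c,z,y,x)" else "(c,z,y,x)"
  cat("<voxel_stack> ", paste(d, collapse = " x "), " ", ax, "\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  cat("  voxel size (z,y,x) um: ",
      paste(signif(x$voxel_size_um, 3), collapse = ", "), "\n", sep = "")
  if (has_time(x))
    cat("  frame interval: ", x$time_interval_s, " s\n", sep = "")
  invisible(x)
}

#' @rdname voxel_stack
#' @param stack a `voxel_stack`.
#' @export
has_time <- function(stack) length(dim(stack$data)) == 5L

#' @rdname voxel_stack
#' @export
n_frames <- function(stack) if (has_time(stack)) dim(stack$data)[1] else 1L

#' Extract one channel as a bare (z, y, x) array
#'
#' @param stack a `voxel_stack`.
#' @param channel channel name or integer index.
#' @param frame time frame (1-based) for time lapses.
#' @return 3-D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel, frame = 1L) {
  ci <- channel_index(stack, channel)
  d <- dim(stack$data)
  if (has_time(stack)) {
    out <- stack$data[frame, ci, , , , drop = FALSE]
    dim(out) <- d[3:5]
  } else {
    out <- stack$data[ci, , , , drop = FALSE]
    dim(out) <- d[2:4]
  }
  out
}

#' Replace one channel of a stack
#'
#' @inheritParams get_channel
#' @param value 3-D `(z, y, x)` array of matching extent.
#' @return The modified `voxel_stack`.
#' @export
set_channel <- function(stack, channel, value, frame = 1L) {
  ci <- channel_index(stack, channel)
  if (has_time(stack)) stack$data[frame, ci, , , ] <- value
  else stack$data[ci, , , ] <- value
  stack
}

channel_index <- function(stack, channel) {
  if (is.character(channel)) {
    ci <- match(channel, stack$channel_names)
    if (is.na(ci)) stop("no channel named '", channel, "'")
    ci
  } else as.integer(channel)
}

#' Read and write voxel stacks
#'
#' Pixel data are stored as a multi-page 32-bit TIFF (pages run fastest
#' over z, then channel, then time), linearly rescaled to the file's
#' `[0, 1]` storage range; the intensity range plus the acquisition
#' metadata — axis sizes, channel names, voxel size and frame interval —
#' travel in a JSON sidecar `<stem>.meta.json` written and read together
#' with the TIFF. Round-trips are exact to the 32-bit quantization step
#' (about 2e-10 of the intensity range). A stack whose sidecar is missing
#' or lacks channel names is refused rather than silently defaulted.
#'
#' @param stack a `voxel_stack`.
#' @param path TIFF file path (the sidecar path is derived from it).
#' @return `read_stack` returns a `voxel_stack`; `write_stack` returns
#'   `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  has_t <- has_time(stack)
  nt <- if (has_t) d[1] else 1L
  nc <- if (has_t) d[2] else d[1]
  nz <- if (has_t) d[3] else d[2]
  lo <- min(stack$data); hi <- max(stack$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", nt * nc * nz)
  k <- 1L
  for (t in seq_len(nt)) for (ci in seq_len(nc)) for (z in seq_len(nz)) {
    pg <- if (has_t) stack$data[t, ci, z, , ] else stack$data[ci, z, , ]
    pages[[k]] <- (pg - lo) / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    axes = if (has_t) "tczyx" else "czyx",
    shape = as.integer(d),
    channel_names = stack$channel_names,
    voxel_size_um = stack$voxel_size_um,
    time_interval_s = stack$time_interval_s,
    intensity_range = c(lo, hi))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  mp <- sidecar_path(path)
  if (!file.exists(mp))
    stop("missing stack metadata sidecar '", mp,
         "': axes and channel names are required")
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (fld in c("axes", "shape", "channel_names", "voxel_size_um"))
    if (is.null(meta[[fld]]) || length(meta[[fld]]) == 0)
      stop("stack metadata lacks required field '", fld, "'")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  d <- as.integer(meta$shape)
  has_t <- identical(meta$axes, "tczyx")
  nt <- if (has_t) d[1] else 1L
  nc <- if (has_t) d[2] else d[1]
  nz <- if (has_t) d[3] else d[2]
  if (length(pages) != nt * nc * nz)
    stop("page count (", length(pages), ") disagrees with metadata shape")
  rng <- meta$intensity_range
  lo <- if (is.null(rng)) 0 else rng[1]
  scale <- if (is.null(rng) || rng[2] <= rng[1]) 1 else rng[2] - rng[1]
  data <- array(0, d)
  k <- 1L
  for (t in seq_len(nt)) for (ci in seq_len(nc)) for (z in seq_len(nz)) {
    pg <- pages[[k]] * scale + lo
    if (has_t) data[t, ci, z, , ] <- pg else data[ci, z, , ] <- pg
    k <- k + 1L
  }
  voxel_stack(data, meta$channel_names, meta$voxel_size_um,
              time_interval_s = meta$time_interval_s)
}

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.json")
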
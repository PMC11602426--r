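#' Maximum-intensity projection over z
#'
#' @param x a 3-D `(z, y, x)` array, or a `voxel_stack` (every channel and
#'   frame is projected).
#' @return For an array, the 2-D `(y, x)` per-pixel maximum over z. For a
#'   `voxel_stack`, an array `(c, y, x)` or `(t, c, y, x)`.
#' @export
max_project <- function(x) {
  if (inherits(x, "voxel_stack")) {
    d <- dim(x$data)
    if (has_time(x)) {
      out <- array(0, c(d[1], d[2], d[4], d[5]))
      for (t in seq_len(d[1])) for (ci in seq_len(d[2]))
        out[t, ci, , ] <- max_project(get_channel(x, ci, frame = t))
    } else {
      out <- array(0, c(d[1], d[3], d[4]))
      for (ci in seq_len(d[1])) out[ci, , ] <- max_project(get_channel(x, ci))
    }
    return(out)
  }
  stopifnot(length(dim(x)) == 3L)
  apply(x, c(2, 3), max)
}

#' Percentile-clipped intensity normalization
#'
#' Rescales a channel to `[0, 1]`: intensities are clipped at the given
#' lower/upper percentiles and mapped linearly so the clip points land on
#' 0 and 1. Both segmentation channels are normalized this way before the
#' threshold and detector stages, whose cutoffs assume a `[0, 1]` scale.
#'
#' @param x numeric array of any dimensionality.
#' @param clip length-2 percentiles in `[0, 100]`, low then high.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(x, clip = c(0, 100)) {
  stopifnot(length(clip) == 2L, clip[1] < clip[2])
  lo <- quantile(x, clip[1] / 100, names = FALSE)
  hi <- quantile(x, clip[2] / 100, names = FALSE)
  if (hi <= lo) stop("constant image: normalization is undefined")
  out <- (x - lo) / (hi - lo)
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grey-scale opening of the image
#' by a disc of the given radius (applied slice-wise for 3-D input) and
#' subtracts it. Features narrower than the ball survive; any structure
#' the ball can roll under — flat offsets, slow gradients — is removed.
#' Negative residuals are clipped to 0, as the downstream segmentation
#' operators assume non-negative input.
#'
#' @param x 2-D `(y, x)` or 3-D `(z, y, x)` numeric array.
#' @param radius_px ball radius in pixels (the classic macro's
#'   "pixel size"); default 10.
#' @return Background-subtracted array of the same shape.
#' @export
rolling_ball_subtract <- function(x, radius_px = 10) {
  stopifnot(radius_px > 0)
  d <- dim(x)
  if (length(d) == 3L) {
    if (2 * radius_px + 1 > min(d[2], d[3]))
      stop("ball diameter exceeds slice extent")
    for (z in seq_len(d[1])) x[z, , ] <- rolling_ball_subtract(x[z, , ], radius_px)
    return(x)
  }
  stopifnot(length(d) == 2L)
  if (2 * radius_px + 1 > min(d)) stop("ball diameter exceeds image extent")
  r <- as.integer(radius_px)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(array(0, d))   # flat image: background is all of it
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  # replicate-pad so the opening sees no artificial zero border, and map
  # to [0, 1] (the grey-morphology working range), undone afterwards
  xi <- c(rep(1L, r), seq_len(d[1]), rep(d[1], r))
  yi <- c(rep(1L, r), seq_len(d[2]), rep(d[2], r))
  sc <- (x[xi, yi] - lo) / (hi - lo)
  bg <- EBImage::opening(sc, brush)[r + seq_len(d[1]), r + seq_len(d[2])] *
    (hi - lo) + lo
  out <- x - bg
  out[out < 0] <- 0
  out
}

# --- rigid 2-D registration ------------------------------------------------

# Forward rigid warp: rotates content by rot_deg about the image centre and
# then shifts it by (dy, dx) pixels. Bilinear sampling; pixels drawn from
# outside the field are 0 and reported in the "valid" attribute.
#' Apply a rigid 2-D transform to an image
#'
#' Moves image content by `rot_deg` about the centre and `(dy, dx)`
#' pixels. Used both by the time-lapse phantom generator (to impose known
#' drift) and by [register_rigid()] (with negated parameters, to undo it).
#'
#' @param img 2-D `(y, x)` numeric matrix.
#' @param rot_deg rotation in degrees (counter-clockwise in (y, x) index
#'   space).
#' @param dy,dx translation in pixels.
#' @return Warped matrix with attribute `"valid"`, a logical matrix marking
#'   pixels sampled from inside the source field.
#' @export
warp_rigid <- function(img, rot_deg, dy, dx) {
  d <- dim(img)
  ny <- d[1]; nx <- d[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  th <- rot_deg * pi / 180
  gy <- matrix(seq_len(ny), ny, nx) - cy - dy
  gx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx - dx
  # inverse rotation of the (content-forward) transform
  sy <- cos(th) * gy + sin(th) * gx + cy
  sx <- -sin(th) * gy + cos(th) * gx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  valid <- y0 >= 1 & y0 <= ny - 1 & x0 >= 1 & x0 <= nx - 1
  out <- matrix(0, ny, nx)
  if (any(valid)) {
    i00 <- cbind(y0[valid], x0[valid])
    v <- (1 - fy[valid]) * (1 - fx[valid]) * img[i00] +
         (1 - fy[valid]) * fx[valid] * img[i00 + rep(c(0, 1), each = sum(valid))] +
         fy[valid] * (1 - fx[valid]) * img[i00 + rep(c(1, 0), each = sum(valid))] +
         fy[valid] * fx[valid] * img[i00 + 1]
    out[valid] <- v
  }
  attr(out, "valid") <- valid
  out
}

# Translation estimate by phase correlation with 3-point parabolic
# sub-pixel refinement. Returns the displacement of `mov` content
# relative to `ref`.
phase_correlate <- function(ref, mov) {
  Fa <- fft(ref); Fb <- fft(mov)
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  mag[mag < 1e-12] <- 1e-12
  r <- Re(fft(R / mag, inverse = TRUE))
  d <- dim(r)
  pk <- which.max(r)
  py <- (pk - 1) %% d[1] + 1
  px <- (pk - 1) %/% d[1] + 1
  sub <- function(m, i, n) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    c(m[im], m[i], m[ip])
  }
  para <- function(v) {
    den <- v[1] - 2 * v[2] + v[3]
    if (abs(den) < 1e-12) 0 else 0.5 * (v[1] - v[3]) / den
  }
  oy <- para(sub(r[, px], py, d[1]))
  ox <- para(sub(r[py, ], px, d[2]))
  dy <- py - 1 + oy; dx <- px - 1 + ox
  if (dy > d[1] / 2) dy <- dy - d[1]
  if (dx > d[2] / 2) dx <- dx - d[2]
  # phase correlation peak at +s when ref(p) = mov(p - s); mov content is
  # displaced by -s relative to ref
  c(dy = -dy, dx = -dx)
}

# Joint (rotation, shift) estimate: coarse rotation grid with
# phase-correlation shifts for initialisation, then Nelder-Mead refinement
# of the mean squared intensity difference over the in-field region.
estimate_rigid <- function(ref, mov, rotation = TRUE, max_rotation_deg = 10) {
  s0 <- phase_correlate(ref, mov)
  obj <- function(p) {
    w <- warp_rigid(mov, -p[1], -p[2], -p[3])
    v <- attr(w, "valid")
    if (!any(v)) return(Inf)
    mean((w[v] - ref[v])^2)
  }
  if (rotation) {
    init <- c(0, s0[1], s0[2]); best <- obj(init)
    for (th in seq(-max_rotation_deg, max_rotation_deg, by = 2)) {
      un <- warp_rigid(mov, -th, 0, 0)
      s <- phase_correlate(ref, un)
      cand <- c(th, s[1], s[2])
      val <- obj(cand)
      if (val < best) { best <- val; init <- cand }
    }
    fit <- optim(init, obj, method = "Nelder-Mead",
                 control = list(maxit = 300, reltol = 1e-10))
    p <- fit$par
  } else {
    fit <- optim(c(s0[1], s0[2]), function(q) obj(c(0, q)),
                 method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10))
    p <- c(0, fit$par)
  }
  list(rotation_deg = unname(p[1]), shift_px = c(dy = unname(p[2]),
                                                 dx = unname(p[3])))
}

#' Rigid alignment of a stack on one channel
#'
#' Estimates one rigid 2-D transform per frame (time lapse) or per z slice
#' (single-timepoint stack, slice-to-slice mode) from the named channel
#' with the previous frame/slice as reference (or the first, composing
#' transforms accordingly), and applies the identical transform to every
#' channel. For a time lapse the transform is estimated on the maximum
#' projection and applied to every z slice of that frame.
#'
#' @param stack a `voxel_stack`.
#' @param channel channel used to estimate the transforms (e.g. the
#'   structural reporter).
#' @param reference `"previous"` (default) or `"first"`.
#' @param rotation estimate rotation as well as translation (default TRUE).
#' @param max_shift_px displacement above which a frame is flagged with a
#'   warning; default half the smaller lateral field extent.
#' @return List with `stack` (aligned `voxel_stack`), `transforms`
#'   (data.frame: frame, rotation_deg, dy, dx — cumulative, relative to the
#'   first frame/slice) and `flagged` (frames whose displacement exceeded
#'   `max_shift_px`).
#' @export
register_rigid <- function(stack, channel, reference = c("previous", "first"),
                           rotation = TRUE, max_shift_px = NULL) {
  reference <- match.arg(reference)
  d <- dim(stack$data)
  timelapse <- has_time(stack)
  n_units <- if (timelapse) d[1] else d[2]
  if (n_units < 2)
    stop("need at least 2 ", if (timelapse) "frames" else "z slices")
  lat <- if (timelapse) d[4:5] else d[3:4]
  if (is.null(max_shift_px)) max_shift_px <- min(lat) / 2

  unit_image <- function(i) {
    if (timelapse) max_project(get_channel(stack, channel, frame = i))
    else get_channel(stack, channel)[i, , ]
  }

  cum <- data.frame(frame = seq_len(n_units), rotation_deg = 0, dy = 0, dx = 0)
  prev_aligned <- unit_image(1)
  first <- prev_aligned
  for (i in 2:n_units) {
    ref_img <- if (reference == "previous") prev_aligned else first
    tr <- estimate_rigid(ref_img, unit_image(i), rotation = rotation)
    # transforms are composed by accumulation; estimating against the
    # already-aligned previous unit makes the estimate directly cumulative
    cum$rotation_deg[i] <- tr$rotation_deg
    cum$dy[i] <- tr$shift_px[1]
    cum$dx[i] <- tr$shift_px[2]
    prev_aligned <- warp_rigid(unit_image(i), -tr$rotation_deg,
                               -tr$shift_px[1], -tr$shift_px[2])
  }

  flagged <- cum$frame[sqrt(cum$dy^2 + cum$dx^2) > max_shift_px]
  if (length(flagged))
    warning("displacement exceeds ", signif(max_shift_px, 3),
            " px for frame(s) ", paste(flagged, collapse = ", "))

  out <- stack
  nc <- if (timelapse) d[2] else d[1]
  for (i in 2:n_units) {
    if (abs(cum$rotation_deg[i]) < 1e-12 && abs(cum$dy[i]) < 1e-12 &&
        abs(cum$dx[i]) < 1e-12) next
    for (ci in seq_len(nc)) {
      if (timelapse) {
        nz <- d[3]
        for (z in seq_len(nz)) {
          w <- warp_rigid(stack$data[i, ci, z, , ], -cum$rotation_deg[i],
                          -cum$dy[i], -cum$dx[i])
          attr(w, "valid") <- NULL
          out$data[i, ci, z, , ] <- w
        }
      } else {
        w <- warp_rigid(stack$data[ci, i, , ], -cum$rotation_deg[i],
                        -cum$dy[i], -cum$dx[i])
        attr(w, "valid") <- NULL
        out$data[ci, i, , ] <- w
      }
    }
  }
  list(stack = out, transforms = cum, flagged = flagged)
}
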
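#' Triangle threshold
#'
#' Histogram-geometry global threshold: a line is drawn from the histogram
#' peak to the far end of its longer tail, and the threshold is placed at
#' the bin whose histogram point lies furthest from that line. Suited to
#' strongly skewed foreground/background histograms such as a blurred
#' reporter channel.
#'
#' @param x numeric array or vector.
#' @param n_bins number of histogram bins (default 256).
#' @return Threshold on the intensity scale of `x`.
#' @export
triangle_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: threshold undefined")
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  pk <- which.max(h)
  nz <- which(h > 0)
  left_tail <- pk - nz[1]
  right_tail <- nz[length(nz)] - pk
  if (right_tail >= left_tail) { a <- pk; b <- nz[length(nz)] }
  else { a <- pk; b <- nz[1] }
  if (a == b) return(centers[pk])
  idx <- if (a < b) a:b else b:a
  # distance from (i, h[i]) to the peak-to-tail line, histogram normalized
  # so bin index and count are commensurate
  hn <- h / max(h) * n_bins
  x1 <- a; y1 <- hn[a]; x2 <- b; y2 <- hn[b]
  dist <- abs((y2 - y1) * idx - (x2 - x1) * hn[idx] + x2 * y1 - y2 * x1)
  best <- idx[which.max(dist)]
  centers[best]
}

#' Multi-level Otsu thresholds
#'
#' Computes `n_classes - 1` thresholds maximizing the between-class
#' variance over a histogram, by dynamic programming (exact over the
#' binned histogram).
#'
#' @param x numeric array or vector.
#' @param n_classes number of intensity classes (default 5).
#' @param n_bins histogram bins (default 128).
#' @return Increasing numeric vector of `n_classes - 1` thresholds.
#' @export
multiotsu_thresholds <- function(x, n_classes = 5L, n_bins = 128L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("constant image: thresholds undefined")
  if (length(unique(v)) < n_classes)
    stop("fewer distinct intensity values (", length(unique(v)),
         ") than classes (", n_classes, ")")
  h <- tabulate(pmin(pmax(floor((v - lo) / (hi - lo) * n_bins) + 1L, 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  cw <- cumsum(p)
  cm <- cumsum(p * centers)
  # class score for bins (i..j]: w * mu^2 with w = weight, mu = class mean;
  # maximizing the sum over classes maximizes between-class variance
  score <- function(i, j) {            # i < j, bins (i+1)..j
    w <- cw[j] - if (i == 0) 0 else cw[i]
    if (w <= 0) return(0)
    m <- cm[j] - if (i == 0) 0 else cm[i]
    m * m / w
  }
  nc <- as.integer(n_classes)
  best <- matrix(-Inf, nc, n_bins)   # best[c, j]: bins 1..j split into c classes
  argt <- matrix(0L, nc, n_bins)
  for (j in 1:n_bins) best[1, j] <- score(0, j)
  for (cl in 2:nc) {
    for (j in cl:n_bins) {
      sc <- -Inf; ab <- 0L
      for (i in (cl - 1):(j - 1)) {
        val <- best[cl - 1, i] + score(i, j)
        if (val > sc) { sc <- val; ab <- i }
      }
      best[cl, j] <- sc
      argt[cl, j] <- ab
    }
  }
  cuts <- integer(nc - 1)
  j <- n_bins
  for (cl in nc:2) {
    cuts[cl - 1] <- argt[cl, j]
    j <- argt[cl, j]
  }
  # threshold = upper edge of the last bin of each class
  lo + cuts * (hi - lo) / n_bins
}

#' Sauvola local threshold
#'
#' Local adaptive threshold `t = m (1 + k (s/R - 1))` with `m`, `s` the
#' mean and standard deviation over a `window_px` square neighbourhood
#' (edge-clamped), `k` the sensitivity and `R` the dynamic range
#' parameter. For 3-D input the threshold is computed slice-wise (each z
#' plane independently), matching the slice-wise detector stages.
#'
#' @param x 2-D `(y, x)` or 3-D `(z, y, x)` numeric array.
#' @param window_px odd window edge length (default 45).
#' @param k sensitivity (default 0.2).
#' @param r dynamic range parameter; default half the data range of `x`.
#' @return Logical array of the same shape: `x > t`.
#' @export
sauvola_mask <- function(x, window_px = 45L, k = 0.2, r = NULL) {
  if (window_px %% 2L != 1L || window_px < 3L)
    stop("`window_px` must be odd and >= 3")
  if (is.null(r)) r <- diff(range(x)) / 2
  if (r <= 0) stop("constant image: Sauvola threshold undefined")
  d <- dim(x)
  if (length(d) == 3L) {
    out <- array(FALSE, d)
    for (z in seq_len(d[1]))
      out[z, , ] <- sauvola_mask(x[z, , ], window_px, k, r)
    return(out)
  }
  stopifnot(length(d) == 2L)
  half <- (window_px - 1L) %/% 2L
  S <- local_window_sums(x, half)
  m <- S$sum / S$n
  vr <- pmax(S$sum2 / S$n - m * m, 0)
  thr <- m * (1 + k * (sqrt(vr) / r - 1))
  x > thr
}

# Clamped-window box sums via integral images; returns sum, sum of squares
# and window pixel count for every pixel.
local_window_sums <- function(x, half) {
  ny <- nrow(x); nx <- ncol(x)
  pad_cum <- function(m) {
    cs <- apply(m, 2, cumsum)
    t(apply(cs, 1, cumsum))
  }
  I1 <- pad_cum(x)
  I2 <- pad_cum(x * x)
  ys <- seq_len(ny); xs <- seq_len(nx)
  y0 <- pmax(ys - half - 1L, 0L); y1 <- pmin(ys + half, ny)
  x0 <- pmax(xs - half - 1L, 0L); x1 <- pmin(xs + half, nx)
  box <- function(I) {
    Iz <- rbind(0, cbind(0, I))   # 1-padded integral image
    Iz[y1 + 1L, x1 + 1L, drop = FALSE] - Iz[y0 + 1L, x1 + 1L, drop = FALSE] -
      Iz[y1 + 1L, x0 + 1L, drop = FALSE] + Iz[y0 + 1L, x0 + 1L, drop = FALSE]
  }
  n <- outer(y1 - y0, x1 - x0)
  list(sum = box(I1), sum2 = box(I2), n = n)
}
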
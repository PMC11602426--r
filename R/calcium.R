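#' A single-cell calcium trace
#'
#' @param intensities per-frame mean ROI intensities (raw scale, > 0).
#' @param cell_id cell identifier.
#' @param condition condition label (e.g. `"neo100_acute"`).
#' @param fate `"dying"` or `"living"`.
#' @param frame_interval_s frame interval in seconds (default 30).
#' @param baseline_frames frames recorded before drug addition
#'   (default 5, i.e. 2.5 min at 30 s).
#' @param frag_frame fragmentation frame index for dying cells (the frame
#'   at which the cell visibly breaks up); `NA` for living cells.
#' @return A `calcium_trace` object.
#' @export
calcium_trace <- function(intensities, cell_id = NA, condition = NA,
                          fate = c("living", "dying"),
                          frame_interval_s = 30, baseline_frames = 5L,
                          frag_frame = NA_integer_) {
  fate <- match.arg(fate)
  n <- length(intensities)
  if (baseline_frames < 2L) stop("need at least 2 baseline frames")
  if (baseline_frames >= n) stop("baseline must be shorter than the trace")
  if (fate == "dying") {
    if (is.na(frag_frame)) stop("dying cells need a fragmentation frame")
    if (frag_frame > n) stop("frag_frame beyond the last frame")
  }
  structure(list(intensities = as.numeric(intensities), cell_id = cell_id,
                 condition = condition, fate = fate,
                 frame_interval_s = frame_interval_s,
                 baseline_frames = as.integer(baseline_frames),
                 frag_frame = as.integer(frag_frame)),
            class = "calcium_trace")
}

#' Baseline-normalized fluorescence (F/F0)
#'
#' Divides the trace by the mean intensity over its baseline window, so
#' the baseline-window mean of the result is exactly 1. Baseline mean and
#' SD are also reported on the F/F0 scale for the responder rule.
#'
#' @param trace a [calcium_trace()].
#' @return List: `ff0` (per-frame F/F0), `baseline_mean` (= 1 by
#'   construction), `baseline_sd`, `baseline_mean_raw`.
#' @export
dff <- function(trace) {
  bl <- trace$intensities[seq_len(trace$baseline_frames)]
  bl <- bl[!is.na(bl)]
  if (length(bl) < 2) stop("fewer than 2 usable baseline frames")
  f0 <- mean(bl)
  if (f0 <= 0) stop("non-positive baseline mean")
  ff0 <- trace$intensities / f0
  list(ff0 = ff0,
       baseline_mean = mean(bl / f0),
       baseline_sd = sd(bl / f0),
       baseline_mean_raw = f0)
}

response_window <- function(trace) {
  n <- length(trace$intensities)
  last <- if (trace$fate == "dying") trace$frag_frame else n
  (trace$baseline_frames + 1L):last
}

#' Two-standard-deviation responder rule
#'
#' A cell responds if its F/F0 exceeds baseline mean + 2 baseline SD at
#' any frame of the response window. For dying cells the window runs from
#' the end of the baseline to the fragmentation frame (signal after
#' fragmentation is meaningless); for living cells to the last frame.
#'
#' @param ff0 per-frame F/F0 values.
#' @param baseline_mean,baseline_sd baseline statistics on the F/F0 scale.
#' @param window integer frame indices of the response window.
#' @param n_sd threshold multiplier (default 2).
#' @return List: `responder` (flag), `max_ff0` (maximum over the window),
#'   `threshold`.
#' @export
classify_responder <- function(ff0, baseline_mean, baseline_sd, window,
                               n_sd = 2) {
  if (length(window) == 0) stop("zero-length response window")
  if (any(window < 1 | window > length(ff0)))
    stop("response window outside the trace")
  mx <- max(ff0[window], na.rm = TRUE)
  thr <- baseline_mean + n_sd * baseline_sd
  list(responder = mx > thr, max_ff0 = mx, threshold = thr)
}

#' Align dying-cell traces to the fragmentation endpoint
#'
#' Re-indexes every trace so its fragmentation frame sits at time index 0;
#' earlier frames get negative indices. Traces with shorter histories are
#' padded with `NA`.
#'
#' @param traces list of dying [calcium_trace()]s (on any common scale,
#'   e.g. F/F0 — supply values via `values`, defaulting to intensities).
#' @param values optional list of per-trace numeric vectors to align
#'   (e.g. the `ff0` component of [dff()]); defaults to raw intensities.
#' @return Matrix with one row per trace, columns named by index relative
#'   to fragmentation (..., -2, -1, 0).
#' @export
align_to_endpoint <- function(traces, values = NULL) {
  if (any(vapply(traces, function(t) t$fate, "") != "dying"))
    stop("endpoint alignment is defined for dying cells only")
  if (is.null(values)) values <- lapply(traces, function(t) t$intensities)
  frag <- vapply(traces, function(t) t$frag_frame, 1L)
  hist_len <- frag   # frames 1..frag map to indices -(frag-1)..0
  width <- max(hist_len)
  out <- matrix(NA_real_, length(traces), width,
                dimnames = list(NULL, as.character(-(width - 1):0)))
  for (i in seq_along(traces)) {
    v <- values[[i]][seq_len(frag[i])]
    out[i, (width - frag[i] + 1):width] <- v
  }
  out
}

#' Condition summary: responder counts and maxima
#'
#' Runs [dff()] and [classify_responder()] on every dying trace of one
#' condition and reports the responder count together with the mean and SD
#' of the per-cell maximum F/F0.
#'
#' @param traces list of [calcium_trace()]s (living cells are ignored).
#' @param n_sd responder threshold multiplier (default 2).
#' @return One-row data.frame: `condition`, `n_dying`, `n_responders`,
#'   `max_ff0_mean`, `max_ff0_sd`.
#' @export
summarize_condition <- function(traces, n_sd = 2) {
  dying <- Filter(function(t) t$fate == "dying", traces)
  if (length(dying) == 0) stop("no dying traces in this condition")
  cond <- dying[[1]]$condition
  res <- lapply(dying, function(t) {
    d <- dff(t)
    classify_responder(d$ff0, d$baseline_mean, d$baseline_sd,
                       response_window(t), n_sd = n_sd)
  })
  mx <- vapply(res, function(r) r$max_ff0, 1)
  data.frame(condition = if (is.null(cond)) NA else cond,
             n_dying = length(dying),
             n_responders = sum(vapply(res, function(r) r$responder, TRUE)),
             max_ff0_mean = mean(mx),
             max_ff0_sd = sd(mx))
}

#' Dunn's post-hoc z tests after Kruskal-Wallis
#'
#' Pairwise rank-based z tests on the pooled ranks with the tie-corrected
#' Kruskal-Wallis variance, multiplicity-adjusted (Holm by default).
#'
#' @param values numeric vector of observations.
#' @param groups factor of group membership.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame: `group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  zs <- ps <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    ia <- groups == combs[1, j]; ib <- groups == combs[2, j]
    na <- sum(ia); nb <- sum(ib)
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / na + 1 / nb))
    zs[j] <- (mean(r[ia]) - mean(r[ib])) / se
    ps[j] <- 2 * pnorm(-abs(zs[j]))
  }
  data.frame(group_a = combs[1, ], group_b = combs[2, ], z = zs,
             p_value = ps, p_adjusted = p.adjust(ps, method = p_adjust))
}

#' Cross-condition statistics on responder proportions and maxima
#'
#' Builds the conditions-by-outcome (responder / non-responder)
#' contingency table and computes Pearson's chi-square without continuity
#' correction; when per-cell maxima are supplied, adds a tie-corrected
#' Kruskal-Wallis test across conditions with Dunn's post-hoc z tests.
#'
#' @param table data.frame with columns `condition`, `n_dying`,
#'   `n_responders` (one row per condition, all `n_dying` > 0), e.g. rows
#'   of [summarize_condition()].
#' @param maxima optional named list of per-condition numeric vectors of
#'   per-cell maximum F/F0.
#' @param p_adjust Dunn adjustment method (default `"holm"`).
#' @return List: `chisq` (`statistic`, `df`, `p_value`), and with maxima
#'   `kruskal` (`statistic`, `df`, `p_value`) and `dunn` (data.frame).
#' @export
condition_stats <- function(table, maxima = NULL, p_adjust = "holm") {
  stopifnot(all(c("condition", "n_dying", "n_responders") %in% names(table)))
  if (nrow(table) < 2) stop("need at least 2 conditions")
  if (any(table$n_dying <= 0)) stop("every condition needs n_dying > 0")
  if (any(table$n_responders < 0 | table$n_responders > table$n_dying))
    stop("responder counts must lie in [0, n_dying]")
  m <- cbind(responder = table$n_responders,
             nonresponder = table$n_dying - table$n_responders)
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  out <- list(chisq = list(statistic = unname(ht$statistic),
                           df = unname(ht$parameter),
                           p_value = ht$p.value))
  if (!is.null(maxima)) {
    v <- unlist(maxima, use.names = FALSE)
    g <- factor(rep(names(maxima), lengths(maxima)))
    kw <- kruskal.test(v, g)
    out$kruskal <- list(statistic = unname(kw$statistic),
                        df = unname(kw$parameter), p_value = kw$p.value)
    out$dunn <- dunn_posthoc(v, g, p_adjust = p_adjust)
  }
  out
}

#' Extract per-cell traces from an aligned time lapse
#'
#' For every frame, the named channel is maximum-projected over z and
#' averaged within each ROI; one trace per ROI label results.
#'
#' @param timelapse a time-lapse `voxel_stack` (already aligned, or pass
#'   through [register_rigid()] first).
#' @param rois integer `(y, x)` matrix of ROI labels (0 = outside), drawn
#'   on the projected field.
#' @param channel channel to measure.
#' @param baseline_frames,frame_interval_s trace metadata (defaults 5
#'   frames, 30 s).
#' @param fates,frag_frames optional per-ROI fate labels and
#'   fragmentation frames (vectors indexed by ROI label).
#' @return List of [calcium_trace()]s. ROIs that average zero pixels are
#'   flagged with a warning and skipped.
#' @export
extract_traces <- function(timelapse, rois, channel,
                           baseline_frames = 5L, frame_interval_s = 30,
                           fates = NULL, frag_frames = NULL) {
  stopifnot(has_time(timelapse))
  nt <- n_frames(timelapse)
  ids <- sort(setdiff(unique(as.vector(rois)), 0L))
  if (length(ids) == 0) stop("no ROI labels")
  mat <- matrix(NA_real_, nt, length(ids))
  for (t in seq_len(nt)) {
    proj <- max_project(get_channel(timelapse, channel, frame = t))
    for (j in seq_along(ids)) {
      px <- proj[rois == ids[j]]
      if (length(px)) mat[t, j] <- mean(px)
    }
  }
  empty <- apply(mat, 2, function(v) all(is.na(v)))
  if (any(empty))
    warning("empty ROI(s) skipped: ", paste(ids[empty], collapse = ", "))
  traces <- list()
  for (j in which(!empty)) {
    id <- ids[j]
    fate <- if (!is.null(fates)) fates[[id]] else "living"
    fr <- if (!is.null(frag_frames)) frag_frames[[id]] else NA_integer_
    traces[[length(traces) + 1]] <- calcium_trace(
      mat[, j], cell_id = id, fate = fate,
      frame_interval_s = frame_interval_s,
      baseline_frames = baseline_frames, frag_frame = fr)
  }
  traces
}

#' Read and write calcium traces as long-format CSV
#'
#' Columns: `cell`, `condition`, `fate`, `frame`, `intensity`,
#' `frag_frame`, `baseline_frames`, `frame_interval_s`.
#'
#' @param traces list of [calcium_trace()]s.
#' @param path CSV path.
#' @return `read_traces` returns a list of `calcium_trace`s.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(t) {
    data.frame(cell = t$cell_id, condition = t$condition, fate = t$fate,
               frame = seq_along(t$intensities), intensity = t$intensities,
               frag_frame = t$frag_frame,
               baseline_frames = t$baseline_frames,
               frame_interval_s = t$frame_interval_s)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  df <- read.csv(path)
  lapply(split(df, df$cell), function(d) {
    d <- d[order(d$frame), ]
    calcium_trace(d$intensity, cell_id = d$cell[1], condition = d$condition[1],
                  fate = d$fate[1], frame_interval_s = d$frame_interval_s[1],
                  baseline_frames = d$baseline_frames[1],
                  frag_frame = d$frag_frame[1])
  })
}
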
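flat_trace <- function(level = 100, n = 30, fate = "living", frag = NA) {
  calcium_trace(rep(level, n), fate = fate, frag_frame = frag)
}

test_that("F/F0 normalizes to the baseline mean exactly", {
  tr <- calcium_trace(c(100, 100, 100, 100, 100, 150, 220),
                      baseline_frames = 5)
  d <- dff(tr)
  expect_equal(d$ff0[7], 2.2)
  expect_equal(d$baseline_mean, 1)
  expect_equal(d$baseline_sd, 0)

  tr2 <- calcium_trace(c(90, 110, 100, 95, 105, 120), baseline_frames = 5)
  d2 <- dff(tr2)
  expect_equal(mean(d2$ff0[1:5]), 1)

  flat <- flat_trace()
  df <- dff(flat)
  expect_true(all(df$ff0 == 1))
  expect_equal(df$baseline_sd, 0)
  bad <- calcium_trace(c(0, 0, 0, 1, 1), baseline_frames = 3)
  expect_error(dff(bad), "baseline")
})

test_that("the 2-SD rule thresholds strictly above mean + 2 SD", {
  ff0 <- c(rep(1, 5), 1.09)
  r1 <- classify_responder(ff0, 1, 0.05, window = 6)
  expect_false(r1$responder)            # 1.09 < 1.10
  ff0[6] <- 1.11
  r2 <- classify_responder(ff0, 1, 0.05, window = 6)
  expect_true(r2$responder)
  expect_equal(r2$threshold, 1.1)
  expect_error(classify_responder(ff0, 1, 0.05, window = integer(0)),
               "zero-length")
  # monotonicity: adding a positive constant never demotes a responder
  up <- ff0 + c(rep(0, 5), 0.5)
  expect_true(classify_responder(up, 1, 0.05, window = 6)$responder)
})

test_that("guaranteed-suprathreshold generators give 16/16 responders", {
  g <- gen_calcium_traces(trace_phantom_params(n_dying = 16, n_living = 0,
                                               responder_fraction = 1,
                                               seed = 42))
  s <- summarize_condition(g$traces)
  expect_equal(s$n_dying, 16)
  expect_equal(s$n_responders, 16)
})

test_that("responder-free generators with small noise give 0 responders", {
  g <- gen_calcium_traces(trace_phantom_params(n_dying = 12, n_living = 0,
                                               responder_fraction = 0,
                                               noise_sd = 0.002, seed = 1))
  s <- summarize_condition(g$traces)
  expect_equal(s$n_responders, 0)
  expect_equal(s$max_ff0_mean, 1, tolerance = 0.02)
})

test_that("generator labels agree with the rule on noiseless traces", {
  # with zero noise the construction is exact: responders exceed the
  # threshold, non-responders never leave baseline
  for (frac in c(0, 0.5, 1)) {
    g <- gen_calcium_traces(trace_phantom_params(n_dying = 10, n_living = 2,
                                                 responder_fraction = frac,
                                                 noise_sd = 0, seed = 3))
    s <- vapply(g$traces, function(t) {
      d <- dff(t)
      classify_responder(d$ff0, d$baseline_mean, max(d$baseline_sd, 1e-9),
                         lateralline:::response_window(t))$responder
    }, TRUE)
    expect_identical(unname(s), g$truth$responder)
  }
})

test_that("endpoint alignment indexes fragmentation at zero", {
  t1 <- calcium_trace(1:10, fate = "dying", frag_frame = 10)
  t2 <- calcium_trace(1:20, fate = "dying", frag_frame = 20)
  m <- align_to_endpoint(list(t1, t2))
  expect_equal(colnames(m)[ncol(m)], "0")
  expect_equal(m[, "0"], c(10, 20))
  expect_equal(m[, "-1"], c(9, 19))
  expect_true(is.na(m[1, 1]))           # shorter history padded
  expect_error(align_to_endpoint(list(flat_trace())), "dying")
  single <- align_to_endpoint(list(t1))
  expect_equal(unname(single[1, ]), 1:10)
})

test_that("the mean aligned responder trace peaks at the generator lag", {
  prm <- trace_phantom_params(n_dying = 50, n_living = 0,
                              responder_fraction = 1, noise_sd = 0.02,
                              seed = 9)
  g <- gen_calcium_traces(prm)
  ff0s <- lapply(g$traces, function(t) dff(t)$ff0)
  m <- align_to_endpoint(g$traces, values = ff0s)
  avg <- colMeans(m, na.rm = TRUE)
  peak_idx <- as.integer(names(which.max(avg)))
  expect_lte(abs(peak_idx + prm$peak_lag_frames), 2)
})

test_that("condition summaries recover the generating peak distribution", {
  means <- vapply(1:60, function(r) {
    g <- gen_calcium_traces(trace_phantom_params(n_dying = 16, n_living = 0,
                                                 seed = 2000 + r))
    summarize_condition(g$traces)$max_ff0_mean
  }, 1)
  se <- 0.46 / sqrt(60 * 16)
  # the realized maximum rides on baseline noise, hence the small
  # allowance beyond 3 SE of the generating mean
  expect_lt(abs(mean(means) - 2.2), 3 * se + 0.05)
})

test_that("the generator's drawn peaks average to the requested mean", {
  peaks <- unlist(lapply(1:200, function(r) {
    g <- gen_calcium_traces(trace_phantom_params(n_dying = 16, n_living = 0,
                                                 seed = 5000 + r))
    g$truth$peak_true
  }))
  se <- 0.46 / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - 2.2), 3 * se + 0.01)  # + truncation at floor
})

test_that("condition statistics reproduce contingency and rank tests", {
  ct <- data.frame(condition = c("neo100_acute", "g418_100_delayed",
                                 "g418_400_acute"),
                   n_dying = c(16, 11, 14), n_responders = c(16, 2, 10))
  cs <- condition_stats(ct)
  expect_equal(cs$chisq$statistic, chisq_oracle(
    cbind(c(16, 2, 10), c(0, 9, 4))))
  expect_equal(cs$chisq$df, 2)
  # permutation invariance
  cs2 <- condition_stats(ct[c(3, 1, 2), ])
  expect_equal(cs2$chisq$statistic, cs$chisq$statistic)
  # proportional rows give zero
  prop <- data.frame(condition = c("a", "b"), n_dying = c(10, 20),
                     n_responders = c(4, 8))
  expect_equal(condition_stats(prop)$chisq$statistic, 0)
  # 2x2 brute-force oracle
  t22 <- data.frame(condition = c("a", "b"), n_dying = c(10, 10),
                    n_responders = c(3, 8))
  expect_equal(condition_stats(t22)$chisq$statistic,
               chisq_oracle(cbind(c(3, 8), c(7, 2))))
  expect_error(condition_stats(ct[1, , drop = FALSE]), "2 conditions")
  bad <- ct; bad$n_dying[1] <- 0
  expect_error(condition_stats(bad), "n_dying")
})

test_that("Kruskal-Wallis + Dunn follow the base test and adjust upward", {
  set.seed(13)
  maxima <- list(neo = rnorm(16, 2.2, 0.46), g418lo = rnorm(11, 1.2, 0.32),
                 g418hi = rnorm(14, 1.7, 0.4))
  ct <- data.frame(condition = names(maxima), n_dying = c(16, 11, 14),
                   n_responders = c(16, 2, 10))
  cs <- condition_stats(ct, maxima = maxima)
  v <- unlist(maxima); g <- factor(rep(names(maxima), lengths(maxima)))
  kw <- kruskal.test(v, g)
  expect_equal(cs$kruskal$statistic, unname(kw$statistic))
  expect_true(all(cs$dunn$p_adjusted >= cs$dunn$p_value - 1e-12))
})

test_that("traces extracted from a time lapse match the projected ROI mean", {
  p <- stack_phantom_params(seed = 14, shape_px = c(14, 110, 110),
                            snr = Inf)
  tl <- gen_timelapse(p, n_frames = 4)
  rois <- matrix(0L, 110, 110)
  rois[40:70, 40:70] <- 1L
  traces <- extract_traces(tl$stack, rois, "reporter", baseline_frames = 2)
  expect_length(traces, 1)
  proj <- max_project(get_channel(tl$stack, "reporter", frame = 1))
  expect_equal(traces[[1]]$intensities[1], mean(proj[rois == 1]))
  # without drift and noise the trace is flat
  expect_lt(diff(range(traces[[1]]$intensities)), 1e-6)
})

test_that("alignment before extraction reduces trace variance under drift", {
  p <- stack_phantom_params(seed = 15, shape_px = c(14, 110, 110),
                            drift_px_per_frame = c(2, 3), snr = 50)
  tl <- gen_timelapse(p, n_frames = 6)
  rois <- matrix(0L, 110, 110)
  rois[30:80, 30:80] <- 1L
  raw <- extract_traces(tl$stack, rois, "reporter", baseline_frames = 2)
  reg <- register_rigid(tl$stack, "reporter")
  fix <- extract_traces(reg$stack, rois, "reporter", baseline_frames = 2)
  expect_lt(var(fix[[1]]$intensities), var(raw[[1]]$intensities))
})

test_that("traces survive a CSV round-trip", {
  g <- gen_calcium_traces(trace_phantom_params(n_dying = 3, n_living = 2,
                                               seed = 8), condition = "neo")
  f <- withr::local_tempfile(fileext = ".csv")
  write_traces(g$traces, f)
  back <- read_traces(f)
  expect_length(back, 5)
  orig <- g$traces[[1]]
  got <- back[[as.character(orig$cell_id)]]
  expect_equal(got$intensities, orig$intensities)
  expect_equal(got$frag_frame, orig$frag_frame)
  expect_equal(got$fate, orig$fate)
})
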
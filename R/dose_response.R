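#' Normalize hair-cell counts to untreated controls
#'
#' Converts per-fish summed hair-cell counts to survival percentages,
#' where 100% is the mean count of the dose-0 control fish of the same
#' batch. Normalization never crosses batches.
#'
#' @param records data.frame with columns `dose_um`, `count`, and
#'   optionally `batch` (a single batch is assumed when absent).
#' @return The records with a `survival_pct` column appended.
#' @export
normalize_survival <- function(records) {
  stopifnot(all(c("dose_um", "count") %in% names(records)))
  if (is.null(records$batch)) records$batch <- 1L
  records$survival_pct <- NA_real_
  for (b in unique(records$batch)) {
    sel <- records$batch == b
    ctrl <- records$count[sel & records$dose_um == 0]
    if (length(ctrl) == 0) stop("no dose-0 control fish in batch '", b, "'")
    records$survival_pct[sel] <- 100 * records$count[sel] / mean(ctrl)
  }
  records
}

#' Hill dose-response fit and HC50
#'
#' Least-squares fit of the survival Hill curve
#' `S(d) = bottom + (top - bottom) / (1 + (d / HC50)^h)` to per-fish
#' survival percentages, with the asymptotes fixed at 100 and 0 by
#' default. HC50 is fitted on the log10 scale (doses must span it);
#' dose-0 controls define the normalization and are excluded from the
#' curve fit. When no dose brings mean survival below 60% the data do not
#' determine an HC50 and the fit reports exactly that instead of
#' extrapolating.
#'
#' @param records data.frame with `dose_um` and `survival_pct` (see
#'   [normalize_survival()]), one row per fish.
#' @param free_asymptotes fit `top` and `bottom` as free parameters
#'   (default FALSE).
#' @param max_survival_for_fit mean-survival ceiling above which the HC50
#'   is declared not determined (default 60).
#' @param n_boot fish-level bootstrap replicates for the HC50 standard
#'   error (default 0 = skip).
#' @param seed seed for the bootstrap resampling.
#' @return A `hill_fit`: `hc50_um`, `hill_slope`, `top_pct`, `bottom_pct`,
#'   `se_hc50`, `converged`, `determined`.
#' @export
fit_hill <- function(records, free_asymptotes = FALSE,
                     max_survival_for_fit = 60, n_boot = 0, seed = 1L) {
  stopifnot(all(c("dose_um", "survival_pct") %in% names(records)))
  tr <- records[records$dose_um > 0, ]
  doses <- sort(unique(tr$dose_um))
  if (length(doses) < 4) stop("need >= 4 distinct non-zero doses")
  mean_by_dose <- tapply(tr$survival_pct, tr$dose_um, mean)
  if (min(mean_by_dose) > max_survival_for_fit) {
    return(structure(list(hc50_um = NA_real_, hill_slope = NA_real_,
                          top_pct = NA_real_, bottom_pct = NA_real_,
                          se_hc50 = NA_real_, converged = FALSE,
                          determined = FALSE),
                     class = "hill_fit"))
  }
  fit1 <- function(d) {
    # start near the dose whose mean survival is closest to halfway
    mb <- tapply(d$survival_pct, d$dose_um, mean)
    start_hc50 <- as.numeric(names(mb))[which.min(abs(mb - 50))]
    st <- list(lh = log10(start_hc50), h = 1.5)
    fo <- survival_pct ~ 100 / (1 + (dose_um / 10^lh)^h)
    if (free_asymptotes) {
      st <- c(st, list(top = 100, bottom = 0))
      fo <- survival_pct ~ bottom + (top - bottom) / (1 + (dose_um / 10^lh)^h)
    }
    minpack.lm::nlsLM(fo, data = d, start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(fit1(tr), error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(hc50_um = NA_real_, hill_slope = NA_real_,
                          top_pct = NA_real_, bottom_pct = NA_real_,
                          se_hc50 = NA_real_, converged = FALSE,
                          determined = TRUE),
                     class = "hill_fit"))
  }
  cf <- coef(fit)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    bs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample(nrow(tr), replace = TRUE)
      f <- tryCatch(fit1(tr[idx, ]), error = function(e) NULL)
      bs[b] <- if (is.null(f)) NA else 10^coef(f)[["lh"]]
    }
    se <- sd(bs, na.rm = TRUE)
  }
  structure(list(hc50_um = 10^cf[["lh"]], hill_slope = cf[["h"]],
                 top_pct = if (free_asymptotes) cf[["top"]] else 100,
                 bottom_pct = if (free_asymptotes) cf[["bottom"]] else 0,
                 se_hc50 = se, converged = TRUE, determined = TRUE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$determined) {
    cat("<hill_fit> HC50 not determined (maximal kill too small)\n")
  } else if (!x$converged) {
    cat("<hill_fit> fit failed to converge\n")
  } else {
    cat("<hill_fit> HC50 = ", signif(x$hc50_um, 4), " uM, slope = ",
        signif(x$hill_slope, 3), sep = "")
    if (!is.na(x$se_hc50)) cat(" (bootstrap SE ", signif(x$se_hc50, 3), ")",
                               sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Delayed-loss time-course summary
#'
#' Summarizes survival by (dose, post-wash time): per-cell means and SDs,
#' a monotone-loss check along time within each dose, and a two-way ANOVA
#' (dose x time, type-II sums of squares). Counts are normalized within
#' each time point (its own controls); time points lacking controls are
#' flagged and dropped.
#'
#' @param records data.frame with `dose_um`, `post_wash_h`, `count` (one
#'   row per fish), controls as dose 0 at every time.
#' @return List: `summary` (dose, post_wash_h, n, mean_survival,
#'   sd_survival), `anova` (data.frame of F tests), `flagged_times`,
#'   `monotone_loss` (per-dose flag: mean survival non-increasing in
#'   time).
#' @export
timecourse_summary <- function(records) {
  stopifnot(all(c("dose_um", "post_wash_h", "count") %in% names(records)))
  flagged <- c()
  parts <- list()
  for (tp in sort(unique(records$post_wash_h))) {
    sub <- records[records$post_wash_h == tp, ]
    if (!any(sub$dose_um == 0)) { flagged <- c(flagged, tp); next }
    sub$batch <- tp
    parts[[as.character(tp)]] <- normalize_survival(sub)
  }
  if (length(flagged))
    warning("no controls at post-wash time(s) ",
            paste(flagged, collapse = ", "), " h; dropped")
  df <- do.call(rbind, parts)
  tr <- df[df$dose_um > 0, ]
  if (length(unique(tr$post_wash_h)) < 2)
    stop("need >= 2 post-wash time points")
  agg <- aggregate(survival_pct ~ dose_um + post_wash_h, tr,
                   function(v) c(n = length(v), mean = mean(v), sd = sd(v)))
  summ <- data.frame(dose_um = agg$dose_um, post_wash_h = agg$post_wash_h,
                     n = agg$survival_pct[, "n"],
                     mean_survival = agg$survival_pct[, "mean"],
                     sd_survival = agg$survival_pct[, "sd"])
  if (all(summ$sd_survival == 0))
    warning("degenerate variance: survival identical within every cell")
  mono <- vapply(split(summ, summ$dose_um), function(s) {
    s <- s[order(s$post_wash_h), ]
    all(diff(s$mean_survival) <= 1e-9)
  }, TRUE)
  # the ANOVA runs on raw counts: normalizing by the (noisy) control mean
  # would leak control sampling error into the between-group variance
  fo <- if (length(unique(tr$dose_um)) > 1)
    count ~ factor(dose_um) * factor(post_wash_h)
  else count ~ factor(post_wash_h)
  fit <- stats::lm(fo, data = tr)
  an <- car::Anova(fit, type = 2)
  anova_df <- data.frame(term = rownames(an), sum_sq = an[["Sum Sq"]],
                         df = an$Df, F = an[["F value"]],
                         p_value = an[["Pr(>F)"]])
  list(summary = summ, anova = anova_df, flagged_times = flagged,
       monotone_loss = mono)
}

#' Protection-experiment statistics
#'
#' Two-way ANOVA (dose x protectant arm, type-II) on per-fish survival,
#' with per-dose pairwise comparisons between arms, Sidak-adjusted across
#' doses. Reports whether, and at which doses, the protectant arm retains
#' significantly more hair cells.
#'
#' @param records data.frame with `dose_um`, `protectant` (two levels,
#'   e.g. `"none"` and `"GPN"`), `count`, and optionally `survival_pct`
#'   (computed via [normalize_survival()] from dose-0 controls per arm
#'   when absent).
#' @param control_level level of `protectant` regarded as the untreated
#'   arm (default `"none"`).
#' @param alpha per-family significance level (default 0.05).
#' @return List: `anova` (data.frame), `per_dose` (dose, diff =
#'   protectant - control mean survival, t, p, p_sidak, protected),
#'   `protected_any`.
#' @export
protection_stats <- function(records, control_level = "none", alpha = 0.05) {
  stopifnot(all(c("dose_um", "protectant", "count") %in% names(records)))
  arms <- unique(records$protectant)
  if (length(arms) < 2)
    stop("need both a protectant and a control arm")
  if (!control_level %in% arms)
    stop("no arm named '", control_level, "'")
  if (is.null(records$survival_pct)) {
    records$batch <- records$protectant
    records <- normalize_survival(records)
  }
  tr <- records[records$dose_um > 0, ]
  if (length(unique(tr$dose_um)) < 2) stop("need >= 2 non-zero doses")
  tr$arm <- factor(ifelse(tr$protectant == control_level, "control",
                          "protectant"), levels = c("control", "protectant"))
  # statistics on raw counts; survival percentages are the presentation
  # scale (see timecourse_summary for the rationale)
  fit <- stats::lm(count ~ factor(dose_um) * arm, data = tr)
  an <- car::Anova(fit, type = 2)
  anova_df <- data.frame(term = rownames(an), sum_sq = an[["Sum Sq"]],
                         df = an$Df, F = an[["F value"]],
                         p_value = an[["Pr(>F)"]])
  doses <- sort(unique(tr$dose_um))
  m <- length(doses)
  per <- lapply(doses, function(d) {
    a <- tr$count[tr$dose_um == d & tr$arm == "protectant"]
    b <- tr$count[tr$dose_um == d & tr$arm == "control"]
    sa <- tr$survival_pct[tr$dose_um == d & tr$arm == "protectant"]
    sb <- tr$survival_pct[tr$dose_um == d & tr$arm == "control"]
    ht <- t.test(a, b, var.equal = FALSE)
    data.frame(dose_um = d, diff = mean(sa) - mean(sb),
               t = unname(ht$statistic), p_value = ht$p.value)
  })
  per <- do.call(rbind, per)
  per$p_sidak <- pmin(1, 1 - (1 - per$p_value)^m)
  per$protected <- per$p_sidak < alpha & per$diff > 0
  list(anova = anova_df, per_dose = per,
       protected_any = any(per$protected))
}
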
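test_that("survival normalization anchors controls at 100%", {
  recs <- data.frame(dose_um = c(0, 0, 50), count = c(70, 50, 30))
  out <- normalize_survival(recs)
  expect_equal(out$survival_pct[3], 50)
  expect_equal(mean(out$survival_pct[1:2]), 100)
  expect_error(normalize_survival(data.frame(dose_um = 50, count = 10)),
               "control")
})

test_that("normalization stays within batches and ignores count scaling", {
  recs <- data.frame(dose_um = c(0, 100, 0, 100),
                     count = c(60, 30, 30, 15),
                     batch = c("a", "a", "b", "b"))
  out <- normalize_survival(recs)
  expect_equal(out$survival_pct, c(100, 50, 100, 50))
  doubled <- recs; doubled$count <- doubled$count * 3
  expect_equal(normalize_survival(doubled)$survival_pct, out$survival_pct)
})

test_that("a noise-free Hill curve is recovered essentially exactly", {
  doses <- c(0, 5, 10, 25, 50, 100, 200, 400)
  surv <- 100 / (1 + (doses / 50)^2)
  recs <- data.frame(dose_um = doses, survival_pct = surv)
  fit <- fit_hill(recs)
  expect_true(fit$determined && fit$converged)
  expect_lt(abs(fit$hc50_um - 50) / 50, 1e-6)
  expect_lt(abs(fit$hill_slope - 2) / 2, 1e-6)
})

test_that("flat survival yields 'not determined', never a number", {
  recs <- data.frame(dose_um = rep(c(0, 25, 50, 100, 200, 400), each = 5),
                     survival_pct = 100 + rnorm(30, 0, 3))
  fit <- fit_hill(recs)
  expect_false(fit$determined)
  expect_true(is.na(fit$hc50_um))
  expect_output(print(fit), "not determined")
  # a 20%-maximal-kill regime (shallow gentamicin-1h-like) is also refused
  surv20 <- 100 - 20 * (recs$dose_um / 400)
  fit2 <- fit_hill(data.frame(dose_um = recs$dose_um, survival_pct = surv20))
  expect_false(fit2$determined)
})

test_that("HC50 estimates scale with dose units and recover the truth", {
  cp <- count_phantom_params(true_hc50_um = 44, seed = 2)
  df <- normalize_survival(gen_doseresponse_counts(cp))
  f1 <- fit_hill(df)
  df10 <- df; df10$dose_um <- df10$dose_um * 10
  f10 <- fit_hill(df10)
  expect_equal(f10$hc50_um / f1$hc50_um, 10, tolerance = 1e-6)
  expect_equal(f10$hill_slope, f1$hill_slope, tolerance = 1e-6)

  meds <- vapply(1:15, function(r) {
    cpr <- count_phantom_params(true_hc50_um = 44, seed = 100 + r)
    fit_hill(normalize_survival(gen_doseresponse_counts(cpr)))$hc50_um
  }, 1)
  expect_lt(abs(median(meds) - 44) / 44, 0.15)
})

test_that("the bootstrap SE is reproducible and positive", {
  cp <- count_phantom_params(true_hc50_um = 44, seed = 3)
  df <- normalize_survival(gen_doseresponse_counts(cp))
  f1 <- fit_hill(df, n_boot = 30, seed = 7)
  f2 <- fit_hill(df, n_boot = 30, seed = 7)
  expect_equal(f1$se_hc50, f2$se_hc50)
  expect_gt(f1$se_hc50, 0)
})

test_that("time-course summaries expose dose-dependent loss rates", {
  set.seed(21)
  mk <- function(dose, tp) {
    surv <- if (dose == 0) 1
            else max(0.03, 1 - (tp / 23) * (dose / (dose + 30)) * 1.8)
    data.frame(dose_um = dose, post_wash_h = tp,
               count = rpois(10, 60 * min(surv, 1)))
  }
  recs <- do.call(rbind, lapply(c(5, 11, 17, 23), function(tp)
    do.call(rbind, lapply(c(0, 25, 50, 100, 200), mk, tp = tp))))
  tc <- timecourse_summary(recs)
  s <- tc$summary
  # higher dose reaches half-survival earlier
  t50 <- vapply(unique(s$dose_um), function(d) {
    sd <- s[s$dose_um == d, ]
    sd <- sd[order(sd$post_wash_h), ]
    idx <- which(sd$mean_survival < 50)[1]
    if (is.na(idx)) Inf else sd$post_wash_h[idx]
  }, 1)
  expect_true(t50[4] <= t50[1])
  an <- tc$anova
  expect_lt(an$p_value[an$term == "factor(dose_um)"], 0.001)
  expect_lt(an$p_value[an$term == "factor(post_wash_h)"], 0.001)
})

test_that("time points without controls are flagged and dropped", {
  recs <- data.frame(dose_um = rep(c(0, 50), 20),
                     post_wash_h = rep(c(5, 11), each = 20),
                     count = rpois(40, 40))
  recs <- recs[!(recs$post_wash_h == 11 & recs$dose_um == 0), ]
  expect_warning(expect_error(timecourse_summary(recs), "time points"),
                 "no controls")
})

test_that("a flat single-dose time course shows no time effect", {
  set.seed(22)
  rej <- vapply(1:60, function(i) {
    recs <- do.call(rbind, lapply(c(5, 11, 17, 23), function(tp)
      data.frame(dose_um = rep(c(0, 50), each = 10), post_wash_h = tp,
                 count = rpois(20, 55))))
    tc <- suppressWarnings(timecourse_summary(recs))
    an <- tc$anova
    an$p_value[an$term == "factor(post_wash_h)"] < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.15)   # near the nominal 5% false-positive rate
})

test_that("identical arms show no protection", {
  set.seed(23)
  recs <- do.call(rbind, lapply(c("none", "GPN"), function(a)
    do.call(rbind, lapply(c(0, 50, 100, 200), function(d)
      data.frame(dose_um = d, protectant = a,
                 count = rpois(10, 60 * if (d == 0) 1 else 0.5))))))
  ps <- protection_stats(recs)
  expect_false(ps$protected_any)
  expect_true(all(ps$per_dose$p_sidak > 0.2))
  expect_error(protection_stats(recs[recs$protectant == "none", ]), "arm")
})

test_that("a 30-point survival offset is detected as protection", {
  hits <- vapply(1:40, function(i) {
    set.seed(400 + i)
    recs <- do.call(rbind, lapply(c("none", "GPN"), function(a)
      do.call(rbind, lapply(c(0, 50, 100, 200), function(d) {
        surv <- if (d == 0) 1 else if (a == "GPN") 0.75 else 0.45
        data.frame(dose_um = d, protectant = a, count = rpois(10, 60 * surv))
      }))))
    protection_stats(recs)$protected_any
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("dose-restricted protection flags only the protected doses", {
  set.seed(24)
  recs <- do.call(rbind, lapply(c("none", "GPN"), function(a)
    do.call(rbind, lapply(c(0, 25, 50, 100, 200), function(d) {
      base <- if (d == 0) 1 else 1 - d / 250
      surv <- if (a == "GPN" && d > 0 && d <= 50) base + 0.35 else base
      data.frame(dose_um = d, protectant = a,
                 count = rpois(12, 60 * max(surv, 0.05)))
    }))))
  ps <- protection_stats(recs)
  pd <- ps$per_dose
  expect_true(all(pd$protected[pd$dose_um <= 50]))
  expect_false(any(pd$protected[pd$dose_um > 50]))
})
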
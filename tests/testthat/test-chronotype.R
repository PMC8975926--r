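fast_sres <- function(seed = 1) sres_config(lambda = 80, mu = 12,
                                            generations = 120, seed = seed)

test_that("phase wrapping is 24h-periodic and lands in (-12, 12]", {
  expect_equal(wrap_phase(26 - 0), 2)
  expect_equal(wrap_phase(0 - 26), -2)
  expect_equal(wrap_phase(12), 12)
  expect_equal(wrap_phase(12.5), -11.5)
  for (k in -3:3) {
    x <- c(-11, 0, 5.5, 12)
    expect_equal(wrap_phase(x + 24 * k), wrap_phase(x))
  }
})

test_that("SRES solves canonical objectives to tolerance", {
  sphere <- sres_minimize(function(m) rowSums(m^2), rep(-5, 3), rep(5, 3),
                          sres_config(lambda = 100, mu = 15,
                                      generations = 200, seed = 2))
  expect_lte(sphere$value, 1e-4)
  # best-so-far trace never increases
  expect_true(all(diff(sphere$trace) <= 0))
  # 1-D quadratic against a dense grid oracle
  quad <- function(m) (m[, 1] - 2)^2
  fit <- sres_minimize(quad, 0, 5, sres_config(lambda = 60, mu = 10,
                                               generations = 150, seed = 3))
  grid <- seq(0, 5, by = 1e-4)
  oracle <- grid[which.min((grid - 2)^2)]
  expect_lt(abs(fit$par - oracle), 1e-3)
  expect_error(
    sres_minimize(function(m) rep(NaN, nrow(m)), -1, 1,
                  sres_config(lambda = 10, mu = 2, generations = 2)),
    "non-finite")
})

test_that("stochastic ranking reduces to objective sort when feasible", {
  withr::local_seed(4)
  obj <- stats::runif(20)
  idx <- chronoanx:::stochastic_rank(obj, rep(0, 20), pf = 0.45)
  expect_equal(obj[idx], sort(obj))
})

test_that("training curve recovery from noiseless references is near exact", {
  truth <- oscillation_model(1.2, 7, 0.3)
  times <- c(2, 8, 14, 20)
  ref <- purrr::map_dfr(1:5, function(s) {
    tibble::tibble(subject_id = paste0("r", s), time_h = times,
                   rel_expr = oscillation_value(truth, times))
  })
  model <- build_training_curve(ref, fast_sres(7))
  # z-scoring rescales amplitude/mesor but the acrophase is preserved
  expect_lt(abs(wrap_phase(model$acrophase - truth$acrophase)), 1e-2)
  expect_false(attr(model, "degenerate"))
})

test_that("antiphase references cancel to a degenerate flat curve", {
  times <- c(0, 6, 12, 18)
  m1 <- oscillation_model(1, 0, 0); m2 <- oscillation_model(1, 12, 0)
  ref <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", time_h = times,
                   rel_expr = oscillation_value(m1, times)),
    tibble::tibble(subject_id = "b", time_h = times,
                   rel_expr = oscillation_value(m2, times))
  )
  model <- build_training_curve(ref, fast_sres(8))
  expect_true(attr(model, "degenerate"))
  expect_error(build_training_curve(
    dplyr::mutate(ref, time_h = ifelse(subject_id == "b", time_h + 1,
                                       time_h))), "mismatched")
})

test_that("subject fits recover noiseless parameters and the identity case", {
  training <- oscillation_model(1.5, 8, 0)
  times <- c(8, 16, 17, 20)
  # identical to training -> zero shift and zero error
  s0 <- tibble::tibble(time_h = times,
                       rel_expr = oscillation_value(training, times))
  f0 <- fit_subject(s0, training, fast_sres(9))
  expect_lt(abs(f0$phase_shift), 0.02)
  expect_lt(f0$sse, 1e-6)
  # planted A=1.5, acrophase 5 h
  truth <- oscillation_model(1.5, 5, 0)
  s1 <- tibble::tibble(time_h = times,
                       rel_expr = oscillation_value(truth, times))
  f1 <- fit_subject(s1, training, sres_config(seed = 10))
  expect_lt(abs(f1$model$amplitude - 1.5), 0.02)
  expect_lt(abs(wrap_phase(f1$model$acrophase - 5)), 0.02)
  expect_equal(f1$phase_shift, 3, tolerance = 0.02)
  # phase 26 h against training at 0 wraps to -2 h
  tr0 <- oscillation_model(1, 0, 0)
  s2 <- tibble::tibble(time_h = times,
                       rel_expr = oscillation_value(
                         oscillation_model(1, 26, 0), times))
  f2 <- fit_subject(s2, tr0, fast_sres(11))
  expect_equal(f2$phase_shift, -2, tolerance = 0.05)
  expect_error(fit_subject(s0[1:2, ], training), ">= 3 distinct")
})

test_that("fit error never exceeds the training curve's own error", {
  withr::local_seed(12)
  training <- oscillation_model(1, 8, 0)
  times <- c(8, 16, 17, 20)
  for (i in 1:10) {
    vals <- stats::rnorm(4)
    s <- tibble::tibble(time_h = times, rel_expr = vals)
    f <- fit_subject(s, training, fast_sres(100 + i))
    sse_train <- sum((oscillation_value(training, times) - vals)^2)
    expect_lte(f$sse, sse_train + 1e-9)
  }
})

test_that("a planted +2 h advance is recovered from noiseless sampling", {
  co <- simulate_cohort(two_loci(), effect_plan(phase_sd = 0,
                                                meq_phase_slope = 0),
                        4, c(2, 2), seed = 13)
  co$.phase_h <- rep(2, 4) # advance everyone by exactly 2 h
  ex <- simulate_expression(co, genes = "PER3", times = c(8, 16, 17, 20),
                            phase_jitter_sd = 0, noise_sd = 0, seed = 14,
                            acrophase = c(PER3 = 8))
  training <- oscillation_model(1, 8, 0)
  z <- zscore_expression(ex)
  s <- dplyr::filter(z, subject_id == co$subject_id[1])
  f <- fit_subject(s, training, sres_config(seed = 15))
  expect_equal(f$phase_shift, 2, tolerance = 0.05)
})

test_that("cohort z-scores standardize per gene and shift-invariantly", {
  fits <- tibble::tibble(
    gene = rep("PER3", 2), phase_shift_h = c(-1, 1), amplitude = c(1, 2)
  )
  z <- cohort_zscores(fits)
  expect_equal(z$phase_z, c(-1, 1) / stats::sd(c(-1, 1)))
  expect_equal(mean(z$phase_z), 0)
  shifted <- dplyr::mutate(fits, phase_shift_h = phase_shift_h + 5)
  expect_equal(cohort_zscores(shifted)$phase_z, z$phase_z)
  withr::local_seed(16)
  many <- tibble::tibble(gene = "g", phase_shift_h = stats::rnorm(100),
                         amplitude = stats::runif(100, .5, 2))
  zm <- cohort_zscores(many)
  expect_lt(abs(mean(zm$phase_z)), 1e-12)
  expect_equal(stats::sd(zm$phase_z), 1, tolerance = 1e-12)
  expect_error(cohort_zscores(many[1, ]), ">= 2")
  expect_error(cohort_zscores(dplyr::mutate(many, amplitude = 1)),
               "zero variance")
})

test_that("misalignment requires advanced phase AND evening preference", {
  d <- tibble::tibble(
    phase_z = c(2, 2, -2, 2), meq = c(30, 70, 30, 30),
    anxiety = c(1, 0, 0, 1)
  )
  # morning type (meq 70) never flagged despite advanced phase
  mis <- d$phase_z > 1 & d$meq < 41
  expect_equal(mis, c(TRUE, FALSE, FALSE, TRUE))
  expect_warning(
    r <- misalignment_risk(dplyr::mutate(d, phase_z = -5)),
    "no misaligned")
  expect_true(r$masked)
})

test_that("a planted misalignment odds ratio is recovered", {
  plan <- effect_plan(intercept = -1, misalignment_logOR = log(6))
  co <- simulate_cohort(default_loci(), plan, 20000, c(7000, 13000),
                        seed = 17)
  r <- misalignment_risk(
    tibble::tibble(phase_z = co$.phase_z, meq = co$meq,
                   anxiety = co$anxiety))
  expect_gte(r$odds_ratio, 4.5)
  expect_lte(r$odds_ratio, 8.0)
  # null effect: CI covers 1 in most seeds
  cover <- vapply(1:15, function(s) {
    con <- simulate_cohort(two_loci(), effect_plan(intercept = -1), 1500,
                           c(750, 750), seed = 800 + s)
    rr <- misalignment_risk(tibble::tibble(phase_z = con$.phase_z,
                                           meq = con$meq,
                                           anxiety = con$anxiety))
    rr$ci_low <= 1 && rr$ci_high >= 1
  }, logical(1))
  expect_gte(sum(cover), 13)
})

test_that("cohort chronotyping pipeline recovers planted phases", {
  co <- simulate_cohort(two_loci(), effect_plan(phase_sd = 2), 24, c(12, 12),
                        seed = 18)
  ex <- simulate_expression(co, genes = "PER3", phase_jitter_sd = 0,
                            noise_sd = 0.1, seed = 19,
                            acrophase = c(PER3 = 8))
  fits <- chronotype_cohort(ex, training = list(PER3 = oscillation_model(1, 8, 0)),
                            config = fast_sres(20))
  expect_equal(nrow(fits), 24)
  merged <- dplyr::left_join(fits, co[c("subject_id", ".phase_h")],
                             by = "subject_id")
  err <- abs(wrap_phase(merged$phase_shift_h - merged$.phase_h))
  expect_lt(stats::median(err), 0.5)
  expect_true(all(c("phase_z", "amplitude_z") %in% names(fits)))
})
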
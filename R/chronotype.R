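#' Wrap a phase difference into (-12, 12] hours
#'
#' @param x hours (any real).
#' @return wrapped hours; `wrap_phase(x + 24k) == wrap_phase(x)`.
#' @export
wrap_phase <- function(x) {
  w <- x %% 24
  ifelse(w > 12, w - 24, w)
}

#' A 24-h cosinor oscillation model
#'
#' `value(t) = mesor + amplitude * cos(2*pi*(t - acrophase)/24)` with a fixed
#' 24-h period. The single-harmonic cosinor is the minimal oscillation model
#' with the phase and amplitude outputs molecular chronotyping needs; the
#' fitting interface (`fit_subject()`) only touches it through
#' `oscillation_value()`, so richer curve models can be slotted in.
#'
#' @param amplitude non-negative amplitude (z-units).
#' @param acrophase peak time in hours, wrapped into \[0, 24).
#' @param mesor rhythm-adjusted mean.
#' @return an `oscillation_model` list.
#' @export
oscillation_model <- function(amplitude, acrophase, mesor = 0) {
  stopifnot(amplitude >= 0)
  structure(list(amplitude = amplitude, acrophase = acrophase %% 24,
                 mesor = mesor),
            class = "oscillation_model")
}

#' @rdname oscillation_model
#' @param model an `oscillation_model`.
#' @param t clock times in hours.
#' @export
oscillation_value <- function(model, t) {
  model$mesor + model$amplitude * cos(2 * pi * (t - model$acrophase) / 24)
}

# (a, b, c) <-> (amplitude, acrophase, mesor): the fit works on the linear
# sin/cos parameterization so the phase has no 0/24 boundary.
ab_to_model <- function(par) {
  a <- par[1]; b <- par[2]
  amp <- sqrt(a^2 + b^2)
  acro <- (atan2(b, a) * 24 / (2 * pi)) %% 24
  oscillation_model(amp, acro, par[3])
}
model_to_ab <- function(model) {
  w <- 2 * pi * model$acrophase / 24
  c(model$amplitude * cos(w), model$amplitude * sin(w), model$mesor)
}

#' Z-score an expression series per subject and gene
#'
#' @param expression long tibble: `subject_id`, `gene`, `time_h`, `rel_expr`.
#' @return same tibble with `rel_expr` replaced by its within-subject,
#'   within-gene z-score (mean 0, sample SD 1).
#' @export
zscore_expression <- function(expression) {
  expression |>
    dplyr::group_by(.data$subject_id, .data$gene) |>
    dplyr::mutate(rel_expr = as.numeric(scale(.data$rel_expr))) |>
    dplyr::ungroup()
}

#' SRES configuration
#'
#' @param lambda offspring population size.
#' @param mu parent count (`mu < lambda`).
#' @param generations generation count.
#' @param pf stochastic-ranking probability of comparing by objective when
#'   constraint violations are involved; in (0, 0.5).
#' @param seed integer seed.
#' @return an `sres_config` list.
#' @export
sres_config <- function(lambda = 200, mu = 30, generations = 300,
                        pf = 0.45, seed = 1) {
  stopifnot(mu < lambda, pf > 0, pf < 0.5)
  structure(list(lambda = lambda, mu = mu, generations = generations,
                 pf = pf, seed = seed),
            class = "sres_config")
}

# Stochastic-ranking bubble sort (Runarsson & Yao). With all-feasible
# populations it reduces to an objective sort.
stochastic_rank <- function(obj, viol, pf) {
  n <- length(obj)
  idx <- seq_len(n)
  for (sweep in seq_len(n)) {
    swapped <- FALSE
    for (i in seq_len(n - 1L)) {
      a <- idx[i]; b <- idx[i + 1L]
      by_obj <- (viol[a] == 0 && viol[b] == 0) || stats::runif(1) < pf
      out_of_order <- if (by_obj) obj[a] > obj[b] else viol[a] > viol[b]
      if (out_of_order) {
        idx[i] <- b; idx[i + 1L] <- a
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  idx
}

#' Stochastic-ranking evolution strategy over a box
#'
#' A (mu, lambda) evolution strategy with log-normal step-size
#' self-adaptation. Candidates are ranked by stochastic-ranking bubble sort:
#' when constraint violations are involved, adjacent candidates are compared
#' by objective with probability `pf`, by violation otherwise; fully feasible
#' populations are ranked purely by objective. Offspring are clipped to the
#' box. The best feasible candidate ever evaluated is returned, so the
#' best-so-far trace is non-increasing.
#'
#' @param objective function of a parameter matrix (rows = candidates)
#'   returning a numeric vector; must be finite on feasible points.
#' @param lower,upper finite bound vectors.
#' @param config an [sres_config()].
#' @param violation optional function of the parameter matrix returning
#'   non-negative constraint violations (0 = feasible); `NULL` means the box
#'   is the only constraint.
#' @param init optional matrix of candidate rows injected into the initial
#'   population (e.g. a known feasible solution).
#' @return list: `par`, `value`, `trace` (best-so-far per generation).
#' @export
sres_minimize <- function(objective, lower, upper, config = sres_config(),
                          violation = NULL, init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(c(lower, upper))),
            all(upper > lower))
  lam <- config$lambda; mu <- config$mu; G <- config$generations
  tau <- 1 / sqrt(2 * sqrt(d)); tau_p <- 1 / sqrt(2 * d)
  sigma0 <- (upper - lower) / sqrt(d)

  clip <- function(x) pmin(pmax(x, matrix(lower, nrow(x), d, byrow = TRUE)),
                           matrix(upper, nrow(x), d, byrow = TRUE))
  eval_pop <- function(x) {
    f <- objective(x)
    v <- if (is.null(violation)) numeric(nrow(x)) else violation(x)
    if (any(!is.finite(f) & v == 0)) {
      stop("sres_minimize(): non-finite objective at a feasible point")
    }
    list(f = f, v = v)
  }

  with_seed(config$seed, {
    x <- matrix(stats::runif(lam * d), lam, d)
    x <- sweep(sweep(x, 2, upper - lower, "*"), 2, lower, "+")
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      x[seq_len(min(nrow(init), lam)), ] <- clip(init)
    }
    sig <- matrix(sigma0, lam, d, byrow = TRUE)
    ev <- eval_pop(x)
    feas <- ev$v == 0
    best_i <- which(feas)[which.min(ev$f[feas])]
    best <- list(par = x[best_i, ], value = ev$f[best_i])
    trace <- numeric(G)

    for (g in seq_len(G)) {
      rank <- stochastic_rank(ev$f, ev$v, config$pf)
      px <- x[rank[seq_len(mu)], , drop = FALSE]
      ps <- sig[rank[seq_len(mu)], , drop = FALSE]
      parent <- rep_len(seq_len(mu), lam)
      g_noise <- stats::rnorm(lam)
      sig <- ps[parent, , drop = FALSE] *
        exp(tau_p * g_noise + tau * matrix(stats::rnorm(lam * d), lam, d))
      x <- clip(px[parent, , drop = FALSE] +
                  sig * matrix(stats::rnorm(lam * d), lam, d))
      ev <- eval_pop(x)
      feas <- ev$v == 0
      if (any(feas)) {
        i <- which(feas)[which.min(ev$f[feas])]
        if (ev$f[i] < best$value) best <- list(par = x[i, ], value = ev$f[i])
      }
      trace[g] <- best$value
    }
    list(par = best$par, value = best$value, trace = trace)
  })
}

# Vectorized cosinor SSE objective for SRES: params are (a, b, c) rows.
cosinor_sse_objective <- function(times, values) {
  B <- rbind(cos(2 * pi * times / 24), sin(2 * pi * times / 24),
             rep(1, length(times)))
  function(par) {
    pred <- par %*% B
    rowSums((pred - matrix(values, nrow(par), length(values),
                           byrow = TRUE))^2)
  }
}

#' Build the reference (training) oscillation curve
#'
#' Z-scores each reference subject's series, averages the values per
#' timepoint across subjects (all references must share the same sampling
#' times), and fits the cosinor to the averaged points with
#' [sres_minimize()]. Reference subjects should be known intermediate
#' chronotypes so the curve defines the zero of the phase-shift scale.
#'
#' @param reference long tibble for one gene: `subject_id`, `time_h`,
#'   `rel_expr` (a `gene` column, if present, must be single-valued).
#' @param config an [sres_config()].
#' @return an `oscillation_model`; attribute `degenerate` is `TRUE` when the
#'   fitted amplitude is below 0.01 (e.g. antiphase references cancelling).
#' @export
build_training_curve <- function(reference, config = sres_config()) {
  if ("gene" %in% names(reference) &&
      length(unique(reference$gene)) > 1L) {
    stop("build_training_curve(): one gene at a time")
  }
  if (length(unique(reference$subject_id)) < 1L) {
    stop("build_training_curve(): need at least one reference subject")
  }
  tsets <- reference |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(key = paste(sort(.data$time_h), collapse = ","),
                     .groups = "drop")
  if (length(unique(tsets$key)) != 1L) {
    stop("build_training_curve(): reference subjects have mismatched timepoints")
  }
  z <- reference |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(rel_expr = as.numeric(scale(.data$rel_expr))) |>
    dplyr::ungroup()
  avg <- z |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(rel_expr = mean(.data$rel_expr), .groups = "drop")
  obj <- cosinor_sse_objective(avg$time_h, avg$rel_expr)
  fit <- sres_minimize(obj, lower = c(-5, -5, -3), upper = c(5, 5, 3),
                       config = config)
  model <- ab_to_model(fit$par)
  attr(model, "degenerate") <- model$amplitude < 0.01
  attr(model, "sse") <- fit$value
  model
}

#' Fit one subject's series against the training curve
#'
#' Minimizes the SSE between the cosinor and the subject's (z-scored) points
#' over amplitude, acrophase and mesor, on the linear sin/cos
#' parameterization (no 0/24 phase boundary), with the training-curve
#' parameters seeded into the initial SRES population — so the fit can never
#' be worse on the subject's points than the training curve itself. The
#' phase shift is the circular difference `training acrophase - subject
#' acrophase` wrapped into (-12, 12]; positive = the subject peaks earlier
#' (advanced).
#'
#' @param series tibble for one subject x gene: `time_h`, `rel_expr`
#'   (z-scored), with >= 3 distinct timepoints in \[0, 24).
#' @param training the reference `oscillation_model`.
#' @param config an [sres_config()].
#' @return an `oscillation_fit` list: `model`, `phase_shift`, `sse`.
#' @export
fit_subject <- function(series, training, config = sres_config()) {
  times <- series$time_h
  values <- series$rel_expr
  if (length(unique(times)) < 3L) {
    stop("fit_subject(): need >= 3 distinct timepoints")
  }
  if (any(times < 0 | times >= 24)) stop("fit_subject(): times must lie in [0, 24)")
  obj <- cosinor_sse_objective(times, values)
  fit <- sres_minimize(obj, lower = c(-5, -5, -3), upper = c(5, 5, 3),
                       config = config,
                       init = matrix(model_to_ab(training), nrow = 1))
  model <- ab_to_model(fit$par)
  structure(
    list(model = model,
         phase_shift = wrap_phase(training$acrophase - model$acrophase),
         sse = fit$value),
    class = "oscillation_fit"
  )
}

#' Molecular chronotyping of a cohort
#'
#' Z-scores the expression table per subject x gene, builds (or accepts) a
#' per-gene training curve, fits every subject, and returns the fit table
#' with cohort z-scores of phase shift and amplitude per gene.
#'
#' @param expression long tibble: `subject_id`, `gene`, `time_h`, `rel_expr`.
#' @param training named list of `oscillation_model`s per gene; `NULL` builds
#'   each gene's curve from the cohort itself (intermediate-type references
#'   are preferable when available).
#' @param config an [sres_config()]; each subject fit gets a distinct seed
#'   derived from `config$seed`.
#' @return a `chronotype_fits` tibble: `subject_id`, `gene`, `amplitude`,
#'   `acrophase`, `mesor`, `phase_shift_h`, `sse`, `phase_z`, `amplitude_z`.
#' @export
chronotype_cohort <- function(expression, training = NULL,
                              config = sres_config()) {
  z <- zscore_expression(expression)
  genes <- unique(z$gene)
  if (is.null(training)) {
    training <- purrr::map(stats::setNames(genes, genes), function(g) {
      build_training_curve(dplyr::filter(z, .data$gene == g), config)
    })
  }
  groups <- z |>
    dplyr::group_by(.data$subject_id, .data$gene) |>
    dplyr::group_split()
  seeds <- spawn_seeds(config$seed, length(groups), "chronofit")
  fits <- purrr::map2_dfr(groups, seeds, function(gdat, s) {
    cfg <- config; cfg$seed <- s
    ft <- fit_subject(gdat, training[[gdat$gene[1]]], cfg)
    tibble(subject_id = gdat$subject_id[1], gene = gdat$gene[1],
           amplitude = ft$model$amplitude, acrophase = ft$model$acrophase,
           mesor = ft$model$mesor, phase_shift_h = ft$phase_shift,
           sse = ft$sse)
  })
  out <- cohort_zscores(fits)
  attr(out, "training") <- training
  class(out) <- c("chronotype_fits", class(out))
  out
}

#' Cohort z-scores of phase and amplitude
#'
#' Standardizes `phase_shift_h` and `amplitude` across the cohort within
#' each gene (mean 0, sample SD 1).
#'
#' @param fits tibble with `gene`, `phase_shift_h`, `amplitude`.
#' @return the tibble with `phase_z` and `amplitude_z` columns.
#' @export
cohort_zscores <- function(fits) {
  if (nrow(fits) < 2L) stop("cohort_zscores(): need >= 2 fits")
  out <- fits |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      phase_z = as.numeric(scale(.data$phase_shift_h)),
      amplitude_z = as.numeric(scale(.data$amplitude))
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(out$phase_z)) || any(!is.finite(out$amplitude_z))) {
    stop("cohort_zscores(): zero variance in phase or amplitude")
  }
  out
}

#' Circadian misalignment risk of anxiety
#'
#' Defines misalignment as an advanced molecular phase
#' (`phase_z > phase_z_threshold`) combined with evening behavioural
#' preference (`meq < meq_threshold`) — morning types are never flagged —
#' and estimates the odds ratio of anxiety for misaligned subjects versus
#' all others by logistic regression with a Wald 95% CI.
#'
#' @param data tibble with one row per subject.
#' @param phase_z,meq,anxiety column names.
#' @param phase_z_threshold advanced-phase cutoff in SD units (default 1).
#' @param meq_threshold evening-preference cutoff (default 41, the
#'   conventional evening-type boundary).
#' @return a `misalignment_risk` list: `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `n_misaligned`, `n`, `masked`.
#' @export
misalignment_risk <- function(data, phase_z = "phase_z", meq = "meq",
                              anxiety = "anxiety",
                              phase_z_threshold = 1, meq_threshold = 41) {
  mis <- as.integer(data[[phase_z]] > phase_z_threshold &
                      data[[meq]] < meq_threshold)
  y <- data[[anxiety]]
  ok <- !(is.na(mis) | is.na(y))
  mis <- mis[ok]; y <- y[ok]
  if (sum(mis) == 0L) {
    warning("misalignment_risk(): no misaligned subjects at these thresholds")
    out <- list(odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p_value = NA_real_, n_misaligned = 0L, n = length(y),
                masked = TRUE)
    class(out) <- "misalignment_risk"
    return(out)
  }
  fit <- stats::glm(y ~ mis, family = stats::binomial())
  sm <- summary(fit)$coefficients
  est <- sm["mis", "Estimate"]; se <- sm["mis", "Std. Error"]
  out <- list(odds_ratio = exp(est),
              ci_low = exp(est - 1.96 * se),
              ci_high = exp(est + 1.96 * se),
              p_value = sm["mis", "Pr(>|z|)"],
              n_misaligned = sum(mis), n = length(y), masked = FALSE)
  class(out) <- "misalignment_risk"
  out
}
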
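#' Logistic-regression risk table
#'
#' Fits maximum-likelihood logistic models and tabulates odds ratios with
#' Wald 95% confidence intervals and Benjamini-Hochberg adjusted p-values.
#' In `"univariate"` mode each feature group (one-hot families stay together)
#' is fitted in its own model and a likelihood-ratio p-value for the whole
#' group is reported alongside the per-coefficient Wald p; in
#' `"multivariate"` mode a single model holds every requested feature.
#' Coefficients showing numerical separation are flagged and reported with an
#' infinite odds-ratio sentinel rather than failing.
#'
#' @param data feature tibble (a `feature_matrix` or any numeric tibble).
#' @param outcome binary 0/1 vector.
#' @param features feature names to include (default: all numeric columns).
#' @param mode `"univariate"` or `"multivariate"`.
#' @param groups optional named character mapping feature -> group; defaults
#'   to the `feature_matrix` provenance when present, else each feature is
#'   its own group.
#' @return a `risk_table` tibble: `feature`, `group`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value` (Wald), `p_group_lrt`, `p_adj` (BH over
#'   the table's Wald p-values), `separation` flag.
#' @export
logistic_risk_table <- function(data, outcome,
                                features = NULL,
                                mode = c("univariate", "multivariate"),
                                groups = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(outcome %in% c(0, 1)))
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  features <- features %||% num
  missing_f <- setdiff(features, names(data))
  if (length(missing_f)) stop("logistic_risk_table(): unknown features: ",
                              paste(missing_f, collapse = ", "))
  if (is.null(groups)) {
    prov <- attr(data, "provenance")
    groups <- if (!is.null(prov)) {
      stats::setNames(prov$group, prov$feature)[features]
    } else stats::setNames(features, features)
    groups[is.na(groups)] <- features[is.na(groups)]
  }

  # fit on an explicit design matrix so coefficient rows are "X<feature>"
  # regardless of non-syntactic feature names (e.g. "PER3B_AG/CRY1_CG")
  fit_glm <- function(feats) {
    X <- as.matrix(data[feats])
    suppressWarnings(stats::glm(outcome ~ X, family = stats::binomial()))
  }
  coef_rows <- function(fit, feats, lrt_p) {
    sm <- summary(fit)$coefficients
    # positional map feature -> glm coefficient name (robust to the matrix
    # column-name mangling of single-column fits)
    cn <- names(stats::coef(fit))[-1]
    purrr::map_dfr(seq_along(feats), function(fi) {
      f <- feats[fi]
      rn <- cn[fi]
      if (is.na(rn) || !rn %in% rownames(sm)) {
        return(tibble(feature = f, odds_ratio = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_value = NA_real_,
                      p_group_lrt = lrt_p, separation = FALSE))
      }
      est <- sm[rn, "Estimate"]; se <- sm[rn, "Std. Error"]
      sep <- abs(est) > 15 | se > 50
      if (sep) {
        warning("logistic_risk_table(): separation detected for ", f)
        or <- if (est > 0) Inf else 0
        tibble(feature = f, odds_ratio = or,
               ci_low = if (est > 0) 0 else 0, ci_high = Inf,
               p_value = NA_real_, p_group_lrt = lrt_p, separation = TRUE)
      } else {
        tibble(feature = f,
               odds_ratio = exp(est),
               ci_low = exp(est - 1.96 * se),
               ci_high = exp(est + 1.96 * se),
               p_value = sm[rn, "Pr(>|z|)"],
               p_group_lrt = lrt_p, separation = FALSE)
      }
    })
  }

  if (mode == "multivariate") {
    rows <- coef_rows(fit_glm(features), features, NA_real_)
  } else {
    null_dev <- stats::glm(outcome ~ 1, family = stats::binomial())$deviance
    rows <- purrr::map_dfr(unique(groups), function(g) {
      feats <- features[groups == g]
      fit <- fit_glm(feats)
      lrt_p <- stats::pchisq(null_dev - fit$deviance,
                             df = length(feats), lower.tail = FALSE)
      coef_rows(fit, feats, lrt_p)
    })
  }
  rows$group <- groups[rows$feature]
  rows$p_adj <- stats::p.adjust(rows$p_value, method = "BH")
  out <- rows[c("feature", "group", "odds_ratio", "ci_low", "ci_high",
                "p_value", "p_group_lrt", "p_adj", "separation")]
  class(out) <- c("risk_table", class(out))
  out
}

criterion_value <- function(fit, criterion, n) {
  if (criterion == "AIC") stats::AIC(fit) else stats::BIC(fit)
}

#' Sequential-replacement subset search for multivariate logistic models
#'
#' Starting from the empty model, repeatedly tries every add, drop, and
#' one-for-one swap of candidate features, accepting the move that most
#' improves the information criterion, until no move improves it. Ties are
#' broken toward the smaller subset, then lexicographically, so the search is
#' deterministic given the data. Non-converging candidate fits are skipped
#' with a warning.
#'
#' @param data numeric feature tibble.
#' @param outcome binary 0/1 vector.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param features candidate feature names (default all numeric columns).
#' @return a `subset_search` list: `features` (selected), `model` (the
#'   fitted `glm`), `criterion`, `value`.
#' @export
subset_search <- function(data, outcome, criterion = c("AIC", "BIC"),
                          features = NULL) {
  criterion <- match.arg(criterion)
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  features <- features %||% num
  if (length(features) < 2L) stop("subset_search(): need >= 2 candidates")
  df <- dplyr::bind_cols(data[features], tibble(.y = outcome))

  fit_crit <- function(sel) {
    fml <- if (length(sel)) {
      stats::reformulate(sprintf("`%s`", sel), response = ".y")
    } else .y ~ 1
    fit <- tryCatch(
      stats::glm(fml, data = df, family = stats::binomial()),
      warning = function(w) {
        fitq <- suppressWarnings(stats::glm(fml, data = df,
                                            family = stats::binomial()))
        if (!fitq$converged) NULL else fitq
      },
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      warning("subset_search(): non-converging fit skipped for subset {",
              paste(sel, collapse = ", "), "}")
      return(list(fit = NULL, value = Inf))
    }
    list(fit = fit, value = criterion_value(fit, criterion, nrow(df)))
  }

  current <- character()
  best <- fit_crit(current)
  repeat {
    moves <- list()
    for (f in setdiff(features, current)) {
      moves[[length(moves) + 1L]] <- sort(c(current, f))
    }
    for (f in current) {
      moves[[length(moves) + 1L]] <- setdiff(current, f)
    }
    for (f in current) for (g in setdiff(features, current)) {
      moves[[length(moves) + 1L]] <- sort(c(setdiff(current, f), g))
    }
    if (!length(moves)) break
    vals <- vapply(moves, function(m) fit_crit(m)$value, numeric(1))
    keys <- vapply(moves, function(m) paste(m, collapse = "|"), character(1))
    sizes <- lengths(moves)
    ord <- order(vals, sizes, keys)
    if (vals[ord[1]] < best$value - 1e-9) {
      current <- moves[[ord[1]]]
      best <- fit_crit(current)
    } else break
  }
  structure(list(features = current, model = best$fit,
                 criterion = criterion, value = best$value),
            class = "subset_search")
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Exact p by the "sum of hypergeometric probabilities no greater than the
#' observed table's" convention (the same two-sided rule as
#' `stats::fisher.test`), computed directly from the hypergeometric pmf so
#' that cutoff scans over many tables stay cheap.
#'
#' @param a,b,c,d cell counts, rows = first variable, columns = second.
#' @return the two-sided p-value.
#' @export
fisher2x2_p <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fisher exact cutoff-scan heatmap
#'
#' For every pair of cutoffs, dichotomizes the phenotype (`x > x_cutoff`) and
#' the anxiety score (`y >= y_cutoff`) and stores the base-10 log of the
#' two-sided Fisher exact p-value of the induced 2x2 table (the conventional
#' "sum of tables no more probable than observed" two-sided rule). A cutoff
#' that empties a table margin gives p = 1 (cell 0) and is flagged masked.
#'
#' @param x continuous phenotype per subject (e.g. a phase or amplitude
#'   z-score).
#' @param y anxiety score per subject (STAI).
#' @param x_cutoffs,y_cutoffs ascending cutoff grids.
#' @return a `cutoff_heatmap` tibble: `x_cutoff`, `y_cutoff`, `log10_p`,
#'   `p_value`, `masked`, plus `n` per cell.
#' @export
fisher_cutoff_heatmap <- function(x, y, x_cutoffs, y_cutoffs) {
  stopifnot(!is.unsorted(x_cutoffs), !is.unsorted(y_cutoffs))
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  out <- tidyr::expand_grid(y_cutoff = y_cutoffs, x_cutoff = x_cutoffs) |>
    dplyr::mutate(purrr::map2_dfr(.data$x_cutoff, .data$y_cutoff, function(xc, yc) {
      hx <- x > xc; hy <- y >= yc
      a <- sum(!hx & !hy); b <- sum(!hx & hy)
      cc <- sum(hx & !hy); d <- sum(hx & hy)
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) {
        tibble(p_value = 1, log10_p = 0, masked = TRUE, n = a + b + cc + d)
      } else {
        p <- fisher2x2_p(a, b, cc, d)
        tibble(p_value = p, log10_p = log10(p), masked = FALSE,
               n = a + b + cc + d)
      }
    }))
  class(out) <- c("cutoff_heatmap", class(out))
  out
}

#' Heatmap tibble to matrix (rows = anxiety cutoffs, columns = phenotype
#' cutoffs, both ascending)
#'
#' @param hm a `cutoff_heatmap`.
#' @param value column to spread (default `"log10_p"`).
#' @return numeric matrix with cutoff dimnames.
#' @export
heatmap_matrix <- function(hm, value = "log10_p") {
  wide <- tidyr::pivot_wider(hm[c("y_cutoff", "x_cutoff", value)],
                             names_from = "x_cutoff",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$y_cutoff
  m
}

#' Type-III two-way ANOVA with Tukey follow-up
#'
#' Fits `response ~ A * B` under sum-to-zero contrasts and reports type-III
#' F-tests for both main effects and the interaction, plus Tukey-adjusted
#' pairwise comparisons of the four cell means (via estimated marginal
#' means). Built for the sex x genotype-combination contrasts on mean
#' anxiety scores.
#'
#' @param data tibble holding the response and both factors.
#' @param response,factor_a,factor_b column names (factors may be binary
#'   numerics; they are converted).
#' @return an `anova_type3` list: `anova` tibble (`term`, `sumsq`, `df`,
#'   `statistic`, `p_value`), `tukey` tibble of pairwise contrasts, `model`.
#' @export
anova_type3 <- function(data, response, factor_a, factor_b) {
  df <- tibble(
    y = data[[response]],
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    stop("anova_type3(): both factors need at least two observed levels")
  }
  cells <- table(df$A, df$B)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("anova_type3(): empty cell A=%s, B=%s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  fit <- stats::lm(y ~ A * B, data = df,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  an_tb <- tibble(
    term = rownames(an),
    sumsq = an[["Sum Sq"]],
    df = an[["Df"]],
    statistic = an[["F value"]],
    p_value = an[["Pr(>F)"]]
  ) |>
    dplyr::filter(!.data$term %in% c("(Intercept)", "Residuals"))
  emm <- emmeans::emmeans(fit, ~ A * B)
  tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  out <- list(anova = an_tb, tukey = as_tibble(tk), model = fit)
  class(out) <- "anova_type3"
  out
}

#' Nonparametric bootstrap mediation analysis
#'
#' Estimates the average causal mediation effect (ACME, the indirect
#' treatment -> mediator -> outcome path), the average direct effect (ADE),
#' the total effect, and the proportion mediated. For a continuous outcome
#' both models are linear and ACME is the product of paths `a * b`, with the
#' identity `total = acme + ade` holding exactly. For a binary outcome the
#' outcome model is logistic and effects are computed by counterfactual
#' composition on the response scale (mediator set to its model-predicted
#' mean under each treatment level, averaged over the sample). Percentile
#' confidence intervals come from `B` nonparametric resamples of subjects.
#'
#' @param data tibble with all variables.
#' @param treatment,mediator,outcome column names; treatment binary or
#'   numeric, mediator continuous.
#' @param covariates character vector of adjustment columns.
#' @param B bootstrap replicates (default 1000; below 100 warns).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return a `mediation_boot` list with an `estimates` tibble (`term`,
#'   `estimate`, `ci_low`, `ci_high`), `B`, and the two fitted models.
#' @export
mediation_bootstrap <- function(data, treatment, mediator, outcome,
                                covariates = character(), B = 1000, seed = 1,
                                conf = 0.95) {
  if (B < 100) warning("mediation_bootstrap(): B < 100 gives unstable CIs")
  vars <- c(treatment, mediator, outcome, covariates)
  stopifnot(all(vars %in% names(data)))
  df <- data[vars]
  mm <- stats::model.matrix(~ ., data = df[c(treatment, covariates)])
  if (qr(mm)$rank < ncol(mm)) stop("mediation_bootstrap(): collinear covariates")
  binary_y <- all(stats::na.omit(df[[outcome]]) %in% c(0, 1))

  point <- function(d) {
    f_m <- stats::reformulate(c(treatment, covariates), response = mediator)
    fit_m <- stats::lm(f_m, data = d)
    a <- stats::coef(fit_m)[[treatment]]
    f_y <- stats::reformulate(c(mediator, treatment, covariates),
                              response = outcome)
    if (!binary_y) {
      fit_y <- stats::lm(f_y, data = d)
      b <- stats::coef(fit_y)[[mediator]]
      ade <- stats::coef(fit_y)[[treatment]]
      acme <- a * b
      total <- acme + ade
    } else {
      fit_y <- stats::glm(f_y, data = d, family = stats::binomial())
      d0 <- d; d0[[treatment]] <- 0
      d1 <- d; d1[[treatment]] <- 1
      m0 <- stats::predict(fit_m, d0); m1 <- stats::predict(fit_m, d1)
      pr <- function(tval, mval) {
        dd <- d; dd[[treatment]] <- tval; dd[[mediator]] <- mval
        mean(stats::predict(fit_y, dd, type = "response"))
      }
      acme <- mean(c(pr(1, m1) - pr(1, m0), pr(0, m1) - pr(0, m0)) / 1)
      ade <- mean(c(pr(1, m0) - pr(0, m0), pr(1, m1) - pr(0, m1)) / 1)
      total <- pr(1, m1) - pr(0, m0)
    }
    c(acme = acme, ade = ade, total = total,
      prop_mediated = if (abs(total) > 1e-12) acme / total else NA_real_)
  }

  est <- point(df)
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      point(df[sample.int(nrow(df), replace = TRUE), ])
    }, numeric(4))
  })
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- list(
    estimates = tibble(
      term = names(est),
      estimate = unname(est),
      ci_low = ci[1, ],
      ci_high = ci[2, ]
    ),
    B = B, conf = conf, binary_outcome = binary_y
  )
  class(out) <- "mediation_boot"
  out
}
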
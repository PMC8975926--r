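#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a bootstrap mediation result
#'
#' @param x a `mediation_boot`.
#' @param ... unused.
#' @return tibble: `term` (acme, ade, total, prop_mediated), `estimate`,
#'   `ci_low`, `ci_high`.
#' @export
tidy.mediation_boot <- function(x, ...) x$estimates

#' @rdname tidy.mediation_boot
#' @export
glance.mediation_boot <- function(x, ...) {
  est <- x$estimates
  tibble(
    acme = est$estimate[est$term == "acme"],
    ade = est$estimate[est$term == "ade"],
    total = est$estimate[est$term == "total"],
    prop_mediated = est$estimate[est$term == "prop_mediated"],
    B = x$B, conf = x$conf, binary_outcome = x$binary_outcome
  )
}

#' Tidy a misalignment-risk estimate
#'
#' @param x a `misalignment_risk`.
#' @param ... unused.
#' @return one-row tibble with the odds ratio, CI, p-value and counts.
#' @export
tidy.misalignment_risk <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, n_misaligned = x$n_misaligned, n = x$n,
         masked = x$masked)
}

#' Tidy a type-III ANOVA
#'
#' @param x an `anova_type3`.
#' @param ... unused.
#' @return the F-table tibble (`term`, `sumsq`, `df`, `statistic`,
#'   `p_value`).
#' @export
tidy.anova_type3 <- function(x, ...) x$anova

#' Tidy / summarize a sequential-replacement subset search
#'
#' @param x a `subset_search`.
#' @param ... unused.
#' @return `tidy()`: one row per selected feature with its coefficient;
#'   `glance()`: one row with the criterion and subset size.
#' @export
tidy.subset_search <- function(x, ...) {
  if (is.null(x$model) || !length(x$features)) {
    return(tibble(feature = character(), estimate = numeric()))
  }
  cf <- stats::coef(x$model)
  pos <- match(x$features, gsub("`", "", names(cf)))
  tibble(feature = x$features, estimate = unname(cf[pos]))
}

#' @rdname tidy.subset_search
#' @export
glance.subset_search <- function(x, ...) {
  tibble(criterion = x$criterion, value = x$value,
         n_features = length(x$features))
}

#' Tidy an oscillation fit
#'
#' @param x an `oscillation_fit`.
#' @param ... unused.
#' @return one-row tibble: amplitude, acrophase, mesor, phase shift, SSE.
#' @export
tidy.oscillation_fit <- function(x, ...) {
  tibble(amplitude = x$model$amplitude, acrophase = x$model$acrophase,
         mesor = x$model$mesor, phase_shift_h = x$phase_shift, sse = x$sse)
}
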
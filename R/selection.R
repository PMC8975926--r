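#' Information gain of a feature for a class label
#'
#' `H(Y) - H(Y|X)` with plug-in entropies, base 2 — identically `I(X;Y)`.
#' Continuous inputs must be discretized first (see [discretize_ef()]).
#'
#' @param x discrete feature vector.
#' @param labels class labels.
#' @return information gain in bits.
#' @export
info_gain <- function(x, labels) {
  if (length(x) == 0L) stop("info_gain(): empty input")
  mutual_information(x, labels)
}

#' ReliefF feature weights
#'
#' For each of `m_samples` sampled instances, each feature's weight is
#' decreased by its mean range-normalized difference to the `k_neighbors`
#' nearest same-class instances (hits) and increased by the class-prior
#' weighted mean difference to the `k_neighbors` nearest instances of every
#' other class (misses). Positive weights mark features that separate
#' classes locally.
#'
#' @param data numeric tibble/matrix without missing values.
#' @param labels class labels.
#' @param k_neighbors neighbours per class (default 10).
#' @param m_samples sampled instances; `NULL` (default) uses every instance
#'   in order, making the result deterministic.
#' @param seed seed for instance sampling when `m_samples` is given.
#' @return named numeric vector of weights, one per feature.
#' @export
relieff <- function(data, labels, k_neighbors = 10, m_samples = NULL, seed = 1) {
  x <- as.matrix(data)
  if (anyNA(x)) stop("relieff(): missing values not allowed")
  y <- as.character(labels)
  cls <- sort(unique(y))
  counts <- table(y)
  if (any(counts <= k_neighbors)) {
    stop("relieff(): k_neighbors must be smaller than every class size")
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xn <- sweep(x, 2, rng, "/")
  n <- nrow(x)
  priors <- counts / n

  idx <- if (is.null(m_samples)) seq_len(n) else {
    with_seed(seed, sample.int(n, min(m_samples, n)))
  }
  w <- stats::setNames(numeric(ncol(x)), colnames(x))
  by_class <- split(seq_len(n), y)
  for (i in idx) {
    d <- colSums((t(xn) - xn[i, ])^2)
    for (cl in cls) {
      members <- setdiff(by_class[[cl]], i)
      nn <- members[order(d[members])][seq_len(k_neighbors)]
      mean_diff <- colMeans(abs(xn[nn, , drop = FALSE] -
                                  matrix(xn[i, ], k_neighbors, ncol(x),
                                         byrow = TRUE)))
      if (cl == y[i]) {
        w <- w - mean_diff / length(idx)
      } else {
        w <- w + (priors[[cl]] / (1 - priors[[y[i]]])) * mean_diff / length(idx)
      }
    }
  }
  w
}

# I(X, Z; Y) via pasted joint variable — the JMI summand.
joint_mi <- function(x, z, y) {
  mutual_information(paste(x, z, sep = "\r"), y)
}

#' Greedy forward selection by mRMR or JMI
#'
#' Both criteria start from the feature maximizing `I(X;Y)`. At each later
#' step, mRMR scores a candidate as relevance minus mean redundancy,
#' `I(X;Y) - mean_s I(X;X_s)`; JMI scores it as `sum_s I(X,X_s;Y)` over the
#' already-selected set. Ties break lexicographically on feature name.
#'
#' @param data tibble of discrete (or discretizable) features; continuous
#'   columns are equal-frequency binned via [discretize_ef()].
#' @param labels class labels.
#' @param k_select number of features to pick.
#' @param criterion `"mrmr"` or `"jmi"`.
#' @param bins bins for discretizing continuous columns (default 4).
#' @return character vector of selected names, in greedy order.
#' @export
greedy_mi_select <- function(data, labels, k_select,
                             criterion = c("mrmr", "jmi"), bins = 4) {
  criterion <- match.arg(criterion)
  if (k_select < 1) stop("greedy_mi_select(): k_select must be >= 1")
  disc <- lapply(data, function(v) {
    if (is.numeric(v)) discretize_ef(v, bins) else v
  })
  feats <- names(disc)
  k_select <- min(k_select, length(feats))
  rel <- vapply(disc, function(v) mutual_information(v, labels), numeric(1))

  pick_best <- function(scores) {
    nm <- names(scores)[order(-scores, names(scores))]
    nm[1]
  }
  selected <- pick_best(rel)
  remaining <- setdiff(feats, selected)
  # redundancy cache for mRMR: rows = remaining candidates, cols = selected
  red_sum <- stats::setNames(numeric(length(feats)), feats)
  jmi_sum <- stats::setNames(numeric(length(feats)), feats)

  while (length(selected) < k_select) {
    last <- selected[length(selected)]
    for (f in remaining) {
      if (criterion == "mrmr") {
        red_sum[f] <- red_sum[f] + mutual_information(disc[[f]], disc[[last]])
      } else {
        jmi_sum[f] <- jmi_sum[f] + joint_mi(disc[[f]], disc[[last]], labels)
      }
    }
    scores <- if (criterion == "mrmr") {
      rel[remaining] - red_sum[remaining] / length(selected)
    } else {
      jmi_sum[remaining]
    }
    nxt <- pick_best(scores)
    selected <- c(selected, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  selected
}

#' Run one feature-selection method
#'
#' Dispatcher over the four criteria: `"infogain"` and `"relieff"` rank all
#' features and keep the top `k_select`; `"mrmr"` and `"jmi"` select greedily.
#'
#' @param data numeric tibble of features (no missing values).
#' @param labels class labels.
#' @param method one of `"infogain"`, `"relieff"`, `"mrmr"`, `"jmi"`.
#' @param k_select number of features to keep.
#' @param bins discretization bins for the information-theoretic criteria.
#' @param relieff_k,relieff_m ReliefF neighbour and sample counts.
#' @param seed seed (ReliefF sampling only).
#' @return character vector of selected feature names.
#' @export
select_features <- function(data, labels,
                            method = c("infogain", "relieff", "mrmr", "jmi"),
                            k_select = 60, bins = 4,
                            relieff_k = 10, relieff_m = NULL, seed = 1) {
  method <- match.arg(method)
  k_select <- min(k_select, ncol(data))
  if (method == "infogain") {
    disc <- lapply(data, function(v) if (is.numeric(v)) discretize_ef(v, bins) else v)
    ig <- vapply(disc, function(v) info_gain(v, labels), numeric(1))
    names(ig)[order(-ig, names(ig))][seq_len(k_select)]
  } else if (method == "relieff") {
    k <- min(relieff_k, min(table(labels)) - 1L)
    w <- relieff(data, labels, k_neighbors = k, m_samples = relieff_m, seed = seed)
    names(w)[order(-w, names(w))][seq_len(k_select)]
  } else {
    greedy_mi_select(data, labels, k_select, criterion = method, bins = bins)
  }
}

# Stratified fold assignment: within each class, shuffled round-robin, so
# per-fold class counts differ from exact proportion by at most one.
make_folds <- function(labels, folds, seed) {
  if (folds > min(table(labels))) {
    stop("make_folds(): fold count exceeds the smallest class size")
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  assign
}

#' Repeated cross-validated feature selection
#'
#' Runs each selection method once per fold of a repeated stratified
#' cross-validation (`folds * repeats` runs per method, 100 under the default
#' 10 x 10 protocol). By default each run selects on the training part of its
#' fold; `whole_data = TRUE` instead selects on the full dataset in every run,
#' mirroring protocols that derive the robust set from the entire cohort.
#'
#' @param data numeric feature tibble (missing values are imputed per run via
#'   [impute_knn()]).
#' @param labels binary class labels.
#' @param methods subset of the four criteria.
#' @param folds,repeats cross-validation geometry (defaults 10 and 10).
#' @param k_select features per run.
#' @param whole_data select on all rows instead of the training part.
#' @param seed master seed.
#' @param ... passed to [select_features()].
#' @return a `selection_profile` tibble: `method`, `rep`, `fold`,
#'   `features` (list-column of character vectors).
#' @export
run_selection_cv <- function(data, labels,
                             methods = c("infogain", "relieff", "mrmr", "jmi"),
                             folds = 10, repeats = 10, k_select = 60,
                             whole_data = FALSE, seed = 1, ...) {
  seeds <- spawn_seeds(seed, repeats, "selcv")
  res <- purrr::map_dfr(seq_len(repeats), function(r) {
    fold_of <- make_folds(labels, folds, seeds[r])
    purrr::map_dfr(seq_len(folds), function(f) {
      rows <- if (whole_data) rep(TRUE, nrow(data)) else fold_of != f
      dat <- impute_knn(data[rows, , drop = FALSE])
      purrr::map_dfr(methods, function(m) {
        sel <- select_features(dat, labels[rows], method = m,
                               k_select = k_select,
                               seed = seeds[r] + f, ...)
        tibble(method = m, rep = r, fold = f, features = list(sel))
      })
    })
  })
  class(res) <- c("selection_profile", class(res))
  res
}

#' Aggregate selection runs into the robust feature set
#'
#' A feature is robust when it appears in at least `within` (default 95%) of
#' a method's runs, for at least `across` (default 3) of the methods. Both
#' thresholds are inclusive.
#'
#' @param profiles a `selection_profile` tibble from [run_selection_cv()] (or
#'   any tibble with `method` and a `features` list-column).
#' @param within within-method run fraction required (default 0.95).
#' @param across number of methods required (default 3).
#' @return a `robust_features` tibble: `feature`, `n_methods`, one
#'   `freq_<method>` column per method; attributes record the thresholds.
#' @export
aggregate_robust <- function(profiles, within = 0.95, across = 3) {
  if (nrow(profiles) == 0L) {
    out <- tibble(feature = character(), n_methods = integer())
  } else {
    freq <- profiles |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        n_runs = dplyr::n(),
        tab = list(table(unlist(.data$features))),
        .groups = "drop"
      ) |>
      dplyr::mutate(freq = purrr::map2(.data$tab, .data$n_runs, function(tb, nr) {
        tibble(feature = as.character(names(tb)),
               freq = as.numeric(tb) / nr)
      })) |>
      dplyr::select("method", "freq") |>
      tidyr::unnest("freq")
    out <- freq |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(n_methods = sum(.data$freq >= within), .groups = "drop") |>
      dplyr::filter(.data$n_methods >= across)
    if (nrow(out)) {
      wide <- tidyr::pivot_wider(freq, names_from = "method",
                                 values_from = "freq", names_prefix = "freq_",
                                 values_fill = 0)
      out <- dplyr::left_join(out, wide, by = "feature") |>
        dplyr::arrange(dplyr::desc(.data$n_methods), .data$feature)
    }
  }
  attr(out, "within") <- within
  attr(out, "across") <- across
  class(out) <- c("robust_features", class(out))
  out
}
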
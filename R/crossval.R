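# Impute a target block using only donor rows: same metric as impute_knn()
# (unit-variance scaling, mean squared difference over mutually observed
# columns), but neighbour search restricted to the donor matrix, so held-out
# rows can be completed without influencing the training fold.
impute_from_donors <- function(target, donors, k = 5) {
  num <- vapply(target, is.numeric, logical(1))
  xt <- as.matrix(target[num])
  if (!anyNA(xt)) return(target)
  xd <- as.matrix(donors[names(target)[num]])
  sds <- apply(xd, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  xds <- sweep(xd, 2, sds, "/")
  xts <- sweep(xt, 2, sds, "/")
  for (i in which(rowSums(is.na(xt)) > 0)) {
    d2 <- rowMeans((xds - matrix(xts[i, ], nrow(xds), ncol(xds),
                                 byrow = TRUE))^2, na.rm = TRUE)
    for (j in which(is.na(xt[i, ]))) {
      cand <- which(!is.na(xd[, j]) & is.finite(d2))
      if (!length(cand)) stop("impute_from_donors(): no donors for column ",
                              colnames(xt)[j])
      nn <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      xt[i, j] <- mean(xd[nn, j])
    }
  }
  target[num] <- as_tibble(xt)
  target
}

default_grids <- function() {
  list(
    rf  = tibble(num.trees = 300, mtry_frac = c(0.33, 0.6)),
    xgb = tibble(nrounds = 50, max_depth = c(2, 4), eta = 0.3),
    svm = tibble(cost = c(0.1, 1), kernel = "linear"),
    majority = tibble(.dummy = 0)
  )
}

fit_classifier <- function(kind, x, y, pars, seed) {
  x <- as.matrix(x)
  yf <- factor(y, levels = c(0, 1))
  if (kind == "majority") {
    # chance-level reference: predicts the training class-1 frequency
    structure(list(p1 = mean(y == 1)), class = "majority_clf")
  } else if (kind == "rf") {
    ranger::ranger(
      x = x, y = yf, probability = TRUE,
      num.trees = pars$num.trees,
      mtry = max(1L, floor(pars$mtry_frac * ncol(x))),
      seed = seed, num.threads = 1
    )
  } else if (kind == "xgb") {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.numeric(y), nthread = 1)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = pars$max_depth, eta = pars$eta,
                    nthread = 1, seed = seed),
      data = dtrain, nrounds = pars$nrounds, verbose = 0
    )
  } else if (kind == "svm") {
    e1071::svm(x = x, y = yf, kernel = pars$kernel, cost = pars$cost,
               probability = TRUE)
  } else stop("unknown classifier: ", kind)
}

predict_prob <- function(kind, model, x) {
  x <- as.matrix(x)
  if (kind == "majority") {
    rep(model$p1, nrow(x))
  } else if (kind == "rf") {
    stats::predict(model, data = x, num.threads = 1)$predictions[, "1"]
  } else if (kind == "xgb") {
    stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  } else {
    p <- stats::predict(model, x, probability = TRUE)
    attr(p, "probabilities")[, "1"]
  }
}

# Inner grid search: 3-fold CV accuracy on the training block; single-row
# grids are returned directly.
grid_search <- function(kind, x, y, grid, seed) {
  if (nrow(grid) == 1L) return(grid[1, ])
  fold_of <- make_folds(y, min(3L, min(table(y))), seed)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(unique(fold_of), function(f) {
      tr <- fold_of != f
      m <- fit_classifier(kind, x[tr, , drop = FALSE], y[tr], grid[g, ], seed)
      p <- predict_prob(kind, m, x[!tr, , drop = FALSE])
      mean((p >= 0.5) == (y[!tr] == 1))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(acc), ]
}

#' Repeated stratified cross-validation of the classifier grid
#'
#' The per-fold pipeline is leakage-safe: the training part is imputed on its
#' own rows, the validation part is imputed using training rows as the only
#' donors, feature selection (when a method is given) runs on the training
#' part, SMOTE balances only the training part, hyperparameters are grid
#' searched inside the training part, and accuracy / AUROC are measured on
#' the untouched validation part.
#'
#' @param data numeric feature tibble.
#' @param labels binary 0/1 outcome.
#' @param classifiers subset of `"rf"` (random forest), `"xgb"` (boosted
#'   trees), `"svm"` (max-margin, linear kernel), `"majority"` (chance-level
#'   reference predicting the training majority class).
#' @param selection `"all"` (no selection) and/or selection method names;
#'   each entry becomes one row block of the result grid.
#' @param folds,repeats cross-validation geometry.
#' @param k_select features per selection run.
#' @param grid named list of hyperparameter tibbles (see `default_grids`);
#'   `NULL` uses the package defaults.
#' @param smote balance training folds by SMOTE (default `TRUE`).
#' @param seed master seed; results are bit-reproducible given it.
#' @return a `cv_result` tibble: `selection`, `classifier`, `rep`, `fold`,
#'   `accuracy`, `auroc`, `hyperparams` (list-column).
#' @export
crossval_evaluate <- function(data, labels,
                              classifiers = c("rf", "xgb", "svm"),
                              selection = "all",
                              folds = 10, repeats = 10, k_select = 60,
                              grid = NULL, smote = TRUE, seed = 1) {
  stopifnot(all(labels %in% c(0, 1)))
  if (folds > min(table(labels))) {
    stop("crossval_evaluate(): fold count exceeds the minority class size")
  }
  grids <- utils::modifyList(default_grids(), grid %||% list())
  seeds <- spawn_seeds(seed, repeats, "cv")

  res <- purrr::map_dfr(seq_len(repeats), function(r) {
    fold_of <- make_folds(labels, folds, seeds[r])
    purrr::map_dfr(seq_len(folds), function(f) {
      tr <- fold_of != f
      dtr <- impute_knn(data[tr, , drop = FALSE])
      dva <- impute_from_donors(data[!tr, , drop = FALSE], dtr)
      ytr <- labels[tr]; yva <- labels[!tr]
      purrr::map_dfr(selection, function(selm) {
        feats <- if (identical(selm, "all")) names(dtr) else {
          select_features(dtr, ytr, method = selm, k_select = k_select,
                          seed = seeds[r] + f)
        }
        xtr <- dtr[feats]; ytr2 <- ytr
        if (smote) {
          bal <- smote_balance(dplyr::mutate(xtr, .y = ytr), ".y",
                               seed = seeds[r] + 13L * f)
          ytr2 <- bal$.y
          xtr <- dplyr::select(bal, -".y", -".synthetic")
        }
        purrr::map_dfr(classifiers, function(cl) {
          pars <- grid_search(cl, xtr, ytr2, grids[[cl]], seeds[r] + f)
          model <- fit_classifier(cl, xtr, ytr2, pars, seeds[r] + f)
          p <- predict_prob(cl, model, dva[feats])
          auc <- if (length(unique(yva)) == 2L) {
            as.numeric(pROC::auc(pROC::roc(yva, p, quiet = TRUE,
                                           direction = "<", levels = c(0, 1))))
          } else NA_real_
          tibble(selection = selm, classifier = cl, rep = r, fold = f,
                 accuracy = mean((p >= 0.5) == (yva == 1)),
                 auroc = auc, hyperparams = list(as.list(pars)))
        })
      })
    })
  })
  class(res) <- c("cv_result", class(res))
  res
}

#' Summarize a cross-validation result into the accuracy grid
#'
#' @param cv a `cv_result` tibble.
#' @return tibble: `selection`, `classifier`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_auroc`, `n_folds`.
#' @export
summarize_cv <- function(cv) {
  cv |>
    dplyr::group_by(.data$selection, .data$classifier) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = stats::sd(.data$accuracy),
      mean_auroc = mean(.data$auroc, na.rm = TRUE),
      n_folds = dplyr::n(),
      .groups = "drop"
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
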
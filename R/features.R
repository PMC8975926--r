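#' Encode genotype and clinical tables into the analysis feature matrix
#'
#' One-hot encodes each tri-state locus dropping the most frequent state as
#' the reference (reducing multicollinearity), builds all two-way genotype
#' combination indicators (up to 9 joint states per locus pair, again minus
#' the most frequent joint state), and appends the clinical features: MEQ
#' (continuous), `sex` and `age_group` (already binary), and SES one-hot
#' minus its most frequent level. Reference-category ties are broken
#' lexicographically. A missing genotype makes every indicator of its
#' group(s) `NA` (zero would silently assert the reference state); missing
#' indicators are meant to be filled by [impute_knn()].
#'
#' @param genotypes tibble: `subject_id` plus one character column per locus.
#' @param clinical tibble: `subject_id`, `sex`, `age_group`, `ses`, `meq`
#'   (further columns such as `stai` are ignored).
#' @param pairwise build two-way combination indicators (default `TRUE`).
#' @param loci optional list of [locus_spec()]; when given, genotype strings
#'   are validated against each locus's three states.
#' @return a `feature_matrix`: a tibble `subject_id` + numeric feature
#'   columns, with attributes `provenance` (tibble: feature, group, type one
#'   of single/pair/clinical) and `reference_log` (named list group ->
#'   dropped reference category).
#' @export
encode_features <- function(genotypes, clinical, pairwise = TRUE, loci = NULL) {
  stopifnot("subject_id" %in% names(genotypes), "subject_id" %in% names(clinical))
  locus_names <- setdiff(names(genotypes), "subject_id")
  if (!is.null(loci)) {
    valid <- stats::setNames(lapply(loci, `[[`, "states"),
                             vapply(loci, `[[`, character(1), "name"))
    for (loc in intersect(locus_names, names(valid))) {
      g <- genotypes[[loc]]
      bad <- which(!is.na(g) & !(g %in% valid[[loc]]))
      if (length(bad)) {
        stop(sprintf("encode_features(): invalid genotype '%s' at locus %s for subject %s",
                     g[bad[1]], loc, genotypes$subject_id[bad[1]]))
      }
    }
  }

  ord <- match(genotypes$subject_id, clinical$subject_id)
  if (anyNA(ord)) stop("encode_features(): subject_id mismatch between tables")
  clinical <- clinical[ord, ]

  cols <- list()
  prov <- list()
  refs <- list()

  # reference = most frequent category, ties broken lexicographically
  pick_ref <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    names(tab)[order(-tab, names(tab))][1]
  }
  add_group <- function(values, group, type, label_fun = identity) {
    obs <- unique(values[!is.na(values)])
    if (length(obs) <= 1L) {
      refs[[group]] <<- if (length(obs)) obs else NA_character_
      return(invisible(NULL))
    }
    ref <- pick_ref(values[!is.na(values)])
    refs[[group]] <<- ref
    for (st in setdiff(sort(obs), ref)) {
      nm <- label_fun(st)
      cols[[nm]] <<- ifelse(is.na(values), NA_real_, as.numeric(values == st))
      prov[[nm]] <<- tibble(feature = nm, group = group, type = type)
    }
  }

  for (loc in locus_names) {
    add_group(genotypes[[loc]], group = loc, type = "single",
              label_fun = function(st) genotype_label(loc, st))
  }

  if (pairwise && length(locus_names) >= 2L) {
    pairs <- utils::combn(locus_names, 2, simplify = FALSE)
    for (pr in pairs) {
      g1 <- genotypes[[pr[1]]]; g2 <- genotypes[[pr[2]]]
      joint <- ifelse(is.na(g1) | is.na(g2), NA_character_,
                      paste0(genotype_label(pr[1], g1), "/",
                             genotype_label(pr[2], g2)))
      add_group(joint, group = paste(pr, collapse = "/"), type = "pair")
    }
  }

  for (bin in c("sex", "age_group")) {
    if (bin %in% names(clinical)) {
      cols[[bin]] <- as.numeric(clinical[[bin]])
      prov[[bin]] <- tibble(feature = bin, group = bin, type = "clinical")
    }
  }
  if ("meq" %in% names(clinical)) {
    cols[["meq"]] <- as.numeric(clinical$meq)
    prov[["meq"]] <- tibble(feature = "meq", group = "meq", type = "clinical")
  }
  if ("ses" %in% names(clinical)) {
    add_group(as.character(clinical$ses), group = "ses", type = "clinical",
              label_fun = function(st) paste0("ses_", st))
  }

  out <- dplyr::bind_cols(tibble(subject_id = genotypes$subject_id),
                          as_tibble(cols))
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  attr(out, "reference_log") <- refs
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Decode an encoded genotype group back to states
#'
#' Inverse of the one-hot encoding for a single group: rows with all-zero
#' indicators map to the reference category. Used by the round-trip tests.
#'
#' @param fm a `feature_matrix`.
#' @param group group name (a locus, `"locusA/locusB"`, or `"ses"`).
#' @return character vector of states (`NA` where any indicator is missing).
#' @export
decode_group <- function(fm, group) {
  prov <- attr(fm, "provenance")
  refs <- attr(fm, "reference_log")
  feats <- prov$feature[prov$group == group]
  ref <- refs[[group]]
  if (!length(feats)) return(rep(ref, nrow(fm)))
  sub <- as.matrix(fm[feats])
  state_of <- function(row) {
    if (anyNA(row)) return(NA_character_)
    hit <- which(row == 1)
    if (!length(hit)) ref else feats[hit[1]]
  }
  labels <- apply(sub, 1, state_of)
  # strip the "LOCUS_" / "ses_" prefix back off single-group labels
  ifelse(is.na(labels) | labels == ref, labels,
         sub(paste0("^", group, "_|^ses_"), "", labels))
}

#' Binarize the anxiety outcome from STAI scores
#'
#' Deterministic thresholding of trait anxiety scores: scores at or above the
#' cutoff are the high-anxiety class. The instrument's high-anxiety band
#' starts at 45, which is the default; 38 (the moderate-anxiety floor) is the
#' conventional alternative.
#'
#' @param stai numeric scores, each within \[20, 80\].
#' @param cutoff threshold (default 45).
#' @return integer 0/1 vector with attribute `cutoff`.
#' @export
binarize_outcome <- function(stai, cutoff = 45) {
  if (any(stai < 20 | stai > 80, na.rm = TRUE)) {
    stop("binarize_outcome(): STAI scores must lie in [20, 80]")
  }
  structure(as.integer(stai >= cutoff), cutoff = cutoff)
}

#' k-nearest-neighbour imputation
#'
#' Fills missing numeric entries with the unweighted mean of the k nearest
#' rows, with distances computed as the mean squared difference over mutually
#' observed columns after scaling each column to unit variance. Complete
#' entries are never altered, so the operation is idempotent. Only rows with
#' the target column observed are candidate neighbours.
#'
#' @param data tibble; non-numeric columns pass through untouched.
#' @param k neighbour count (default 5); clamped with a warning when it
#'   exceeds the number of available donors.
#' @return tibble of the same shape with numeric `NA`s filled.
#' @export
impute_knn <- function(data, k = 5) {
  stopifnot(k >= 1)
  num <- vapply(data, is.numeric, logical(1))
  x <- as.matrix(data[num])
  if (!anyNA(x)) return(data)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop("impute_knn(): column(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  }
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- 1
  xs <- sweep(x, 2, sds, "/")
  filled <- x
  need <- which(rowSums(is.na(x)) > 0)
  for (i in need) {
    d2 <- rowMeans((xs - matrix(xs[i, ], nrow(xs), ncol(xs), byrow = TRUE))^2,
                   na.rm = TRUE)
    shared <- rowSums(!is.na(xs) & !is.na(matrix(xs[i, ], nrow(xs), ncol(xs),
                                                 byrow = TRUE)))
    d2[shared == 0] <- Inf
    d2[i] <- Inf
    for (j in which(is.na(x[i, ]))) {
      donors <- which(!is.na(x[, j]) & is.finite(d2))
      kk <- k
      if (!length(donors)) stop("impute_knn(): no donor rows for column ",
                                colnames(x)[j])
      if (length(donors) < kk) {
        warning(sprintf("impute_knn(): k clamped from %d to %d for column %s",
                        k, length(donors), colnames(x)[j]))
        kk <- length(donors)
      }
      nn <- donors[order(d2[donors])][seq_len(kk)]
      filled[i, j] <- mean(x[nn, j])
    }
  }
  data[num] <- as_tibble(filled)
  data
}

#' Balance classes by SMOTE
#'
#' Synthetic minority oversampling: each synthetic point is
#' `x_i + lambda * (x_nn - x_i)` with `lambda ~ Uniform(0, 1)` and `x_nn`
#' drawn among the `k` nearest minority-class neighbours of a random minority
#' row `x_i`. Original rows are never altered or removed; exactly enough
#' synthetic rows are added to equalize the class counts.
#'
#' @param data tibble of numeric features (impute first) plus the outcome
#'   column; an optional `subject_id` column is carried with synthetic ids.
#' @param outcome name of the binary outcome column in `data`.
#' @param k neighbour count (default 5, the empirical choice for this
#'   protocol); clamped with a warning if the minority class is too small.
#' @param seed integer seed.
#' @return tibble of originals followed by synthetic minority rows, with a
#'   logical `.synthetic` column.
#' @export
smote_balance <- function(data, outcome, k = 5, seed = 1) {
  stopifnot(outcome %in% names(data))
  y <- data[[outcome]]
  tab <- table(y)
  if (length(tab) < 2L) stop("smote_balance(): both classes must be present")
  if (length(tab) > 2L) stop("smote_balance(): outcome must be binary")
  out <- dplyr::mutate(data, .synthetic = FALSE)
  n_new <- abs(diff(as.integer(tab)))
  if (n_new == 0L) return(out)
  minority <- names(tab)[which.min(tab)]
  feat_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       outcome)
  xm <- as.matrix(data[y == minority, feat_cols, drop = FALSE])
  if (anyNA(xm)) stop("smote_balance(): impute missing values before SMOTE")
  n_min <- nrow(xm)
  kk <- min(k, n_min - 1L)
  if (kk < 1L) stop("smote_balance(): minority class too small for SMOTE")
  if (kk < k) warning(sprintf("smote_balance(): k clamped from %d to %d", k, kk))
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn_idx <- do.call(rbind, lapply(seq_len(n_min), function(r) {
    order(d[r, ])[seq_len(kk)]
  }))
  with_seed(seed, {
    i <- sample.int(n_min, n_new, replace = TRUE)
    j <- nn_idx[cbind(i, sample.int(kk, n_new, replace = TRUE))]
    lambda <- stats::runif(n_new)
    syn <- xm[i, , drop = FALSE] +
      lambda * (xm[j, , drop = FALSE] - xm[i, , drop = FALSE])
    syn_tb <- as_tibble(syn)
    syn_tb[[outcome]] <- rep(utils::type.convert(minority, as.is = TRUE), n_new)
    if ("subject_id" %in% names(data)) {
      syn_tb$subject_id <- sprintf("SYN%05d", seq_len(n_new))
    }
    syn_tb$.synthetic <- TRUE
    dplyr::bind_rows(out, syn_tb[names(out)])
  })
}
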
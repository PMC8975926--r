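test_that("information gain matches direct entropy arithmetic", {
  # label identical to a balanced binary feature: IG = H(Y) = 1 bit
  y <- rep(c(0, 1), each = 50)
  expect_equal(info_gain(y, y), 1)
  # constant feature carries nothing
  expect_equal(info_gain(rep(1, 100), y), 0)
  # joint counts {(0,0):40,(0,1):10,(1,0):10,(1,1):40}
  x <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  yy <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  expected <- h(c(.5, .5)) - (0.5 * h(c(.8, .2)) + 0.5 * h(c(.2, .8)))
  expect_equal(info_gain(x, yy), expected, tolerance = 1e-12)
})

test_that("IG, mRMR, JMI and the MI matrix agree with brute-force plug-in MI", {
  for (s in 1:12) {
    n <- 80
    vars <- tibble::tibble(
      v1 = random_discrete(n, 2, s), v2 = random_discrete(n, 3, s + 100),
      v3 = random_discrete(n, 6, s + 200), v4 = random_discrete(n, 4, s + 300)
    )
    y <- random_discrete(n, 2, s + 400) - 1L
    for (v in vars) {
      expect_equal(info_gain(v, y), mi_oracle(v, y), tolerance = 1e-12)
    }
    m <- mutual_information_matrix(vars)
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(m[i, j], mi_oracle(vars[[i]], vars[[j]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("greedy selection reproduces a brute-force recomputation of scores", {
  withr::local_seed(42)
  n <- 120
  d <- tibble::tibble(
    a = sample(0:1, n, TRUE), b = sample(0:2, n, TRUE),
    c = sample(0:1, n, TRUE), d = sample(0:3, n, TRUE),
    e = sample(0:1, n, TRUE)
  )
  y <- ifelse(stats::runif(n) < 0.75, d$a, 1 - d$a)

  brute <- function(criterion) {
    feats <- names(d)
    rel <- sapply(d, function(v) mi_oracle(v, y))
    sel <- names(which.max(rel))[1]
    while (length(sel) < 3) {
      rem <- setdiff(feats, sel)
      score <- sapply(rem, function(f) {
        if (criterion == "mrmr") {
          unname(rel[f]) -
            mean(sapply(sel, function(s2) mi_oracle(d[[f]], d[[s2]])))
        } else {
          sum(sapply(sel, function(s2) {
            mi_oracle(paste(d[[f]], d[[s2]]), y)
          }))
        }
      })
      best <- names(score)[order(-score, names(score))][1]
      sel <- c(sel, best)
    }
    sel
  }
  expect_equal(greedy_mi_select(d, y, 3, "mrmr"), brute("mrmr"))
  expect_equal(greedy_mi_select(d, y, 3, "jmi"), brute("jmi"))
  # both criteria start from argmax I(X;Y)
  expect_equal(greedy_mi_select(d, y, 1, "mrmr"),
               greedy_mi_select(d, y, 1, "jmi"))
  # k >= feature count returns everything
  expect_setequal(greedy_mi_select(d, y, 99, "jmi"), names(d))
  expect_error(greedy_mi_select(d, y, 0, "mrmr"), "k_select")
})

test_that("ReliefF rewards the separating feature and respects symmetry", {
  hits <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      n <- 60
      y <- rep(c(0, 1), each = n / 2)
      d <- tibble::tibble(A = y * 3 + stats::rnorm(n, 0, 0.4),
                          noise = stats::rnorm(n))
      w <- relieff(d, y, k_neighbors = 5)
      w["A"] > 0 && w["A"] > w["noise"]
    })
  }, logical(1))
  expect_true(all(hits))

  # duplicated columns get identical weights; order is irrelevant
  withr::local_seed(2)
  d <- tibble::tibble(a = stats::rnorm(40), b = stats::rnorm(40))
  d$a2 <- d$a
  y <- rep(0:1, 20)
  w <- relieff(d, y, k_neighbors = 3)
  expect_equal(unname(w["a"]), unname(w["a2"]))
  w_perm <- relieff(d[c("b", "a2", "a")], y, k_neighbors = 3)
  expect_equal(w[names(w_perm)], w_perm)
  # label-independent uniform feature stays near zero
  withr::local_seed(3)
  dn <- tibble::tibble(u = stats::runif(500))
  yn <- rep(0:1, 250)
  expect_lt(abs(relieff(dn, yn, k_neighbors = 10)[["u"]]), 0.05)
  expect_error(relieff(dn, yn, k_neighbors = 400), "class size")
})

test_that("robust aggregation applies the 95%-of-runs / 3-of-4 rule exactly", {
  mk_profile <- function(method, n_runs, n_with) {
    tibble::tibble(
      method = method, rep = 1, fold = seq_len(n_runs),
      features = lapply(seq_len(n_runs), function(i) {
        if (i <= n_with) c("F", "other") else "other"
      })
    )
  }
  # 96% in exactly 3 methods, 10% in the fourth -> included
  prof <- dplyr::bind_rows(
    mk_profile("infogain", 100, 96), mk_profile("relieff", 100, 96),
    mk_profile("mrmr", 100, 96), mk_profile("jmi", 100, 10)
  )
  expect_true("F" %in% aggregate_robust(prof)$feature)
  # 96% in only 2 methods -> excluded
  prof2 <- dplyr::bind_rows(
    mk_profile("infogain", 100, 96), mk_profile("relieff", 100, 96),
    mk_profile("mrmr", 100, 10), mk_profile("jmi", 100, 10)
  )
  expect_false("F" %in% aggregate_robust(prof2)$feature)
  # boundary: exactly 95% counts, 94% does not
  prof95 <- dplyr::bind_rows(
    mk_profile("infogain", 100, 95), mk_profile("relieff", 100, 95),
    mk_profile("mrmr", 100, 95), mk_profile("jmi", 100, 0)
  )
  expect_true("F" %in% aggregate_robust(prof95)$feature)
  prof94 <- dplyr::bind_rows(
    mk_profile("infogain", 100, 94), mk_profile("relieff", 100, 95),
    mk_profile("mrmr", 100, 95), mk_profile("jmi", 100, 95)
  )
  expect_true("F" %in% aggregate_robust(prof94)$feature)  # still 3 methods
  prof94b <- dplyr::bind_rows(
    mk_profile("infogain", 100, 94), mk_profile("relieff", 100, 94),
    mk_profile("mrmr", 100, 95), mk_profile("jmi", 100, 95)
  )
  expect_false("F" %in% aggregate_robust(prof94b)$feature)
  # ubiquitous feature always in; empty runs give the empty set
  expect_true("other" %in% aggregate_robust(prof)$feature)
  empty <- tibble::tibble(method = rep(c("a", "b", "c"), each = 2),
                          rep = 1, fold = rep(1:2, 3),
                          features = replicate(6, character(), FALSE))
  expect_equal(nrow(aggregate_robust(empty)), 0)
})

test_that("selection over folds is reproducible and respects its seed", {
  tt <- toy_tables(n = 60, seed = 21)
  fm <- encode_features(tt$genotypes, tt$clinical)
  feat <- fm[setdiff(names(fm), "subject_id")]
  y <- binarize_outcome(tt$cohort$stai)
  p1 <- run_selection_cv(feat, y, methods = c("infogain", "mrmr"),
                         folds = 3, repeats = 2, k_select = 3, seed = 9)
  p2 <- run_selection_cv(feat, y, methods = c("infogain", "mrmr"),
                         folds = 3, repeats = 2, k_select = 3, seed = 9)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 2 * 3 * 2)
  expect_true(all(lengths(p1$features) <= 3))
  expect_true(all(unlist(p1$features) %in% names(feat)))
})
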
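test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  # counts: exposed cases a=20, exposed controls b=10, unexposed cases c=10,
  # unexposed controls d=20 -> OR = (20*20)/(10*10) = 4
  x <- rep(c(1, 1, 0, 0), c(20, 10, 10, 20))
  y <- rep(c(1, 0, 1, 0), c(20, 10, 10, 20))
  rt <- logistic_risk_table(tibble::tibble(exposed = x), y)
  expect_equal(rt$odds_ratio, 4, tolerance = 1e-6)
  expect_true(rt$ci_low <= 4 && rt$ci_high >= 4)
})

test_that("null predictor CI covers 1 at large n", {
  withr::local_seed(10)
  n <- 5000
  x <- stats::rbinom(n, 1, .4)
  y <- stats::rbinom(n, 1, .3)
  rt <- logistic_risk_table(tibble::tibble(x = x), y)
  expect_true(rt$ci_low <= 1 && rt$ci_high >= 1)
})

test_that("BH adjustment in the risk table matches the hand-stepped values", {
  withr::local_seed(11)
  n <- 400
  d <- tibble::tibble(a = stats::rnorm(n), b = stats::rnorm(n),
                      c = stats::rnorm(n))
  y <- stats::rbinom(n, 1, 0.4)
  rt <- logistic_risk_table(d, y)
  # independent step-up oracle
  bh <- function(p) {
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(p[o] * m / (m:1)))[ro]
  }
  expect_equal(rt$p_adj, bh(rt$p_value), tolerance = 1e-12)
  # the canonical worked example
  expect_equal(bh(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  # monotone and idempotent
  expect_equal(order(rt$p_adj), order(rt$p_value))
  expect_equal(bh(bh(rt$p_value)) >= bh(rt$p_value), rep(TRUE, 3))
})

test_that("grouped univariate fits report both Wald and LRT p-values", {
  tt <- toy_tables(n = 200, seed = 31)
  fm <- encode_features(tt$genotypes, tt$clinical, pairwise = FALSE)
  y <- binarize_outcome(tt$cohort$stai)
  rt <- logistic_risk_table(fm[setdiff(names(fm), "subject_id")], y)
  prov <- attr(fm, "provenance")
  l1 <- rt[rt$group == "L1", ]
  expect_true(nrow(l1) >= 1)
  expect_equal(length(unique(l1$p_group_lrt)), 1)
  expect_true(all(rt$p_adj >= rt$p_value - 1e-12, na.rm = TRUE))
})

test_that("separation is flagged, not fatal", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- x
  expect_warning(
    rt <- logistic_risk_table(tibble::tibble(x = x), y),
    "separation")
  expect_true(rt$separation)
  expect_equal(rt$odds_ratio, Inf)
})

test_that("subset search recovers a planted predictor and is deterministic", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      n <- 1000
      noise <- as.data.frame(matrix(stats::rnorm(n * 10), n))
      names(noise) <- paste0("n", 1:10)
      x <- stats::rbinom(n, 1, .4)
      y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 1.2 * x))
      d <- tibble::tibble(signal = x, !!!noise)
      ss <- subset_search(d, y, criterion = "BIC")
      "signal" %in% ss$features
    })
  }, logical(1))
  expect_gte(sum(hits), 9)

  withr::local_seed(12)
  n <- 200
  d <- tibble::tibble(a = stats::rnorm(n), b = stats::rnorm(n))
  y <- stats::rbinom(n, 1, .5)
  s1 <- subset_search(d, y, "AIC"); s2 <- subset_search(d, y, "AIC")
  expect_identical(s1$features, s2$features)
})

test_that("criterion values match hand-computed -2*loglik + penalty", {
  withr::local_seed(13)
  n <- 60
  d <- tibble::tibble(x = stats::rnorm(n), z = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(d$x))
  fit <- stats::glm(y ~ x + z, data = d, family = stats::binomial())
  ll <- sum(y * log(stats::fitted(fit)) + (1 - y) * log(1 - stats::fitted(fit)))
  expect_equal(stats::AIC(fit), -2 * ll + 2 * 3, tolerance = 1e-8)
  expect_equal(stats::BIC(fit), -2 * ll + log(n) * 3, tolerance = 1e-8)
  # the search returns the criterion of its final model
  ss <- subset_search(d, y, "AIC")
  expect_equal(ss$value,
               if (length(ss$features)) stats::AIC(ss$model) else
                 stats::AIC(stats::glm(y ~ 1, family = stats::binomial())),
               tolerance = 1e-8)
})

test_that("Fisher heatmap cells match enumeration and handle degeneracies", {
  # [[2,0],[0,2]] -> two-sided p = 1/3
  expect_equal(fisher2x2_p(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
  x <- c(0, 0, 1, 1); y <- c(20, 20, 50, 50)
  hm <- fisher_cutoff_heatmap(x, y, x_cutoffs = 0.5, y_cutoffs = 45)
  expect_equal(hm$log10_p, log10(1 / 3), tolerance = 1e-12)
  # identical rows -> p = 1, cell 0
  expect_equal(fisher2x2_p(5, 5, 5, 5), 1)
  # empty margin -> masked zero cell
  hm2 <- fisher_cutoff_heatmap(c(1, 2, 3), c(50, 60, 70),
                               x_cutoffs = 10, y_cutoffs = 45)
  expect_true(hm2$masked)
  expect_equal(hm2$log10_p, 0)
  # agreement with stats::fisher.test on random tables (independent oracle)
  withr::local_seed(14)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(4, 6), 2)
    expect_equal(fisher2x2_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # shuffled (independent) data: most cells stay non-significant
  withr::local_seed(15)
  xs <- stats::rnorm(300); ys <- sample(20:80, 300, TRUE)
  hm3 <- fisher_cutoff_heatmap(xs, ys, x_cutoffs = stats::quantile(xs, 1:4 / 5),
                               y_cutoffs = c(30, 38, 45, 55))
  expect_gte(mean(hm3$log10_p >= log10(0.05)), 0.9)
  # matrix orientation: rows = anxiety cutoffs, columns = phenotype cutoffs
  m <- heatmap_matrix(hm3)
  expect_equal(dim(m), c(4, 4))
  expect_equal(rownames(m), as.character(c(30, 38, 45, 55)))
})

test_that("type-III ANOVA equals type-I on balanced designs and finds planted interactions", {
  withr::local_seed(16)
  d <- tidyr::expand_grid(A = 0:1, B = 0:1, i = 1:25) |>
    dplyr::mutate(y = stats::rnorm(dplyr::n()) + 2 * A)
  a3 <- anova_type3(d, "y", "A", "B")
  a1 <- stats::anova(stats::lm(y ~ A * B,
                               data = dplyr::mutate(d, A = factor(A),
                                                    B = factor(B))))
  expect_equal(a3$anova$sumsq, a1$`Sum Sq`[1:3], tolerance = 1e-8)
  # relabeling factor levels leaves F untouched
  d2 <- dplyr::mutate(d, A = ifelse(A == 0, "zz", "aa"))
  a3b <- anova_type3(d2, "y", "A", "B")
  expect_equal(a3$anova$statistic, a3b$anova$statistic, tolerance = 1e-8)

  # planted interaction detected with high power
  pows <- vapply(1:20, function(s) {
    withr::with_seed(300 + s, {
      dd <- tidyr::expand_grid(A = 0:1, B = 0:1, i = 1:50) |>
        dplyr::mutate(y = stats::rnorm(dplyr::n()) + 5 * A * B)
      aa <- anova_type3(dd, "y", "A", "B")
      aa$anova$p_value[aa$anova$term == "A:B"] < 0.001
    })
  }, logical(1))
  expect_true(all(pows))

  # null cells: Tukey rarely reports significance
  nulls <- vapply(1:20, function(s) {
    withr::with_seed(600 + s, {
      dd <- tidyr::expand_grid(A = 0:1, B = 0:1, i = 1:30) |>
        dplyr::mutate(y = stats::rnorm(dplyr::n()))
      aa <- anova_type3(dd, "y", "A", "B")
      all(aa$tukey$p.value >= 0.05)
    })
  }, logical(1))
  expect_gte(sum(nulls), 17)

  expect_error(
    anova_type3(tibble::tibble(y = c(1, 2, 3, 4), A = c(0, 0, 1, 1),
                               B = c(0, 1, 0, 0)),
                "y", "A", "B"), "empty cell")
  expect_error(
    anova_type3(tibble::tibble(y = 1:3, A = c(0, 0, 1), B = c(0, 0, 0)),
                "y", "A", "B"), "two observed levels")
})

test_that("mediation recovers the product of planted paths", {
  withr::local_seed(17)
  n <- 2000
  tr <- stats::rbinom(n, 1, .5)
  m <- 0.5 * tr + stats::rnorm(n)
  y <- 0.3 * m + 0.2 * tr + stats::rnorm(n)
  d <- tibble::tibble(t = tr, m = m, y = y)
  fit <- mediation_bootstrap(d, "t", "m", "y", B = 300, seed = 18)
  td <- tidy(fit)
  acme <- td[td$term == "acme", ]
  expect_true(acme$ci_low <= 0.15 && acme$ci_high >= 0.15)
  expect_lt(abs(acme$estimate - 0.15), 0.05)
  # linear identity: total = acme + ade exactly
  expect_equal(td$estimate[td$term == "total"],
               td$estimate[td$term == "acme"] + td$estimate[td$term == "ade"],
               tolerance = 1e-8)
})

test_that("null mediation CIs cover zero", {
  cover <- vapply(1:15, function(s) {
    withr::with_seed(700 + s, {
      n <- 400
      tr <- stats::rbinom(n, 1, .5)
      m <- stats::rnorm(n)                # no treatment -> mediator path
      y <- 0.2 * tr + stats::rnorm(n)
      fit <- mediation_bootstrap(tibble::tibble(t = tr, m = m, y = y),
                                 "t", "m", "y", B = 200, seed = s)
      td <- tidy(fit)
      a <- td[td$term == "acme", ]
      a$ci_low <= 0 && a$ci_high >= 0
    })
  }, logical(1))
  expect_gte(sum(cover), 13)
})

test_that("mediation input checks fire", {
  d <- tibble::tibble(t = rep(0:1, 10), m = stats::rnorm(20),
                      y = stats::rnorm(20), c1 = 1:20, c2 = (1:20) * 2)
  expect_warning(mediation_bootstrap(d, "t", "m", "y", B = 50, seed = 1),
                 "B < 100")
  expect_error(mediation_bootstrap(d, "t", "m", "y",
                                   covariates = c("c1", "c2"), B = 100),
               "collinear")
})
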
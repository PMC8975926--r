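#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Describe one genotyped locus
#'
#' @param name locus label, e.g. `"PER3B"`.
#' @param alleles character vector of the two allele symbols (major first by
#'   convention, e.g. `c("G", "A")` or the VNTR repeat counts `c("4", "5")`).
#' @param maf minor-allele frequency, in (0, 0.5].
#' @return a `locus_spec` list with the three unordered genotype states.
#' @export
locus_spec <- function(name, alleles, maf) {
  stopifnot(is.character(name), length(alleles) == 2L)
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5) {
    stop("locus_spec(): minor-allele frequency must lie in (0, 0.5]")
  }
  a <- as.character(alleles)
  states <- c(
    paste0(a[1], a[1]),
    paste0(sort(c(a[1], a[2])), collapse = ""),
    paste0(a[2], a[2])
  )
  structure(
    list(name = name, alleles = a, maf = maf, states = states),
    class = "locus_spec"
  )
}

#' The seven clock-gene loci of the study design
#'
#' CLOCK3111, CRY1, CRY2, PER2, PER3A, PER3B (SNPs) and the PER3 VNTR
#' length polymorphism. Minor-allele frequencies are generator defaults in the
#' common-variant range; they are configurable, not estimates from any cohort.
#'
#' @return list of [locus_spec()] objects.
#' @export
default_loci <- function() {
  list(
    locus_spec("CLOCK3111", c("T", "C"), 0.30),
    locus_spec("CRY1",      c("C", "G"), 0.35),
    locus_spec("CRY2",      c("A", "G"), 0.40),
    locus_spec("PER2",      c("A", "G"), 0.45),
    locus_spec("PER3A",     c("C", "G"), 0.15),
    locus_spec("PER3B",     c("G", "A"), 0.20),
    locus_spec("PER3_VNTR", c("4", "5"), 0.35)
  )
}

genotype_label <- function(locus, state) paste0(locus, "_", state)

#' Plan the effects planted in a synthetic cohort
#'
#' Collects every generative effect on the latent log-odds of high anxiety and
#' on diurnal preference. All effects are on the log-odds-ratio scale except
#' `mediation` (MEQ points) and `meq_phase_slope` (hours per MEQ point).
#'
#' @param intercept baseline log-odds of the high-anxiety class.
#' @param main_effects named numeric, `"LOCUS_GT"` -> log-OR.
#' @param pair_effects named numeric, `"LOCUSA_GTA/LOCUSB_GTB"` -> log-OR for
#'   carrying both genotypes (an epistatic effect).
#' @param sex_logOR log-OR for females (sex coded 1 = female, 0 = male).
#' @param age_logOR log-OR for the younger age group (1 = age <= 22).
#' @param meq_logOR_per_point log-OR per MEQ point (MEQ centred at 50).
#' @param mediation named numeric, `"LOCUS_GT"` -> MEQ mean shift: the
#'   genotype -> diurnal preference -> anxiety indirect pathway.
#' @param misalignment_logOR log-OR for circadian misalignment (advanced
#'   latent phase combined with evening preference).
#' @param meq_phase_slope hours of phase advance per MEQ point above 50;
#'   negative values advance morning types (default -0.08).
#' @param phase_sd SD (hours) of the residual latent phase-shift noise.
#' @return an `effect_plan` list.
#' @export
effect_plan <- function(intercept = -0.5,
                        main_effects = numeric(),
                        pair_effects = numeric(),
                        sex_logOR = 0,
                        age_logOR = 0,
                        meq_logOR_per_point = 0,
                        mediation = numeric(),
                        misalignment_logOR = 0,
                        meq_phase_slope = -0.08,
                        phase_sd = 1.5) {
  main_effects <- unlist(main_effects)
  pair_effects <- unlist(pair_effects)
  mediation <- unlist(mediation)
  eff <- c(intercept, main_effects, pair_effects, sex_logOR, age_logOR,
           meq_logOR_per_point, mediation, misalignment_logOR,
           meq_phase_slope, phase_sd)
  if (!all(is.finite(eff))) stop("effect_plan(): all effects must be finite")
  if (length(pair_effects)) {
    loci_of <- function(key) sub("_[^_]+$", "", strsplit(key, "/", fixed = TRUE)[[1]])
    bad <- vapply(names(pair_effects),
                  function(k) anyDuplicated(loci_of(k)) > 0, logical(1))
    if (any(bad)) {
      stop("effect_plan(): pair effects must combine two distinct loci: ",
           paste(names(pair_effects)[bad], collapse = ", "))
    }
  }
  structure(
    list(intercept = intercept, main_effects = main_effects,
         pair_effects = pair_effects, sex_logOR = sex_logOR,
         age_logOR = age_logOR, meq_logOR_per_point = meq_logOR_per_point,
         mediation = mediation, misalignment_logOR = misalignment_logOR,
         meq_phase_slope = meq_phase_slope, phase_sd = phase_sd),
    class = "effect_plan"
  )
}

#' Generate a synthetic cohort
#'
#' Draws genotypes at Hardy-Weinberg proportions, diurnal preference (MEQ,
#' 16-86) with genotype mediation shifts, a latent circadian phase shift
#' coupled to MEQ, and trait anxiety (STAI, 20-80) from a latent logistic
#' high-anxiety model whose log-odds combine the planted genotype main
#' effects, epistatic pair effects, demographic effects, MEQ, and circadian
#' misalignment. The binary class is drawn first; the continuous STAI score is
#' then drawn uniformly inside the class band (45-80 high, 20-44 otherwise) so
#' that both the continuous and binarized analyses see a coherent outcome.
#'
#' Latent generator ground truth is kept in dot-prefixed columns (`.logit`,
#' `.phase_h`, `.phase_z`, `.misaligned`) so recovery tests can compare
#' estimates against truth; downstream stages never read them.
#'
#' @param loci list of [locus_spec()] objects.
#' @param plan an [effect_plan()].
#' @param n cohort size.
#' @param sex_counts length-2 numeric `c(male, female)`; must sum to `n`.
#' @param seed integer seed; same seed and arguments give a byte-identical
#'   cohort.
#' @param p_young probability of the younger (age <= 22) group.
#' @return a tibble with one row per subject: `subject_id`, `sex` (1 =
#'   female), `age_group` (1 = age <= 22), `ses` (4-level factor), `meq`,
#'   `stai`, `anxiety` (1 = STAI >= 45), one genotype column per locus, and
#'   the latent dot-columns.
#' @export
#' @examples
#' co <- simulate_cohort(default_loci(), effect_plan(), n = 200,
#'                       sex_counts = c(60, 140), seed = 1)
#' table(co$anxiety)
simulate_cohort <- function(loci, plan, n, sex_counts, seed,
                            p_young = 0.75) {
  stopifnot(n > 0, inherits(plan, "effect_plan"))
  if (length(sex_counts) != 2L || any(sex_counts < 0) || sum(sex_counts) != n) {
    stop("simulate_cohort(): sex_counts must be c(male, female) summing to n")
  }
  locus_names <- vapply(loci, `[[`, character(1), "name")
  known <- unlist(lapply(loci, function(l) genotype_label(l$name, l$states)))
  pair_keys <- names(plan$pair_effects) %||% character()
  unknown <- setdiff(c(names(plan$main_effects), names(plan$mediation),
                       unlist(strsplit(pair_keys, "/", fixed = TRUE))),
                     known)
  if (length(unknown)) {
    stop("simulate_cohort(): planned effects reference unknown genotypes: ",
         paste(unknown, collapse = ", "))
  }

  with_seed(seed, {
    sex <- sample(rep(c(0L, 1L), times = sex_counts))
    age_group <- stats::rbinom(n, 1L, p_young)
    ses <- factor(
      sample(c("poor", "lower-middle", "upper-middle", "affluent"), n,
             replace = TRUE, prob = c(0.10, 0.30, 0.40, 0.20)),
      levels = c("poor", "lower-middle", "upper-middle", "affluent")
    )

    geno <- lapply(loci, function(l) {
      q <- l$maf; p <- 1 - q
      sample(l$states, n, replace = TRUE, prob = c(p^2, 2 * p * q, q^2))
    })
    names(geno) <- locus_names
    geno <- as_tibble(geno)

    carries <- function(key) {
      parts <- strsplit(key, "/", fixed = TRUE)[[1]]
      hit <- rep(TRUE, n)
      for (p in parts) {
        loc <- sub("_[^_]+$", "", p)
        st <- sub("^.*_", "", p)
        hit <- hit & (geno[[loc]] == st)
      }
      as.integer(hit)
    }

    meq_shift <- rep(0, n)
    for (key in names(plan$mediation)) {
      meq_shift <- meq_shift + plan$mediation[[key]] * carries(key)
    }
    meq <- round(stats::rnorm(n, 50 + meq_shift, 10))
    meq <- pmin(86, pmax(16, meq))

    phase_h <- plan$meq_phase_slope * (meq - 50) +
      stats::rnorm(n, 0, plan$phase_sd)
    phase_z <- if (stats::sd(phase_h) > 0) {
      as.numeric(scale(phase_h))
    } else rep(0, n)  # degenerate noiseless configuration
    misaligned <- as.integer(phase_z > 1 & meq < 41)

    logit <- rep(plan$intercept, n) +
      plan$sex_logOR * sex + plan$age_logOR * age_group +
      plan$meq_logOR_per_point * (meq - 50) +
      plan$misalignment_logOR * misaligned
    for (key in names(plan$main_effects)) {
      logit <- logit + plan$main_effects[[key]] * carries(key)
    }
    for (key in names(plan$pair_effects)) {
      logit <- logit + plan$pair_effects[[key]] * carries(key)
    }

    anxiety <- stats::rbinom(n, 1L, stats::plogis(logit))
    stai <- ifelse(anxiety == 1L,
                   sample(45:80, n, replace = TRUE),
                   sample(20:44, n, replace = TRUE))

    dplyr::bind_cols(
      tibble(subject_id = sprintf("S%05d", seq_len(n)),
             sex = sex, age_group = age_group, ses = ses,
             meq = as.numeric(meq), stai = as.numeric(stai),
             anxiety = anxiety),
      geno,
      tibble(.logit = logit, .phase_h = phase_h, .phase_z = phase_z,
             .misaligned = misaligned)
    )
  })
}

#' Simulate sparse diurnal expression sampling
#'
#' For each subject and gene, samples a 24-h cosinor
#' `mesor + A * cos(2*pi*(t - acrophase)/24)` at the given clock times. The
#' subject's acrophase is the gene's reference acrophase minus the subject's
#' latent phase shift (`.phase_h`; positive shift = earlier peak = advanced),
#' plus optional per-gene jitter. Amplitudes are drawn uniformly in
#' `amp_range`; Gaussian noise is added on the expression scale. Values are
#' left un-normalized: per-subject z-scoring is the first chronotyping step.
#'
#' @param cohort a cohort tibble from [simulate_cohort()].
#' @param genes character vector of gene names.
#' @param times clock times in hours, each in \[0, 24), no duplicates.
#' @param phase_jitter_sd per-gene acrophase jitter SD (hours).
#' @param amp_range length-2 amplitude range.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @param acrophase named reference acrophases per gene (hours); unnamed
#'   genes default to 8 h.
#' @return long tibble: `subject_id`, `gene`, `time_h`, `rel_expr`, plus the
#'   latent `.amp`, `.acrophase` truth columns.
#' @export
simulate_expression <- function(cohort, genes = c("PER3", "NR1D2"),
                                times = c(8, 16, 17, 20),
                                phase_jitter_sd = 0.25,
                                amp_range = c(0.8, 2.0),
                                noise_sd = 0.2, seed = 1,
                                acrophase = c(PER3 = 8, NR1D2 = 6)) {
  if (length(times) == 0L || any(times < 0 | times >= 24)) {
    stop("simulate_expression(): times must lie in [0, 24)")
  }
  if (anyDuplicated(times)) stop("simulate_expression(): duplicate times")
  with_seed(seed, {
    purrr::map_dfr(genes, function(g) {
      acro0 <- if (g %in% names(acrophase)) acrophase[[g]] else 8
      n <- nrow(cohort)
      amp <- stats::runif(n, amp_range[1], amp_range[2])
      acro <- acro0 - cohort$.phase_h + stats::rnorm(n, 0, phase_jitter_sd)
      tidyr::expand_grid(i = seq_len(n), time_h = times) |>
        dplyr::mutate(
          subject_id = cohort$subject_id[.data$i],
          gene = g,
          .amp = amp[.data$i],
          .acrophase = acro[.data$i] %% 24,
          rel_expr = .data$.amp *
            cos(2 * pi * (.data$time_h - acro[.data$i]) / 24) +
            stats::rnorm(dplyr::n(), 0, noise_sd)
        ) |>
        dplyr::select("subject_id", "gene", "time_h", "rel_expr",
                      ".amp", ".acrophase")
    })
  })
}

#' Write / read a cohort as the three analysis CSV tables
#'
#' `write_cohort()` writes `genotypes.csv` (subject_id + one column per
#' locus), `clinical.csv` (subject_id, sex, age_group, ses, meq, stai) and,
#' when expression is supplied, `expression.csv` (subject_id, gene, time_h,
#' rel_expr). Latent dot-columns are never written. `read_cohort()` reads
#' them back into the same shapes.
#'
#' @param cohort cohort tibble.
#' @param dir output directory (created if absent).
#' @param expression optional long expression tibble.
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a list
#'   with `genotypes`, `clinical` and (possibly `NULL`) `expression` tibbles.
#' @export
write_cohort <- function(cohort, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  latent <- grepl("^\\.", names(cohort))
  clin_cols <- c("subject_id", "sex", "age_group", "ses", "meq", "stai")
  geno_cols <- setdiff(names(cohort)[!latent], c(clin_cols, "anxiety"))
  utils::write.csv(cohort[c("subject_id", geno_cols)],
                   file.path(dir, "genotypes.csv"), row.names = FALSE)
  utils::write.csv(cohort[clin_cols],
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  if (!is.null(expression)) {
    utils::write.csv(expression[c("subject_id", "gene", "time_h", "rel_expr")],
                     file.path(dir, "expression.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) as_tibble(utils::read.csv(file.path(dir, f),
                                              check.names = FALSE))
  expr_path <- file.path(dir, "expression.csv")
  list(
    genotypes = rd("genotypes.csv"),
    clinical = rd("clinical.csv") |>
      dplyr::mutate(ses = factor(.data$ses)),
    expression = if (file.exists(expr_path)) rd("expression.csv") else NULL
  )
}
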
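#' Default pipeline configuration
#'
#' Returns the full configuration tree for [run_pipeline()]. The generator
#' block defaults to the study design (982 subjects; 318 males, 664
#' females); the analysis blocks default to the full selection /
#' cross-validation protocol (10 folds x 10 repeats). Smaller smoke-scale
#' runs override these fields. Unknown keys anywhere in a user config are
#' rejected by [validate_config()].
#'
#' @param ... named overrides merged (recursively) into the defaults.
#' @return nested configuration list.
#' @export
default_config <- function(...) {
  base <- list(
    seed = 1,
    stages = list(simulate = TRUE, encode = TRUE, select = TRUE,
                  classify = TRUE, stats = TRUE, rules = TRUE,
                  network = TRUE, chronotype = TRUE, report = TRUE),
    generator = list(
      n = 982, sex_counts = c(318, 664),
      effects = list(
        intercept = -0.5, sex_logOR = 0.6, age_logOR = 1.3,
        meq_logOR_per_point = -0.04,
        main_effects = list(), pair_effects = list(),
        mediation = list(), misalignment_logOR = log(6),
        meq_phase_slope = -0.08, phase_sd = 1.5
      ),
      expression = list(genes = c("PER3", "NR1D2"),
                        times = c(8, 16, 17, 20),
                        noise_sd = 0.2, subset = 100)
    ),
    outcome = list(cutoff = 45),
    select = list(methods = c("infogain", "relieff", "mrmr", "jmi"),
                  folds = 10, repeats = 10, k_select = 60,
                  whole_data = FALSE, within = 0.95, across = 3),
    classify = list(classifiers = c("rf", "xgb", "svm"),
                    selection = c("all", "infogain", "relieff", "mrmr", "jmi"),
                    folds = 10, repeats = 10, k_select = 60, smote = TRUE),
    stats = list(mediation_treatment = NULL, boot_reps = 1000,
                 criterion = "AIC"),
    rules = list(min_support = 0.05, min_confidence = 0.9, max_len = 6,
                 top_n = 20),
    network = list(bins = 4, epsilon = 0, boot_reps = 100),
    chronotype = list(sres = list(lambda = 200, mu = 30, generations = 300,
                                  pf = 0.45),
                      phase_z_threshold = 1, meq_threshold = 41)
  )
  merge_config(base, list(...))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration against the schema
#'
#' Recursively checks every key against [default_config()]; unknown keys are
#' an error, as are structurally impossible settings that are cheap to catch
#' before any stage runs (e.g. sex counts not summing to n).
#'
#' @param config nested list.
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  check <- function(node, ref, path) {
    free <- c("main_effects", "pair_effects", "mediation")
    if (!is.list(node) || is.null(names(ref))) return(invisible(NULL))
    unknown <- setdiff(names(node), names(ref))
    if (length(unknown)) {
      stop("validate_config(): unknown key(s) at ", path, ": ",
           paste(unknown, collapse = ", "))
    }
    for (nm in names(node)) {
      if (is.list(ref[[nm]]) && !nm %in% free) {
        check(node[[nm]], ref[[nm]], paste0(path, "$", nm))
      }
    }
  }
  check(config, default_config(), "config")
  if (sum(config$generator$sex_counts) != config$generator$n) {
    stop("validate_config(): generator sex_counts must sum to n")
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(), raw)
  validate_config(cfg)
  cfg
}

write_tsv_plain <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> encode -> select -> classify -> stats -> rules ->
#' network -> chronotype -> report under one master seed (each stage draws a
#' deterministic child seed, so stages can be reproduced in isolation).
#' Every stage writes its tables under `outdir` and the report stage writes
#' a manifest with the config, seed, and input-file checksums. A stage
#' failure halts the run with a stage-named error; earlier outputs remain.
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory.
#' @return named list of in-memory stage results, invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run")) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 9, "pipeline")
  res <- list()
  stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) return(NULL)
    tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  st <- config$stages

  res$cohort <- stage("simulate", st$simulate, function() {
    eff <- config$generator$effects
    plan <- effect_plan(
      intercept = eff$intercept,
      main_effects = eff$main_effects, pair_effects = eff$pair_effects,
      sex_logOR = eff$sex_logOR, age_logOR = eff$age_logOR,
      meq_logOR_per_point = eff$meq_logOR_per_point,
      mediation = eff$mediation,
      misalignment_logOR = eff$misalignment_logOR,
      meq_phase_slope = eff$meq_phase_slope, phase_sd = eff$phase_sd
    )
    cohort <- simulate_cohort(default_loci(), plan, config$generator$n,
                              config$generator$sex_counts, seed = seeds[1])
    ex_cfg <- config$generator$expression
    sub <- utils::head(cohort, min(ex_cfg$subset, nrow(cohort)))
    expr <- simulate_expression(sub, genes = ex_cfg$genes,
                                times = ex_cfg$times,
                                noise_sd = ex_cfg$noise_sd, seed = seeds[1])
    write_cohort(cohort, outdir, expression = expr)
    list(cohort = cohort, expression = expr)
  })

  res$features <- stage("encode", st$encode, function() {
    co <- res$cohort$cohort
    latent <- grepl("^\\.", names(co))
    clin <- co[c("subject_id", "sex", "age_group", "ses", "meq", "stai")]
    geno <- co[!latent][setdiff(names(co)[!latent],
                                c(names(clin), "anxiety"))]
    geno <- dplyr::bind_cols(co["subject_id"], geno)
    fm <- encode_features(geno, clin, pairwise = TRUE, loci = default_loci())
    y <- binarize_outcome(co$stai, config$outcome$cutoff)
    feat <- dplyr::select(fm, -"subject_id")
    write_tsv_plain(fm, file.path(outdir, "features.tsv"))
    jsonlite::write_json(attr(fm, "reference_log"),
                         file.path(outdir, "references.json"),
                         auto_unbox = TRUE)
    list(fm = fm, features = feat, outcome = y)
  })

  res$selection <- stage("select", st$select, function() {
    sc <- config$select
    prof <- run_selection_cv(res$features$features, res$features$outcome,
                             methods = sc$methods, folds = sc$folds,
                             repeats = sc$repeats, k_select = sc$k_select,
                             whole_data = sc$whole_data, seed = seeds[3])
    robust <- aggregate_robust(prof, within = sc$within, across = sc$across)
    jsonlite::write_json(
      prof |> dplyr::mutate(features = purrr::map(.data$features, identity)),
      file.path(outdir, "selection_profiles.json"))
    jsonlite::write_json(robust, file.path(outdir, "robust_features.json"))
    list(profiles = prof, robust = robust)
  })

  res$cv <- stage("classify", st$classify, function() {
    cc <- config$classify
    cv <- crossval_evaluate(res$features$features, res$features$outcome,
                            classifiers = cc$classifiers,
                            selection = cc$selection, folds = cc$folds,
                            repeats = cc$repeats, k_select = cc$k_select,
                            smote = cc$smote, seed = seeds[4])
    write_tsv_plain(dplyr::select(cv, -"hyperparams"),
                    file.path(outdir, "cv_results.tsv"))
    cv
  })

  res$stats <- stage("stats", st$stats, function() {
    feat <- res$features$features
    y <- res$features$outcome
    robust <- res$selection$robust
    feats <- if (!is.null(robust) && nrow(robust) > 0) {
      robust$feature
    } else {
      intersect(c("sex", "age_group", "meq"), names(feat))
    }
    imp <- impute_knn(feat)
    risk <- logistic_risk_table(imp, y, features = feats,
                                mode = "multivariate")
    write_tsv_plain(risk, file.path(outdir, "risk_table.tsv"))
    med <- NULL
    tr <- config$stats$mediation_treatment
    if (!is.null(tr) && tr %in% names(imp)) {
      med <- mediation_bootstrap(
        dplyr::mutate(imp, stai = res$cohort$cohort$stai),
        treatment = tr, mediator = "meq", outcome = "stai",
        B = config$stats$boot_reps, seed = seeds[5])
      jsonlite::write_json(med$estimates, file.path(outdir, "mediation.json"))
    }
    list(risk_table = risk, mediation = med)
  })

  res$rules <- stage("rules", st$rules, function() {
    co <- res$cohort$cohort
    rc <- config$rules
    base <- co[c("age_group", "meq", "ses",
                 setdiff(names(co), c("subject_id", "sex", "age_group",
                                      "ses", "meq", "stai", "anxiety",
                                      grep("^\\.", names(co), value = TRUE))))]
    by_sex <- purrr::map(c(male = 0, female = 1), function(s) {
      rows <- co$sex == s
      tr <- as_transactions(dplyr::bind_cols(
        base[rows, ], tibble(anxiety = co$anxiety[rows])))
      mine_rules(tr, consequent = c("anxiety=1", "anxiety=0"),
                 min_support = rc$min_support,
                 min_confidence = rc$min_confidence, max_len = rc$max_len)
    })
    write_rules_tsv(dplyr::bind_rows(by_sex, .id = "stratum"),
                    file.path(outdir, "rules.tsv"))
    nets <- stratified_networks(by_sex, top_n = rc$top_n)
    for (s in names(nets)) {
      if (nrow(nets[[s]]$edges)) {
        igraph::write_graph(nets[[s]]$graph,
                            file.path(outdir, paste0("rules_", s, ".graphml")),
                            format = "graphml")
      }
    }
    list(rules = by_sex, networks = nets)
  })

  res$network <- stage("network", st$network, function() {
    co <- res$cohort$cohort
    nc <- config$network
    dat <- co[c("sex", "age_group", "meq", "anxiety",
                setdiff(names(co), c("subject_id", "sex", "age_group", "ses",
                                     "meq", "stai", "anxiety",
                                     grep("^\\.", names(co), value = TRUE))))]
    net <- aracne_bootstrap(dat, bins = nc$bins, epsilon = nc$epsilon,
                            B = nc$boot_reps, seed = seeds[7])
    write_mi_network(net, graphml = file.path(outdir, "mi_network.graphml"),
                     tsv = file.path(outdir, "mi_network.tsv"))
    net
  })

  res$chronotype <- stage("chronotype", st$chronotype, function() {
    cc <- config$chronotype
    cfg <- sres_config(lambda = cc$sres$lambda, mu = cc$sres$mu,
                       generations = cc$sres$generations, pf = cc$sres$pf,
                       seed = seeds[8])
    fits <- chronotype_cohort(res$cohort$expression, config = cfg)
    write_tsv_plain(fits, file.path(outdir, "chronotype.tsv"))
    co <- res$cohort$cohort
    per3 <- dplyr::filter(fits, .data$gene == .data$gene[1]) |>
      dplyr::left_join(co[c("subject_id", "meq", "anxiety")],
                       by = "subject_id")
    risk <- misalignment_risk(per3, phase_z_threshold = cc$phase_z_threshold,
                              meq_threshold = cc$meq_threshold)
    jsonlite::write_json(unclass(risk), file.path(outdir, "misalignment.json"),
                         auto_unbox = TRUE)
    list(fits = fits, misalignment = risk)
  })

  res$report <- stage("report", st$report, function() {
    render_report(res, outdir, config)
  })
  invisible(res)
}

#' Render the report bundle from stage outputs
#'
#' Writes the selection-method x classifier accuracy grid, and a manifest
#' (config, seed, checksums of every table written). Panels whose stage
#' output is missing are skipped with a notice.
#'
#' @param results stage results list from [run_pipeline()].
#' @param outdir output directory.
#' @param config the configuration used.
#' @return paths of the written files, invisibly.
#' @export
render_report <- function(results, outdir, config) {
  paths <- character()
  if (!is.null(results$cv)) {
    grid <- summarize_cv(results$cv)
    p <- file.path(outdir, "accuracy_grid.tsv")
    write_tsv_plain(grid, p)
    paths <- c(paths, p)
  } else message("render_report(): no CV results; accuracy grid skipped")
  files <- list.files(outdir, pattern = "\\.(tsv|json|csv|graphml)$",
                      full.names = TRUE)
  manifest <- list(
    config = config,
    seed = config$seed,
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  )
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
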
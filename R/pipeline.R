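#' Write a cohort configuration to YAML
#'
#' Named per-group vectors are written as YAML maps so that
#' [read_cohort_config()] restores them with their group names.
#'
#' @param config A [cohort_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  cfg <- unclass(config)
  for (f in names(cfg)) {
    if (is.atomic(cfg[[f]]) && !is.null(names(cfg[[f]]))) {
      cfg[[f]] <- as.list(cfg[[f]])
    }
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [cohort_config()]
#'   arguments (named maps become named vectors).
#' @return A `"cohort_config"`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vec_fields <- c("n_subjects", "maturity_delay_months", "antibiotic_fraction",
                  "richness_reduction", "noise_sd")
  for (f in intersect(vec_fields, names(raw))) {
    if (is.list(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  for (f in intersect(c("visits", "age_range_months", "trajectory_amplitude",
                        "trajectory_timescale"), names(raw))) {
    raw[[f]] <- as.numeric(unlist(raw[[f]]))
  }
  do.call(cohort_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full maturity analysis pipeline on a synthetic cohort
#'
#' Executes simulate, filter, diversity, per-taxon testing, maturity-index
#' fitting, mixture modelling and evaluation in order, writing every stage's
#' tables under `out_dir` plus a run manifest (`manifest.json`) with the
#' master seed, configuration snapshot and an MD5 digest per output file.
#' Re-running with the same configuration and seed reproduces identical
#' digests.
#'
#' @param config A [cohort_config()] (or [null_cohort_config()]).
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param comparisons Per-taxon test comparisons to run (see [zibr_test()]).
#' @param n_repetitions Importance repetitions for the maturity stage (the
#'   pipeline default of 100 trades a little ranking stability for runtime;
#'   the model-fitting default is 1000).
#' @param cv_folds,n_repetitions_cv,n_trees,panel_size Passed to
#'   [fit_maturity_model()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         seed = config$seed,
                         comparisons = "VEO_vs_HC_lt7",
                         n_repetitions = 100, cv_folds = 5,
                         n_repetitions_cv = 25, n_trees = 500,
                         panel_size = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # simulate
  cohort <- stage("simulate", {
    cfg <- config
    cfg$seed <- derive_seed(seed, "simulate")
    class(cfg) <- "cohort_config"
    co <- generate_cohort(cfg)
    d <- file.path(out_dir, "simulate")
    write_cohort(co, d)
    files$simulate <- file.path(d, c("taxa.tsv", "samples.tsv",
                                      "truth_samples.tsv",
                                      "truth_species.tsv", "config.yaml"))
    co
  })
  taxa <- cohort$taxa
  samples <- cohort$samples

  # filter
  taxa_prev <- stage("filter", {
    tf <- filter_by_prevalence(taxa, 0.20)
    d <- file.path(out_dir, "filter")
    dir.create(d, showWarnings = FALSE)
    files$filter <- write_tsv(
      data.frame(sample_id = rownames(tf), unclass(tf), check.names = FALSE),
      file.path(d, "taxa_filtered.tsv"))
    tf
  })

  # diversity
  stage("diversity", {
    d <- file.path(out_dir, "diversity")
    dir.create(d, showWarnings = FALSE)
    alpha <- alpha_diversity(taxa)
    dys <- dysbiosis_scores(taxa, samples)
    stab <- suppressWarnings(subject_instability(taxa, samples))
    files$diversity <- c(
      write_tsv(alpha, file.path(d, "alpha.tsv")),
      write_tsv(dys, file.path(d, "dysbiosis.tsv")),
      write_tsv(stab, file.path(d, "stability.tsv")))
  })

  # taxon-test
  stage("taxon_test", {
    d <- file.path(out_dir, "taxon_test")
    dir.create(d, showWarnings = FALSE)
    files$taxon_test <- vapply(comparisons, function(cmp) {
      res <- zibr_test(taxa, samples, cmp)
      write_tsv(res, file.path(d, paste0(cmp, ".tsv")))
    }, character(1))
  })

  # maturity
  model <- stage("maturity", {
    mod <- fit_maturity_model(
      taxa, samples, n_repetitions = n_repetitions, cv_folds = cv_folds,
      n_repetitions_cv = n_repetitions_cv, n_trees = n_trees,
      panel_size = panel_size, seed = derive_seed(seed, "maturity"))
    d <- file.path(out_dir, "maturity")
    dir.create(d, showWarnings = FALSE)
    mmi <- predict_mmi(mod, taxa, samples)
    grid <- seq(mod$healthy_spline$age_range[1],
                mod$healthy_spline$age_range[2], length.out = 100)
    files$maturity <- c(
      write_tsv(mmi, file.path(d, "mmi.tsv")),
      write_tsv(data.frame(species_id = mod$panel,
                           rank = seq_along(mod$panel)),
                file.path(d, "panel.tsv")),
      write_tsv(mod$importance_table, file.path(d, "importance.tsv")),
      if (!is.null(mod$cv_error_curve)) {
        write_tsv(mod$cv_error_curve, file.path(d, "cv_curve.tsv"))
      },
      write_tsv(data.frame(age_months = grid,
                           expected_mmi = spline_predict(mod$healthy_spline,
                                                         grid)),
                file.path(d, "healthy_spline.tsv")))
    mod
  })
  mmi <- predict_mmi(model, taxa, samples)

  # mixture
  stage("mixture", {
    d <- file.path(out_dir, "mixture")
    dir.create(d, showWarnings = FALSE)
    fit <- fit_two_component(mmi$mmi_months, mmi$age_months,
                             model$healthy_spline,
                             seed = derive_seed(seed, "mixture"))
    post <- posterior_membership(fit, mmi$mmi_months, mmi$age_months,
                                 mmi$sample_id)
    sw <- component_switching(post, samples)
    fit_json <- file.path(d, "fit.json")
    jsonlite::write_json(
      list(beta2 = fit$beta2, pi1 = fit$pi1, sigma1 = fit$sigma1,
           sigma2 = fit$sigma2, convergence_age = fit$convergence_age,
           convergence_mmi = fit$convergence_mmi, loglik = fit$loglik,
           converged = fit$converged),
      fit_json, auto_unbox = TRUE, digits = NA)
    files$mixture <- c(
      fit_json,
      write_tsv(post, file.path(d, "posteriors.tsv")),
      write_tsv(sw$per_subject, file.path(d, "switching_subjects.tsv")),
      write_tsv(sw$by_therapy, file.path(d, "switching_by_therapy.tsv")))
  })

  # evaluate
  stage("evaluate", {
    d <- file.path(out_dir, "evaluate")
    dir.create(d, showWarnings = FALSE)
    merged <- merge(mmi, samples, by = "sample_id")
    is_dis <- merged$group %in% c("VEO", "PIBD")
    roc_all <- rmmi_roc(merged$rmmi_months, is_dis)
    young <- merged$group %in% c("VEO", "HC_lt7")
    old <- merged$group %in% c("PIBD", "HC_ge7")
    aucs <- list(
      overall = roc_all$auc,
      pediatric_ibd = rmmi_roc(merged$rmmi_months[old],
                               merged$group[old] == "PIBD")$auc,
      veo_ibd = rmmi_roc(merged$rmmi_months[young],
                         merged$group[young] == "VEO")$auc)
    gs <- group_summary(merged$rmmi_months, merged$group,
                        pairs = list(c("HC_lt7", "VEO"), c("HC_ge7", "PIBD")))
    auc_json <- file.path(d, "auc.json")
    jsonlite::write_json(aucs, auc_json, auto_unbox = TRUE, digits = NA)
    files$evaluate <- c(
      auc_json,
      write_tsv(data.frame(threshold = roc_all$thresholds,
                           tpr = roc_all$tpr, fpr = roc_all$fpr),
                file.path(d, "roc_points.tsv")),
      write_tsv(gs$summary, file.path(d, "rmmi_group_summary.tsv")),
      write_tsv(gs$tests, file.path(d, "rmmi_group_tests.tsv")))
  })

  all_files <- unlist(files, use.names = FALSE)
  manifest <- list(
    package = "gutmaturity",
    version = as.character(utils::packageVersion("gutmaturity")),
    master_seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    stages = lapply(files, function(f) {
      f <- f[!vapply(f, is.null, logical(1))]
      stats::setNames(as.list(unname(tools::md5sum(f))), basename(f))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
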
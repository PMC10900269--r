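# age-regression forest used for CV scoring and the final model: a larger
# mtry and small terminal nodes reduce the prediction bias at the ends of
# the age range, which otherwise flattens the recovered maturity delays
grow_age_forest <- function(x, y, ntree) {
  randomForest::randomForest(x = x, y = y, ntree = ntree,
                             mtry = max(1, ceiling(ncol(x) / 2)),
                             nodesize = 2)
}

#' Subject-level train/test split of healthy controls
#'
#' Restricts to healthy-control samples without antibiotic exposure and
#' splits subjects (never individual samples) into training and testing
#' sets, stratified by age tertile so both sets span the age range. All
#' visits of a subject fall on the same side.
#'
#' @param samples Sample metadata.
#' @param train_fraction Fraction of subjects assigned to training.
#' @param seed Integer seed.
#' @return List with `train_subjects`, `test_subjects`, `train_ids`,
#'   `test_ids` (sample ids).
#' @export
split_healthy_training <- function(samples, train_fraction = 0.70, seed = 1) {
  hc <- samples[samples$group %in% c("HC_lt7", "HC_ge7") &
                  !samples$antibiotics, , drop = FALSE]
  if (nrow(hc) == 0) stop("no antibiotic-free healthy-control samples", call. = FALSE)
  age0 <- tapply(hc$age_months, hc$subject_id, min)
  grp <- tapply(hc$group, hc$subject_id, function(g) g[1])
  subjects <- names(age0)
  set.seed(derive_seed(seed, "hc_split"))
  # stratify within each control group by age tertile so both split sides
  # cover the young and the old end of the age range
  strata <- paste(grp, stats::ave(rank(age0, ties.method = "first"), grp,
                                  FUN = function(r) {
                                    if (length(r) < 6) return(rep(1, length(r)))
                                    cut(rank(r, ties.method = "first"), 3,
                                        labels = FALSE)
                                  }))
  if (length(subjects) < 6) {
    warning("too few subjects to stratify by age; unstratified split")
    strata <- rep(1L, length(subjects))
  }
  train <- unlist(lapply(split(subjects, strata), function(s) {
    sample(s, round(train_fraction * length(s)))
  }), use.names = FALSE)
  test <- setdiff(subjects, train)
  if (length(intersect(train, test)) > 0) {
    stop("internal error: subject appears in both split sides", call. = FALSE)
  }
  list(train_subjects = sort(train), test_subjects = sort(test),
       train_ids = hc$sample_id[hc$subject_id %in% train],
       test_ids = hc$sample_id[hc$subject_id %in% test])
}

#' Repeated Random-Forest importance ranking of species
#'
#' Regresses chronological age (months) on species relative abundances with
#' a regression forest, repeated `n_repetitions` times under distinct
#' derived seeds to average out forest randomness. Species are ranked by
#' mean permutation (out-of-bag) importance, ties broken lexicographically
#' by species id. By default only baseline-visit samples enter the ranking.
#'
#' @param taxa A [taxa_profile()] (already max-abundance filtered).
#' @param samples Sample metadata for the training subjects.
#' @param subjects Subject ids to use (training side of the split).
#' @param n_repetitions Number of forests averaged (default 1000).
#' @param n_trees Trees per forest.
#' @param baseline_only Rank on baseline-visit (week 0) samples only.
#' @param seed Integer master seed.
#' @return Data frame `species_id`, `importance`, `rank` (descending).
#' @export
rank_species_importance <- function(taxa, samples, subjects,
                                    n_repetitions = 1000, n_trees = 500,
                                    baseline_only = TRUE, seed = 1) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  use <- samples$subject_id %in% subjects
  if (baseline_only) use <- use & samples$visit_week == 0
  meta <- samples[use, , drop = FALSE]
  m <- as.matrix(taxa)[meta$sample_id, , drop = FALSE]
  total <- numeric(ncol(m))
  for (r in seq_len(n_repetitions)) {
    set.seed(derive_seed(seed, paste0("importance_rep_", r)))
    rf <- randomForest::randomForest(x = m, y = meta$age_months,
                                     ntree = n_trees, importance = TRUE)
    total <- total + randomForest::importance(rf, type = 1)[, 1]
  }
  imp <- total / n_repetitions
  ord <- order(-imp, colnames(m))
  data.frame(species_id = colnames(m)[ord], importance = unname(imp[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Nested cross-validated selection of the species panel size
#'
#' Outer K-fold cross-validation at subject level; within each fold the
#' importance ranking is recomputed on the fold's training subjects only
#' (nested, avoiding selection bias), and forests restricted to the top-k
#' species are scored on the held-out subjects by squared error of predicted
#' versus chronological age. Candidate sizes default to successive halvings
#' of the species count; a fine integer grid around the coarse minimum is
#' then evaluated with the same folds and rankings. Ties go to the smaller
#' panel.
#'
#' @param taxa A [taxa_profile()] (max-abundance filtered).
#' @param samples Sample metadata.
#' @param subjects Training-side subject ids.
#' @param candidate_sizes Optional decreasing integer vector of panel sizes.
#' @param folds Number of outer folds (default 5).
#' @param n_repetitions_cv Importance repetitions inside each fold.
#' @param n_trees Trees per forest.
#' @param baseline_only Passed to [rank_species_importance()].
#' @param seed Integer master seed.
#' @return List with `panel_size` and `cv_error_curve` (data frame `size`,
#'   `cv_error`).
#' @export
select_panel_size_nested_cv <- function(taxa, samples, subjects,
                                        candidate_sizes = NULL, folds = 5,
                                        n_repetitions_cv = 25, n_trees = 500,
                                        baseline_only = TRUE, seed = 1) {
  subjects <- sort(unique(subjects))
  if (folds > length(subjects)) {
    stop("more folds than training subjects", call. = FALSE)
  }
  m <- as.matrix(taxa)
  p <- ncol(m)
  auto_grid <- is.null(candidate_sizes)
  if (auto_grid) {
    candidate_sizes <- p
    while (utils::tail(candidate_sizes, 1) > 2) {
      candidate_sizes <- c(candidate_sizes,
                           max(2, floor(utils::tail(candidate_sizes, 1) / 2)))
    }
  }
  candidate_sizes <- sort(unique(pmin(pmax(candidate_sizes, 1), p)),
                          decreasing = TRUE)
  set.seed(derive_seed(seed, "cv_folds"))
  fold_of <- stats::setNames(sample(rep(seq_len(folds),
                                        length.out = length(subjects))),
                             subjects)
  fold_data <- lapply(seq_len(folds), function(k) {
    tr_subj <- subjects[fold_of != k]
    te_subj <- subjects[fold_of == k]
    stopifnot(length(intersect(tr_subj, te_subj)) == 0)
    ranking <- rank_species_importance(
      taxa, samples, tr_subj, n_repetitions = n_repetitions_cv,
      n_trees = n_trees, baseline_only = baseline_only,
      seed = derive_seed(seed, paste0("cv_rank_fold_", k)))
    tr_ids <- samples$sample_id[samples$subject_id %in% tr_subj]
    te_ids <- samples$sample_id[samples$subject_id %in% te_subj]
    list(k = k, ranking = ranking$species_id, train_ids = tr_ids,
         test_ids = te_ids)
  })
  ages <- stats::setNames(samples$age_months, samples$sample_id)
  score_size <- function(size) {
    sq <- unlist(lapply(fold_data, function(fd) {
      panel <- fd$ranking[seq_len(size)]
      set.seed(derive_seed(seed, paste0("cv_fit_f", fd$k, "_s", size)))
      rf <- grow_age_forest(m[fd$train_ids, panel, drop = FALSE],
                            ages[fd$train_ids], n_trees)
      pred <- stats::predict(rf, m[fd$test_ids, panel, drop = FALSE])
      (pred - ages[fd$test_ids])^2
    }))
    mean(sq)
  }
  err <- vapply(candidate_sizes, score_size, numeric(1))
  curve <- data.frame(size = candidate_sizes, cv_error = err)
  if (auto_grid) {
    # refine with a fine grid between the coarse minimum's grid neighbours
    best <- coarse_min(curve)
    sizes_sorted <- sort(candidate_sizes)
    pos <- match(best, sizes_sorted)
    lo <- if (pos > 1) sizes_sorted[pos - 1] else max(2, floor(best / 2))
    hi <- if (pos < length(sizes_sorted)) {
      sizes_sorted[pos + 1]
    } else {
      min(p, best * 2)
    }
    fine <- setdiff(unique(round(seq(lo, hi, length.out = 9))), curve$size)
    fine <- fine[fine >= 1 & fine <= p]
    if (length(fine) > 0) {
      curve <- rbind(curve, data.frame(size = fine,
                                       cv_error = vapply(fine, score_size,
                                                         numeric(1))))
    }
  }
  curve <- curve[order(curve$size), ]
  rownames(curve) <- NULL
  list(panel_size = coarse_min(curve), cv_error_curve = curve)
}

# smallest size attaining the minimum CV error
coarse_min <- function(curve) {
  min(curve$size[curve$cv_error <= min(curve$cv_error) + 1e-12])
}

#' Fit the microbiota maturity index model
#'
#' End-to-end training of the maturity index: species with maximum abundance
#' at or below `max_abundance_threshold` are removed; 70% of antibiotic-free
#' healthy-control subjects are assigned to training; species are ranked by
#' repeated Random-Forest importance on baseline training samples; the panel
#' size is chosen by nested subject-level cross-validation (unless
#' `panel_size` is supplied); a final regression forest is trained on all
#' training samples restricted to the selected panel; and a smoothing spline
#' of MMI versus chronological age is fitted on the held-out healthy test
#' samples to define the healthy expectation used by the Relative MMI.
#'
#' @param taxa A [taxa_profile()] for the whole cohort.
#' @param samples Sample metadata.
#' @param train_fraction Fraction of healthy subjects used for training.
#' @param n_repetitions Importance-ranking repetitions (default 1000).
#' @param cv_folds Outer folds of the nested cross-validation.
#' @param n_repetitions_cv Importance repetitions inside each fold.
#' @param n_trees Trees per forest.
#' @param max_abundance_threshold Species max-abundance filter (fraction).
#' @param candidate_sizes Optional candidate panel sizes.
#' @param panel_size Optional fixed panel size (skips the nested CV).
#' @param baseline_only_ranking Rank species on baseline samples only.
#' @param seed Integer master seed.
#' @return An object of class `"maturity_model"`: `panel`, `panel_size`,
#'   `forest`, `healthy_spline`, `importance_table`, `cv_error_curve`,
#'   `split`, and the training parameters.
#' @export
fit_maturity_model <- function(taxa, samples, train_fraction = 0.70,
                               n_repetitions = 1000, cv_folds = 5,
                               n_repetitions_cv = 25, n_trees = 500,
                               max_abundance_threshold = 1e-4,
                               candidate_sizes = NULL, panel_size = NULL,
                               baseline_only_ranking = TRUE, seed = 1) {
  taxa_f <- filter_by_max_abundance(taxa, max_abundance_threshold)
  split <- split_healthy_training(samples, train_fraction, seed)
  importance_table <- rank_species_importance(
    taxa_f, samples, split$train_subjects, n_repetitions = n_repetitions,
    n_trees = n_trees, baseline_only = baseline_only_ranking, seed = seed)
  cv_error_curve <- NULL
  if (is.null(panel_size)) {
    sel <- select_panel_size_nested_cv(
      taxa_f, samples, split$train_subjects,
      candidate_sizes = candidate_sizes, folds = cv_folds,
      n_repetitions_cv = n_repetitions_cv, n_trees = n_trees,
      baseline_only = baseline_only_ranking, seed = seed)
    panel_size <- sel$panel_size
    cv_error_curve <- sel$cv_error_curve
  }
  panel <- importance_table$species_id[seq_len(panel_size)]
  m <- as.matrix(taxa_f)
  ages <- stats::setNames(samples$age_months, samples$sample_id)
  set.seed(derive_seed(seed, "final_forest"))
  forest <- grow_age_forest(m[split$train_ids, panel, drop = FALSE],
                            ages[split$train_ids], n_trees)
  test_mmi <- stats::predict(forest, m[split$test_ids, panel, drop = FALSE])
  test_subjects <- samples$subject_id[match(split$test_ids, samples$sample_id)]
  healthy_spline <- fit_healthy_spline(unname(test_mmi),
                                       unname(ages[split$test_ids]),
                                       subjects = test_subjects)
  structure(list(
    panel = panel, panel_size = panel_size, forest = forest,
    healthy_spline = healthy_spline, importance_table = importance_table,
    cv_error_curve = cv_error_curve, split = split,
    params = list(train_fraction = train_fraction,
                  n_repetitions = n_repetitions, cv_folds = cv_folds,
                  n_trees = n_trees,
                  max_abundance_threshold = max_abundance_threshold,
                  seed = seed)),
    class = "maturity_model")
}

#' @export
print.maturity_model <- function(x, ...) {
  cat(sprintf("maturity_model: panel of %d species, %d training samples\n",
              x$panel_size, length(x$split$train_ids)))
  cat("top species:", paste(utils::head(x$panel, 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Predict the microbiota maturity index
#'
#' Applies the fitted maturity forest to any samples. Panel species missing
#' from the table are treated as absent (zero) with a warning. Samples that
#' were part of the forest's training set receive their out-of-bag
#' prediction rather than an in-sample one, so training and non-training
#' MMI values are comparable against the held-out-calibrated healthy
#' spline. If `samples` with an `age_months` column is supplied, the
#' Relative MMI (MMI minus the healthy-spline expectation at the sample's
#' age) is added.
#'
#' @param model A [fit_maturity_model()] result.
#' @param taxa A [taxa_profile()] or abundance matrix.
#' @param samples Optional metadata supplying `age_months` per sample.
#' @return Data frame `sample_id`, `mmi_months` and, when ages are known,
#'   `rmmi_months`.
#' @export
predict_mmi <- function(model, taxa, samples = NULL) {
  m <- as.matrix(taxa)
  missing <- setdiff(model$panel, colnames(m))
  if (length(missing) > 0) {
    warning(sprintf("%d panel species missing from table; treated as absent",
                    length(missing)))
    m <- cbind(m, matrix(0, nrow(m), length(missing),
                         dimnames = list(NULL, missing)))
  }
  mmi <- stats::predict(model$forest, m[, model$panel, drop = FALSE])
  oob <- model$forest$predicted
  in_train <- intersect(rownames(m), names(oob))
  mmi[in_train] <- oob[in_train]
  out <- data.frame(sample_id = rownames(m), mmi_months = unname(mmi),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(samples)) {
    age <- samples$age_months[match(out$sample_id, samples$sample_id)]
    out$age_months <- age
    out$rmmi_months <- compute_rmmi(out$mmi_months, age, model$healthy_spline)
  }
  out
}

#' Smoothing spline of MMI versus chronological age in healthy controls
#'
#' Cross-validated smoothing spline giving the expected MMI of a healthy
#' child at each age; the reference curve the Relative MMI subtracts. When
#' subject identifiers are supplied the effective degrees of freedom are
#' chosen by leave-one-subject-out cross-validation (repeated visits of one
#' subject are correlated, which makes point-wise generalised
#' cross-validation overfit); otherwise GCV is used. Prediction beyond the
#' observed age range is the natural-spline linear continuation and
#' triggers a warning.
#'
#' @param mmi Predicted MMI values (months) of healthy test samples.
#' @param ages Chronological ages (months) of the same samples.
#' @param subjects Optional subject id per sample, enabling subject-level
#'   cross-validation of the smoothing parameter.
#' @param df_grid Candidate effective degrees of freedom searched when
#'   `subjects` is given.
#' @return Object of class `"healthy_spline"`.
#' @export
fit_healthy_spline <- function(mmi, ages, subjects = NULL, df_grid = 3:8) {
  if (length(mmi) != length(ages)) stop("mmi and ages differ in length", call. = FALSE)
  if (length(mmi) < 10) stop("need >= 10 samples to fit the healthy spline", call. = FALSE)
  if (stats::sd(ages) < 1e-8) stop("degenerate age spread", call. = FALSE)
  ord <- order(ages, mmi)
  mmi <- mmi[ord]
  ages <- ages[ord]
  if (is.null(subjects)) {
    fit <- stats::smooth.spline(ages, mmi)
  } else {
    subjects <- subjects[ord]
    df_grid <- df_grid[df_grid < length(unique(ages))]
    sse <- vapply(df_grid, function(df) {
      err <- 0
      for (s in unique(subjects)) {
        hold <- subjects == s
        if (length(unique(ages[!hold])) <= max(df, 4)) return(Inf)
        f <- stats::smooth.spline(ages[!hold], mmi[!hold], df = df)
        err <- err + sum((mmi[hold] - stats::predict(f, ages[hold])$y)^2)
      }
      err
    }, numeric(1))
    fit <- stats::smooth.spline(ages, mmi, df = df_grid[which.min(sse)])
  }
  structure(list(fit = fit, age_range = range(ages)),
            class = "healthy_spline")
}

#' Evaluate a healthy spline at given ages
#'
#' @param spline A [fit_healthy_spline()] object.
#' @param age Ages in months.
#' @return Expected MMI in months.
#' @export
spline_predict <- function(spline, age) {
  stopifnot(inherits(spline, "healthy_spline"))
  outside <- age < spline$age_range[1] | age > spline$age_range[2]
  if (any(outside)) {
    warning(sprintf("%d age(s) outside the fitted range [%.1f, %.1f]: linear extrapolation",
                    sum(outside), spline$age_range[1], spline$age_range[2]))
  }
  stats::predict(spline$fit, age)$y
}

#' Relative microbiota maturity index
#'
#' `RMMI = MMI - healthy_spline(age)`: the sample's microbial age minus the
#' expected microbial age of a healthy child of the same chronological age.
#' Negative values indicate reduced maturity.
#'
#' @param mmi MMI values in months.
#' @param age Chronological ages in months.
#' @param healthy_spline A [fit_healthy_spline()] object.
#' @return RMMI in months.
#' @export
compute_rmmi <- function(mmi, age, healthy_spline) {
  mmi - spline_predict(healthy_spline, age)
}
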
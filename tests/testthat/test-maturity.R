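# metadata for 10 healthy subjects x 3 visits
hc_meta <- function() {
  subj <- sprintf("h%02d", 1:10)
  do.call(rbind, lapply(seq_along(subj), function(i) {
    data.frame(sample_id = paste0(subj[i], ".", c(0, 4, 8)),
               subject_id = subj[i], visit_week = c(0, 4, 8),
               age_months = 10 + i * 20, group = "HC_lt7",
               antibiotics = FALSE, therapy = "none",
               stringsAsFactors = FALSE)
  }))
}

test_that("healthy split is subject-level, 70/30, leak-free and reproducible", {
  s <- hc_meta()
  sp <- split_healthy_training(s, seed = 3)
  expect_equal(length(sp$train_subjects), 7)
  expect_equal(length(sp$test_subjects), 3)
  expect_length(intersect(sp$train_subjects, sp$test_subjects), 0)
  # all visits of a subject on the same side
  side <- s$subject_id %in% sp$train_subjects
  expect_true(all(tapply(side, s$subject_id, function(z) length(unique(z))) == 1))
  expect_identical(split_healthy_training(s, seed = 3), sp)
  expect_false(identical(split_healthy_training(s, seed = 4)$train_subjects,
                         sp$train_subjects))
  # antibiotic-exposed controls are excluded entirely
  s2 <- s
  s2$antibiotics[s2$subject_id == "h01"] <- TRUE
  sp2 <- split_healthy_training(s2, seed = 3)
  expect_false("h01" %in% c(sp2$train_subjects, sp2$test_subjects))
})

test_that("importance ranking is deterministic and recovers informative taxa", {
  cfg <- cohort_config(
    n_subjects = c(HC_lt7 = 35, HC_ge7 = 12, VEO = 4, PIBD = 4),
    n_veo_late = 0, n_species = 100, n_maturation_species = 10,
    n_marker_species = 0, n_antibiotic_sensitive = 0, seed = 15)
  co <- generate_cohort(cfg)
  sp <- split_healthy_training(co$samples, seed = 5)
  r1 <- rank_species_importance(co$taxa, co$samples, sp$train_subjects,
                                n_repetitions = 2, seed = 9)
  r2 <- rank_species_importance(co$taxa, co$samples, sp$train_subjects,
                                n_repetitions = 2, seed = 9)
  expect_identical(r1, r2)
  expect_error(rank_species_importance(co$taxa, co$samples, sp$train_subjects,
                                       n_repetitions = 0), ">= 1")
  r <- rank_species_importance(co$taxa, co$samples, sp$train_subjects,
                               n_repetitions = 10, seed = 9)
  informative <- co$truth$species$species_id[grepl("maturation",
                                                   co$truth$species$role)]
  expect_gte(length(intersect(r$species_id[1:15], informative)), 8)
})

test_that("nested CV honours its contract on degenerate inputs", {
  co <- generate_cohort(test_cohort_config(seed = 27))
  sp <- split_healthy_training(co$samples, seed = 2)
  expect_error(select_panel_size_nested_cv(co$taxa, co$samples,
                                           sp$train_subjects, folds = 1000),
               "more folds")
  sel <- select_panel_size_nested_cv(
    co$taxa, co$samples, sp$train_subjects,
    candidate_sizes = ncol(co$taxa), folds = 3, n_repetitions_cv = 2,
    n_trees = 100, seed = 4)
  expect_equal(sel$panel_size, ncol(co$taxa))
  expect_equal(nrow(sel$cv_error_curve), 1)
  sel2 <- select_panel_size_nested_cv(
    co$taxa, co$samples, sp$train_subjects,
    candidate_sizes = ncol(co$taxa), folds = 3, n_repetitions_cv = 2,
    n_trees = 100, seed = 4)
  expect_identical(sel$cv_error_curve, sel2$cv_error_curve)
})

test_that("healthy spline interpolates a line and is order-invariant", {
  ages <- seq(5, 220, length.out = 40)
  mmi <- ages  # noiseless identity
  sp <- fit_healthy_spline(mmi, ages)
  expect_lt(max(abs(spline_predict(sp, ages) - ages)), 1)
  # permuted input gives identical function values
  o <- sample(seq_along(ages))
  sp2 <- fit_healthy_spline(mmi[o], ages[o])
  expect_equal(spline_predict(sp2, ages), spline_predict(sp, ages))
  # fitted values stay within the data envelope
  set.seed(6)
  noisy <- ages + rnorm(40, 0, 6)
  spn <- fit_healthy_spline(noisy, ages, subjects = rep(1:20, each = 2))
  expect_true(all(spline_predict(spn, ages) >= min(noisy) - 1 &
                    spline_predict(spn, ages) <= max(noisy) + 1))
  expect_warning(spline_predict(sp, 500), "outside the fitted range")
  expect_error(fit_healthy_spline(1:5, 1:5), ">= 10")
  expect_error(fit_healthy_spline(rep(1, 20), rep(7, 20)), "degenerate")
})

test_that("RMMI is the exact spline residual", {
  ages <- seq(10, 200, length.out = 30)
  sp <- fit_healthy_spline(ages * 0.9 + 4, ages)
  at <- c(20, 77.5, 150)
  on_curve <- spline_predict(sp, at)
  expect_equal(compute_rmmi(on_curve, at, sp), c(0, 0, 0))
  expect_equal(compute_rmmi(on_curve + 12, at, sp), rep(12, 3))
})

test_that("MMI prediction is reproducible, bounded and panel-robust", {
  co <- generate_cohort(test_cohort_config(seed = 29))
  mod <- suppressMessages(fit_maturity_model(
    co$taxa, co$samples, n_repetitions = 5, panel_size = 12, n_trees = 150,
    seed = 8))
  pred <- suppressWarnings(predict_mmi(mod, co$taxa, co$samples))
  # duplicate rows get identical MMI
  dup <- as.matrix(co$taxa)[c(1, 1, 2), ]
  rownames(dup) <- c("a", "b", "c")
  pd <- predict_mmi(mod, dup)
  expect_equal(pd$mmi_months[1], pd$mmi_months[2])
  # regression-forest predictions cannot leave the training age range
  ages <- co$samples$age_months
  expect_true(all(pred$mmi_months >= min(ages) - 1e-9 &
                    pred$mmi_months <= max(ages) + 1e-9))
  # missing panel species are treated as absent, with a warning
  drop1 <- as.matrix(co$taxa)[1:4, setdiff(colnames(co$taxa), mod$panel[1])]
  expect_warning(pm <- predict_mmi(mod, drop1), "panel species missing")
  expect_equal(nrow(pm), 4)
  # end-to-end determinism of the whole fit under one master seed
  mod2 <- suppressMessages(fit_maturity_model(
    co$taxa, co$samples, n_repetitions = 5, panel_size = 12, n_trees = 150,
    seed = 8))
  expect_identical(mod$panel, mod2$panel)
  expect_equal(suppressWarnings(predict_mmi(mod2, co$taxa, co$samples)), pred)
})

test_that("an uninformative panel yields no age signal", {
  co <- generate_cohort(test_cohort_config(seed = 35))
  inert <- co$truth$species$species_id[co$truth$species$role == "inert"][1]
  sp <- split_healthy_training(co$samples, seed = 2)
  m <- as.matrix(co$taxa)
  ages <- setNames(co$samples$age_months, co$samples$sample_id)
  set.seed(1)
  rf <- randomForest::randomForest(m[sp$train_ids, inert, drop = FALSE],
                                   ages[sp$train_ids], ntree = 200)
  held <- predict(rf, m[sp$test_ids, inert, drop = FALSE])
  expect_lt(abs(cor(held, ages[sp$test_ids], method = "spearman")), 0.45)
})
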
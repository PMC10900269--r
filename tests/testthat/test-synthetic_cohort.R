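test_that("configuration is validated", {
  expect_error(cohort_config(n_species = 0), "n_species")
  expect_error(cohort_config(n_subjects = c(HC_lt7 = -1, HC_ge7 = 1,
                                            VEO = 1, PIBD = 1)),
               "non-negative")
  expect_error(cohort_config(maturity_delay_months = c(HC_lt7 = 0, HC_ge7 = 0,
                                                       VEO = -5, PIBD = 0)),
               "delays")
  expect_error(cohort_config(maturity_delay_months = c(HC_lt7 = 0, HC_ge7 = 0,
                                                       VEO = 300, PIBD = 0)),
               "exceeds")
  expect_error(cohort_config(antibiotic_fraction = c(HC_lt7 = 1.4, HC_ge7 = 0,
                                                     VEO = 0, PIBD = 0)),
               "\\[0, 1\\]")
  expect_error(cohort_config(n_maturation_species = 200), "exceed")
})

test_that("identical config and seed give identical cohorts", {
  a <- generate_cohort(test_cohort_config(seed = 7))
  b <- generate_cohort(test_cohort_config(seed = 7))
  expect_identical(unclass(a$taxa), unclass(b$taxa))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$samples, b$truth$samples)
  c <- generate_cohort(test_cohort_config(seed = 8))
  expect_false(identical(unclass(a$taxa), unclass(c$taxa)))
})

test_that("abundances are a closed composition with structural zeros", {
  co <- generate_cohort(test_cohort_config(seed = 3))
  m <- as.matrix(co$taxa)
  expect_true(all(m >= 0))
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  expect_gt(mean(m == 0), 0.05) # zero inflation present
})

test_that("trajectory follows role semantics and is monotone", {
  expect_equal(trajectory("inert", c(0, 10, 200)), c(0, 0, 0))
  expect_equal(trajectory("disease_marker", 50), 0)
  up <- trajectory("maturation_up", c(12, 120))
  expect_gte(up[2], up[1])
  down <- trajectory("maturation_down", c(12, 120))
  expect_equal(down, -up)
  expect_error(trajectory("weird_role", 10), "unknown species role")
  expect_error(trajectory("maturation_up", -1), ">= 0")

  # property: monotone over random parameter draws
  set.seed(41)
  for (i in seq_len(1000)) {
    a <- runif(1, 0, 200)
    b <- a + runif(1, 0, 50)
    A <- runif(1, 0.5, 8)
    tau <- exp(runif(1, log(3), log(1200)))
    expect_lte(trajectory("maturation_up", a, A, tau),
               trajectory("maturation_up", b, A, tau))
    expect_gte(trajectory("maturation_down", a, A, tau),
               trajectory("maturation_down", b, A, tau))
  }
})

test_that("ground truth carries the configured delays and disjoint roles", {
  co <- generate_cohort(test_cohort_config(seed = 5))
  tr <- merge(co$truth$samples, co$samples[, c("sample_id", "therapy")],
              by = "sample_id")
  # maintenance-therapy disease samples older than the delay lag exactly
  for (g in c("VEO", "PIBD")) {
    d <- cohort_config()$maturity_delay_months[[g]]
    rows <- tr[tr$group == g & tr$therapy == "maintenance" &
                 tr$age_months > d, ]
    expect_true(nrow(rows) > 0)
    expect_equal(rows$age_months - rows$effective_age_months,
                 rep(d, nrow(rows)))
  }
  # healthy controls have no delay
  hc <- tr[tr$group %in% c("HC_lt7", "HC_ge7"), ]
  expect_equal(hc$age_months, hc$effective_age_months)
  # one role per species, one component label per sample
  expect_false(anyDuplicated(co$truth$species$species_id) > 0)
  expect_true(all(co$truth$samples$component %in% c("healthy", "reduced")))
  expect_true(all(tr$component[tr$group %in% c("VEO", "PIBD")] == "reduced"))
})

test_that("calprotectin and human DNA have the configured rank correlation", {
  co <- generate_cohort(cohort_config(seed = 19))
  s <- co$samples
  expect_gte(nrow(s), 400)
  rho <- spearman_brute(s$calprotectin_ug_g, s$human_dna_pct)
  expect_lt(abs(rho - 0.46), 0.1)
  # disease groups exceed the 250 ug/g activity threshold much more often
  dis <- s$group %in% c("VEO", "PIBD")
  base <- s$visit_week == 0
  expect_gt(mean(s$calprotectin_ug_g[dis & base] > 250), 0.3)
  expect_lt(mean(s$calprotectin_ug_g[!dis] > 250), 0.1)
  expect_true(all(s$human_dna_pct >= 0 & s$human_dna_pct <= 100))
})

test_that("antibiotic exposure lowers richness among VEO samples", {
  co <- generate_cohort(cohort_config(seed = 23))
  r <- rowSums(as.matrix(co$taxa) > 0)
  veo <- co$samples$group == "VEO"
  w <- wilcox.test(r[veo & co$samples$antibiotics],
                   r[veo & !co$samples$antibiotics],
                   alternative = "less")
  expect_lt(w$p.value, 0.05)
})

test_that("null configuration removes group-label signal", {
  cfg <- null_cohort_config(n_subjects = c(HC_lt7 = 25, HC_ge7 = 0, VEO = 25,
                                           PIBD = 0),
                            n_species = 40, n_maturation_species = 12,
                            n_marker_species = 4, n_antibiotic_sensitive = 12,
                            seed = 31)
  expect_true(all(cfg$maturity_delay_months == 0))
  co <- generate_cohort(cfg)
  # per-species group differences at subject level, adjusted for age (visits
  # within a subject are correlated, and a chance age imbalance between the
  # small groups shifts all maturation species jointly): rejections should
  # look like chance
  m <- as.matrix(co$taxa)
  subj_mean <- rowsum(m, co$samples$subject_id) /
    as.vector(table(co$samples$subject_id)[sort(unique(co$samples$subject_id))])
  idx <- match(rownames(subj_mean), co$samples$subject_id)
  grp <- co$samples$group[idx]
  age <- co$samples$age_months[idx]
  p <- apply(subj_mean, 2, function(y) {
    fit <- summary(lm(rank(y) ~ age + grp))
    fit$coefficients["grpVEO", "Pr(>|t|)"]
  })
  expect_gte(sum(!is.na(p)), 30)
  expect_lt(mean(p < 0.05, na.rm = TRUE), 0.15)
})

test_that("per-group noise is honoured and raises instability", {
  cfg <- test_cohort_config(
    seed = 9, noise_sd = c(HC_lt7 = 0.1, HC_ge7 = 0.1, VEO = 1.2, PIBD = 0.1))
  co <- generate_cohort(cfg)
  inst <- suppressWarnings(subject_instability(co$taxa, co$samples))
  inst$group <- co$samples$group[match(inst$subject_id,
                                       co$samples$subject_id)]
  expect_gt(mean(inst$mean_distance[inst$group == "VEO"]),
            mean(inst$mean_distance[inst$group == "HC_lt7"]))
})

test_that("cohort round-trips to a directory of plain-text tables", {
  co <- generate_cohort(test_cohort_config(seed = 2))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(
    d, c("taxa.tsv", "samples.tsv", "truth_samples.tsv",
         "truth_species.tsv", "config.yaml")))))
  back <- read_taxa_table(file.path(d, "taxa.tsv"))
  expect_equal(unclass(back), unclass(co$taxa), tolerance = 1e-12)
  cfg <- read_cohort_config(file.path(d, "config.yaml"))
  expect_equal(cfg$n_subjects, co$truth$config$n_subjects)
  expect_equal(cfg$seed, co$truth$config$seed)
})
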
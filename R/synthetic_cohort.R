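#' Configuration for the synthetic cohort generator
#'
#' Describes a four-group longitudinal pediatric study: healthy controls
#' under and over 7 years (`HC_lt7`, `HC_ge7`), very early onset IBD (`VEO`)
#' and pediatric-onset IBD (`PIBD`), each sampled at weeks 0, 4 and 8.
#' Disease groups mature on a delayed age axis (`maturity_delay_months`),
#' carry enriched dysbiosis-marker species, and lose a fraction of species
#' per sample (`richness_reduction`). Antibiotic-exposed samples additionally
#' zero antibiotic-sensitive species. Fecal calprotectin and stool human-DNA
#' percentage are generated from a shared latent inflammation scale with a
#' configurable rank correlation.
#'
#' All ages are in months. Identical `config` (including `seed`) gives
#' byte-identical output.
#'
#' @param n_subjects Named counts of longitudinal subjects per group.
#' @param n_veo_late Number of extra VEO subjects sampled once at an older
#'   age (single cross-sectional visit), giving the cohort some subjects
#'   with incomplete visit sets.
#' @param visits Week offsets of the study visits.
#' @param age_range_months Overall age span; groups `HC_lt7`/`VEO` enrol
#'   below 84 months, `HC_ge7`/`PIBD` at or above 84 months.
#' @param age_mean_sd Per-group mean and SD (months) of the truncated-normal
#'   enrolment-age distributions, defaulting to the demographic profile of a
#'   pediatric IBD cohort: young groups centred near 4 years, older groups
#'   in adolescence. `VEO_late` applies to the cross-sectional older VEO
#'   subjects.
#' @param n_species Total species count.
#' @param n_maturation_species Species whose abundance follows a saturating
#'   age trajectory (half increasing, half decreasing).
#' @param n_marker_species Disease-marker species enriched in IBD groups.
#' @param n_antibiotic_sensitive Species zeroed (with probability
#'   `abx_zero_prob`) in antibiotic-exposed samples.
#' @param maturity_delay_months Named non-negative delay of the effective
#'   (microbial) age per group; the true disease effect.
#' @param dysbiosis_effect Log-fold enrichment of marker species in disease.
#' @param antibiotic_fraction Named probability of antibiotic exposure per
#'   group (subject level).
#' @param richness_reduction Named expected fraction of all species
#'   structurally zeroed per sample in that group. The loss is concentrated
#'   on the fragile (antibiotic-sensitive) taxa pool, mirroring the
#'   preferential depletion of oxygen-sensitive commensals in IBD; when no
#'   fragile pool exists the loss is spread over all species.
#' @param noise_sd Within-subject visit-to-visit log-abundance noise; a
#'   scalar or a named per-group vector.
#' @param subject_sd SD of subject-level log-abundance random intercepts.
#' @param baseline_sd SD of species baseline log abundances.
#' @param trajectory_amplitude Range (log units) of maturation amplitudes.
#' @param trajectory_timescale Range (months) of saturation timescales.
#'   Decreasing (infancy-associated) species draw timescales log-uniformly
#'   from the lower half of the range, increasing (adult-associated) species
#'   from the upper half, so the community carries age information in
#'   infancy and throughout childhood and adolescence.
#' @param presence_logit_mean,presence_logit_sd Species-level baseline
#'   presence log-odds distribution (controls zero inflation and gives a
#'   tail of low-prevalence species).
#' @param presence_subject_sd SD of subject-level presence random intercepts.
#' @param presence_trajectory_coupling Log-odds swing of a maturation
#'   species' presence over its full trajectory (applied to the normalised
#'   trajectory shape), so maturation also shows in prevalence without
#'   driving species extinct.
#' @param abx_zero_prob Probability an antibiotic-sensitive species is zeroed
#'   in an exposed sample.
#' @param abx_suppression Log-unit abundance suppression of surviving
#'   antibiotic-sensitive species in exposed samples.
#' @param new_therapy_fraction Probability a disease subject starts new
#'   therapy (vs stable maintenance) during the study.
#' @param new_therapy_delay_sd SD (months) of per-visit jitter added to the
#'   maturity delay of new-therapy subjects, making their trajectories less
#'   stable across visits.
#' @param calprotectin_model List with `healthy_median`, `disease_median`
#'   (ug/g), `sdlog`, and `new_therapy_decline` (latent SD units per week of
#'   calprotectin decline on new therapy).
#' @param human_dna_rho Target Spearman correlation between calprotectin and
#'   human-DNA percentage.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(
    n_subjects = c(HC_lt7 = 63, HC_ge7 = 20, VEO = 58, PIBD = 46),
    n_veo_late = 8,
    visits = c(0, 4, 8),
    age_range_months = c(3, 228),
    age_mean_sd = list(HC_lt7 = c(43, 20), HC_ge7 = c(149, 43),
                       VEO = c(52, 21), PIBD = c(171, 35),
                       VEO_late = c(126, 32)),
    n_species = 120,
    n_maturation_species = 30,
    n_marker_species = 10,
    n_antibiotic_sensitive = 40,
    maturity_delay_months = c(HC_lt7 = 0, HC_ge7 = 0, VEO = 25, PIBD = 55),
    dysbiosis_effect = 1.5,
    antibiotic_fraction = c(HC_lt7 = 0.15, HC_ge7 = 0, VEO = 0.4, PIBD = 0),
    richness_reduction = c(HC_lt7 = 0, HC_ge7 = 0, VEO = 0.05, PIBD = 0.05),
    noise_sd = 0.2,
    subject_sd = 0.2,
    baseline_sd = 1.0,
    trajectory_amplitude = c(5, 8),
    trajectory_timescale = c(6, 1200),
    presence_logit_mean = 1.2,
    presence_logit_sd = 1.2,
    presence_subject_sd = 0.2,
    presence_trajectory_coupling = 3,
    abx_zero_prob = 0.2,
    abx_suppression = 2,
    new_therapy_fraction = 0.45,
    new_therapy_delay_sd = 15,
    calprotectin_model = list(healthy_median = 25, disease_median = 220,
                              sdlog = 1.1, new_therapy_decline = 0.08),
    human_dna_rho = 0.46,
    seed = 1) {
  config <- list(
    n_subjects = n_subjects, n_veo_late = n_veo_late, visits = visits,
    age_range_months = age_range_months, age_mean_sd = age_mean_sd,
    n_species = n_species,
    n_maturation_species = n_maturation_species,
    n_marker_species = n_marker_species,
    n_antibiotic_sensitive = n_antibiotic_sensitive,
    maturity_delay_months = maturity_delay_months,
    dysbiosis_effect = dysbiosis_effect,
    antibiotic_fraction = antibiotic_fraction,
    richness_reduction = richness_reduction,
    noise_sd = noise_sd, subject_sd = subject_sd, baseline_sd = baseline_sd,
    trajectory_amplitude = trajectory_amplitude,
    trajectory_timescale = trajectory_timescale,
    presence_logit_mean = presence_logit_mean,
    presence_logit_sd = presence_logit_sd,
    presence_subject_sd = presence_subject_sd,
    presence_trajectory_coupling = presence_trajectory_coupling,
    abx_zero_prob = abx_zero_prob, abx_suppression = abx_suppression,
    new_therapy_fraction = new_therapy_fraction,
    new_therapy_delay_sd = new_therapy_delay_sd,
    calprotectin_model = calprotectin_model,
    human_dna_rho = human_dna_rho, seed = seed)
  validate_cohort_config(config)
  class(config) <- "cohort_config"
  config
}

validate_cohort_config <- function(c) {
  groups <- c("HC_lt7", "HC_ge7", "VEO", "PIBD")
  if (!all(groups %in% names(c$n_subjects))) {
    stop("n_subjects must name all four groups", call. = FALSE)
  }
  if (any(c$n_subjects < 0) || sum(c$n_subjects) + c$n_veo_late <= 0) {
    stop("subject counts must be non-negative with at least one subject",
         call. = FALSE)
  }
  if (c$n_species < 1) stop("n_species must be positive", call. = FALSE)
  n_roles <- c$n_maturation_species + c$n_marker_species +
    c$n_antibiotic_sensitive
  if (n_roles > c$n_species) {
    stop("role species counts exceed n_species", call. = FALSE)
  }
  probs <- c(c$antibiotic_fraction, c$richness_reduction, c$abx_zero_prob,
             c$new_therapy_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(c$maturity_delay_months < 0)) stop("delays must be >= 0", call. = FALSE)
  if (any(c$maturity_delay_months >= c$age_range_months[2])) {
    stop("maturity delay exceeds the maximum age", call. = FALSE)
  }
  if (c$age_range_months[1] <= 0 ||
      c$age_range_months[2] <= c$age_range_months[1]) {
    stop("age_range_months must be an increasing positive pair", call. = FALSE)
  }
  invisible(c)
}

#' Null (no disease effect) cohort configuration
#'
#' All maturity delays, the dysbiosis marker effect, richness reduction and
#' therapy-related instability are set to zero; antibiotic exposure is
#' equalised across groups; and the enrolment-age distributions are matched
#' between each disease group and its healthy comparator (the age-matched
#' design of such studies), so group labels carry no signal at all. Used
#' for type-I-error calibration of downstream tests.
#'
#' @param ... Further overrides passed to [cohort_config()].
#' @return A `"cohort_config"`.
#' @export
null_cohort_config <- function(...) {
  defaults <- list(
    maturity_delay_months = c(HC_lt7 = 0, HC_ge7 = 0, VEO = 0, PIBD = 0),
    dysbiosis_effect = 0,
    richness_reduction = c(HC_lt7 = 0, HC_ge7 = 0, VEO = 0, PIBD = 0),
    antibiotic_fraction = c(HC_lt7 = 0.15, HC_ge7 = 0.15, VEO = 0.15,
                            PIBD = 0.15),
    age_mean_sd = list(HC_lt7 = c(48, 20), HC_ge7 = c(160, 40),
                       VEO = c(48, 20), PIBD = c(160, 40),
                       VEO_late = c(126, 32)),
    new_therapy_delay_sd = 0,
    n_veo_late = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

#' Maturation trajectory of a species
#'
#' Log-abundance offset of a species at a given effective age. Maturation
#' species follow a saturating curve `A * s(a)` with
#' `s(a) = (a / (a + tau)) / (ref_age / (ref_age + tau))`: increasing
#' species rise towards their adult level with timescale `tau`, decreasing
#' species are the mirror image (taxa abundant in infancy that decline with
#' age). The curve is normalised so the full amplitude `A` is realised at
#' `ref_age` whatever the timescale: small `tau` concentrates the change in
#' infancy, large `tau` spreads it across childhood and adolescence. All
#' other roles return zero offset.
#'
#' @param role One of `maturation_up`, `maturation_down`, `disease_marker`,
#'   `antibiotic_sensitive`, `inert`.
#' @param effective_age_months Non-negative effective age(s).
#' @param amplitude Log-unit amplitude `A` realised at `ref_age`.
#' @param timescale Saturation timescale `tau` in months.
#' @param ref_age Age (months) at which the full amplitude is reached;
#'   defaults to the upper end of the study's age range.
#' @return Numeric vector of log-abundance offsets.
#' @export
trajectory <- function(role, effective_age_months, amplitude = 4,
                       timescale = 36, ref_age = 228) {
  roles <- c("maturation_up", "maturation_down", "disease_marker",
             "antibiotic_sensitive", "inert")
  if (length(role) != 1L || !role %in% roles) {
    stop("unknown species role: ", paste(role, collapse = ", "), call. = FALSE)
  }
  if (any(effective_age_months < 0)) {
    stop("effective age must be >= 0", call. = FALSE)
  }
  sat <- (effective_age_months / (effective_age_months + timescale)) /
    (ref_age / (ref_age + timescale))
  base <- amplitude * sat
  switch(role,
         maturation_up = base,
         maturation_down = -base,
         rep(0, length(effective_age_months)))
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates the post-classification data of a longitudinal four-group
#' pediatric microbiome study: a species relative-abundance table, a sample
#' metadata table and a ground-truth record. Per-species log abundance is
#' baseline + maturation trajectory (evaluated at the group's delayed
#' effective age) + disease-marker enrichment + subject random intercept +
#' visit noise; structural zeros are then applied with species-, age- and
#' group-dependent probability (plus antibiotic and richness-reduction
#' zeroing), and finally each sample is closed to sum one, so zeros are
#' structural in the compositional output.
#'
#' @param config A [cohort_config()].
#' @return A list of class `"synthetic_cohort"` with elements `taxa`
#'   ([taxa_profile()]), `samples` (metadata data frame) and `truth` (list
#'   with `samples`, `species` and the generating `config`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be created by cohort_config()", call. = FALSE)
  }
  set.seed(config$seed)
  ns <- config$n_species

  # species roles and parameters
  n_up <- ceiling(config$n_maturation_species / 2)
  n_down <- config$n_maturation_species - n_up
  role <- c(rep("maturation_up", n_up), rep("maturation_down", n_down),
            rep("disease_marker", config$n_marker_species),
            rep("antibiotic_sensitive", config$n_antibiotic_sensitive),
            rep("inert", ns - n_up - n_down - config$n_marker_species -
                  config$n_antibiotic_sensitive))
  species_id <- sprintf("sp%03d", seq_len(ns))
  amplitude <- stats::runif(ns, config$trajectory_amplitude[1],
                            config$trajectory_amplitude[2])
  # infancy-associated (decreasing) species saturate early, adult-associated
  # (increasing) species keep changing into adolescence
  lt <- log(config$trajectory_timescale)
  mid <- mean(lt)
  early <- role != "maturation_up"
  timescale <- exp(ifelse(early, stats::runif(ns, lt[1], mid),
                          stats::runif(ns, mid, lt[2])))
  baseline <- stats::rnorm(ns, 0, config$baseline_sd)
  pres_logit <- stats::rnorm(ns, config$presence_logit_mean,
                             config$presence_logit_sd)
  traj_sign <- ifelse(role == "maturation_up", 1,
                      ifelse(role == "maturation_down", -1, 0))

  # subjects; enrolment ages from truncated normals within group age windows
  rtnorm <- function(n, mean_sd, lo, hi) {
    p <- stats::runif(n, stats::pnorm(lo, mean_sd[1], mean_sd[2]),
                      stats::pnorm(hi, mean_sd[1], mean_sd[2]))
    stats::qnorm(p, mean_sd[1], mean_sd[2])
  }
  groups <- c("HC_lt7", "HC_ge7", "VEO", "PIBD")
  young_max <- min(83.9, config$age_range_months[2])
  subj <- do.call(rbind, lapply(groups, function(g) {
    n <- config$n_subjects[[g]]
    if (n == 0) return(NULL)
    young <- g %in% c("HC_lt7", "VEO")
    age0 <- if (young) {
      rtnorm(n, config$age_mean_sd[[g]], config$age_range_months[1],
             young_max)
    } else {
      rtnorm(n, config$age_mean_sd[[g]],
             max(84, config$age_range_months[1]), config$age_range_months[2])
    }
    data.frame(group = g, age0 = age0, late = FALSE,
               stringsAsFactors = FALSE)
  }))
  if (config$n_veo_late > 0) {
    subj <- rbind(subj, data.frame(
      group = "VEO",
      age0 = rtnorm(config$n_veo_late, config$age_mean_sd[["VEO_late"]],
                    max(96, config$age_range_months[1]),
                    config$age_range_months[2]),
      late = TRUE, stringsAsFactors = FALSE))
  }
  nsub <- nrow(subj)
  subj$subject_id <- sprintf("S%03d", seq_len(nsub))
  subj$antibiotics <- stats::runif(nsub) <
    per_group(config$antibiotic_fraction, subj$group, "antibiotic_fraction")
  disease <- subj$group %in% c("VEO", "PIBD")
  subj$therapy <- ifelse(!disease, "none",
                         ifelse(stats::runif(nsub) < config$new_therapy_fraction,
                                "new", "maintenance"))
  subj$delay <- per_group(config$maturity_delay_months, subj$group,
                          "maturity_delay_months")

  # samples: one row per subject x visit (late subjects: baseline only)
  samples <- do.call(rbind, lapply(seq_len(nsub), function(i) {
    wk <- if (subj$late[i]) 0 else config$visits
    data.frame(subject_id = subj$subject_id[i], visit_week = wk,
               stringsAsFactors = FALSE)
  }))
  samples <- merge(samples, subj, by = "subject_id", sort = FALSE)
  samples <- samples[order(samples$subject_id, samples$visit_week), ]
  samples$sample_id <- sprintf("%s.wk%d", samples$subject_id,
                               samples$visit_week)
  samples$age_months <- samples$age0 + samples$visit_week / 4.345
  nsamp <- nrow(samples)

  # per-visit maturity delay (new-therapy subjects jitter between visits)
  jitter_sd <- ifelse(samples$therapy == "new", config$new_therapy_delay_sd, 0)
  delay_visit <- pmax(0, samples$delay + stats::rnorm(nsamp, 0, jitter_sd))
  eff_age <- pmax(0, samples$age_months - delay_visit)

  # log-abundance kernel (amplitude normalised at the age-range maximum);
  # each maturation species' peak abundance is anchored at its baseline, so
  # increasing species rise towards (and decreasing species fall from) an
  # ordinary abundance level and community mass stays age-stable
  ref_age <- config$age_range_months[2]
  sat <- outer(eff_age, timescale, function(a, t) a / (a + t))
  sat <- sweep(sat, 2, ref_age / (ref_age + timescale), `/`)
  traj <- sweep(sat, 2, amplitude * traj_sign, `*`)
  # disease markers are likewise anchored: rare pathobionts in health that
  # bloom to ordinary abundance in disease
  peak_anchor <- ifelse(role == "maturation_up", amplitude,
                        ifelse(role == "disease_marker",
                               config$dysbiosis_effect, 0))
  is_disease <- samples$group %in% c("VEO", "PIBD")
  marker <- outer(is_disease, role == "disease_marker") * config$dysbiosis_effect
  u_subject <- matrix(stats::rnorm(nsub * ns, 0, config$subject_sd),
                      nrow = nsub,
                      dimnames = list(subj$subject_id, species_id))
  noise_sd <- per_group(config$noise_sd, samples$group, "noise_sd")
  fragile <- role == "antibiotic_sensitive"
  abx_sup <- outer(samples$antibiotics, fragile) * config$abx_suppression
  logab <- sweep(traj + marker - abx_sup, 2, baseline - peak_anchor, `+`) +
    u_subject[samples$subject_id, , drop = FALSE] +
    matrix(stats::rnorm(nsamp * ns), nsamp, ns) * noise_sd
  abund <- exp(logab)

  # structural zeros: presence model, richness reduction, antibiotics
  w_subject <- matrix(stats::rnorm(nsub * ns, 0, config$presence_subject_sd),
                      nrow = nsub, dimnames = list(subj$subject_id, NULL))
  pres_shift <- sweep(sat, 2, traj_sign * config$presence_trajectory_coupling,
                      `*`)
  pres_eta <- sweep(pres_shift, 2, pres_logit, `+`) +
    w_subject[samples$subject_id, , drop = FALSE]
  present <- matrix(stats::runif(nsamp * ns), nsamp, ns) < stats::plogis(pres_eta)
  rr <- per_group(config$richness_reduction, samples$group,
                  "richness_reduction")
  # disease richness loss concentrated on the fragile taxa pool
  if (any(fragile)) {
    rr_prob <- outer(pmin(rr * ns / sum(fragile), 1), as.numeric(fragile))
  } else {
    rr_prob <- matrix(rr, nsamp, ns)
  }
  kill_rich <- matrix(stats::runif(nsamp * ns), nsamp, ns) < rr_prob
  kill_abx <- outer(samples$antibiotics, fragile) &
    matrix(stats::runif(nsamp * ns), nsamp, ns) < config$abx_zero_prob
  abund[!present | kill_rich | kill_abx] <- 0
  # guard: never emit an empty sample
  empty <- rowSums(abund) == 0
  if (any(empty)) {
    top <- max.col(exp(logab)[empty, , drop = FALSE])
    abund[cbind(which(empty), top)] <- exp(logab)[cbind(which(empty), top)]
  }
  abund <- abund / rowSums(abund)
  dimnames(abund) <- list(samples$sample_id, species_id)

  # calprotectin and human-DNA from a shared latent inflammation scale
  cm <- config$calprotectin_model
  d_shift <- log(cm$disease_median / cm$healthy_median) / cm$sdlog
  z_cal <- ifelse(is_disease, d_shift, 0) -
    ifelse(samples$therapy == "new", cm$new_therapy_decline *
             samples$visit_week, 0) + stats::rnorm(nsamp)
  calprotectin <- exp(log(cm$healthy_median) + cm$sdlog * z_cal)
  r <- 2 * sin(pi * config$human_dna_rho / 6)
  z_h <- r * as.vector(scale(z_cal)) + sqrt(1 - r^2) * stats::rnorm(nsamp)
  human_dna <- 100 * stats::plogis(-2.5 + z_h)

  meta <- data.frame(
    sample_id = samples$sample_id, subject_id = samples$subject_id,
    visit_week = samples$visit_week, age_months = samples$age_months,
    group = samples$group, antibiotics = samples$antibiotics,
    therapy = samples$therapy,
    calprotectin_ug_g = round(calprotectin, 2),
    human_dna_pct = round(human_dna, 4),
    stringsAsFactors = FALSE, row.names = NULL)
  validate_sample_table(meta)

  truth_samples <- data.frame(
    sample_id = samples$sample_id, subject_id = samples$subject_id,
    group = samples$group, age_months = samples$age_months,
    delay_months = delay_visit, effective_age_months = eff_age,
    component = ifelse(samples$delay > 0, "reduced", "healthy"),
    stringsAsFactors = FALSE, row.names = NULL)
  truth_species <- data.frame(
    species_id = species_id, role = role, amplitude = amplitude,
    timescale = timescale, baseline = baseline,
    presence_logit = pres_logit, stringsAsFactors = FALSE)

  structure(list(taxa = taxa_profile(abund), samples = meta,
                 truth = list(samples = truth_samples,
                              species = truth_species, config = config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d subjects, %d species\n",
              nrow(x$taxa), length(unique(x$samples$subject_id)),
              ncol(x$taxa)))
  print(table(x$samples$group))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `taxa.tsv` (samples x species fractions), `samples.tsv`,
#' `truth_samples.tsv`, `truth_species.tsv` and `config.yaml`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxa_table(cohort$taxa, file.path(dir, "taxa.tsv"))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$samples,
                     file.path(dir, "truth_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$species,
                     file.path(dir, "truth_species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_cohort_config(cohort$truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
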
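#' Construct a validated taxa profile matrix
#'
#' A taxa profile is a numeric matrix of relative-abundance fractions with
#' samples in rows and species in columns, the shape produced by shotgun
#' taxonomic profilers. Row sums must lie in `(0, 1 + 1e-9]`; sample and
#' species identifiers must be unique.
#'
#' @param abundance Numeric matrix, samples x species.
#' @param sample_ids,species_ids Row/column identifiers; default to dimnames.
#' @return The matrix with class `"taxa_profile"`.
#' @export
taxa_profile <- function(abundance, sample_ids = rownames(abundance),
                         species_ids = colnames(abundance)) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop("abundance must be a numeric matrix (samples x species)", call. = FALSE)
  }
  if (is.null(sample_ids) || is.null(species_ids)) {
    stop("sample and species identifiers are required", call. = FALSE)
  }
  rownames(abundance) <- as.character(sample_ids)
  colnames(abundance) <- as.character(species_ids)
  validate_taxa_profile(abundance)
  class(abundance) <- c("taxa_profile", class(abundance))
  abundance
}

validate_taxa_profile <- function(m) {
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing abundance at sample '%s', species '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at sample '%s', species '%s'",
                 rownames(m)[bad[1]], colnames(m)[bad[2]]), call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(sprintf("duplicated sample id: '%s'",
                 rownames(m)[anyDuplicated(rownames(m))]), call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(sprintf("duplicated species id: '%s'",
                 colnames(m)[anyDuplicated(colnames(m))]), call. = FALSE)
  }
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    stop(sprintf("sample '%s' has zero total abundance",
                 rownames(m)[which(rs <= 0)[1]]), call. = FALSE)
  }
  if (any(rs > 1 + 1e-9)) {
    stop(sprintf("sample '%s' has abundance sum %.4f > 1",
                 rownames(m)[which(rs > 1 + 1e-9)[1]], max(rs)), call. = FALSE)
  }
  invisible(m)
}

as_taxa_profile <- function(x) {
  if (inherits(x, "taxa_profile")) return(x)
  taxa_profile(as.matrix(x))
}

#' @export
print.taxa_profile <- function(x, ...) {
  cat(sprintf("taxa_profile: %d samples x %d species\n", nrow(x), ncol(x)))
  cat(sprintf("  mean richness %.1f, row sums in [%.4g, %.4g]\n",
              mean(rowSums(x > 0)), min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Read a taxa table from TSV
#'
#' Reads a tab-separated species abundance table. The default orientation is
#' samples in rows (first column = sample id, header = species names); the
#' transposed orientation written by some taxonomic profilers is accepted via
#' `orientation = "species_by_samples"`. Percentage tables (row sums near
#' 100) are detected by mean row sum > 50 and rescaled to fractions, with a
#' message.
#'
#' @param path Path to a TSV file.
#' @param orientation `"samples_by_species"` (default) or
#'   `"species_by_samples"`.
#' @return A [taxa_profile()].
#' @export
read_taxa_table <- function(path,
                            orientation = c("samples_by_species",
                                            "species_by_samples")) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("taxa table needs an id column plus >=1 species", call. = FALSE)
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric abundance in column '%s', row '%s'",
                   names(vals)[j], ids[bad]), call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "species_by_samples") m <- t(m)
  if (mean(rowSums(m)) > 50) {
    message("row sums look like percentages; rescaling to fractions")
    m <- m / 100
  }
  taxa_profile(m)
}

#' Write a taxa table to TSV
#'
#' @param taxa A [taxa_profile()] or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(taxa, path) {
  m <- as_taxa_profile(taxa)
  df <- data.frame(sample_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Checks the per-sample metadata schema used throughout the package: one
#' record per (subject, visit), group constant within subject, healthy
#' controls not on IBD therapy, calprotectin and human-DNA fields optionally
#' missing.
#'
#' @param samples A data frame with columns `sample_id`, `subject_id`,
#'   `visit_week` (0/4/8), `age_months`, `group` (one of `HC_lt7`, `HC_ge7`,
#'   `VEO`, `PIBD`), `antibiotics` (logical), `therapy` (`new`,
#'   `maintenance`, `none`), and optionally `calprotectin_ug_g`,
#'   `human_dna_pct`.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_sample_table <- function(samples) {
  required <- c("sample_id", "subject_id", "visit_week", "age_months",
                "group", "antibiotics", "therapy")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    stop("sample table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         samples$sample_id[anyDuplicated(samples$sample_id)], call. = FALSE)
  }
  if (!all(samples$group %in% c("HC_lt7", "HC_ge7", "VEO", "PIBD"))) {
    stop("group must be one of HC_lt7, HC_ge7, VEO, PIBD", call. = FALSE)
  }
  if (!all(samples$therapy %in% c("new", "maintenance", "none"))) {
    stop("therapy must be one of new, maintenance, none", call. = FALSE)
  }
  key <- paste(samples$subject_id, samples$visit_week)
  if (anyDuplicated(key)) {
    stop("more than one record for subject/visit: ", key[anyDuplicated(key)],
         call. = FALSE)
  }
  ngroup <- tapply(samples$group, samples$subject_id,
                   function(g) length(unique(g)))
  if (any(ngroup > 1)) {
    stop("group changes within subject: ", names(ngroup)[ngroup > 1][1],
         call. = FALSE)
  }
  hc <- samples$group %in% c("HC_lt7", "HC_ge7")
  if (any(samples$therapy[hc] != "none")) {
    stop("healthy-control samples must have therapy = 'none'", call. = FALSE)
  }
  if (any(samples$age_months <= 0)) stop("age_months must be positive", call. = FALSE)
  if ("human_dna_pct" %in% names(samples)) {
    h <- samples$human_dna_pct
    if (any(!is.na(h) & (h < 0 | h > 100))) {
      stop("human_dna_pct outside [0, 100]", call. = FALSE)
    }
  }
  invisible(samples)
}

#' Read a sample metadata table from TSV
#'
#' @param path Path to a TSV file with the schema of
#'   [validate_sample_table()].
#' @return A validated data frame.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(df$antibiotics)) {
    df$antibiotics <- df$antibiotics %in% c("TRUE", "true", "1", "yes")
  }
  df$antibiotics <- as.logical(df$antibiotics)
  validate_sample_table(df)
  df
}

#' Remove low-prevalence species
#'
#' Species present (abundance strictly greater than zero) in fewer than
#' `min_prevalence` of samples are removed; a species present in exactly
#' `min_prevalence` of samples is retained. Remaining abundances are not
#' renormalised, so filtered tables keep the fractions of the full profile.
#'
#' @param taxa A [taxa_profile()] or matrix.
#' @param min_prevalence Fraction of samples in `[0, 1]`; default 0.20.
#' @return Filtered [taxa_profile()].
#' @export
filter_by_prevalence <- function(taxa, min_prevalence = 0.20) {
  m <- as_taxa_profile(taxa)
  if (min_prevalence < 0 || min_prevalence > 1) {
    stop("min_prevalence must be in [0, 1]", call. = FALSE)
  }
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) stop("all species filtered by prevalence threshold", call. = FALSE)
  message(sprintf("prevalence filter (>= %.0f%%): retained %d of %d species",
                  100 * min_prevalence, sum(keep), ncol(m)))
  out <- m[, keep, drop = FALSE]
  class(out) <- class(m)
  out
}

#' Remove species with low maximum abundance
#'
#' Species whose maximum relative abundance across samples is less than or
#' equal to `max_threshold` (default 0.01% = 1e-4 as a fraction) are removed,
#' boundary inclusive. Used before maturity-index model fitting.
#'
#' @param taxa A [taxa_profile()] or matrix.
#' @param max_threshold Abundance fraction; species with max <= this value
#'   are dropped.
#' @return Filtered [taxa_profile()].
#' @export
filter_by_max_abundance <- function(taxa, max_threshold = 1e-4) {
  m <- as_taxa_profile(taxa)
  if (max_threshold < 0) stop("max_threshold must be >= 0", call. = FALSE)
  mx <- apply(m, 2, max)
  keep <- mx > max_threshold
  if (!any(keep)) stop("all species filtered by max-abundance threshold", call. = FALSE)
  message(sprintf("max-abundance filter (> %g): retained %d of %d species",
                  max_threshold, sum(keep), ncol(m)))
  out <- m[, keep, drop = FALSE]
  class(out) <- class(m)
  out
}

#' Keep only subjects with a complete set of visits
#'
#' Longitudinal per-taxon tests require every subject to contribute all
#' visits; subjects with any missing visit are dropped.
#'
#' @param samples A sample metadata table.
#' @param required_visits Vector of visit weeks each subject must have;
#'   default `c(0, 4, 8)`.
#' @return The filtered sample table.
#' @export
complete_case_subjects <- function(samples, required_visits = c(0, 4, 8)) {
  have <- tapply(samples$visit_week, samples$subject_id,
                 function(v) all(required_visits %in% v))
  keep_subjects <- names(have)[have]
  out <- samples[samples$subject_id %in% keep_subjects, , drop = FALSE]
  dropped <- length(have) - length(keep_subjects)
  if (dropped > 0) {
    message(sprintf("complete-case filter: dropped %d subject(s) with missing visits",
                    dropped))
  }
  if (nrow(out) == 0) warning("no subjects with complete visits remain")
  out
}
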
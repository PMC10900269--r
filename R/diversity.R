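#' Species richness of one sample
#'
#' Number of species with abundance strictly greater than zero.
#'
#' @param abundances Non-negative numeric vector.
#' @return Integer count.
#' @export
richness <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  sum(abundances > 0)
}

#' Shannon diversity (natural log) of one sample
#'
#' `H = -sum p_i log p_i` over the nonzero entries, after renormalising them
#' to sum one. An all-zero vector has undefined entropy and returns `NA`
#' with a warning.
#'
#' @param abundances Non-negative numeric vector.
#' @return Entropy in nats.
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative", call. = FALSE)
  p <- abundances[abundances > 0]
  if (length(p) == 0) {
    warning("all-zero abundance vector: Shannon diversity undefined")
    return(NA_real_)
  }
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `BC = 1 - 2 * sum(min(x, y)) / (sum(x) + sum(y))`, the abundance-weighted
#' community dissimilarity in `[0, 1]`.
#'
#' @param x,y Equal-length non-negative vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(x) + sum(y)
  if (s == 0) stop("both vectors are all-zero", call. = FALSE)
  1 - 2 * sum(pmin(x, y)) / s
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' @param taxa A [taxa_profile()] or abundance matrix (samples in rows).
#' @return A symmetric matrix of dissimilarities.
#' @export
bray_curtis_matrix <- function(taxa) {
  m <- as.matrix(taxa)
  n <- nrow(m)
  rs <- rowSums(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    shared <- colSums(pmin(t(m[rest, , drop = FALSE]), m[i, ]))
    d <- 1 - 2 * shared / (rs[i] + rs[rest])
    out[i, rest] <- d
    out[rest, i] <- d
  }
  out
}

#' Alpha diversity per sample
#'
#' @param taxa A [taxa_profile()] or abundance matrix.
#' @return Data frame with `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(taxa) {
  m <- as.matrix(taxa)
  data.frame(sample_id = rownames(m),
             richness = apply(m, 1, richness),
             shannon = apply(m, 1, shannon),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dysbiosis score of one sample against a healthy reference set
#'
#' The sample's aggregated Bray-Curtis dissimilarity to each reference
#' sample. The median is the default aggregator; larger scores indicate a
#' community further from the healthy older-child configuration, i.e. more
#' dysbiotic.
#'
#' @param sample Abundance vector.
#' @param reference Matrix of reference samples (rows), same species order.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Score in `[0, 1]`.
#' @export
dysbiosis_score <- function(sample, reference,
                            aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  reference <- as.matrix(reference)
  if (nrow(reference) == 0) stop("empty reference set", call. = FALSE)
  d <- apply(reference, 1, bray_curtis, y = sample)
  if (aggregate == "median") stats::median(d) else mean(d)
}

#' Dysbiosis scores for every sample of a cohort
#'
#' The reference panel is all samples of healthy children aged >= 7 years
#' (`HC_ge7`) without antibiotic exposure. For each scored sample the
#' reference excludes the sample itself and every other sample from the same
#' subject, so no sample is compared with its own subject.
#'
#' @param taxa A [taxa_profile()].
#' @param samples Sample metadata (see [validate_sample_table()]).
#' @param reference_group Group label of the reference panel.
#' @param aggregate `"median"` (default) or `"mean"`.
#' @return Data frame with `sample_id`, `score`, `n_reference`.
#' @export
dysbiosis_scores <- function(taxa, samples, reference_group = "HC_ge7",
                             aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  m <- as.matrix(taxa)
  samples <- samples[match(rownames(m), samples$sample_id), ]
  if (anyNA(samples$sample_id)) {
    stop("taxa table contains samples absent from metadata", call. = FALSE)
  }
  ref_ids <- samples$sample_id[samples$group == reference_group &
                                 !samples$antibiotics]
  if (length(ref_ids) == 0) stop("no reference samples available", call. = FALSE)
  scores <- vapply(seq_len(nrow(m)), function(i) {
    own <- samples$sample_id[samples$subject_id == samples$subject_id[i]]
    use <- setdiff(ref_ids, own)
    if (length(use) == 0) return(NA_real_)
    dysbiosis_score(m[i, ], m[use, , drop = FALSE], aggregate)
  }, numeric(1))
  n_ref <- vapply(seq_len(nrow(m)), function(i) {
    own <- samples$sample_id[samples$subject_id == samples$subject_id[i]]
    length(setdiff(ref_ids, own))
  }, integer(1))
  data.frame(sample_id = samples$sample_id, score = scores,
             n_reference = n_ref, stringsAsFactors = FALSE, row.names = NULL)
}

#' Within-subject community stability across visits
#'
#' All pairwise Bray-Curtis distances among each subject's visits (three
#' values for three visits). Subjects with fewer than two visits are skipped
#' with a warning.
#'
#' @param taxa A [taxa_profile()].
#' @param samples Sample metadata.
#' @return Data frame with `subject_id`, `visit_a`, `visit_b`, `distance`.
#' @export
within_subject_stability <- function(taxa, samples) {
  m <- as.matrix(taxa)
  out <- list()
  skipped <- 0L
  for (s in unique(samples$subject_id)) {
    rows <- samples[samples$subject_id == s, ]
    rows <- rows[order(rows$visit_week), ]
    if (nrow(rows) < 2) {
      skipped <- skipped + 1L
      next
    }
    pairs <- utils::combn(seq_len(nrow(rows)), 2)
    out[[s]] <- data.frame(
      subject_id = s,
      visit_a = rows$visit_week[pairs[1, ]],
      visit_b = rows$visit_week[pairs[2, ]],
      distance = apply(pairs, 2, function(p) {
        bray_curtis(m[rows$sample_id[p[1]], ], m[rows$sample_id[p[2]], ])
      }),
      stringsAsFactors = FALSE)
  }
  if (skipped > 0) {
    warning(sprintf("%d subject(s) with fewer than 2 visits skipped", skipped))
  }
  if (length(out) == 0) return(data.frame(subject_id = character(),
                                          visit_a = numeric(),
                                          visit_b = numeric(),
                                          distance = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-subject instability summary
#'
#' Mean of the within-subject pairwise Bray-Curtis distances; the subject's
#' instability over the study window.
#'
#' @inheritParams within_subject_stability
#' @return Data frame with `subject_id`, `mean_distance`, `n_pairs`.
#' @export
subject_instability <- function(taxa, samples) {
  pairs <- within_subject_stability(taxa, samples)
  if (nrow(pairs) == 0) {
    return(data.frame(subject_id = character(), mean_distance = numeric(),
                      n_pairs = integer()))
  }
  agg <- stats::aggregate(distance ~ subject_id, pairs, mean)
  n <- stats::aggregate(distance ~ subject_id, pairs, length)
  data.frame(subject_id = agg$subject_id, mean_distance = agg$distance,
             n_pairs = n$distance, stringsAsFactors = FALSE)
}

#' Principal coordinates of the Bray-Curtis matrix
#'
#' Classical multidimensional scaling of the pairwise Bray-Curtis matrix;
#' a plotting convenience.
#'
#' @param taxa A [taxa_profile()].
#' @param k Number of axes.
#' @return Data frame of sample coordinates with eigenvalue attribute.
#' @export
pcoa_bray <- function(taxa, k = 2) {
  d <- bray_curtis_matrix(taxa)
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  out <- data.frame(sample_id = rownames(d), fit$points,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[-1] <- paste0("PCo", seq_len(k))
  attr(out, "eig") <- fit$eig
  out
}
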
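#' Empirical ROC curve and rank-based AUC
#'
#' Threshold-sweep ROC with the area computed by the Mann-Whitney rank
#' formulation (midranks for ties): the probability that a random positive
#' scores above a random negative, with ties counted half.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return Object of class `"roc_result"`: `thresholds`, `tpr`, `fpr`,
#'   `auc`, `positive_label`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(scores[!labels] >= t), numeric(1))
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 positive_label = TRUE, n_positive = n1, n_negative = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' ROC of the Relative MMI as a disease classifier
#'
#' Lower RMMI indicates reduced maturity and hence disease, so the
#' classifier score is the negated RMMI; the orientation is recorded in the
#' result.
#'
#' @param rmmi Relative MMI values (months).
#' @param is_disease Logical disease-status labels.
#' @return A [roc_auc()] result with an `orientation` note.
#' @export
rmmi_roc <- function(rmmi, is_disease) {
  res <- roc_auc(-rmmi, is_disease)
  res$orientation <- "score = -RMMI (lower maturity scores as more diseased)"
  res
}

#' Spearman rank correlation with midrank ties
#'
#' @param x,y Paired numeric vectors; missing pairs are dropped.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning for a constant
#'   vector or fewer than 3 pairs.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    warning("fewer than 3 complete pairs")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Group summaries with rank-based pairwise tests
#'
#' Per-group n, median and interquartile range, with two-sided Wilcoxon
#' rank-sum (unpaired) or signed-rank (paired) tests between requested
#' group pairs.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels.
#' @param pairs Optional list of length-2 character vectors naming group
#'   pairs to test; unknown groups raise an error.
#' @param paired Use the signed-rank test on pair-aligned values (vectors
#'   within each group must then align).
#' @return List with `summary` (per-group) and `tests` (per pair, or `NULL`
#'   when no pairs were requested).
#' @export
group_summary <- function(values, groups, pairs = NULL, paired = FALSE) {
  groups <- as.character(groups)
  summary <- do.call(rbind, lapply(split(values, groups), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    data.frame(n = sum(!is.na(v)), median = q[2], q1 = q[1], q3 = q[3])
  }))
  summary <- data.frame(group = rownames(summary), summary,
                        row.names = NULL, stringsAsFactors = FALSE)
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- do.call(rbind, lapply(pairs, function(p) {
      if (!all(p %in% groups)) {
        stop("unknown group(s) in pair: ", paste(p, collapse = " vs "),
             call. = FALSE)
      }
      a <- values[groups == p[1]]
      b <- values[groups == p[2]]
      w <- suppressWarnings(stats::wilcox.test(a, b, paired = paired))
      data.frame(group_a = p[1], group_b = p[2], p_value = w$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summary, tests = tests)
}
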
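#' Derive a reproducible sub-seed from a master seed
#'
#' Pipeline stages and repeated model fits each draw their own RNG seed from
#' the single master seed via this arithmetic rule, so that any stage can be
#' re-run in isolation and reproduce its output exactly.
#'
#' @param seed Integer master seed.
#' @param key Character label of the consumer (stage name, repetition index).
#' @return An integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' derive_seed(1, "importance_rep_3")
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(as.character(key))
  h <- sum(codes * seq_along(codes)) %% 1e6
  as.integer((as.numeric(seed) %% 2147400000 * 1103 + h * 7919 + 1) %% 2147483629)
}

# row maxima without apply() overhead (few columns, many rows)
row_max <- function(mat) {
  m <- mat[, 1]
  for (k in seq_len(ncol(mat))[-1]) m <- pmax(m, mat[, k])
  m
}

# log(sum_k w_k * exp(mat[, k])) per row, numerically stable
log_weighted_sum_exp <- function(mat, logw) {
  m <- row_max(mat)
  m + log(rowSums(exp(sweep(mat, 2, logw, `+`) - m)))
}

# recycle a scalar or named-vector parameter over group labels
per_group <- function(x, groups, what = deparse(substitute(x))) {
  if (length(x) == 1L && is.null(names(x))) {
    return(rep(unname(x), length(groups)))
  }
  missing <- setdiff(unique(as.character(groups)), names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s has no value for group(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unname(x[as.character(groups)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
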
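#' Zero-inflated beta regression with subject random effects
#'
#' Longitudinal per-taxon model with two sub-models sharing covariates:
#' a logistic presence sub-model `presence ~ Bernoulli(logit^-1(X b + u))`
#' and a beta abundance sub-model for present samples with mean
#' `logit^-1(X c + v)` and precision `phi`. `u` and `v` are independent
#' Gaussian subject random intercepts, integrated out of the likelihood by
#' Gauss-Hermite quadrature; each sub-model is maximised by L-BFGS-B.
#'
#' Degenerate taxa are handled by dropping the impossible component: if all
#' samples are present (or all absent) the presence sub-model is skipped; if
#' too few samples are present the abundance sub-model is skipped.
#'
#' @param y Relative abundances in `[0, 1)`; values >= 1 are nudged to
#'   `1 - 1e-6`.
#' @param X Design matrix including an intercept column.
#' @param subject Subject identifier per row of `X` (random-intercept
#'   grouping).
#' @param gh_nodes Number of Gauss-Hermite quadrature nodes (default 9).
#' @param start Optional list of starting values: `logistic` as
#'   `c(coefficients, log sigma)` and/or `beta` as
#'   `c(coefficients, log phi, log sigma)`; used to rescue fits from poor
#'   default starts.
#' @return An object of class `"zibr_fit"` with elements `logistic` and
#'   `beta` (each `NULL` if degenerate, otherwise coefficient vector,
#'   random-intercept SD, log-likelihood and convergence flag), plus the
#'   total `loglik` and `converged`.
#' @export
fit_zibr <- function(y, X, subject, gh_nodes = 9, start = NULL) {
  X <- as.matrix(X)
  if (length(y) != nrow(X) || length(subject) != nrow(X)) {
    stop("y, X and subject must have matching lengths", call. = FALSE)
  }
  if (any(y < 0) || any(y > 1)) stop("abundances must lie in [0, 1]", call. = FALSE)
  gh <- pracma::gaussHermite(gh_nodes)
  logw <- log(gh$w) - 0.5 * log(pi)
  subject <- as.integer(factor(subject))

  present <- as.numeric(y > 0)
  logistic <- NULL
  if (stats::var(present) > 0) {
    logistic <- fit_logistic_re(present, X, subject, gh, logw,
                                start = start$logistic)
  }
  beta_fit <- NULL
  idx <- which(y > 0)
  if (length(idx) >= max(5, ncol(X) + 2) && stats::var(y[idx]) > 0) {
    ya <- pmin(y[idx], 1 - 1e-6)
    # renumber so subject indices stay contiguous within the present subset
    beta_fit <- fit_beta_re(ya, X[idx, , drop = FALSE],
                            as.integer(factor(subject[idx])), gh,
                            logw, start = start$beta)
  }
  if (is.null(logistic) && is.null(beta_fit)) {
    stop("taxon is degenerate in both sub-models (constant presence and abundance)",
         call. = FALSE)
  }
  structure(list(
    logistic = logistic, beta = beta_fit,
    loglik = sum(c(logistic$loglik, beta_fit$loglik)),
    converged = all(c(logistic$converged, beta_fit$converged)),
    n = length(y), n_present = length(idx), gh_nodes = gh_nodes),
    class = "zibr_fit")
}

# marginal negative log-likelihood of the logistic sub-model
nll_logistic_re <- function(par, y, X, subject, gh, logw) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  sig <- exp(par[p + 1])
  E <- eta + tcrossprod(rep(1, length(y)), sqrt(2) * sig * gh$x)
  ll <- y * stats::plogis(E, log.p = TRUE) +
    (1 - y) * stats::plogis(-E, log.p = TRUE)
  -sum(log_weighted_sum_exp(rowsum(ll, subject), logw))
}

# posterior node weights per observation row: A[j, k] is the weight of
# quadrature node k for observation j's subject given the data
node_weights <- function(ll, subject, logw) {
  Lw <- sweep(rowsum(ll, subject), 2, logw, `+`)
  m <- row_max(Lw)
  A <- exp(Lw - m)
  A <- A / rowSums(A)
  A[subject, , drop = FALSE]
}

# analytic gradient of nll_logistic_re
grad_logistic_re <- function(par, y, X, subject, gh, logw) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  sig <- exp(par[p + 1])
  zz <- sqrt(2) * sig * gh$x
  E <- eta + tcrossprod(rep(1, length(y)), zz)
  ll <- y * stats::plogis(E, log.p = TRUE) +
    (1 - y) * stats::plogis(-E, log.p = TRUE)
  W <- node_weights(ll, subject, logw) * (y - stats::plogis(E))
  unname(c(-drop(crossprod(X, rowSums(W))), -sum(W %*% zz)))
}

fit_logistic_re <- function(y, X, subject, gh, logw, start = NULL) {
  p <- ncol(X)
  if (is.null(start)) {
    b0 <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
      error = function(e) rep(0, p))
    b0[!is.finite(b0)] <- 0
    b0 <- pmin(pmax(b0, -5), 5)
    start <- c(b0, log(0.5))
  }
  fit <- optimise_marginal(start, nll_logistic_re, grad_logistic_re,
                           lower = c(rep(-50, p), -6),
                           upper = c(rep(50, p), 3),
                           y = y, X = X, subject = subject, gh = gh, logw = logw)
  list(coef = stats::setNames(fit$par[seq_len(p)], colnames(X)),
       sigma = exp(fit$par[p + 1]), loglik = -fit$value,
       df = p + 1, converged = fit$converged)
}

# marginal negative log-likelihood of the beta sub-model (present samples)
nll_beta_re <- function(par, y, X, subject, gh, logw) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  phi <- exp(par[p + 1])
  sig <- exp(par[p + 2])
  E <- eta + tcrossprod(rep(1, length(y)), sqrt(2) * sig * gh$x)
  mu <- pmin(pmax(stats::plogis(E), 1e-12), 1 - 1e-12)
  ll <- matrix(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE),
               nrow = length(y))
  ll[!is.finite(ll)] <- -1e10
  -sum(log_weighted_sum_exp(rowsum(ll, subject), logw))
}

# analytic gradient of nll_beta_re
grad_beta_re <- function(par, y, X, subject, gh, logw) {
  p <- ncol(X)
  eta <- drop(X %*% par[seq_len(p)])
  phi <- exp(par[p + 1])
  sig <- exp(par[p + 2])
  zz <- sqrt(2) * sig * gh$x
  E <- eta + tcrossprod(rep(1, length(y)), zz)
  mu <- pmin(pmax(stats::plogis(E), 1e-12), 1 - 1e-12)
  a <- mu * phi
  b <- (1 - mu) * phi
  ll <- matrix(stats::dbeta(y, a, b, log = TRUE), nrow = length(y))
  ll[!is.finite(ll)] <- -1e10
  A <- node_weights(ll, subject, logw)
  ly <- log(y)
  l1y <- log1p(-y)
  dga <- digamma(a)
  dgb <- digamma(b)
  # d loglik / d eta and (scaled) d loglik / d log(phi)
  R <- mu * (1 - mu) * phi * (ly - l1y - dga + dgb)
  Dphi <- phi * (mu * ly + (1 - mu) * l1y - mu * dga - (1 - mu) * dgb +
                   digamma(phi))
  WA <- A * R
  unname(c(-drop(crossprod(X, rowSums(WA))), -sum(A * Dphi),
           -sum(WA %*% zz)))
}

fit_beta_re <- function(y, X, subject, gh, logw, start = NULL) {
  p <- ncol(X)
  if (is.null(start)) {
    z <- stats::qlogis(pmin(pmax(y, 1e-6), 1 - 1e-6))
    b0 <- tryCatch(stats::lm.fit(X, z)$coefficients, error = function(e) rep(0, p))
    b0[!is.finite(b0)] <- 0
    mu0 <- mean(y)
    phi0 <- min(max(mu0 * (1 - mu0) / max(stats::var(y), 1e-8) - 1, 0.5), 200)
    start <- c(b0, log(phi0), log(0.5))
  }
  fit <- optimise_marginal(start, nll_beta_re, grad_beta_re,
                           lower = c(rep(-50, p), -3, -6),
                           upper = c(rep(50, p), 10, 3),
                           y = y, X = X, subject = subject, gh = gh, logw = logw)
  list(coef = stats::setNames(fit$par[seq_len(p)], colnames(X)),
       phi = exp(fit$par[p + 1]), sigma = exp(fit$par[p + 2]),
       loglik = -fit$value, df = p + 2, converged = fit$converged)
}

optimise_marginal <- function(start, fn, gr, lower, upper, ...) {
  res <- tryCatch(
    stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 300), ...),
    error = function(e) NULL)
  if (is.null(res)) {
    res <- stats::optim(start, fn, method = "Nelder-Mead",
                        control = list(maxit = 2000), ...)
  }
  list(par = res$par, value = res$value, converged = res$convergence == 0)
}

#' @export
print.zibr_fit <- function(x, ...) {
  cat(sprintf("zibr_fit: %d samples (%d present), loglik %.2f%s\n",
              x$n, x$n_present, x$loglik,
              if (x$converged) "" else " [not converged]"))
  if (!is.null(x$logistic)) {
    cat("presence:  ", paste(sprintf("%s=%.3f", names(x$logistic$coef),
                                     x$logistic$coef), collapse = " "),
        sprintf(" sigma=%.3f\n", x$logistic$sigma))
  }
  if (!is.null(x$beta)) {
    cat("abundance: ", paste(sprintf("%s=%.3f", names(x$beta$coef),
                                     x$beta$coef), collapse = " "),
        sprintf(" phi=%.2f sigma=%.3f\n", x$beta$phi, x$beta$sigma))
  }
  invisible(x)
}

#' Combined likelihood-ratio test of nested zero-inflated beta fits
#'
#' Per-component likelihood-ratio statistics (presence and abundance) plus
#' their sum as the combined test; the null fit must nest the full fit
#' (typically: group terms removed from both sub-models). Degrees of freedom
#' are the number of removed parameters per component. A slightly negative
#' likelihood-ratio statistic (within numerical tolerance) is floored at
#' zero; a substantially negative one signals a failed fit and triggers a
#' warning.
#'
#' @param fit Full-model [fit_zibr()].
#' @param null_fit Nested null-model fit on the same data.
#' @return A one-row data frame with `p_prevalence`, `p_abundance`,
#'   `p_combined`, the statistics and degrees of freedom.
#' @export
combined_test <- function(fit, null_fit) {
  comp <- function(full, null) {
    if (is.null(full) || is.null(null)) return(NULL)
    stat <- 2 * (full$loglik - null$loglik)
    if (stat < -0.05) {
      warning(sprintf("negative likelihood-ratio statistic (%.3f): refit advised",
                      stat))
    }
    stat <- max(stat, 0)
    df <- full$df - null$df
    if (df <= 0) return(list(stat = stat, df = 0, p = 1))
    list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  prev <- comp(fit$logistic, null_fit$logistic)
  abund <- comp(fit$beta, null_fit$beta)
  stat <- sum(c(prev$stat, abund$stat))
  df <- sum(c(prev$df, abund$df))
  p_comb <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else 1
  data.frame(
    p_prevalence = prev$p %||% NA_real_,
    p_abundance = abund$p %||% NA_real_,
    p_combined = p_comb,
    stat_prevalence = prev$stat %||% NA_real_,
    stat_abundance = abund$stat %||% NA_real_,
    stat_combined = stat, df = df, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values controlling the FDR over the tested family.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

# when a full-model component fits worse than its nested null, refit it
# starting from the null optimum (with zeros for the extra columns); a
# correct optimum can never fall below the null's likelihood
rescue_nested_fit <- function(fit, null_fit, y, X, subject, gh_nodes) {
  worse <- function(f, n) {
    !is.null(f) && !is.null(n) && f$loglik < n$loglik - 1e-6
  }
  if (!worse(fit$logistic, null_fit$logistic) &&
      !worse(fit$beta, null_fit$beta)) {
    return(fit)
  }
  pad <- function(coef) {
    b <- stats::setNames(rep(0, ncol(X)), colnames(X))
    b[names(coef)] <- coef
    b
  }
  start <- list()
  if (worse(fit$logistic, null_fit$logistic)) {
    start$logistic <- c(pad(null_fit$logistic$coef),
                        log(max(null_fit$logistic$sigma, 1e-3)))
  }
  if (worse(fit$beta, null_fit$beta)) {
    start$beta <- c(pad(null_fit$beta$coef), log(null_fit$beta$phi),
                    log(max(null_fit$beta$sigma, 1e-3)))
  }
  refit <- fit_zibr(y, X, subject, gh_nodes, start = start)
  if (!is.null(fit$logistic) && refit$logistic$loglik > fit$logistic$loglik) {
    fit$logistic <- refit$logistic
  }
  if (!is.null(fit$beta) && refit$beta$loglik > fit$beta$loglik) {
    fit$beta <- refit$beta
  }
  fit$loglik <- sum(c(fit$logistic$loglik, fit$beta$loglik))
  fit$converged <- all(c(fit$logistic$converged, fit$beta$converged))
  fit
}

zibr_comparisons <- list(
  VEO_vs_HC_lt7 = list(groups = c("HC_lt7", "VEO"), reference = "HC_lt7",
                       exclude_abx_in = character()),
  PIBD_vs_HC_ge7 = list(groups = c("HC_ge7", "PIBD"), reference = "HC_ge7",
                        exclude_abx_in = character()),
  # no antibiotic-exposed PIBD subjects exist, so exposed VEO subjects are
  # removed to keep the comparison balanced on exposure
  VEO_vs_PIBD = list(groups = c("PIBD", "VEO"), reference = "PIBD",
                     exclude_abx_in = "VEO"))

#' Longitudinal per-taxon group testing
#'
#' Runs the zero-inflated beta regression with subject random effects for
#' every species of a comparison: subjects with incomplete visits are
#' excluded, species are prevalence-filtered within the comparison (default:
#' species present in less than 20% of the compared samples are removed),
#' and each species is tested by the combined likelihood-ratio test of the
#' group term in both sub-models, with age, antibiotic exposure and visit
#' week as covariates. q-values are Benjamini-Hochberg adjusted over all
#' species tested in the comparison.
#'
#' @param taxa A [taxa_profile()].
#' @param samples Sample metadata.
#' @param comparison One of `"VEO_vs_HC_lt7"`, `"PIBD_vs_HC_ge7"`,
#'   `"VEO_vs_PIBD"` (the latter excludes antibiotic-exposed VEO subjects).
#' @param min_prevalence Prevalence threshold applied within the comparison;
#'   set `prevalence_scope = "none"` if the table is already filtered.
#' @param prevalence_scope `"comparison"` (default) or `"none"`.
#' @param gh_nodes Gauss-Hermite nodes for the marginal likelihood.
#' @return Data frame with one row per tested taxon: component and combined
#'   p-values, q-value, direction of the group effect per sub-model, and a
#'   convergence flag (non-converged fits are excluded from the tested
#'   family).
#' @export
zibr_test <- function(taxa, samples, comparison = names(zibr_comparisons),
                      min_prevalence = 0.20,
                      prevalence_scope = c("comparison", "none"),
                      gh_nodes = 9) {
  comparison <- match.arg(comparison)
  prevalence_scope <- match.arg(prevalence_scope)
  spec <- zibr_comparisons[[comparison]]
  keep <- samples$group %in% spec$groups
  if (length(spec$exclude_abx_in)) {
    keep <- keep & !(samples$group %in% spec$exclude_abx_in &
                       samples$antibiotics)
  }
  sub <- complete_case_subjects(samples[keep, , drop = FALSE])
  if (length(unique(sub$group)) < 2) {
    stop("comparison requires samples from both groups", call. = FALSE)
  }
  m <- as.matrix(taxa)[sub$sample_id, , drop = FALSE]
  if (prevalence_scope == "comparison") {
    prev <- colMeans(m > 0)
    m <- m[, prev >= min_prevalence, drop = FALSE]
    message(sprintf("%s: testing %d species in %d samples (%d subjects)",
                    comparison, ncol(m), nrow(m),
                    length(unique(sub$subject_id))))
  }
  X <- cbind(intercept = 1,
             group = as.numeric(sub$group != spec$reference),
             age = as.vector(scale(sub$age_months)),
             antibiotics = as.numeric(sub$antibiotics),
             week = sub$visit_week / 8 - 0.5)
  if (stats::var(X[, "antibiotics"]) == 0) {
    X <- X[, colnames(X) != "antibiotics", drop = FALSE]
  }
  X0 <- X[, colnames(X) != "group", drop = FALSE]
  rows <- lapply(colnames(m), function(sp) {
    y <- m[, sp]
    res <- tryCatch({
      null <- fit_zibr(y, X0, sub$subject_id, gh_nodes)
      fit <- fit_zibr(y, X, sub$subject_id, gh_nodes)
      # a full-model optimum can never fall below the nested null's; where
      # the default-start fit does, refit from the null optimum and keep
      # the better likelihood per component
      fit <- rescue_nested_fit(fit, null, y, X, sub$subject_id, gh_nodes)
      tt <- combined_test(fit, null)
      tt$taxon <- sp
      tt$direction_prevalence <-
        if (is.null(fit$logistic)) NA_real_ else sign(fit$logistic$coef["group"])
      tt$direction_abundance <-
        if (is.null(fit$beta)) NA_real_ else sign(fit$beta$coef["group"])
      tt$converged <- fit$converged && null$converged
      tt
    }, error = function(e) {
      message(sprintf("taxon %s skipped: %s", sp, conditionMessage(e)))
      NULL
    })
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no taxa could be tested", call. = FALSE)
  n_bad <- sum(!out$converged)
  if (n_bad > 0) {
    message(sprintf("%d taxon fit(s) did not converge; excluded from FDR family",
                    n_bad))
  }
  out$q_combined <- NA_real_
  out$q_combined[out$converged] <- adjust_fdr(out$p_combined[out$converged])
  cols <- c("taxon", "p_prevalence", "p_abundance", "p_combined",
            "q_combined", "direction_prevalence", "direction_abundance",
            "stat_combined", "df", "converged")
  out[, cols]
}
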
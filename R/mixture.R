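#' Healthy-constrained two-component mixture of MMI versus age
#'
#' Models each sample's MMI as coming from one of two Gaussian components:
#' a healthy-like component whose mean function is the frozen healthy spline
#' (never re-estimated), and a reduced-maturity component whose mean is a
#' line constrained to meet the healthy curve at a convergence age (default:
#' the youngest age of the spline's range, where healthy and delayed
#' trajectories coincide). The EM algorithm estimates only the reduced
#' component's slope, the two residual scales and the mixing weight;
#' multiple restarts keep the best likelihood.
#'
#' @param mmi MMI values (months).
#' @param age Chronological ages (months).
#' @param healthy_spline A [fit_healthy_spline()] object (frozen).
#' @param convergence_age Age (months) where the two component means meet;
#'   defaults to the lower end of the spline's fitted range.
#' @param n_starts Number of EM restarts (first start deterministic,
#'   remainder random slopes).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param free_intercept If `TRUE`, the reduced component's intercept is
#'   also estimated (unconstrained line) instead of being pinned to the
#'   convergence point.
#' @param seed Integer seed for the random restarts.
#' @return Object of class `"mixture_fit"`: `beta2` (slope, months MMI per
#'   month age), `intercept`, `sigma1`, `sigma2`, `pi1`, `loglik`,
#'   `loglik_trace`, `converged`, `degenerate`, plus the convergence point.
#' @export
fit_two_component <- function(mmi, age, healthy_spline,
                              convergence_age = NULL, n_starts = 10,
                              max_iter = 500, tol = 1e-6,
                              free_intercept = FALSE, seed = 1) {
  stopifnot(length(mmi) == length(age))
  x0 <- convergence_age %||% healthy_spline$age_range[1]
  y0 <- spline_predict(healthy_spline, x0)
  m1 <- spline_predict(healthy_spline, age)
  s_init <- max(stats::sd(mmi - m1), 1e-3)
  set.seed(derive_seed(seed, "mixture_starts"))
  slopes <- c(0.5, stats::runif(max(n_starts - 1, 0), 0, 1.2))
  best <- NULL
  for (b0 in slopes) {
    fit <- em_two_component(mmi, age, m1, x0, y0, b0, s_init, max_iter, tol,
                            free_intercept)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$convergence_age <- x0
  best$convergence_mmi <- y0
  best$healthy_spline <- healthy_spline
  if (best$degenerate) {
    warning("degenerate mixture fit: all mass on one component")
  }
  class(best) <- "mixture_fit"
  best
}

em_two_component <- function(y, age, m1, x0, y0, beta2, s_init, max_iter,
                             tol, free_intercept) {
  dx <- age - x0
  a2 <- if (free_intercept) y0 else y0  # intercept at the convergence age
  sigma1 <- sigma2 <- s_init
  pi1 <- 0.5
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- a2 + beta2 * dx
    l1 <- stats::dnorm(y, m1, sigma1, log = TRUE) + log(pi1)
    l2 <- stats::dnorm(y, m2, sigma2, log = TRUE) + log(1 - pi1)
    mx <- pmax(l1, l2)
    lse <- mx + log(exp(l1 - mx) + exp(l2 - mx))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    r1 <- exp(l1 - lse)
    r2 <- 1 - r1
    pi1 <- min(max(mean(r1), 1e-8), 1 - 1e-8)
    if (free_intercept) {
      # weighted least squares for intercept and slope
      w <- r2
      sw <- sum(w)
      mx_ <- sum(w * dx) / sw
      my_ <- sum(w * y) / sw
      beta2 <- sum(w * (dx - mx_) * (y - my_)) / max(sum(w * (dx - mx_)^2), 1e-12)
      a2 <- my_ - beta2 * mx_
    } else {
      beta2 <- sum(r2 * dx * (y - y0)) / max(sum(r2 * dx^2), 1e-12)
    }
    m2 <- a2 + beta2 * dx
    sigma1 <- sqrt(max(sum(r1 * (y - m1)^2) / max(sum(r1), 1e-12), 1e-6))
    sigma2 <- sqrt(max(sum(r2 * (y - m2)^2) / max(sum(r2), 1e-12), 1e-6))
  }
  m2 <- a2 + beta2 * dx
  l1 <- stats::dnorm(y, m1, sigma1, log = TRUE) + log(pi1)
  l2 <- stats::dnorm(y, m2, sigma2, log = TRUE) + log(1 - pi1)
  mx <- pmax(l1, l2)
  lse <- mx + log(exp(l1 - mx) + exp(l2 - mx))
  list(beta2 = beta2, intercept = a2, sigma1 = sigma1, sigma2 = sigma2,
       pi1 = pi1, loglik = sum(lse), loglik_trace = trace,
       converged = converged,
       degenerate = pi1 <= 1e-6 || pi1 >= 1 - 1e-6,
       posterior1 = exp(l1 - lse))
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("mixture_fit: slope %.3f through (%.1f, %.1f), ",
                     "pi1 %.3f, sigma (%.2f, %.2f), loglik %.2f%s\n"),
              x$beta2, x$convergence_age, x$convergence_mmi, x$pi1,
              x$sigma1, x$sigma2, x$loglik,
              if (x$converged) "" else " [max iterations]"))
  invisible(x)
}

#' Posterior component membership of samples
#'
#' Bayes posterior probability of the healthy-like component from the two
#' Gaussian densities and the mixing weight, with confidence bands:
#' `confident_c1` for posterior above 0.75, `confident_c2` below 0.25, and
#' `uncertain` for the inclusive band between.
#'
#' @param fit A [fit_two_component()] result.
#' @param mmi,age MMI values and ages of the samples to score.
#' @param sample_id Optional identifiers.
#' @return Data frame `sample_id`, `p_component1`, `band`.
#' @export
posterior_membership <- function(fit, mmi, age, sample_id = NULL) {
  stopifnot(inherits(fit, "mixture_fit"))
  m1 <- spline_predict(fit$healthy_spline, age)
  m2 <- fit$convergence_mmi + fit$beta2 * (age - fit$convergence_age)
  l1 <- stats::dnorm(mmi, m1, fit$sigma1, log = TRUE) + log(fit$pi1)
  l2 <- stats::dnorm(mmi, m2, fit$sigma2, log = TRUE) + log(1 - fit$pi1)
  mx <- pmax(l1, l2)
  p1 <- exp(l1 - (mx + log(exp(l1 - mx) + exp(l2 - mx))))
  band <- posterior_band_of(p1)
  data.frame(sample_id = sample_id %||% seq_along(mmi),
             p_component1 = p1, band = band, stringsAsFactors = FALSE,
             row.names = NULL)
}

# confidence band of a component-1 posterior; the 0.25/0.75 boundaries are
# inclusive on the uncertain side
posterior_band_of <- function(p1) {
  ifelse(p1 > 0.75, "confident_c1",
         ifelse(p1 < 0.25, "confident_c2", "uncertain"))
}

#' Visit-to-visit component switching
#'
#' Assigns each sample a hard component label (healthy-like if the posterior
#' probability of component 1 is at or above `threshold`) and counts label
#' changes across consecutive visits within each subject, summarised by
#' therapy stratum.
#'
#' @param posteriors Data frame with `sample_id`, `p_component1`.
#' @param samples Sample metadata with `subject_id`, `visit_week`, `therapy`.
#' @param threshold Hard-label threshold on the component-1 posterior.
#' @return List with `per_subject` (subject, labels, switch count) and
#'   `by_therapy` (therapy stratum, subjects, switch rate).
#' @export
component_switching <- function(posteriors, samples, threshold = 0.5) {
  merged <- merge(posteriors, samples, by = "sample_id")
  per <- lapply(split(merged, merged$subject_id), function(d) {
    d <- d[order(d$visit_week), ]
    if (nrow(d) < 2) return(NULL)
    labels <- ifelse(d$p_component1 >= threshold, "c1", "c2")
    data.frame(subject_id = d$subject_id[1], therapy = d$therapy[1],
               n_visits = nrow(d),
               labels = paste(labels, collapse = ","),
               n_switches = sum(labels[-1] != labels[-length(labels)]),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, list(make.row.names = FALSE)))
  if (is.null(per) || nrow(per) == 0) {
    stop("no subject with >= 2 visits to assess switching", call. = FALSE)
  }
  by_th <- do.call(rbind, lapply(split(per, per$therapy), function(d) {
    data.frame(therapy = d$therapy[1], n_subjects = nrow(d),
               n_switching = sum(d$n_switches > 0),
               switch_rate = mean(d$n_switches > 0),
               mean_switches = mean(d$n_switches), stringsAsFactors = FALSE)
  }))
  rownames(by_th) <- NULL
  list(per_subject = per, by_therapy = by_th)
}
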
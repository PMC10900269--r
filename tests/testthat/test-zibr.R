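test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(adjust_fdr(p), bh_brute(p))
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a model compared with itself gives a null test", {
  sim <- sim_zibr_taxon(40, seed = 1)
  fit <- fit_zibr(sim$y, sim$X, sim$subject)
  out <- combined_test(fit, fit)
  expect_equal(out$stat_combined, 0)
  expect_equal(out$p_combined, 1)
})

test_that("the combined test separates nested models with a group effect", {
  sim <- sim_zibr_taxon(80, seed = 2, group_presence = 2,
                        group_abundance = 1.5)
  X0 <- sim$X[, colnames(sim$X) != "group"]
  fit <- fit_zibr(sim$y, sim$X, sim$subject)
  null <- fit_zibr(sim$y, X0, sim$subject)
  out <- combined_test(fit, null)
  expect_lt(out$p_combined, 0.001)
  expect_equal(out$df, 2)
  expect_true(all(c(out$p_prevalence, out$p_abundance) <= 1))
})

test_that("presence-only effects load on the prevalence component", {
  p_prev <- p_ab <- numeric(8)
  for (r in 1:8) {
    sim <- sim_zibr_taxon(60, seed = 100 + r, group_presence = 1.5,
                          group_abundance = 0)
    fit <- fit_zibr(sim$y, sim$X, sim$subject)
    null <- fit_zibr(sim$y, sim$X[, -2], sim$subject)
    out <- combined_test(fit, null)
    p_prev[r] <- out$p_prevalence
    p_ab[r] <- out$p_abundance
  }
  expect_lt(mean(log(p_prev)), mean(log(p_ab)))
})

test_that("without zeros or subject effects the beta sub-model matches plain beta ML", {
  # no zero inflation, random-effect scale ~0: reduces to ordinary beta regression
  sim <- sim_zibr_taxon(100, seed = 3, sigma_presence = 0, sigma_abundance = 0,
                        intercept_presence = 30, group_abundance = 0.8)
  expect_true(all(sim$y > 0))
  fit <- fit_zibr(sim$y, sim$X, sim$subject)
  expect_lt(fit$beta$sigma, 0.1)

  # independent oracle: direct ML of the marginal beta regression
  nll <- function(par) {
    mu <- plogis(drop(sim$X %*% par[1:3]))
    -sum(dbeta(sim$y, mu * exp(par[4]), (1 - mu) * exp(par[4]), log = TRUE))
  }
  ml <- optim(c(0, 0, 0, log(10)), nll, method = "BFGS")
  expect_equal(unname(fit$beta$coef), ml$par[1:3], tolerance = 5e-3)
  expect_equal(unname(fit$beta$phi), exp(ml$par[4]), tolerance = 0.05)
})

test_that("the presence sub-model agrees with an independent mixed logistic fit", {
  skip_if_not_installed("lme4")
  sim <- sim_zibr_taxon(120, seed = 4, group_presence = 1,
                        sigma_presence = 0.8)
  fit <- fit_zibr(sim$y, sim$X, sim$subject)
  d <- data.frame(pres = as.numeric(sim$y > 0), group = sim$X[, "group"],
                  week = sim$X[, "week"], subject = sim$subject)
  ref <- lme4::glmer(pres ~ group + week + (1 | subject), data = d,
                     family = binomial, nAGQ = 9)
  expect_lt(abs(fit$logistic$coef["group"] - lme4::fixef(ref)["group"]), 0.05)
  expect_lt(abs(fit$logistic$sigma -
                  sqrt(unname(lme4::VarCorr(ref)$subject[1]))), 0.1)
})

test_that("estimates are stable under quadrature refinement", {
  sim <- sim_zibr_taxon(60, seed = 5, group_presence = 0.8,
                        group_abundance = 0.5, sigma_presence = 0.25,
                        sigma_abundance = 0.25)
  f9 <- fit_zibr(sim$y, sim$X, sim$subject, gh_nodes = 9)
  f17 <- fit_zibr(sim$y, sim$X, sim$subject, gh_nodes = 17)
  expect_lt(max(abs(f9$logistic$coef - f17$logistic$coef)), 1e-3)
  expect_lt(max(abs(f9$beta$coef - f17$beta$coef)), 1e-3)
  # marginal likelihood cannot degrade with a finer rule beyond tolerance
  expect_gt(f17$loglik, f9$loglik - 0.01)
})

test_that("analytic likelihood gradients match finite differences", {
  sim <- sim_zibr_taxon(30, seed = 11, group_presence = 0.7,
                        group_abundance = 0.4)
  gh <- pracma::gaussHermite(9)
  logw <- log(gh$w) - 0.5 * log(pi)
  subject <- as.integer(factor(sim$subject))
  num_grad <- function(fn, par, ..., h = 1e-6) {
    vapply(seq_along(par), function(i) {
      e <- replace(numeric(length(par)), i, h)
      (fn(par + e, ...) - fn(par - e, ...)) / (2 * h)
    }, numeric(1))
  }
  pres <- as.numeric(sim$y > 0)
  par_l <- c(0.3, -0.2, 0.1, log(0.6))
  ga <- gutmaturity:::grad_logistic_re(par_l, pres, sim$X, subject, gh, logw)
  gn <- num_grad(gutmaturity:::nll_logistic_re, par_l, y = pres, X = sim$X,
                 subject = subject, gh = gh, logw = logw)
  expect_equal(ga, gn, tolerance = 1e-5)

  idx <- which(sim$y > 0)
  sub_b <- as.integer(factor(subject[idx]))
  par_b <- c(-1.2, 0.2, -0.1, log(15), log(0.4))
  gab <- gutmaturity:::grad_beta_re(par_b, sim$y[idx],
                                    sim$X[idx, , drop = FALSE], sub_b,
                                    gh, logw)
  gnb <- num_grad(gutmaturity:::nll_beta_re, par_b, y = sim$y[idx],
                  X = sim$X[idx, , drop = FALSE], subject = sub_b,
                  gh = gh, logw = logw)
  expect_equal(gab, gnb, tolerance = 1e-5)
})

test_that("degenerate taxa fall back to the informative sub-model", {
  sim <- sim_zibr_taxon(40, seed = 6, intercept_presence = 30)
  expect_true(all(sim$y > 0))
  fit <- fit_zibr(sim$y, sim$X, sim$subject)
  expect_null(fit$logistic)
  expect_false(is.null(fit$beta))
  # nearly-always-absent taxon: abundance sub-model dropped
  sim2 <- sim_zibr_taxon(40, seed = 7, intercept_presence = -3.5)
  stopifnot(sum(sim2$y > 0) %in% 1:4)
  fit2 <- fit_zibr(sim2$y, sim2$X, sim2$subject)
  expect_null(fit2$beta)
  expect_false(is.null(fit2$logistic))
  expect_error(fit_zibr(rep(0, 12), cbind(1, rep(0:1, 6)), rep(1:4, each = 3)),
               "degenerate")
})

test_that("the comparison driver tests taxa and controls the FDR family", {
  co <- generate_cohort(test_cohort_config(seed = 25))
  res <- suppressMessages(zibr_test(co$taxa, co$samples,
                                    comparison = "VEO_vs_HC_lt7"))
  expect_true(all(c("taxon", "p_prevalence", "p_abundance", "p_combined",
                    "q_combined", "direction_prevalence",
                    "direction_abundance", "converged") %in% names(res)))
  conv <- res[res$converged, ]
  expect_true(all(conv$q_combined >= conv$p_combined - 1e-12))
  expect_equal(conv$q_combined, bh_brute(conv$p_combined))
  # marker species enriched in disease should be discovered
  markers <- co$truth$species$species_id[co$truth$species$role ==
                                           "disease_marker"]
  hits <- res$taxon[!is.na(res$q_combined) & res$q_combined < 0.05]
  expect_gt(length(intersect(hits, markers)), 0)
  # VEO-vs-PIBD excludes antibiotic-exposed VEO subjects
  suppressMessages(
    expect_message(res2 <- zibr_test(co$taxa, co$samples,
                                     comparison = "VEO_vs_PIBD"),
                   "testing \\d+ species"))
  expect_true(nrow(res2) > 0)
})
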
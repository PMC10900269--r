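# simulate one longitudinal zero-inflated taxon under the model's own
# assumptions: logistic presence and beta abundance with subject intercepts
sim_zibr_taxon <- function(n_subjects, seed, group_presence = 0,
                           group_abundance = 0, sigma_presence = 0.5,
                           sigma_abundance = 0.5, phi = 20,
                           intercept_presence = 0.5,
                           intercept_abundance = -1.5, visits = 3) {
  set.seed(seed)
  subject <- rep(seq_len(n_subjects), each = visits)
  group <- rep(rep(c(0, 1), length.out = n_subjects), each = visits)
  week <- rep(seq_len(visits) - 1, n_subjects) / (visits - 1) - 0.5
  n <- length(subject)
  u <- rnorm(n_subjects, 0, sigma_presence)[subject]
  v <- rnorm(n_subjects, 0, sigma_abundance)[subject]
  pres <- rbinom(n, 1, plogis(intercept_presence + group_presence * group + u))
  mu <- plogis(intercept_abundance + group_abundance * group + v)
  y <- ifelse(pres == 1, rbeta(n, mu * phi, (1 - mu) * phi), 0)
  y <- pmin(y, 1 - 1e-9)
  X <- cbind(intercept = 1, group = group, week = week)
  list(y = y, X = X, subject = subject)
}
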
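# Brute-force oracle implementations, kept deliberately independent of the
# package's own code paths.

richness_brute <- function(x) {
  n <- 0L
  for (v in x) if (v > 0) n <- n + 1L
  n
}

shannon_brute <- function(x) {
  p <- x[x > 0]
  p <- p / sum(p)
  h <- 0
  for (v in p) h <- h - v * log(v)
  h
}

# Bray-Curtis via the |x-y| identity, a different algebraic route than the
# package's 2*min formulation
bc_brute <- function(x, y) {
  sum(abs(x - y)) / (sum(x) + sum(y))
}

median_brute <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# BH step-up by the definition q(i) = min_{j >= i} p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# rank-then-Pearson with midranks
spearman_brute <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# AUC by pair enumeration with half-credit ties
auc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# small, fast cohort for module tests
test_cohort_config <- function(seed = 1, ...) {
  defaults <- list(
    n_subjects = c(HC_lt7 = 16, HC_ge7 = 8, VEO = 12, PIBD = 10),
    n_veo_late = 2, n_species = 60, n_maturation_species = 16,
    n_marker_species = 6, n_antibiotic_sensitive = 20, seed = seed)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# random valid taxa matrix (rows sum to 1)
random_taxa <- function(n, p, seed, zero_frac = 0.3) {
  set.seed(seed)
  m <- matrix(rexp(n * p), n, p)
  m[matrix(runif(n * p) < zero_frac, n, p)] <- 0
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1
  m <- m / rowSums(m)
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), sprintf("sp%03d", seq_len(p)))
  m
}
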
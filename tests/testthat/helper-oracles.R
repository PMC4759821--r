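# Independent reference implementations used as oracles. These are written
# naively (explicit loops, no log-space tricks) on purpose, so they share
# no code path with the package internals they check.

# Composite log-likelihood by direct double-loop evaluation.
oracle_logcl <- function(x, prior, pi, mu, sigma) {
  n <- nrow(x); m <- ncol(x)
  K <- nrow(mu); L <- ncol(mu)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- 0
    for (k in seq_len(K)) for (l in seq_len(L))
      s <- s + prior[i, k] * pi[l] * dnorm(x[i, j], mu[k, l], sigma[k, l])
    tot <- tot + log(s)
  }
  tot
}

# Per-cell joint responsibilities by direct Bayes rule.
oracle_joint <- function(x, prior, pi, mu, sigma) {
  n <- nrow(x); m <- ncol(x)
  K <- nrow(mu); L <- ncol(mu)
  t <- array(0, c(n, m, K, L))
  for (i in seq_len(n)) for (j in seq_len(m)) {
    for (k in seq_len(K)) for (l in seq_len(L))
      t[i, j, k, l] <- prior[i, k] * pi[l] * dnorm(x[i, j], mu[k, l], sigma[k, l])
    t[i, j, , ] <- t[i, j, , ] / sum(t[i, j, , ])
  }
  t
}

# Backcross interval-mapping probabilities by enumeration of the gamete
# recombination events in the two sub-intervals (no interference): the
# chromosome is Markov, so P(z = g | a, b) is proportional to the product
# of the flip/no-flip probabilities of the two sub-intervals.
oracle_interval_prob <- function(a, b, r1, r2) {
  flip <- function(g1, g2, r) if (is.na(g1) || is.na(g2)) 1 else if (g1 == g2) 1 - r else r
  w <- vapply(c(0, 1), function(g) flip(a, g, r1) * flip(g, b, r2), numeric(1))
  w / sum(w)
}

# Composite-likelihood surrogate Q(theta; t) for a fixed joint weight
# array; used for the numerical-gradient check of the M step.
surrogate_Q <- function(x, joint, prior, pi, mu, sigma) {
  K <- nrow(mu); L <- ncol(mu)
  q <- 0
  for (k in seq_len(K)) for (l in seq_len(L)) {
    t <- joint[, , k, l]
    q <- q + sum(t * (log(prior[, k]) + log(pi[l]) +
                        dnorm(x, mu[k, l], sigma[k, l], log = TRUE)))
  }
  q
}

rdirichlet1 <- function(k) { g <- rgamma(k, 1); g / sum(g) }

# internal helper surfaced for the M-step tests
weights_from_joint_ <- function(x, joint) blockeqtl:::weights_from_joint(x, joint)

# Small block-structured dataset generated directly (independent of the
# package simulator).
make_block_data <- function(n, m, mu, sigma, p1 = 0.5, pi = NULL, seed = 1) {
  set.seed(seed)
  K <- nrow(mu); L <- ncol(mu)
  if (is.null(pi)) pi <- rep(1 / L, L)
  z <- sample.int(K, n, replace = TRUE, prob = c(p1, 1 - p1)[seq_len(K)])
  w <- sample.int(L, m, replace = TRUE, prob = pi)
  x <- mu[z, w, drop = FALSE] + sigma * matrix(rnorm(n * m), n, m)
  dimnames(x) <- list(paste0("i", 1:n), paste0("j", 1:m))
  list(x = x, z = z, w = w)
}

# Tiny two-marker null design reused by the scan calibration checks.
null_scan_data <- function(n = 40, m = 24, seed = 1) {
  set.seed(seed)
  map <- genetic_map(c("mA", "mB"), "1", c(0, 20))
  g1 <- rbinom(n, 1, 0.5)
  flip <- rbinom(n, 1, haldane(20))
  g2 <- ifelse(flip == 1, 1 - g1, g1)
  geno <- cbind(mA = g1, mB = g2)
  rownames(geno) <- paste0("i", 1:n)
  # expression with cluster structure but no genotype effect
  mu <- rbind(c(-1.5, 1.5), c(-1.5, 1.5))
  w <- sample.int(2, m, replace = TRUE)
  x <- mu[1, w][col(matrix(0, n, m))] + matrix(rnorm(n * m), n, m)
  dimnames(x) <- list(paste0("i", 1:n), paste0("j", 1:m))
  list(x = x, map = map, geno = geno)
}
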
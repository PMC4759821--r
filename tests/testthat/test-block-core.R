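test_that("composite log-likelihood: degenerate block, oracle, symmetries", {
  set.seed(7)
  # K = L = 1 reduces to the iid normal log-likelihood
  x <- matrix(rnorm(12), 3, 4)
  m11 <- block_model(1, matrix(0.3), matrix(1.2))
  expect_equal(composite_log_likelihood(x, matrix(1, 3, 1), m11),
               sum(dnorm(x, 0.3, 1.2, log = TRUE)))

  # matches the naive double-loop oracle on small matrices (1e-10)
  for (rep in 1:8) {
    n <- sample(2:3, 1); m <- sample(2:3, 1)
    x <- matrix(rnorm(n * m, sd = 2), n, m)
    prior <- matrix(runif(n * 2), n, 2); prior <- prior / rowSums(prior)
    pi <- as.numeric(rdirichlet1(2))
    mu <- matrix(rnorm(4), 2, 2)
    sg <- matrix(runif(4, 0.5, 2), 2, 2)
    mod <- block_model(pi, mu, sg)
    expect_equal(composite_log_likelihood(x, prior, mod),
                 oracle_logcl(x, prior, pi, mu, sg), tolerance = 1e-10)
  }

  # label-permutation invariance and location equivariance
  x <- matrix(rnorm(20), 4, 5)
  prior <- cbind(c(0.7, 0.3, 0.7, 0.3), c(0.3, 0.7, 0.3, 0.7))
  mod <- block_model(c(0.4, 0.6), matrix(c(-1, 0, 1, 2), 2, 2),
                     matrix(c(1, 0.8, 1.2, 0.9), 2, 2))
  perm <- block_model(mod$pi[2:1], mod$mu[, 2:1], mod$sigma[, 2:1])
  expect_equal(composite_log_likelihood(x, prior, mod),
               composite_log_likelihood(x, prior, perm))
  shift <- block_model(mod$pi, mod$mu + 5, mod$sigma)
  expect_equal(composite_log_likelihood(x, prior, mod),
               composite_log_likelihood(x + 5, prior, shift))
})

test_that("E step matches direct Bayes computation and limits", {
  set.seed(11)
  x <- matrix(rnorm(12, sd = 2), 3, 4)
  prior <- matrix(runif(6), 3, 2); prior <- prior / rowSums(prior)
  mod <- block_model(c(0.3, 0.7), matrix(c(-2, 0, 1, 3), 2, 2),
                     matrix(c(1, 1.5, 0.7, 1.1), 2, 2))
  w <- e_step(x, prior, mod, return_joint = TRUE)
  want <- oracle_joint(x, prior, mod$pi, mod$mu, mod$sigma)
  expect_equal(w$joint, want, tolerance = 1e-10)
  expect_equal(w$row_post, apply(want, c(1, 3), sum) / ncol(x),
               tolerance = 1e-10)
  expect_equal(w$col_post, apply(want, c(2, 4), sum) / nrow(x),
               tolerance = 1e-10)
  expect_equal(unname(rowSums(w$row_post)), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(rowSums(w$col_post)), rep(1, 4), tolerance = 1e-8)

  # full symmetry: uniform everything -> uniform posteriors
  uni <- block_model(c(0.5, 0.5), matrix(0, 2, 2), matrix(1, 2, 2))
  wu <- e_step(x, matrix(0.5, 3, 2), uni)
  expect_equal(unname(wu$row_post), matrix(0.5, 3, 2))
  expect_equal(unname(wu$col_post), matrix(0.5, 4, 2))

  # separation limit: posteriors are one-hot on the generating labels
  mu <- rbind(c(-20, 0), c(20, 40))
  dat <- make_block_data(10, 12, mu, sigma = 0.5, seed = 3)
  pr <- cbind(as.numeric(dat$z == 1), as.numeric(dat$z == 2)) * 0.98 + 0.01
  ws <- e_step(dat$x, pr, block_model(c(0.5, 0.5), mu, matrix(0.5, 2, 2)))
  expect_true(all(abs(ws$col_post[cbind(seq_along(dat$w), dat$w)] - 1) < 1e-6))
  expect_true(all(abs(ws$row_post[cbind(seq_along(dat$z), dat$z)] - 1) < 1e-6))
})

test_that("M step reduces to block statistics under hard weights", {
  set.seed(5)
  mu <- rbind(c(-3, 1), c(2, 5))
  n <- 8; m <- 10
  z <- rep(1:2, each = n / 2)                 # every block occupied
  w <- rep(1:2, length.out = m)
  dat <- list(x = mu[z, w] + matrix(rnorm(n * m), n, m), z = z, w = w)
  joint <- array(0, c(n, m, 2, 2))
  for (i in 1:n) for (j in 1:m) joint[i, j, dat$z[i], dat$w[j]] <- 1
  prior <- matrix(0.5, n, 2)
  fit <- m_step(dat$x, weights_from_joint_(dat$x, joint), prior)
  for (k in 1:2) for (l in 1:2) {
    cells <- dat$x[dat$z == k, dat$w == l]
    expect_equal(fit$mu[k, l], mean(cells))
    expect_equal(fit$sigma[k, l], sqrt(mean((cells - mean(cells))^2)))
  }
  expect_equal(fit$pi, tabulate(dat$w, 2) / m)

  # uniform weights: every block mean is the grand mean
  joint[] <- 0.25
  fitu <- m_step(dat$x, weights_from_joint_(dat$x, joint), prior)
  expect_equal(unname(fitu$mu), matrix(mean(dat$x), 2, 2))
})

test_that("M step output is a stationary point of the surrogate", {
  set.seed(13)
  n <- 4; m <- 5
  x <- matrix(rnorm(n * m, sd = 2), n, m)
  prior <- matrix(runif(n * 2), n, 2); prior <- prior / rowSums(prior)
  joint <- array(runif(n * m * 4), c(n, m, 2, 2))
  tot <- apply(joint, c(1, 2), sum)
  joint <- sweep(joint, c(1, 2), tot, "/")
  fit <- m_step(x, weights_from_joint_(x, joint), prior)

  # numerical gradient wrt every mu_kl and sigma_kl is ~ 0
  h <- 1e-5
  for (k in 1:2) for (l in 1:2) {
    mup <- fit$mu; mum <- fit$mu
    mup[k, l] <- mup[k, l] + h; mum[k, l] <- mum[k, l] - h
    g_mu <- (surrogate_Q(x, joint, prior, fit$pi, mup, fit$sigma) -
               surrogate_Q(x, joint, prior, fit$pi, mum, fit$sigma)) / (2 * h)
    expect_lt(abs(g_mu), 1e-6)
    sgp <- fit$sigma; sgm <- fit$sigma
    sgp[k, l] <- sgp[k, l] + h; sgm[k, l] <- sgm[k, l] - h
    g_sg <- (surrogate_Q(x, joint, prior, fit$pi, fit$mu, sgp) -
               surrogate_Q(x, joint, prior, fit$pi, fit$mu, sgm)) / (2 * h)
    expect_lt(abs(g_sg), 1e-6)
  }
  # pi optimum has the closed form: average joint cluster mass
  mass <- c(sum(joint[, , , 1]), sum(joint[, , , 2]))
  expect_equal(fit$pi, mass / (n * m))
})

test_that("EM ascends monotonically and is deterministic given the seed", {
  mu <- rbind(c(-2, 0, 2), c(-1, 1, 3))
  for (s in 1:20) {
    dat <- make_block_data(15, 20, mu, sigma = 1, seed = s)
    pr <- matrix(0.5, 15, 2)
    fit <- fit_em(dat$x, pr, L = 3, n_starts = 1, seed = s, max_iter = 60)
    expect_true(all(diff(fit$trace) > -1e-8))
    expect_equal(fit$logcl, fit$trace[length(fit$trace)])
  }
  dat <- make_block_data(15, 20, mu, sigma = 1, seed = 99)
  f1 <- fit_em(dat$x, matrix(0.5, 15, 2), L = 3, n_starts = 3, seed = 4)
  f2 <- fit_em(dat$x, matrix(0.5, 15, 2), L = 3, n_starts = 3, seed = 4)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$trace, f2$trace)
})

test_that("trivial single-block EM converges immediately to mean and SD", {
  set.seed(21)
  x <- matrix(rnorm(50, 3, 2), 5, 10)
  fit <- fit_em(x, matrix(1, 5, 1), K = 1, L = 1, n_starts = 1, seed = 1)
  expect_lte(fit$n_iter, 3)
  expect_equal(fit$model$mu[1, 1], mean(x), tolerance = 1e-6)
  expect_equal(fit$model$sigma[1, 1], sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-6)
})

test_that("EM recovers generating block means and labels under separation", {
  mu <- rbind(c(-3, 0, 3), c(-2, 1, 4))
  dat <- make_block_data(60, 120, mu, sigma = 1, seed = 17)
  pr <- cbind(as.numeric(dat$z == 1), as.numeric(dat$z == 2)) * 0.9 + 0.05
  fit <- fit_em(dat$x, pr, L = 3, n_starts = 3, seed = 2)
  # canonical order sorts by mu[1, ], matching the generating order
  se <- fit$model$sigma / sqrt(pmax(fit$weights$S0, 1))
  expect_true(all(abs(fit$model$mu - mu) < 3 * se + 0.05))
  lab <- assign_labels(fit)
  expect_gte(mean(lab$col == dat$w), 0.95)
})

test_that("mu estimates are unbiased over repeated replicates", {
  # separation regime: 2 sigma genotype gap, 3 sigma cluster spacing
  mu <- rbind(c(-3, 0, 3), c(-1, 2, 5))
  est <- array(NA_real_, c(2, 3, 50))
  for (s in 1:50) {
    dat <- make_block_data(60, 120, mu, sigma = 1, seed = 100 + s)
    pr <- cbind(as.numeric(dat$z == 1), as.numeric(dat$z == 2)) * 0.9 + 0.05
    fit <- fit_em(dat$x, pr, L = 3, n_starts = 1, seed = s)
    est[, , s] <- fit$model$mu
  }
  bias <- apply(est, c(1, 2), mean) - mu
  expect_true(all(abs(bias) < 0.05))
})

test_that("MAP assignment breaks ties toward the lowest index", {
  w <- structure(list(row_post = rbind(c(0.5, 0.5), c(0.2, 0.8)),
                      col_post = rbind(c(1, 0), c(0.5, 0.5), c(0, 1))),
                 class = "cl_weights")
  lab <- assign_labels(w)
  expect_equal(lab$row, c(1L, 2L))           # exact tie -> label 1
  expect_equal(lab$col, c(1L, 1L, 2L))
})

test_that("degenerate inputs are rejected with informative errors", {
  x <- matrix(rnorm(12), 3, 4)
  expect_error(block_model(c(0.5, 0.6), matrix(0, 2, 2), 1), "sum to 1")
  expect_error(block_model(c(0.5, 0.5), matrix(0, 2, 2), -1), "positive")
  bad_prior <- matrix(c(0.6, 0.6), 3, 2)
  expect_error(composite_log_likelihood(x, bad_prior,
                                        block_model(1, matrix(0), matrix(1))),
               "sum to 1")
})
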
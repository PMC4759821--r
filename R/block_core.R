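# Gaussian block mixture core: composite likelihood, two-layer EM,
# posterior weights and MAP labels.

#' Construct a block mixture model
#'
#' Parameters of the Gaussian block mixture: cluster proportions `pi`
#' (length `L`), block means `mu` and block standard deviations `sigma`
#' (both `K x L`). Under `variance = "pooled"` a single standard deviation
#' is shared by all blocks (still stored as a `K x L` matrix of equal
#' entries).
#'
#' @param pi Cluster proportions, positive, summing to 1.
#' @param mu `K x L` matrix of block means.
#' @param sigma `K x L` matrix (or scalar, recycled) of block SDs, all
#'   positive.
#' @param variance `"block"` (one SD per block) or `"pooled"`.
#' @return A `block_model` object.
#' @export
block_model <- function(pi, mu, sigma, variance = c("block", "pooled")) {
  variance <- match.arg(variance)
  mu <- as.matrix(mu)
  if (length(sigma) == 1L) sigma <- matrix(sigma, nrow(mu), ncol(mu))
  sigma <- as.matrix(sigma)
  pi <- as.numeric(pi)
  if (length(pi) != ncol(mu) || !all(dim(sigma) == dim(mu)))
    stop("inconsistent shapes: pi has length ", length(pi),
         ", mu is ", nrow(mu), "x", ncol(mu),
         ", sigma is ", nrow(sigma), "x", ncol(sigma))
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("cluster proportions must be positive and sum to 1")
  if (any(sigma <= 0) || any(!is.finite(sigma)) || any(!is.finite(mu)))
    stop("block means must be finite and SDs positive")
  structure(list(K = nrow(mu), L = ncol(mu), pi = pi, mu = mu, sigma = sigma,
                 variance = variance),
            class = "block_model")
}

#' @export
print.block_model <- function(x, ...) {
  cat("Gaussian block mixture model: K =", x$K, "genotypes, L =", x$L,
      "clusters,", x$variance, "variance\n")
  cat("pi:", signif(x$pi, 4), "\n")
  cat("mu (K x L):\n"); print(signif(x$mu, 4))
  invisible(x)
}

# Seeded functions must not disturb the caller's RNG stream (they are
# called inside permutation and replicate loops): snapshot .Random.seed,
# restore on exit.
preserve_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

check_expression <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("expression matrix must be numeric with finite entries")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("expression matrix needs at least 2 individuals and 2 transcripts")
  x
}

cell_stats <- function(x, prior, model, want_stats = TRUE) {
  st <- .cl_cell_stats(x, log(prior), log(model$pi), model$mu, model$sigma,
                       want_stats)
  if (!is.finite(st$logcl))
    stop("composite log-likelihood is not finite; degenerate sigma or ",
         "zero mixture mass")
  st
}

#' Composite log-likelihood of a block mixture model
#'
#' Evaluates
#' \deqn{\sum_i \sum_j \log \sum_{k=1}^{K} \sum_{l=1}^{L}
#'       p_{ik}\, \pi_l\, \phi(x_{ij}; \mu_{kl}, \sigma_{kl}),}
#' the per-cell composite likelihood in which every matrix cell contributes
#' the marginal mixture density over its latent (genotype, cluster) block.
#' Computed in log space with a log-sum-exp per cell.
#'
#' @param x Expression matrix, individuals x transcripts.
#' @param prior Genotype prior, n x K, rows summing to 1 (see
#'   [genotype_prior()] / [uniform_prior()]).
#' @param model A [block_model()].
#' @return The composite log-likelihood (scalar).
#' @export
composite_log_likelihood <- function(x, prior, model) {
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  if (ncol(prior) != model$K)
    stop("prior has ", ncol(prior), " genotype columns but model K = ", model$K)
  cell_stats(x, prior, model, want_stats = FALSE)$logcl
}

#' E step of the two-layer EM
#'
#' Computes the per-cell joint responsibilities
#' \eqn{t_{ijkl} \propto p_{ik} \pi_l \phi(x_{ij}; \mu_{kl}, \sigma_{kl})}
#' of the composite-likelihood surrogate, and returns their block sums
#' (`S0`, `S1`, `S2`, the zeroth/first/second weighted moments used by the
#' M step) together with the row- and column-marginal posteriors
#' (`row_post`: n x K, `col_post`: m x L; each averaged over the other
#' dimension, rows summing to 1).
#'
#' @inheritParams composite_log_likelihood
#' @param return_joint If `TRUE`, also return the full n x m x K x L joint
#'   responsibility array (intended for small problems and checks).
#' @return A `cl_weights` list with `row_post`, `col_post`, `S0`, `S1`,
#'   `S2`, `logcl` and optionally `joint`.
#' @export
e_step <- function(x, prior, model, return_joint = FALSE) {
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  st <- cell_stats(x, prior, model)
  w <- structure(list(row_post = st$row_post, col_post = st$col_post,
                      S0 = st$S0, S1 = st$S1, S2 = st$S2, logcl = st$logcl),
                 class = "cl_weights")
  if (return_joint) {
    n <- nrow(x); m <- ncol(x); K <- model$K; L <- model$L
    lj <- array(NA_real_, c(n, m, K, L))
    for (k in seq_len(K)) for (l in seq_len(L))
      lj[, , k, l] <- log(prior[, k]) + log(model$pi[l]) +
        dnorm(x, model$mu[k, l], model$sigma[k, l], log = TRUE)
    mx <- apply(lj, c(1, 2), max)
    t <- exp(sweep(lj, c(1, 2), mx, "-"))
    tot <- apply(t, c(1, 2), sum)
    w$joint <- sweep(t, c(1, 2), tot, "/")
  }
  w
}

# Builds a cl_weights object from an explicit joint responsibility array
# (n x m x K x L); used to drive the M step with arbitrary weights.
weights_from_joint <- function(x, joint) {
  x <- as.matrix(x)
  d <- dim(joint)
  stopifnot(length(d) == 4, d[1] == nrow(x), d[2] == ncol(x))
  K <- d[3]; L <- d[4]
  S0 <- matrix(0, K, L); S1 <- S0; S2 <- S0
  for (k in seq_len(K)) for (l in seq_len(L)) {
    t <- joint[, , k, l]
    S0[k, l] <- sum(t)
    S1[k, l] <- sum(t * x)
    S2[k, l] <- sum(t * x^2)
  }
  row_post <- apply(joint, c(1, 3), sum) / ncol(x)
  col_post <- apply(joint, c(2, 4), sum) / nrow(x)
  structure(list(row_post = row_post, col_post = col_post,
                 S0 = S0, S1 = S1, S2 = S2, logcl = NA_real_, joint = joint),
            class = "cl_weights")
}

#' M step of the two-layer EM
#'
#' Maximises the composite-likelihood surrogate given responsibilities:
#' \eqn{\pi_l} is the average column posterior, block means are the
#' responsibility-weighted cell means and block SDs the weighted SDs (or a
#' single pooled SD). The genotype prior `p_ik` is held fixed throughout and
#' never re-estimated. Optional equality constraints on the means implement
#' the nulls of the composite-LR tests.
#'
#' @param x Expression matrix.
#' @param weights A `cl_weights` object from [e_step()] (or
#'   `weights_from_joint`).
#' @param prior Genotype prior (fixed; carried through for shape checks).
#' @param variance `"block"` or `"pooled"`.
#' @param constraint `NULL`, or a list: `list(type = "equal_means_cluster",
#'   cluster = l)` forces \eqn{\mu_{1l} = \mu_{2l}} for one cluster;
#'   `list(type = "additive")` forces a common genotype shift
#'   \eqn{\mu_{kl} = a_l + g_k} (K = 2 only). Constrained mean updates use
#'   the current SDs as weights (conditional maximisation).
#' @param sigma_prev `K x L` SDs of the current model, required by
#'   constrained updates; defaults to pooled unit weights.
#' @param sigma_floor Lower bound for SDs (guards degenerate blocks).
#' @return A [block_model()].
#' @export
m_step <- function(x, weights, prior, variance = c("block", "pooled"),
                   constraint = NULL, sigma_prev = NULL,
                   sigma_floor = NULL) {
  variance <- match.arg(variance)
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (!is.null(weights$joint) && is.na(weights$logcl[1]))
    weights <- weights_from_joint(x, weights$joint)
  S0 <- weights$S0; S1 <- weights$S1; S2 <- weights$S2
  K <- nrow(S0); L <- ncol(S0)
  if (is.null(sigma_floor)) sigma_floor <- 1e-4 * max(sd(x), 1e-12)

  mass <- colSums(S0)                     # per-cluster responsibility mass
  if (any(mass < 1e-9 * n * m))
    stop(errorCondition(
      paste0("cluster collapsed (responsibility mass ~ 0 for cluster ",
             paste(which(mass < 1e-9 * n * m), collapse = ", "),
             "); re-initialise"),
      class = c("blockeqtl_collapse", "error", "condition")))

  pi_new <- mass / (n * m)
  pi_new <- pi_new / sum(pi_new)

  W <- pmax(S0, 1e-300)
  mu <- S1 / W
  if (!is.null(constraint)) {
    sp <- if (is.null(sigma_prev)) matrix(1, K, L) else as.matrix(sigma_prev)
    if (constraint$type == "equal_means_cluster") {
      l <- constraint$cluster
      if (l < 1 || l > L) stop("cluster index out of range: ", l)
      mu[, l] <- sum(S1[, l]) / sum(W[, l])
    } else if (constraint$type == "additive") {
      if (K != 2) stop("additive constraint requires K = 2")
      # weighted LS for mu_1l = a_l + c, mu_2l = a_l given current SDs
      xb <- S1 / W
      u <- W[1, ] / sp[1, ]^2
      v <- W[2, ] / sp[2, ]^2
      h <- u * v / (u + v)
      cc <- sum(h * (xb[1, ] - xb[2, ])) / sum(h)
      a <- (u * (xb[1, ] - cc) + v * xb[2, ]) / (u + v)
      mu <- rbind(a + cc, a)
    } else stop("unknown constraint type: ", constraint$type)
  }

  ss <- S2 - 2 * mu * S1 + mu^2 * S0       # weighted residual SS per block
  if (variance == "block") {
    sigma <- sqrt(pmax(ss / W, sigma_floor^2))
  } else {
    sigma <- matrix(sqrt(max(sum(ss) / (n * m), sigma_floor^2)), K, L)
  }
  block_model(pi_new, mu, sigma, variance)
}

# Initial model from hard column labels w0 and the genotype prior:
# mu_kl = prior-weighted mean of cluster-l cells, shared within-cluster SD.
init_from_labels <- function(x, prior, w0, L, variance) {
  n <- nrow(x); K <- ncol(prior)
  pi0 <- tabulate(w0, L)
  pi0 <- pmax(pi0, 0.5) / sum(pmax(pi0, 0.5))
  mu <- matrix(0, K, L)
  pk <- colSums(prior)
  for (l in seq_len(L)) {
    jl <- which(w0 == l)
    if (!length(jl)) { mu[, l] <- mean(x); next }
    xs <- rowSums(x[, jl, drop = FALSE])
    mu[, l] <- colSums(prior * xs) / (pk * length(jl))
  }
  res <- x - mu[max.col(prior, "first"), w0, drop = FALSE]
  # residual spread after removing the block-mean structure
  s0 <- max(sqrt(mean(res^2)), 1e-3 * max(sd(x), 1e-12))
  block_model(pi0, mu, matrix(s0, K, L), variance)
}

# Reorders clusters so mu[1, ] is ascending (canonical label order).
canonicalize <- function(model) {
  o <- order(model$mu[1, ])
  block_model(model$pi[o], model$mu[, o, drop = FALSE],
              model$sigma[, o, drop = FALSE], model$variance)
}

reorder_weights <- function(weights, o) {
  weights$col_post <- weights$col_post[, o, drop = FALSE]
  weights$S0 <- weights$S0[, o, drop = FALSE]
  weights$S1 <- weights$S1[, o, drop = FALSE]
  weights$S2 <- weights$S2[, o, drop = FALSE]
  weights
}

run_em <- function(x, prior, start, variance, constraint, tol, max_iter,
                   sigma_floor) {
  model <- start
  trace <- numeric(0)
  converged <- FALSE
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- cell_stats(x, prior, model)
    trace <- c(trace, st$logcl)
    if (it > 1 &&
        abs(trace[it] - trace[it - 1]) < tol * (1 + abs(trace[it]))) {
      converged <- TRUE
      break
    }
    model <- m_step(x, st, prior, variance, constraint,
                    sigma_prev = model$sigma, sigma_floor = sigma_floor)
  }
  if (!converged) {                         # sync logcl/weights with model
    st <- cell_stats(x, prior, model)
    trace <- c(trace, st$logcl)
  }
  weights <- structure(list(row_post = st$row_post, col_post = st$col_post,
                            S0 = st$S0, S1 = st$S1, S2 = st$S2,
                            logcl = st$logcl),
                       class = "cl_weights")
  list(model = model, weights = weights, logcl = trace[length(trace)],
       trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit the block mixture model by two-layer EM
#'
#' Alternates the [e_step()] and [m_step()] until the composite
#' log-likelihood changes by less than `tol` (relative). The first start
#' initialises column clusters by k-means on transcript profiles and block
#' means from the genotype prior; the remaining `n_starts - 1` starts
#' perturb the k-means solution. The best start by final composite
#' log-likelihood is returned, with clusters re-ordered so that
#' \eqn{\mu_{1l}} is ascending (unconstrained fits only, so reported
#' cluster labels are reproducible).
#'
#' @inheritParams composite_log_likelihood
#' @param K Number of genotype classes (must equal `ncol(prior)`).
#' @param L Number of transcript clusters.
#' @param n_starts Number of EM initialisations.
#' @param tol Relative convergence tolerance on the composite
#'   log-likelihood.
#' @param max_iter Maximum EM iterations per start.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param variance `"block"` or `"pooled"`.
#' @param constraint Mean constraint passed to [m_step()] (used by the
#'   hypothesis tests).
#' @param init Optional [block_model()] used as a warm start; if supplied it
#'   replaces the k-means start.
#' @return A `block_fit` list: `model`, `weights`, `logcl`, `trace`
#'   (nondecreasing), `converged`, `n_iter`, `seed`.
#' @export
fit_em <- function(x, prior, K = ncol(prior), L, n_starts = 5L, tol = 1e-6,
                   max_iter = 500L, seed = 1L,
                   variance = c("block", "pooled"), constraint = NULL,
                   init = NULL) {
  variance <- match.arg(variance)
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  if (K != ncol(prior))
    stop("K = ", K, " but prior has ", ncol(prior), " columns")
  if (L < 1 || n_starts < 1) stop("L and n_starts must be >= 1")
  sigma_floor <- 1e-4 * max(sd(x), 1e-12)

  # start 1: k-means on transcript profiles (multi-restart); further starts
  # re-run k-means from fresh random centers so they explore genuinely
  # different column partitions
  starts <- vector("list", n_starts)
  old_rng <- preserve_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    if (s == 1L && !is.null(init)) { starts[[1]] <- init; next }
    w0 <- tryCatch({
      if (L == 1L) rep(1L, ncol(x))
      else kmeans(t(x), centers = L, nstart = if (s == 1L) 5 else 1,
                  iter.max = 50)$cluster
    }, error = function(e) sample.int(L, ncol(x), replace = TRUE))
    starts[[s]] <- init_from_labels(x, prior, w0, L, variance)
  }

  best <- NULL
  fails <- character(0)
  for (s in seq_len(n_starts)) {
    res <- tryCatch(
      run_em(x, prior, starts[[s]], variance, constraint, tol, max_iter,
             sigma_floor),
      blockeqtl_collapse = function(e) e)
    if (inherits(res, "condition")) {
      fails <- c(fails, paste0("start ", s, ": ", conditionMessage(res)))
      next
    }
    if (is.null(best) || res$logcl > best$logcl) best <- res
  }
  if (is.null(best))
    stop("all EM starts collapsed:\n", paste(fails, collapse = "\n"))

  if (is.null(constraint) && L > 1) {
    o <- order(best$model$mu[1, ])
    best$model <- canonicalize(best$model)
    best$weights <- reorder_weights(best$weights, o)
  }
  best$seed <- seed
  best$K <- K; best$L <- L; best$variance <- variance
  class(best) <- "block_fit"
  best
}

#' @export
print.block_fit <- function(x, ...) {
  cat("Block mixture fit: K =", x$K, ", L =", x$L,
      "| logCL =", format(x$logcl, digits = 8),
      "|", x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}

#' MAP label assignment from posterior weights
#'
#' Assigns every individual to its maximum-a-posteriori genotype class and
#' every transcript to its MAP cluster. Ties are broken toward the lowest
#' index.
#'
#' @param weights A `cl_weights` object (from [e_step()]) or a `block_fit`.
#' @return A list with integer vectors `row` (length n, values in 1..K) and
#'   `col` (length m, values in 1..L).
#' @export
assign_labels <- function(weights) {
  if (inherits(weights, "block_fit")) weights <- weights$weights
  list(row = max.col(weights$row_post, ties.method = "first"),
       col = max.col(weights$col_post, ties.method = "first"))
}
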
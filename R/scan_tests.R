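# Genome-wide eQTL scan over candidate positions, permutation thresholds,
# and the four composite likelihood ratio tests.

null_expanded <- function(null_fit, K, variance) {
  mu <- null_fit$model$mu[rep(1L, K), , drop = FALSE]
  sg <- null_fit$model$sigma[rep(1L, K), , drop = FALSE]
  block_model(null_fit$model$pi, mu, sg, variance)
}

# Scans one list of per-position priors against a fixed null fit, warm
# starting each position from the previous one (chains reset at group
# boundaries via `reset`). Any position whose CLR would come out negative
# is refit from the null-expanded model, which starts the EM exactly at the
# K-collapsed optimum and therefore ends at CLR >= 0.
scan_core <- function(x, priors, reset, L, null_fit, init_models = NULL,
                      tol = 1e-6, max_iter = 500L, variance = "block") {
  K <- 2L
  ne <- null_expanded(null_fit, K, variance)
  P <- length(priors)
  logcl <- numeric(P)
  models <- vector("list", P)
  prev <- NULL
  for (p in seq_len(P)) {
    if (reset[p]) prev <- NULL
    init <- if (!is.null(init_models)) init_models[[p]] else prev
    if (is.null(init)) init <- ne
    fit <- fit_em(x, priors[[p]], K = K, L = L, n_starts = 1L, tol = tol,
                  max_iter = max_iter, variance = variance, init = init)
    if (fit$logcl < null_fit$logcl) {
      fit2 <- fit_em(x, priors[[p]], K = K, L = L, n_starts = 1L, tol = tol,
                     max_iter = max_iter, variance = variance, init = ne)
      if (fit2$logcl > fit$logcl) fit <- fit2
    }
    logcl[p] <- fit$logcl
    models[[p]] <- fit$model
    prev <- fit$model
  }
  list(logcl = logcl, models = models,
       clr = pmax(2 * (logcl - null_fit$logcl), 0))
}

#' Genome-wide eQTL scan for cluster-level genetic effects
#'
#' Slides a candidate eQTL along each linkage group (grid of `step` cM plus
#' every marker), computes the interval-mapping genotype prior at each
#' position, fits the full block mixture (`K = 2`, `L` clusters) and
#' compares it to the position-independent genotype-collapsed null
#' (`K = 1`, fitted once) through the composite likelihood ratio
#' \eqn{\mathrm{CLR} = 2(\ell_c^{full} - \ell_c^{null})}. The position with
#' the largest CLR estimates the eQTL location.
#'
#' @inheritParams fit_em
#' @param map A [genetic_map()].
#' @param geno Genotype matrix (individuals x markers, codes 0/1/NA).
#' @param L Number of transcript clusters (typically from [select_L()]).
#' @param step Scan grid step in cM.
#' @return An `eqtl_scan` list: `table` (group, pos_cM, logcl_full,
#'   logcl_null, clr), `peak` (group, pos_cM, clr at the maximum), `null_fit`,
#'   `peak_fit` (full `block_fit` at the peak), `models` (per-position
#'   fitted [block_model()]s), and the scan settings.
#' @export
scan_genome <- function(x, map, geno, L, step = 1, n_starts = 5L,
                        tol = 1e-6, max_iter = 500L, seed = 1L,
                        variance = c("block", "pooled")) {
  variance <- match.arg(variance)
  x <- check_expression(x)
  geno <- align_genotypes(geno, map)
  if (nrow(geno) != nrow(x))
    stop("expression and genotype matrices disagree on individual count")
  grid <- scan_positions(map, step)
  priors <- lapply(seq_len(nrow(grid)), function(p)
    genotype_prior(map, geno, grid$group[p], grid$pos_cM[p]))
  reset <- c(TRUE, grid$group[-1] != grid$group[-nrow(grid)])

  null_fit <- fit_em(x, matrix(1, nrow(x), 1), K = 1L, L = L,
                     n_starts = n_starts, tol = tol, max_iter = max_iter,
                     seed = seed, variance = variance)
  sc <- scan_core(x, priors, reset, L, null_fit, tol = tol,
                  max_iter = max_iter, variance = variance)

  tab <- data.frame(group = grid$group, pos_cM = grid$pos_cM,
                    logcl_full = sc$logcl, logcl_null = null_fit$logcl,
                    clr = sc$clr, stringsAsFactors = FALSE)
  pk <- which.max(tab$clr)
  peak_fit <- fit_em(x, priors[[pk]], K = 2L, L = L, n_starts = 1L,
                     tol = tol, max_iter = max_iter, variance = variance,
                     init = sc$models[[pk]])
  structure(list(table = tab,
                 peak = list(group = tab$group[pk], pos_cM = tab$pos_cM[pk],
                             clr = tab$clr[pk]),
                 null_fit = null_fit, peak_fit = peak_fit,
                 models = sc$models,
                 settings = list(L = L, step = step, n_starts = n_starts,
                                 tol = tol, max_iter = max_iter, seed = seed,
                                 variance = variance)),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("eQTL scan over", nrow(x$table), "positions | peak: group",
      x$peak$group, "at", x$peak$pos_cM, "cM, CLR =",
      format(x$peak$clr, digits = 6), "\n")
  invisible(x)
}

#' Genome-wide permutation threshold for the scan statistic
#'
#' Breaks the genotype-expression linkage by permuting individual rows of
#' the genotype data against the (fixed) expression rows, re-runs the scan
#' for every permutation, and records each permutation's genome-wide
#' maximum CLR. The threshold is the empirical `1 - alpha` quantile (order
#' statistic) of those maxima. Every permuted scan repeats the observed
#' scan's optimisation procedure exactly (chained warm starts along the
#' grid from the genotype-collapsed fit), so observed and permuted
#' statistics are comparable.
#'
#' @inheritParams scan_genome
#' @param n_perm Number of permutations (>= 20; >= 100 recommended).
#' @param alpha Genome-wide significance level.
#' @param scan Optional precomputed [scan_genome()] result on the same data
#'   and settings (avoids one scan).
#' @return A `perm_threshold` list: `threshold`, `max_clr` (one per
#'   permutation), `alpha`, `n_perm`, `observed` (the observed peak CLR).
#' @export
permutation_threshold <- function(x, map, geno, L, n_perm = 100L,
                                  alpha = 0.05, seed = 1L, step = 1,
                                  n_starts = 5L, tol = 1e-6, max_iter = 500L,
                                  variance = c("block", "pooled"),
                                  scan = NULL) {
  variance <- match.arg(variance)
  if (n_perm < 20) stop("n_perm must be >= 20 for a usable quantile")
  x <- check_expression(x)
  geno <- align_genotypes(geno, map)
  if (is.null(scan))
    scan <- scan_genome(x, map, geno, L, step = step, n_starts = n_starts,
                        tol = tol, max_iter = max_iter, seed = seed,
                        variance = variance)
  grid <- scan$table
  priors <- lapply(seq_len(nrow(grid)), function(p)
    genotype_prior(map, geno, grid$group[p], grid$pos_cM[p]))
  reset <- c(TRUE, grid$group[-1] != grid$group[-nrow(grid)])

  # Permuted scans reuse the observed per-position fits as warm starts;
  # each fit still ascends to its own permutation's optimum (checked
  # against cold chained restarts), so this trades only time. The scan's
  # negative-CLR guard refits from the genotype-collapsed model.
  old_rng <- preserve_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  max_clr <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(x))
    priors_b <- lapply(priors, function(p) p[perm, , drop = FALSE])
    sc <- scan_core(x, priors_b, reset, L, scan$null_fit,
                    init_models = scan$models, tol = tol,
                    max_iter = max_iter, variance = variance)
    max_clr[b] <- max(sc$clr)
  }
  structure(list(threshold = quantile(max_clr, probs = 1 - alpha, type = 1,
                                      names = FALSE),
                 max_clr = max_clr, alpha = alpha, n_perm = n_perm,
                 observed = scan$peak$clr),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat("Genome-wide permutation threshold (alpha =", x$alpha, ",", x$n_perm,
      "permutations):", format(x$threshold, digits = 6),
      "| observed peak CLR:", format(x$observed, digits = 6), "\n")
  invisible(x)
}

# --- composite-LR hypothesis tests -----------------------------------------

clr_stat <- function(logcl_full, logcl_null) max(2 * (logcl_full - logcl_null), 0)

# Projection of a full model onto a mean constraint, used to initialise the
# constrained refit so the constrained EM starts inside the null space and
# cluster identities stay aligned with the full fit.
project_model <- function(model, constraint) {
  mu <- model$mu
  if (constraint$type == "equal_means_cluster") {
    l <- constraint$cluster
    mu[, l] <- mean(mu[, l])
  } else if (constraint$type == "additive") {
    cc <- mean(mu[1, ] - mu[2, ])
    a <- (mu[1, ] + mu[2, ] - cc) / 2
    mu <- rbind(a + cc, a)
  }
  block_model(model$pi, mu, model$sigma, model$variance)
}

constrained_refit <- function(x, prior, fit_full, constraint, tol, max_iter) {
  fit_em(x, prior, K = fit_full$K, L = fit_full$L, n_starts = 1L, tol = tol,
         max_iter = max_iter, variance = fit_full$variance,
         constraint = constraint, init = project_model(fit_full$model,
                                                       constraint))
}

# If a constrained refit lands above the full fit (full fit stuck in a
# local optimum), promote the constrained solution to a full warm start.
ensure_nesting <- function(x, prior, fit_full, fit_con, tol, max_iter) {
  if (fit_con$logcl > fit_full$logcl + 1e-9) {
    f2 <- fit_em(x, prior, K = fit_full$K, L = fit_full$L, n_starts = 1L,
                 tol = tol, max_iter = max_iter, variance = fit_full$variance,
                 init = fit_con$model)
    if (f2$logcl > fit_full$logcl) fit_full <- f2
  }
  list(full = fit_full, con = fit_con)
}

# Permutation p-value at a fixed position. Permuted full fits start from
# the same constraint-satisfying model the observed optimisation would use
# (never from the observed optimum, whose basin would swallow every
# permutation), so permuted and observed CLRs are comparable.
perm_pvalue <- function(x, prior, fit_full, constraint, obs_clr, n_perm,
                        seed, tol, max_iter, null_fit = NULL) {
  if (n_perm <= 0) return(NA_real_)
  base <- if (!is.null(null_fit)) null_expanded(null_fit, fit_full$K,
                                                fit_full$variance)
          else project_model(fit_full$model, constraint)
  old_rng <- preserve_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample.int(nrow(x))
    pb <- prior[perm, , drop = FALSE]
    fb <- fit_em(x, pb, K = fit_full$K, L = fit_full$L, n_starts = 1L,
                 tol = tol, max_iter = max_iter,
                 variance = fit_full$variance, init = base)
    lb_null <- if (!is.null(null_fit)) null_fit$logcl else
      constrained_refit(x, pb, fb, constraint, tol, max_iter)$logcl
    if (clr_stat(fb$logcl, lb_null) >= obs_clr) exceed <- exceed + 1L
  }
  (1 + exceed) / (1 + n_perm)
}

new_clr_test <- function(test, clr, p_value, ...) {
  structure(c(list(test = test, clr = clr, p_value = p_value), list(...)),
            class = "clr_test")
}

#' @export
print.clr_test <- function(x, ...) {
  cat("Composite-LR test [", x$test, "]: CLR =", format(x$clr, digits = 6),
      if (!is.na(x$p_value)) paste(", permutation p =", format(x$p_value)),
      "\n")
  invisible(x)
}

#' Test whether an eQTL affects the expression of at least one cluster
#'
#' H0: \eqn{\mu_{1l} = \mu_{2l}} for every cluster `l`, i.e. the genotype
#' classes collapse (`K = 1`). The statistic equals the scan CLR at the
#' same position. Significance is judged against the genome-wide
#' permutation threshold or, when `n_perm > 0` and the data are supplied,
#' a position-level permutation p-value.
#'
#' @param fit_full Full `block_fit` (`K = 2`) at the candidate position.
#' @param fit_null Genotype-collapsed `block_fit` (`K = 1`, same `L`).
#' @param x,prior Optional data and genotype prior, required for the
#'   permutation p-value.
#' @param n_perm Number of permutations for the p-value (0 = skip).
#' @param seed Seed for the permutations.
#' @param tol,max_iter EM settings for permutation refits.
#' @return A `clr_test` with the CLR, permutation p-value, and the
#'   per-cluster genotype effects \eqn{\mu_{1l} - \mu_{2l}}.
#' @export
test_any_cluster <- function(fit_full, fit_null, x = NULL, prior = NULL,
                             n_perm = 0L, seed = 1L, tol = 1e-6,
                             max_iter = 500L) {
  clr <- clr_stat(fit_full$logcl, fit_null$logcl)
  p <- if (n_perm > 0 && !is.null(x) && !is.null(prior))
    perm_pvalue(check_expression(x), check_prior(prior), fit_full,
                constraint = NULL, obs_clr = clr, n_perm = n_perm,
                seed = seed, tol = tol, max_iter = max_iter,
                null_fit = fit_null)
  else NA_real_
  new_clr_test("any_cluster", clr, p,
               effects = fit_full$model$mu[1, ] - fit_full$model$mu[2, ])
}

#' Test whether an eQTL affects a given cluster (or each cluster)
#'
#' For cluster `l`, H0: \eqn{\mu_{1l} = \mu_{2l}} with all other clusters
#' unconstrained; the null model is refit with that single equality imposed.
#' With `cluster = NULL` every cluster is tested and Benjamini-Hochberg
#' adjusted p-values are reported across clusters.
#'
#' @inheritParams test_any_cluster
#' @param x Expression matrix.
#' @param prior Genotype prior at the tested position.
#' @param fit_full Full `block_fit` at the position.
#' @param cluster Cluster index in 1..L, or `NULL` for all clusters.
#' @return A `clr_test` (single cluster) or a data frame with columns
#'   `cluster`, `effect`, `clr`, `p_value`, `p_adj` (all clusters).
#' @export
test_per_cluster <- function(x, prior, fit_full, cluster = NULL,
                             n_perm = 0L, seed = 1L, tol = 1e-6,
                             max_iter = 500L) {
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  L <- fit_full$L
  one <- function(l) {
    if (l < 1 || l > L) stop("cluster index out of range: ", l)
    constraint <- list(type = "equal_means_cluster", cluster = l)
    con <- constrained_refit(x, prior, fit_full, constraint, tol, max_iter)
    pair <- ensure_nesting(x, prior, fit_full, con, tol, max_iter)
    clr <- clr_stat(pair$full$logcl, pair$con$logcl)
    p <- perm_pvalue(x, prior, pair$full, constraint, clr, n_perm,
                     seed + l, tol, max_iter)
    new_clr_test("per_cluster", clr, p, cluster = l,
                 effect = pair$full$model$mu[1, l] - pair$full$model$mu[2, l])
  }
  if (!is.null(cluster)) return(one(cluster))
  tests <- lapply(seq_len(L), one)
  out <- data.frame(cluster = seq_len(L),
                    effect = vapply(tests, `[[`, 0, "effect"),
                    clr = vapply(tests, `[[`, 0, "clr"),
                    p_value = vapply(tests, `[[`, 0, "p_value"))
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

# Classifies a pair of genotype effects: opposite signs = the eQTL reverses
# the direction of its effect between the clusters; same sign but different
# magnitude = magnitude-varying interaction.
classify_pair <- function(d1, d2, tol) {
  if (d1 * d2 < 0) "direction"
  else if (abs(abs(d1) - abs(d2)) > tol) "magnitude"
  else "none"
}

#' Test for genotype-by-cluster interaction
#'
#' H0: the genotype effect is a common shift across clusters,
#' \eqn{\mu_{1l} - \mu_{2l} = c} for all `l` (additive model
#' \eqn{\mu_{kl} = a_l + g_k}); the null is refit with a single shift
#' parameter. On top of the CLR, every cluster pair is classified as
#' `"magnitude"`-varying (effects of the same sign, different size),
#' `"direction"`-varying (opposite signs), or `"none"`.
#'
#' @inheritParams test_per_cluster
#' @return A `clr_test` with `effects` (per-cluster \eqn{\mu_{1l} -
#'   \mu_{2l}}), `common_shift` (the fitted `c` under H0), and
#'   `classification` (L x L character matrix over cluster pairs).
#' @export
test_interaction <- function(x, prior, fit_full, n_perm = 0L, seed = 1L,
                             tol = 1e-6, max_iter = 500L) {
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  constraint <- list(type = "additive")
  con <- constrained_refit(x, prior, fit_full, constraint, tol, max_iter)
  pair <- ensure_nesting(x, prior, fit_full, con, tol, max_iter)
  clr <- clr_stat(pair$full$logcl, pair$con$logcl)
  p <- perm_pvalue(x, prior, pair$full, constraint, clr, n_perm, seed,
                   tol, max_iter)
  eff <- pair$full$model$mu[1, ] - pair$full$model$mu[2, ]
  L <- length(eff)
  tol_eff <- 1e-8 * max(abs(eff), 1)
  cls <- matrix("none", L, L)
  for (a in seq_len(L)) for (b in seq_len(L))
    if (a != b) cls[a, b] <- classify_pair(eff[a], eff[b], tol_eff)
  new_clr_test("interaction", clr, p, effects = eff,
               common_shift = mean(pair$con$model$mu[1, ] -
                                     pair$con$model$mu[2, ]),
               classification = cls)
}

#' Test whether an eQTL affects the cluster structure
#'
#' H0: within-genotype cluster contrasts are genotype-independent,
#' \eqn{\mu_{1l} - \mu_{1l'} = \mu_{2l} - \mu_{2l'}} for all cluster pairs;
#' equivalently, the genotype-specific cluster profiles coincide after
#' centering. For `K = 2` this is the additive null of
#' [test_interaction()]; the report decomposes the departure as the
#' contrast of centered genotype profiles per cluster.
#'
#' @inheritParams test_per_cluster
#' @return A `clr_test` with `profile_contrast`, the per-cluster difference
#'   of centered genotype profiles.
#' @export
test_cluster_structure <- function(x, prior, fit_full, n_perm = 0L,
                                   seed = 1L, tol = 1e-6, max_iter = 500L) {
  x <- check_expression(x)
  prior <- check_prior(prior, nrow(x))
  constraint <- list(type = "additive")
  con <- constrained_refit(x, prior, fit_full, constraint, tol, max_iter)
  pair <- ensure_nesting(x, prior, fit_full, con, tol, max_iter)
  clr <- clr_stat(pair$full$logcl, pair$con$logcl)
  p <- perm_pvalue(x, prior, pair$full, constraint, clr, n_perm, seed,
                   tol, max_iter)
  mu <- pair$full$model$mu
  prof <- sweep(mu, 1, rowMeans(mu))       # centered genotype profiles
  new_clr_test("cluster_structure", clr, p,
               profile_contrast = prof[1, ] - prof[2, ])
}
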
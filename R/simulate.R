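# Seeded backcross simulator: Markov marker genotypes along a genetic map
# and block-structured Gaussian expression controlled by one eQTL.

derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 65011 * 32749 + tag * 1009) %% 2147483629 + 1)
}

#' Specify a backcross block-mixture simulation design
#'
#' One linkage group with given marker positions, a single eQTL at
#' `rho_cM` controlling the genotype dimension of a `K = 2` by `L`
#' Gaussian block mixture. Cluster base means are evenly spaced
#' `separation` SD units apart and the genotype effect of cluster `l` is
#' `effect * s_l` with alternating sign and a magnitude cycle
#' `{1, 0.6, 1.4}`, so both magnitude- and direction-varying
#' genotype-by-cluster interactions are present.
#'
#' @param n Number of backcross progeny.
#' @param m Number of transcripts.
#' @param L Number of transcript clusters.
#' @param rho_cM True eQTL position (cM).
#' @param marker_pos Marker positions in cM on the single linkage group.
#' @param group Linkage-group id.
#' @param pi Cluster proportions (default uniform).
#' @param mu Optional explicit `2 x L` block-mean matrix; overrides
#'   `separation`/`effect`.
#' @param sigma Within-block SD.
#' @param separation Spacing of cluster base means, in SD units.
#' @param effect Scale of the genotype effects, in SD units.
#' @param seed Integer seed recorded in the design.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n = 208L, m = 545L, L = 4L, rho_cM = 24,
                       marker_pos = seq(0, 50, by = 10), group = "1",
                       pi = NULL, mu = NULL, sigma = 1, separation = 3,
                       effect = 0.8, seed = 1L) {
  if (is.null(pi)) pi <- rep(1 / L, L)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi <= 0))
    stop("cluster proportions must be positive and sum to 1")
  if (rho_cM < min(marker_pos) || rho_cM > max(marker_pos))
    stop("eQTL position must lie on the marker span")
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(mu)) {
    base <- separation * sigma * (seq_len(L) - (L + 1) / 2)
    d <- effect * sigma * rep_len(c(1, -1), L) * rep_len(c(1, 0.6, 1.4), L)
    mu <- rbind(base + d / 2, base - d / 2)
  }
  mu <- as.matrix(mu)
  if (nrow(mu) != 2 || ncol(mu) != L) stop("mu must be 2 x L")
  structure(list(n = as.integer(n), m = as.integer(m), L = as.integer(L),
                 rho_cM = rho_cM, marker_pos = marker_pos, group = group,
                 pi = pi, mu = mu, sigma = sigma, seed = as.integer(seed)),
            class = "sim_design")
}

#' Reference backcross design at a chosen scale
#'
#' The packaged reference simulation: n = 208 backcross progeny, a 50 cM
#' linkage group with six evenly spaced markers (0, 10, ..., 50 cM) and a
#' single eQTL at 24 cM driving block-structured normal expression over
#' 5,450 transcripts in 43 clusters. `scale` multiplies the transcript
#' count (`m = round(5450 * scale)`) and the cluster count
#' (`L = max(2, round(43 * scale))`) for desk-scale studies, keeping the
#' calibrated block separation (see [sim_design()]).
#'
#' @param scale Scale factor for `m` and `L`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [sim_design()].
#' @return A `sim_design`.
#' @examples
#' backcross_design(scale = 0.1)$m   # 545
#' @export
backcross_design <- function(scale = 1, seed = 1L, ...) {
  args <- list(...)
  if (is.null(args$m)) args$m <- as.integer(round(5450 * scale))
  if (is.null(args$L)) args$L <- max(2L, as.integer(round(43 * scale)))
  do.call(sim_design, c(args, list(seed = seed)))
}

#' Simulate backcross marker and eQTL genotypes
#'
#' The leftmost locus is Bernoulli(1/2); moving rightwards along the map,
#' each subsequent locus (markers and the eQTL, in map order) flips with
#' probability equal to the Haldane recombination fraction of the
#' inter-locus distance (Markov, no interference).
#'
#' @param design A [sim_design()].
#' @param seed Seed (defaults to a stream derived from the design seed).
#' @return A list: `map` ([genetic_map()]), `geno` (n x markers, codes
#'   0/1), `z` (true eQTL genotype index per individual, 1 or 2).
#' @export
simulate_genotypes <- function(design, seed = derive_seed(design$seed, 1L)) {
  old_rng <- preserve_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  pos <- design$marker_pos
  mnames <- paste0("m", seq_along(pos))
  loci <- sort(unique(c(pos, design$rho_cM)))
  n <- design$n
  G <- matrix(0L, n, length(loci))
  G[, 1] <- rbinom(n, 1, 0.5)
  if (length(loci) > 1) {
    r <- haldane(diff(loci))
    for (j in 2:length(loci)) {
      flip <- rbinom(n, 1, r[j - 1])
      G[, j] <- ifelse(flip == 1, 1L - G[, j - 1], G[, j - 1])
    }
  }
  qcol <- match(design$rho_cM, loci)
  z <- G[, qcol] + 1L
  geno <- G[, match(pos, loci), drop = FALSE]
  dimnames(geno) <- list(paste0("ind_", seq_len(n)), mnames)
  list(map = genetic_map(mnames, design$group, pos), geno = geno, z = z)
}

#' Simulate block-structured expression given eQTL genotypes
#'
#' Transcript cluster labels are i.i.d. categorical with probabilities
#' `pi`; cell `(i, j)` is Normal(\eqn{\mu_{z_i w_j}}, \eqn{\sigma^2}),
#' independent given the labels.
#'
#' @param design A [sim_design()].
#' @param z Integer vector of true eQTL genotypes (1/2) from
#'   [simulate_genotypes()].
#' @param seed Seed (defaults to a stream derived from the design seed).
#' @return A list: `x` (n x m expression matrix), `w` (true cluster label
#'   per transcript).
#' @export
simulate_expression <- function(design, z,
                                seed = derive_seed(design$seed, 2L)) {
  old_rng <- preserve_rng()
  on.exit(restore_rng(old_rng), add = TRUE)
  set.seed(seed)
  n <- design$n; m <- design$m
  stopifnot(length(z) == n, all(z %in% 1:2))
  w <- sample.int(design$L, m, replace = TRUE, prob = design$pi)
  x <- design$mu[z, w, drop = FALSE] +
    design$sigma * matrix(rnorm(n * m), n, m)
  dimnames(x) <- list(paste0("ind_", seq_len(n)),
                      sprintf("tr_%05d", seq_len(m)))
  list(x = x, w = w)
}

#' Simulate a complete backcross block-mixture dataset
#'
#' Runs [simulate_genotypes()] and [simulate_expression()] with seed
#' streams derived independently from the design seed (so map/genotypes
#' and expression noise can be varied independently).
#'
#' @param design A [sim_design()].
#' @param seed Optional seed overriding `design$seed`.
#' @return A `sim_output` list: `x`, `geno`, `map`, `z`, `w`, `design`.
#' @export
simulate_dataset <- function(design, seed = NULL) {
  if (!is.null(seed)) design$seed <- as.integer(seed)
  g <- simulate_genotypes(design)
  e <- simulate_expression(design, g$z)
  structure(list(x = e$x, geno = g$geno, map = g$map, z = g$z, w = e$w,
                 design = design),
            class = "sim_output")
}
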
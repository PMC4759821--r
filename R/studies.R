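# Replicate-level simulation studies: eQTL position recovery and
# cluster-number selection. These drive the package's reproducible
# validation runs (and nothing else), so tests and scripts share one
# seeded code path.

#' eQTL position recovery study
#'
#' Repeatedly simulates the reference backcross design ([backcross_design()])
#' and records, for each replicate, the scan-grid position with the largest
#' composite likelihood ratio. With the eQTL simulated at 24 cM, the mean
#' recovered position estimates the scan's location accuracy.
#'
#' @param n_reps Number of simulation replicates.
#' @param scale Design scale passed to [backcross_design()].
#' @param seed Master seed; each replicate derives its own stream.
#' @param step Scan grid step (cM).
#' @param n_starts EM starts for the position-independent null fit.
#' @param ... Further overrides for [backcross_design()].
#' @return A list: `positions` (per-replicate argmax, cM), `mean_position`,
#'   `sd_position`, `n_reps`.
#' @export
position_recovery_study <- function(n_reps = 50L, scale = 0.1, seed = 1L,
                                    step = 1, n_starts = 2L, ...) {
  positions <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    d <- backcross_design(scale = scale,
                          seed = derive_seed(seed, 100L + r), ...)
    sim <- simulate_dataset(d)
    sc <- scan_genome(sim$x, sim$map, sim$geno, L = d$L, step = step,
                      n_starts = n_starts, seed = derive_seed(seed, 300L + r))
    positions[r] <- sc$peak$pos_cM
  }
  list(positions = positions, mean_position = mean(positions),
       sd_position = sd(positions), n_reps = n_reps)
}

#' Cluster-number selection rate study
#'
#' Repeatedly simulates a backcross block mixture with a known number of
#' clusters and records how often CL-BIC ([select_L()], with the
#' interval-mapping prior at the most associated marker) recovers it.
#'
#' @param n_reps Number of simulation replicates.
#' @param n,m Individuals and transcripts per replicate.
#' @param L_true Generating number of clusters.
#' @param L_grid Candidate cluster numbers.
#' @param seed Master seed; each replicate derives its own stream.
#' @param n_starts EM starts per candidate.
#' @param ... Further overrides for [sim_design()].
#' @return A list: `selected` (per-replicate L), `rate` (proportion equal
#'   to `L_true`), `L_true`, `n_reps`.
#' @export
selection_rate_study <- function(n_reps = 50L, n = 208L, m = 300L,
                                 L_true = 5L, L_grid = 3:8, seed = 1L,
                                 n_starts = 4L, ...) {
  selected <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    d <- sim_design(n = n, m = m, L = L_true,
                    seed = derive_seed(seed, 200L + r), ...)
    sim <- simulate_dataset(d)
    pr <- best_marker_prior(sim$x, sim$map, sim$geno)
    sel <- select_L(sim$x, L_grid = L_grid, prior = pr, n_starts = n_starts,
                    seed = derive_seed(seed, 400L + r))
    selected[r] <- sel$L
  }
  list(selected = selected, rate = mean(selected == L_true),
       L_true = L_true, n_reps = n_reps)
}
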
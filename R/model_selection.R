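# Composite-likelihood BIC selection of the number of transcript clusters.

#' Composite-likelihood BIC
#'
#' \deqn{\mathrm{CL\textrm{-}BIC} = -2\,\ell_c + d \log(nm)} where
#' \eqn{\ell_c} is the maximised composite log-likelihood, \eqn{nm} the
#' number of matrix cells (each contributes one composite-likelihood term)
#' and \eqn{d} the free-parameter count: \eqn{L-1} proportions, \eqn{KL}
#' means, and \eqn{KL} (block variance) or 1 (pooled) standard deviations.
#' The fixed genotype prior contributes no parameters. Lower is better.
#'
#' @param fit A `block_fit` from [fit_em()].
#' @param n,m Numbers of individuals and transcripts.
#' @return The CL-BIC value (scalar).
#' @export
cl_bic <- function(fit, n, m) {
  K <- fit$K; L <- fit$L
  d <- (L - 1) + K * L + if (fit$variance == "block") K * L else 1
  -2 * fit$logcl + d * log(n * m)
}

#' Select the number of transcript clusters by CL-BIC
#'
#' Fits the block mixture for every candidate `L` (multi-start EM) and
#' returns the candidate minimising the composite-likelihood BIC. The
#' number of genotype classes is fixed by the cross design.
#'
#' Supply an informative genotype prior (e.g. [best_marker_prior()]): under
#' a uniform prior the `K x L` block means are exchangeable free
#' components, so the genotype layer can absorb extra clusters and CL-BIC
#' systematically underestimates `L`. Anchoring the genotype layer to an
#' associated genome region removes that degeneracy.
#'
#' @inheritParams fit_em
#' @param L_grid Integer vector of candidate cluster numbers.
#' @param prior Genotype prior; defaults to [uniform_prior()] on `K`
#'   classes (see the caveat above).
#' @param K Number of genotype classes (default 2).
#' @return A `cl_selection` list: `L` (selected), `table` (data frame with
#'   columns `L`, `logcl`, `clbic`, `converged`), `fits` (per-candidate
#'   `block_fit`s, named by `L`).
#' @export
select_L <- function(x, L_grid, prior = NULL, K = 2L, n_starts = 5L,
                     tol = 1e-6, max_iter = 500L, seed = 1L,
                     variance = c("block", "pooled")) {
  variance <- match.arg(variance)
  x <- check_expression(x)
  if (!length(L_grid)) stop("L_grid must be nonempty")
  L_grid <- sort(unique(as.integer(L_grid)))
  if (is.null(prior)) prior <- uniform_prior(nrow(x), K)
  prior <- check_prior(prior, nrow(x))

  fits <- vector("list", length(L_grid))
  names(fits) <- as.character(L_grid)
  tab <- data.frame(L = L_grid, logcl = NA_real_, clbic = NA_real_,
                    converged = FALSE)
  for (i in seq_along(L_grid)) {
    fit <- tryCatch(
      fit_em(x, prior, K = K, L = L_grid[i], n_starts = n_starts, tol = tol,
             max_iter = max_iter, seed = seed + i, variance = variance),
      error = function(e) {
        warning("L = ", L_grid[i], " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fits[[i]] <- fit
    tab$logcl[i] <- fit$logcl
    tab$clbic[i] <- cl_bic(fit, nrow(x), ncol(x))
    tab$converged[i] <- fit$converged
  }
  ok <- which(!is.na(tab$clbic))
  if (!length(ok)) stop("no candidate L converged")
  sel <- ok[which.min(tab$clbic[ok])]
  structure(list(L = L_grid[sel], table = tab, fits = fits),
            class = "cl_selection")
}

#' Single-marker association screen
#'
#' For every marker, sums the squared mean expression difference between
#' its two genotype groups over all transcripts. This cheap screen locates
#' the genome region with the strongest aggregate expression association;
#' the interval-mapping prior at the best marker
#' (`genotype_prior(map, geno, ...)`) makes a good genotype prior for
#' [select_L()], anchoring the genotype layer of the block mixture so the
#' cluster number is identified.
#'
#' @param x Expression matrix, individuals x transcripts.
#' @param geno Genotype matrix, individuals x markers, codes 0/1/NA.
#' @return Named numeric vector of per-marker association statistics.
#' @export
screen_markers <- function(x, geno) {
  x <- check_expression(x)
  stopifnot(nrow(geno) == nrow(x))
  vapply(colnames(geno), function(mk) {
    g <- geno[, mk]
    ok <- !is.na(g)
    if (!any(g[ok] == 0) || !any(g[ok] == 1)) return(0)
    d <- colMeans(x[ok & g == 0, , drop = FALSE]) -
      colMeans(x[ok & g == 1, , drop = FALSE])
    sum(d^2)
  }, numeric(1))
}

#' Interval-mapping prior at the most associated marker
#'
#' Convenience wrapper: runs [screen_markers()] and returns the
#' [genotype_prior()] at the winning marker's position.
#'
#' @inheritParams screen_markers
#' @param map A [genetic_map()].
#' @return An n x 2 genotype prior matrix.
#' @export
best_marker_prior <- function(x, map, geno) {
  geno <- align_genotypes(geno, map)
  stat <- screen_markers(x, geno)
  mk <- names(stat)[which.max(stat)]
  i <- match(mk, map$marker)
  genotype_prior(map, geno, map$group[i], map$pos_cM[i])
}

#' @export
print.cl_selection <- function(x, ...) {
  cat("CL-BIC cluster-number selection: L =", x$L, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
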
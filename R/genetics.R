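# Genetic-map handling and interval-mapping genotype priors for a
# two-genotype (backcross / RIL-homozygote) cross.

#' Haldane map function
#'
#' Converts a genetic map distance in centiMorgan to a recombination fraction
#' under the Haldane (no crossover interference) model,
#' \eqn{r = (1 - e^{-2d/100})/2}. The function is monotone increasing, with
#' `haldane(0) == 0` and an asymptote at 0.5 for unlinked loci.
#'
#' @param d_cM Nonnegative map distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(c(0, 10, 50))
#' @export
haldane <- function(d_cM) {
  if (!is.numeric(d_cM) || any(!is.finite(d_cM)) || any(d_cM < 0))
    stop("map distance must be nonnegative and finite (cM)")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

#' Inverse Haldane map function
#'
#' @param r Recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in cM.
#' @export
haldane_inv <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' Construct a genetic map
#'
#' A genetic map is a data frame with columns `marker`, `group` and `pos_cM`,
#' ordered by linkage group and position. Positions must be strictly
#' increasing within each group and marker names unique.
#'
#' @param marker Character vector of marker names (or a data frame already
#'   holding the three columns).
#' @param group Linkage-group identifiers, one per marker.
#' @param pos_cM Numeric map positions in cM.
#' @return A `genetic_map` data frame.
#' @examples
#' genetic_map(paste0("m", 1:6), "1", seq(0, 50, by = 10))
#' @export
genetic_map <- function(marker, group = NULL, pos_cM = NULL) {
  if (is.data.frame(marker)) {
    df <- marker
    need <- c("marker", "group", "pos_cM")
    if (!all(need %in% names(df)))
      stop("map data frame needs columns marker, group, pos_cM")
    df <- df[need]
  } else {
    df <- data.frame(marker = as.character(marker),
                     group = as.character(group),
                     pos_cM = as.numeric(pos_cM),
                     stringsAsFactors = FALSE)
  }
  df$marker <- as.character(df$marker)
  df$group <- as.character(df$group)
  df$pos_cM <- as.numeric(df$pos_cM)
  if (anyDuplicated(df$marker))
    stop("duplicated marker names in map")
  if (any(!is.finite(df$pos_cM)) || any(df$pos_cM < 0))
    stop("map positions must be finite and nonnegative cM")
  glev <- unique(df$group)
  df <- df[order(match(df$group, glev), df$pos_cM), , drop = FALSE]
  for (g in glev) {
    p <- df$pos_cM[df$group == g]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within group ", g)
  }
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

# Checks genotype codes and aligns marker columns with the map order.
align_genotypes <- function(geno, map) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)))
    stop("genotype matrix must carry marker names as column names")
  miss_map <- setdiff(map$marker, colnames(geno))
  miss_gen <- setdiff(colnames(geno), map$marker)
  if (length(miss_map) || length(miss_gen))
    stop("markers in map and genotype matrix disagree: missing from genotypes [",
         paste(miss_map, collapse = ", "), "], absent from map [",
         paste(miss_gen, collapse = ", "), "]")
  storage.mode(geno) <- "double"
  ok <- is.na(geno) | geno == 0 | geno == 1
  if (!all(ok))
    stop("genotype codes must be 0, 1 or NA; offending values: ",
         paste(unique(geno[!ok]), collapse = ", "))
  geno[, map$marker, drop = FALSE]
}

#' Candidate scan positions on a genetic map
#'
#' Returns the grid of candidate eQTL positions used by [scan_genome()]:
#' every `step` cM within each linkage group plus every marker position.
#'
#' @param map A [genetic_map()].
#' @param step Grid step in cM (default 1).
#' @return Data frame with columns `group` and `pos_cM`.
#' @export
scan_positions <- function(map, step = 1) {
  stopifnot(step > 0)
  out <- lapply(unique(map$group), function(g) {
    p <- map$pos_cM[map$group == g]
    grid <- sort(unique(c(seq(min(p), max(p), by = step), p)))
    data.frame(group = g, pos_cM = grid, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Interval-mapping genotype prior at a candidate eQTL position
#'
#' Computes, for every individual, the conditional probability of carrying
#' each of the two eQTL genotypes given the observed genotypes of the
#' flanking markers and the candidate position inside the marker interval.
#' Recombination fractions for the two sub-intervals come from [haldane()],
#' and the four flanking configurations follow classical backcross interval
#' mapping with renormalisation, e.g. for concordant flanking genotypes
#' \eqn{P(\mathrm{same}) = (1-r_1)(1-r_2) / [(1-r_1)(1-r_2) + r_1 r_2]}.
#' A missing flanking genotype falls back to the single informative flanking
#' marker; when both are missing the prior is uniform (0.5, 0.5).
#'
#' @param map A [genetic_map()].
#' @param geno Genotype matrix, individuals x markers, codes 0/1/NA, with
#'   marker names as column names.
#' @param group Linkage-group id of the candidate position.
#' @param pos_cM Candidate position in cM; must lie within the group's
#'   marker span.
#' @return An n x 2 matrix of genotype probabilities (columns `g0`, `g1`,
#'   for marker codes 0 and 1); each row sums to 1.
#' @export
genotype_prior <- function(map, geno, group, pos_cM) {
  geno <- align_genotypes(geno, map)
  mk <- map[map$group == group, , drop = FALSE]
  if (!nrow(mk)) stop("unknown linkage group: ", group)
  lo <- mk$pos_cM[1]; hi <- mk$pos_cM[nrow(mk)]
  if (pos_cM < lo - 1e-9 || pos_cM > hi + 1e-9)
    stop("candidate position ", pos_cM, " cM lies outside the marker span [",
         lo, ", ", hi, "] of group ", group)
  pos_cM <- min(max(pos_cM, lo), hi)
  n <- nrow(geno)

  if (nrow(mk) == 1L) {
    a <- geno[, mk$marker[1]]
    p0 <- ifelse(is.na(a), 0.5, 1 - a)
  } else {
    eta <- findInterval(pos_cM, mk$pos_cM, rightmost.closed = TRUE)
    eta <- max(1L, min(eta, nrow(mk) - 1L))
    r1 <- haldane(pos_cM - mk$pos_cM[eta])
    r2 <- haldane(mk$pos_cM[eta + 1L] - pos_cM)
    a <- geno[, mk$marker[eta]]
    b <- geno[, mk$marker[eta + 1L]]
    # transmission factor: P(no flip)=1-r, P(flip)=r; missing marker -> 1
    tf <- function(g1, g2, r) ifelse(is.na(g1), 1, ifelse(g1 == g2, 1 - r, r))
    w0 <- tf(a, 0, r1) * tf(b, 0, r2)
    w1 <- tf(a, 1, r1) * tf(b, 1, r2)
    p0 <- w0 / (w0 + w1)
  }
  out <- cbind(g0 = p0, g1 = 1 - p0)
  rownames(out) <- rownames(geno)
  out
}

#' Uniform genotype prior
#'
#' An uninformative n x K prior (all entries 1/K), used e.g. to choose the
#' number of clusters before any genome position is considered.
#'
#' @param n Number of individuals.
#' @param K Number of genotype classes (default 2).
#' @export
uniform_prior <- function(n, K = 2L) {
  matrix(1 / K, n, K, dimnames = list(NULL, paste0("g", seq_len(K) - 1L)))
}

check_prior <- function(prior, n = NULL) {
  prior <- as.matrix(prior)
  if (!is.null(n) && nrow(prior) != n)
    stop("genotype prior has ", nrow(prior), " rows; expected ", n)
  if (any(!is.finite(prior)) || any(prior < 0))
    stop("genotype prior entries must be finite and nonnegative")
  if (any(abs(rowSums(prior) - 1) > 1e-8))
    stop("genotype prior rows must sum to 1")
  prior
}
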
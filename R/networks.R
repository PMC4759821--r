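# Cluster-level expression scores and genotype-conditional co-expression
# networks.

#' Per-individual cluster expression scores
#'
#' Aggregates the expression matrix to one score per individual and
#' cluster: the mean expression over the transcripts assigned to the
#' cluster (MAP labels), or a posterior-weighted mean when `col_post` is
#' supplied.
#'
#' @param x Expression matrix, individuals x transcripts.
#' @param labels Integer cluster labels per transcript (1..L), e.g. from
#'   [assign_labels()].
#' @param L Number of clusters (defaults to `max(labels)`).
#' @param col_post Optional m x L posterior cluster weights; when given,
#'   scores are posterior-weighted means instead of hard-label means.
#' @return An n x L matrix of cluster scores (columns `cluster_1`, ...).
#'   Empty clusters give an `NA` column with a warning.
#' @export
cluster_scores <- function(x, labels, L = max(labels), col_post = NULL) {
  x <- check_expression(x)
  if (!is.null(col_post)) {
    col_post <- as.matrix(col_post)
    stopifnot(nrow(col_post) == ncol(x))
    tot <- colSums(col_post)
    sc <- x %*% col_post
    sc <- sweep(sc, 2, pmax(tot, .Machine$double.eps), "/")
    sc[, tot <= 0] <- NA_real_
    if (any(tot <= 0)) warning("cluster(s) with zero posterior mass: ",
                               paste(which(tot <= 0), collapse = ", "))
  } else {
    labels <- as.integer(labels)
    if (length(labels) != ncol(x))
      stop("need one cluster label per transcript")
    sc <- matrix(NA_real_, nrow(x), L)
    for (l in seq_len(L)) {
      jl <- which(labels == l)
      if (length(jl)) sc[, l] <- rowMeans(x[, jl, drop = FALSE])
    }
    if (anyNA(sc[1, ]))
      warning("empty cluster(s): ",
              paste(which(is.na(sc[1, ])), collapse = ", "))
  }
  dimnames(sc) <- list(rownames(x), paste0("cluster_", seq_len(ncol(sc))))
  sc
}

#' Cluster co-expression network
#'
#' Pearson correlation of cluster scores across a subset of individuals;
#' an edge between two clusters is retained when `|r| >= min_abs_corr`.
#'
#' @param scores n x L cluster score matrix from [cluster_scores()].
#' @param subset Indices (or logical mask) of individuals to use; default
#'   all. At least 3 individuals are required.
#' @param min_abs_corr Retention threshold on `|r|` (default 0.3).
#' @param condition Label recorded on the network (e.g. `"all"`,
#'   `"genotype 1"`).
#' @return A `cluster_network` list: `cor` (L x L, unit diagonal), `edges`
#'   (data frame `cluster_a`, `cluster_b`, `r`, `sign`, `retained`),
#'   `condition`, `min_abs_corr`, `n`.
#' @export
build_network <- function(scores, subset = NULL, min_abs_corr = 0.3,
                          condition = "all") {
  scores <- as.matrix(scores)
  if (is.null(subset)) subset <- seq_len(nrow(scores))
  s <- scores[subset, , drop = FALSE]
  if (nrow(s) < 3) stop("network needs at least 3 individuals")
  L <- ncol(s)
  if (is.null(colnames(s))) colnames(s) <- as.character(seq_len(L))
  zv <- apply(s, 2, sd) <= 0 | apply(s, 2, function(v) anyNA(v))
  C <- suppressWarnings(cor(s))
  if (any(zv)) {
    warning("zero-variance or NA cluster score(s), edges dropped: ",
            paste(which(zv), collapse = ", "))
    C[zv, ] <- NA_real_; C[, zv] <- NA_real_
  }
  diag(C) <- 1
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  r <- C[pairs]
  edges <- data.frame(cluster_a = pairs[, 1], cluster_b = pairs[, 2],
                      r = r,
                      sign = ifelse(is.na(r), NA_character_,
                                    ifelse(r >= 0, "positive", "negative")),
                      retained = !is.na(r) & abs(r) >= min_abs_corr,
                      stringsAsFactors = FALSE)
  structure(list(cor = C, edges = edges, condition = condition,
                 min_abs_corr = min_abs_corr, n = nrow(s)),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat("Cluster co-expression network [", x$condition, "]: ", ncol(x$cor),
      " clusters, ", sum(x$edges$retained), "/", nrow(x$edges),
      " edges retained at |r| >= ", x$min_abs_corr, " (n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Heatmap-ready cluster correlation matrix
#'
#' Reorders a network's correlation matrix by hierarchical clustering with
#' correlation distance (`1 - r`, average linkage), the usual presentation
#' for cluster co-expression heatmaps. The ordering is presentation only.
#'
#' @param network A `cluster_network` from [build_network()].
#' @return The L x L correlation matrix with rows/columns in dendrogram
#'   leaf order.
#' @export
network_heatmap_matrix <- function(network) {
  C <- network$cor
  C0 <- C
  C0[is.na(C0)] <- 0
  o <- stats::hclust(stats::as.dist(1 - C0), method = "average")$order
  C[o, o, drop = FALSE]
}

#' Genotype-conditional cluster networks at an eQTL
#'
#' Builds one co-expression network per genotype class (individuals
#' MAP-assigned to the two eQTL genotypes) and lists the differential
#' edges, i.e. edges retained in exactly one genotype.
#'
#' @param scores n x L cluster score matrix.
#' @param genotype Integer vector (1 or 2) of MAP genotype assignments,
#'   e.g. `assign_labels(fit)$row` at the eQTL position.
#' @param min_abs_corr Edge retention threshold.
#' @return A list with `genotype1`, `genotype2` ([build_network()]
#'   results) and `differential` (edge data frame with a `retained_in`
#'   column).
#' @export
genotype_conditional_networks <- function(scores, genotype,
                                          min_abs_corr = 0.3) {
  genotype <- as.integer(genotype)
  if (length(genotype) != nrow(scores))
    stop("need one genotype per individual")
  if (!all(genotype %in% 1:2))
    stop("genotype assignments must be 1 or 2 (two-genotype design)")
  nets <- lapply(1:2, function(k)
    build_network(scores, subset = which(genotype == k),
                  min_abs_corr = min_abs_corr,
                  condition = paste("genotype", k)))
  e1 <- nets[[1]]$edges; e2 <- nets[[2]]$edges
  only <- xor(e1$retained, e2$retained)
  diff <- data.frame(cluster_a = e1$cluster_a[only],
                     cluster_b = e1$cluster_b[only],
                     r_genotype1 = e1$r[only], r_genotype2 = e2$r[only],
                     retained_in = ifelse(e1$retained[only], "genotype 1",
                                          "genotype 2"),
                     stringsAsFactors = FALSE)
  list(genotype1 = nets[[1]], genotype2 = nets[[2]], differential = diff)
}
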
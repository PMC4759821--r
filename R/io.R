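# Tab-delimited readers and writers (expression, genotypes, map), model
# JSON, scan CSV, edge lists, and the transcript SD filter. All files are
# UTF-8 TSV with '.' decimals and a header row.

#' Read / write an expression matrix
#'
#' TSV with a header row: first column holds individual ids, remaining
#' columns one transcript each.
#'
#' @param path File path.
#' @return `read_expression`: numeric matrix with individual row names and
#'   transcript column names.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file needs an id column plus data: ", path)
  ids <- as.character(df[[1]])
  x <- as.matrix(df[-1])
  if (!is.numeric(x)) {
    bad <- which(!vapply(df[-1], is.numeric, TRUE))
    stop("non-numeric expression column(s): ",
         paste(names(df[-1])[bad], collapse = ", "))
  }
  rownames(x) <- ids
  check_expression(x)
}

#' @rdname read_expression
#' @param x Expression matrix (individuals x transcripts).
#' @export
write_expression <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype matrix
#'
#' TSV, first column individual id, remaining columns marker genotype codes
#' 0/1 with NA for missing; header row carries marker names.
#'
#' @param path File path.
#' @return Numeric matrix (0/1/NA) with individual row names and marker
#'   column names.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("genotype file needs an id column plus markers: ", path)
  ids <- as.character(df[[1]])
  g <- as.matrix(df[-1])
  storage.mode(g) <- "double"
  ok <- is.na(g) | g == 0 | g == 1
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop("invalid genotype code at data row ", bad[1, 1], ", marker ",
         colnames(g)[bad[1, 2]], " (must be 0, 1 or NA)")
  }
  rownames(g) <- ids
  g
}

#' @rdname read_genotypes
#' @param geno Genotype matrix.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno), geno, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genetic map
#'
#' TSV with columns `marker`, `group`, `pos_cM`.
#'
#' @param path File path.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genetic_map(df)
}

#' @rdname read_genetic_map
#' @param map A [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Filter transcripts by sample standard deviation
#'
#' Removes transcripts whose sample standard deviation (denominator
#' `n - 1`) falls below `sd_min`; survivors keep their original order. The
#' default threshold of 0.9 is the preprocessing rule applied to
#' quantile-normalised microarray intensities before block-mixture
#' modelling.
#'
#' @param x Expression matrix, individuals x transcripts.
#' @param sd_min Minimum sample SD to keep a transcript.
#' @return The filtered expression matrix.
#' @export
filter_transcripts <- function(x, sd_min = 0.9) {
  if (sd_min < 0) stop("sd_min must be nonnegative")
  x <- check_expression(x)
  sds <- apply(x, 2, sd)
  keep <- sds >= sd_min
  message("filter_transcripts: kept ", sum(keep), " of ", length(keep),
          " transcripts (SD >= ", sd_min, ")")
  x[, keep, drop = FALSE]
}

#' Write / read a fitted block model as JSON
#'
#' @param fit A `block_fit` or [block_model()].
#' @param path File path.
#' @export
write_model_json <- function(fit, path) {
  model <- if (inherits(fit, "block_fit")) fit$model else fit
  obj <- list(K = model$K, L = model$L, pi = model$pi,
              mu = model$mu, sigma = model$sigma,
              variance = model$variance)
  if (inherits(fit, "block_fit")) {
    obj$logcl <- fit$logcl
    obj$converged <- fit$converged
    obj$n_iter <- fit$n_iter
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) {
    if (is.matrix(v)) v
    else matrix(unlist(v), obj$K, obj$L, byrow = TRUE)
  }
  block_model(obj$pi, as_mat(obj$mu), as_mat(obj$sigma), obj$variance)
}

#' Write a scan table as CSV
#'
#' Columns: `group`, `pos_cM`, `clr`, and (when a threshold is supplied)
#' `significant`.
#'
#' @param scan An `eqtl_scan` from [scan_genome()].
#' @param path File path.
#' @param threshold Optional genome-wide CLR threshold used to flag
#'   significant positions.
#' @export
write_scan_csv <- function(scan, path, threshold = NULL) {
  tab <- scan$table[c("group", "pos_cM", "clr")]
  if (!is.null(threshold)) tab$significant <- tab$clr >= threshold
  write.table(tab, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster-network edge list as TSV
#'
#' @param network A `cluster_network` from [build_network()].
#' @param path File path.
#' @export
write_edge_list <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the simulation truth as JSON
#'
#' Records the generating design and the true latent labels of a
#' [simulate_dataset()] draw.
#'
#' @param sim A `sim_output`.
#' @param path File path.
#' @export
write_truth_json <- function(sim, path) {
  d <- sim$design
  jsonlite::write_json(
    list(n = d$n, m = d$m, L = d$L, rho_cM = d$rho_cM,
         marker_pos = d$marker_pos, group = d$group, pi = d$pi,
         mu = d$mu, sigma = d$sigma, seed = d$seed,
         z = sim$z, w = sim$w),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
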
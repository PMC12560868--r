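#' Identity-by-state distance matrix
#'
#' For every pair of individuals, over the loci non-missing in both:
#' similarity is the fraction of shared allele copies (both alleles shared
#' contributes 1, one allele 0.5, none 0) and distance is 1 - similarity.
#' Equivalently, distance = sum |x_j - x_k| / (2 L_jk) on allele counts.
#'
#' @param gm a [genotype_matrix()].
#' @return A symmetric n x n matrix (class `square_matrix`, kind
#'   `"ibs_distance"`), zero diagonal, entries in `[0, 1]`; a pair with no
#'   overlapping loci is `NA` with a warning.
#' @export
ibs_distance <- function(gm) {
  validate_genotype_matrix(gm)
  if (n_samples(gm) < 2L) stop("need at least 2 individuals")
  g <- gm$calls
  M <- !is.na(g)
  I0 <- M & g == 0L; I1 <- M & g == 1L; I2 <- M & g == 2L
  storage.mode(I0) <- storage.mode(I1) <- storage.mode(I2) <- "double"
  storage.mode(M) <- "double"
  # Allele-count differences accumulated over genotype-class cross products.
  diff2 <- I0 %*% t(I2); diff2 <- diff2 + t(diff2)
  d1a <- I1 %*% t(I0 + I2)
  diffs <- 2 * diff2 + d1a + t(d1a)
  Ljk <- M %*% t(M)
  if (any(Ljk[upper.tri(Ljk)] == 0)) {
    warning("pair(s) with no overlapping loci; IBS distance set NA")
  }
  D <- diffs / (2 * Ljk)
  D[Ljk == 0] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- list(gm$samples$iid, gm$samples$iid)
  structure(D, class = c("square_matrix", "matrix"), kind = "ibs_distance")
}

#' Genomic relationship matrix
#'
#' The per-locus-standardized (single-step) estimator:
#' \deqn{G_{jk} = \frac{1}{L_{jk}} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)}}
#' with allele frequencies estimated from the full sample, monomorphic loci
#' excluded, and per-pair complete-case handling of missing calls (`L_jk` =
#' loci non-missing in both members of the pair). Diagonal entries estimate
#' `1 + F_j`, not exactly 1.
#'
#' @param gm a [genotype_matrix()].
#' @return A symmetric n x n matrix (class `square_matrix`, kind `"grm"`).
#' @export
grm <- function(gm) {
  validate_genotype_matrix(gm)
  if (n_samples(gm) < 2L) stop("need at least 2 individuals")
  p <- allele1_freq(gm)
  poly <- !is.nan(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic loci for the GRM")
  g <- gm$calls[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(g, 2L, 2 * p, `-`)
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), `/`)
  M <- !is.na(Z)
  Z[!M] <- 0                      # a missing call contributes 0 to the sum
  storage.mode(M) <- "double"
  Ljk <- M %*% t(M)
  G <- (Z %*% t(Z)) / Ljk
  G[Ljk == 0] <- NA_real_
  dimnames(G) <- list(gm$samples$iid, gm$samples$iid)
  structure(G, class = c("square_matrix", "matrix"), kind = "grm")
}

#' @export
print.square_matrix <- function(x, ...) {
  kind <- attr(x, "kind")
  v <- x[upper.tri(x)]
  cat("square_matrix (", kind, "): ", nrow(x), " x ", ncol(x), "\n", sep = "")
  cat(sprintf("  off-diagonal: %.3f to %.3f (mean %.3f)\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              mean(v, na.rm = TRUE)))
  cat(sprintf("  diagonal mean: %.3f\n", mean(diag(x), na.rm = TRUE)))
  invisible(x)
}

#' Write / read a square matrix as TSV
#'
#' Square layout with an id header row and column, plus a long-format
#' `(id1, id2, value)` companion for downstream ingestion.
#'
#' @param m a `square_matrix`.
#' @param path output path for the square TSV; the long format is written
#'   next to it with suffix `.long.tsv`.
#' @return Invisibly, the two paths.
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  long <- data.frame(id1 = rownames(m)[idx[, 1]],
                     id2 = colnames(m)[idx[, 2]],
                     value = m[idx])
  long_path <- sub("\\.tsv$", ".long.tsv", path)
  if (long_path == path) long_path <- paste0(path, ".long.tsv")
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(square = path, long = long_path))
}

#' @rdname write_square_matrix
#' @param kind matrix kind to stamp on the read object.
#' @export
read_square_matrix <- function(path, kind = "grm") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  structure(m, class = c("square_matrix", "matrix"), kind = kind)
}
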
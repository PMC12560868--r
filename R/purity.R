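#' Principal component analysis of genotypes
#'
#' Genotypes are column-standardized as \eqn{(x - 2p)/\sqrt{2p(1-p)}} with
#' missing entries imputed to the column mean (0 after centering) and
#' monomorphic columns set to zero, then decomposed by SVD. Marker loadings
#' are the right singular vectors; `pc1_contribution` is the squared PC1
#' loading, normalized to sum to 1, the standard variance-contribution
#' measure of a marker to the leading axis of population structure.
#'
#' @param gm a (post-QC) [genotype_matrix()].
#' @param k number of components to retain.
#' @return An object of class `genotype_pca`: `eigenvalues` (descending),
#'   `sample_scores` (n x k, rows named by iid), `snp_loadings` (markers x k),
#'   `pc1_contribution` (named per-marker vector summing to 1).
#' @export
genotype_pca <- function(gm, k = 10L) {
  validate_genotype_matrix(gm)
  n <- n_samples(gm)
  if (n < 2L) stop("PCA requires at least 2 samples")
  k <- min(as.integer(k), n - 1L, n_markers(gm))
  if (k < 1L) stop("k must be >= 1")

  p <- allele1_freq(gm)
  sd2 <- sqrt(2 * p * (1 - p))
  X <- sweep(gm$calls, 2L, 2 * p, `-`)
  X[is.na(X)] <- 0
  poly <- !is.nan(p) & p > 0 & p < 1
  X[, poly] <- sweep(X[, poly, drop = FALSE], 2L, sd2[poly], `/`)
  X[, !poly] <- 0

  sv <- svd(X, nu = k, nv = k)
  eigenvalues <- sv$d^2 / (n - 1L)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(scores) <- gm$samples$iid
  loadings <- sv$v
  rownames(loadings) <- gm$markers$id
  contrib <- loadings[, 1L]^2
  contrib <- contrib / sum(contrib)
  structure(list(eigenvalues = eigenvalues,
                 sample_scores = scores,
                 snp_loadings = loadings,
                 pc1_contribution = contrib,
                 markers = gm$markers[, c("id", "chrom", "bp")]),
            class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  k <- ncol(x$sample_scores)
  cat("genotype_pca:", nrow(x$snp_loadings), "markers,",
      nrow(x$sample_scores), "samples,", k, "components\n")
  cat(sprintf("  variance explained: PC1 %.1f%%, PC1-%d %.1f%%\n",
              100 * x$eigenvalues[1] / tot, k,
              100 * sum(x$eigenvalues[seq_len(k)]) / tot))
  invisible(x)
}

#' Top PC1-contributing loci
#'
#' Markers ranked by `pc1_contribution` (descending); exact ties are broken
#' by chromosome, physical position and id (ascending), making the order
#' reproducible.
#'
#' @param pca a [genotype_pca()].
#' @param k number of loci to return.
#' @return Character vector of marker ids, best first.
#' @export
top_pc1_loci <- function(pca, k = 100L) {
  stopifnot(inherits(pca, "genotype_pca"))
  mk <- pca$markers
  if (k > nrow(mk)) stop("k exceeds the number of markers")
  ord <- order(-pca$pc1_contribution, chrom_rank(mk$chrom), mk$bp, mk$id)
  mk$id[ord][seq_len(k)]
}

#' Allele-concordance classification
#'
#' For each marker the primary allele is the higher-frequency allele among
#' non-missing calls (ties resolved to `allele1`, the canonical alphabetical
#' choice); its frequency is the locus's concordance. Loci are classed
#' `high` above 0.80, `low` below 0.30, `medium` otherwise. For biallelic
#' loci the major-allele frequency is always at least 0.5, so the `low`
#' class is unreachable; it is kept for interface fidelity with the
#' three-way classification used in breed-purity screening.
#'
#' @param gm a [genotype_matrix()].
#' @param high_threshold,low_threshold class boundaries on the primary-allele
#'   frequency (class is `high` strictly above `high_threshold`).
#' @return data.frame of class `concordance_table`: `marker_id`,
#'   `primary_allele`, `primary_freq`, `concordance_class` (`NA` rows flag
#'   all-missing markers, excluded from class counts).
#' @export
concordance_table <- function(gm, high_threshold = 0.80,
                              low_threshold = 0.30) {
  validate_genotype_matrix(gm)
  if (n_samples(gm) < 1L) stop("need at least one sample")
  p1 <- allele1_freq(gm)
  all_missing <- is.nan(p1)
  primary_is_a1 <- !all_missing & p1 >= 0.5
  primary_allele <- ifelse(all_missing, NA,
                           ifelse(primary_is_a1, gm$markers$allele1,
                                  gm$markers$allele2))
  primary_freq <- ifelse(all_missing, NA, pmax(p1, 1 - p1))
  cls <- ifelse(is.na(primary_freq), NA,
                ifelse(primary_freq > high_threshold, "high",
                       ifelse(primary_freq < low_threshold, "low", "medium")))
  out <- data.frame(marker_id = gm$markers$id,
                    primary_allele = primary_allele,
                    primary_freq = primary_freq,
                    concordance_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' Select the purity panel
#'
#' The panel is the ordered intersection (top-loci order preserved) of the
#' top PC1 contributors with the high-concordance loci.
#'
#' @param top_loci ordered marker ids from [top_pc1_loci()].
#' @param table a [concordance_table()] over the same marker universe.
#' @return An object of class `purity_panel`: data.frame with `marker_id`,
#'   `primary_allele`, `primary_freq` in panel order.
#' @export
select_panel <- function(top_loci, table) {
  stopifnot(inherits(table, "concordance_table"))
  if (!all(top_loci %in% table$marker_id)) {
    stop("top loci absent from the concordance table")
  }
  rows <- table[match(top_loci, table$marker_id), ]
  keep <- !is.na(rows$concordance_class) & rows$concordance_class == "high"
  if (!any(keep)) warning("no top locus reaches high concordance; empty panel")
  panel <- rows[keep, c("marker_id", "primary_allele", "primary_freq")]
  rownames(panel) <- NULL
  class(panel) <- c("purity_panel", "data.frame")
  panel
}

#' Per-individual purity scores and ranking
#'
#' The purity score of an individual is the number of panel primary-allele
#' copies it carries over the panel loci (missing genotypes contribute 0
#' copies -- an allele not observed is not counted). Individuals are ranked
#' by descending score, ties broken by id; the top `n_keep` are flagged
#' `selected`.
#'
#' @param gm a [genotype_matrix()] containing all panel markers.
#' @param panel a [purity_panel()].
#' @param n_keep size of the selected set.
#' @return An object of class `purity_ranking`: data.frame with `iid`,
#'   `score`, `rank`, `selected`, sorted by rank.
#' @export
purity_scores <- function(gm, panel, n_keep = 60L) {
  stopifnot(inherits(panel, "purity_panel"))
  if (nrow(panel) == 0L) stop("panel is empty")
  j <- match(panel$marker_id, gm$markers$id)
  if (anyNA(j)) stop("panel markers missing from the genotype matrix")
  g <- gm$calls[, j, drop = FALSE]
  a1 <- matrix(gm$markers$allele1[j], nrow = nrow(g), ncol = ncol(g),
               byrow = TRUE)
  prim <- matrix(panel$primary_allele, nrow = nrow(g), ncol = ncol(g),
                 byrow = TRUE)
  copies <- ifelse(prim == a1, g, 2L - g)
  copies[is.na(copies)] <- 0L
  score <- rowSums(copies)
  ord <- order(-score, gm$samples$iid)
  out <- data.frame(iid = gm$samples$iid[ord], score = score[ord],
                    rank = seq_along(score),
                    selected = seq_along(score) <= min(n_keep, length(score)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("purity_ranking", "data.frame")
  attr(out, "panel_size") <- nrow(panel)
  out
}

#' @export
print.purity_ranking <- function(x, ...) {
  ps <- attr(x, "panel_size")
  cat("purity_ranking:", nrow(x), "individuals over a", ps, "locus panel",
      sprintf("(max attainable score %d)\n", 2L * ps))
  cat("  selected:", sum(x$selected), "| score range:",
      min(x$score), "-", max(x$score), "\n")
  print.data.frame(utils::head(x, 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' One-call purity screening
#'
#' Convenience wrapper chaining [genotype_pca()], [top_pc1_loci()],
#' [concordance_table()], [select_panel()] and [purity_scores()].
#'
#' @param gm a post-QC [genotype_matrix()].
#' @param top_k top PC1 contributors to consider.
#' @param high_threshold concordance threshold for panel membership.
#' @param n_keep individuals to select.
#' @return List with `pca`, `top_loci`, `concordance`, `panel`, `ranking`,
#'   and `selected_ids`.
#' @export
screen_purity <- function(gm, top_k = 100L, high_threshold = 0.80,
                          n_keep = 60L) {
  pca <- genotype_pca(gm, k = min(10L, n_samples(gm) - 1L))
  top <- top_pc1_loci(pca, k = min(top_k, n_markers(gm)))
  conc <- concordance_table(gm, high_threshold = high_threshold)
  panel <- select_panel(top, conc)
  ranking <- purity_scores(gm, panel, n_keep = n_keep)
  list(pca = pca, top_loci = top, concordance = conc, panel = panel,
       ranking = ranking, selected_ids = ranking$iid[ranking$selected])
}
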
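#' Per-locus genetic diversity statistics
#'
#' With `p` the `allele1` frequency over non-missing calls and `q = 1 - p`:
#' minor allele frequency `maf = min(p, q)`, observed heterozygosity
#' `ho = n_het / n_called`, expected heterozygosity `he = 2pq` (no
#' small-sample correction, matching per-locus expected-heterozygosity
#' displays of standard tooling), polymorphism information content
#' `pic = 1 - (p^2 + q^2) - 2 p^2 q^2`, and Shannon information index
#' `shi = -(p log p + q log q)` with `0 log 0 = 0`.
#'
#' @param gm a (post-QC) [genotype_matrix()].
#' @param shi_base logarithm base for the Shannon index: `"e"` (natural,
#'   default) or `"2"` (bits; makes the maximum at `p = 0.5` exactly 1).
#' @return data.frame of class `locus_stats`: `marker_id`, `chrom`, `maf`,
#'   `ho`, `he`, `pic`, `shi`. All-missing markers are dropped with a
#'   warning.
#' @export
locus_stats <- function(gm, shi_base = c("e", "2")) {
  validate_genotype_matrix(gm)
  shi_base <- match.arg(shi_base)
  g <- gm$calls
  n_called <- colSums(!is.na(g))
  drop <- n_called == 0L
  if (any(drop)) {
    warning(sum(drop), " all-missing marker(s) excluded from locus stats")
  }
  keep <- which(!drop)
  g <- g[, keep, drop = FALSE]
  n_called <- n_called[keep]
  p <- colMeans(g, na.rm = TRUE) / 2
  q <- 1 - p
  plogp <- function(x) ifelse(x > 0, x * log(x), 0)
  shi <- -(plogp(p) + plogp(q))
  if (shi_base == "2") shi <- shi / log(2)
  out <- data.frame(
    marker_id = gm$markers$id[keep],
    chrom = gm$markers$chrom[keep],
    maf = pmin(p, q),
    ho = colSums(!is.na(g) & g == 1L) / n_called,
    he = 2 * p * q,
    pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2,
    shi = shi,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("locus_stats", "data.frame")
  attr(out, "shi_base") <- shi_base
  out
}

#' Minor-allele-frequency spectrum
#'
#' Fractions of loci per MAF bin over half-open intervals `[lo, hi)`, the
#' last bin closed at 0.5. Default edges follow the display convention of
#' array-based diversity reports (loci under the QC threshold excluded from
#' the first displayed bin).
#'
#' @param stats a [locus_stats()] data.frame (or any with a `maf` column).
#' @param bin_edges increasing numeric vector of bin boundaries.
#' @return Named numeric vector of bin fractions (sums to 1 over the loci
#'   falling inside the binned range).
#' @export
maf_spectrum <- function(stats,
                         bin_edges = c(0.05, 0.10, 0.20, 0.30, 0.40, 0.50)) {
  if (!nrow(stats)) stop("empty locus table")
  edges <- sort(bin_edges)
  maf <- stats$maf
  k <- length(edges) - 1L
  counts <- integer(k)
  for (i in seq_len(k)) {
    hi_closed <- i == k && edges[i + 1L] >= 0.5
    counts[i] <- sum(maf >= edges[i] &
                       (maf < edges[i + 1L] |
                          (hi_closed & maf <= edges[i + 1L])))
  }
  names(counts) <- paste0("[", edges[-length(edges)], ",", edges[-1L],
                          c(rep(")", k - 1L), "]"))
  if (sum(counts) == 0) return(counts * 0)
  counts / sum(counts)
}

#' Proportion of polymorphic markers
#'
#' @param stats a [locus_stats()] data.frame.
#' @param maf_threshold minimum MAF for a marker to count as polymorphic.
#' @return Fraction in `[0, 1]`.
#' @export
proportion_polymorphic <- function(stats, maf_threshold = 0.01) {
  if (!nrow(stats)) stop("empty locus table")
  mean(stats$maf >= maf_threshold)
}

#' Per-individual method-of-moments inbreeding coefficient
#'
#' `F_i = (O_hom - E_hom) / (L_i - E_hom)` over the individual's non-missing
#' loci, where `O_hom` is the observed homozygous count, `L_i` the number of
#' non-missing loci, and `E_hom = sum_j (1 - 2 p_j q_j * n_j / (n_j - 1))`
#' the sample-size-corrected expected homozygous count (`n_j` = called
#' allele count at locus `j`, frequencies from the full sample). This is the
#' excess-homozygosity estimator reported by standard SNP tooling.
#'
#' @param gm a (post-QC) [genotype_matrix()].
#' @return Named numeric vector of F per individual; `NA` (with a warning)
#'   for individuals with fewer than 2 non-missing loci.
#' @export
individual_f <- function(gm) {
  validate_genotype_matrix(gm)
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  g <- gm$calls
  called_g <- colSums(!is.na(g))
  nn <- 2 * called_g                        # called allele count per locus
  p <- colMeans(g, na.rm = TRUE) / 2
  corr <- ifelse(nn > 1, nn / (nn - 1), 0)
  e_hom_j <- 1 - 2 * p * (1 - p) * corr     # per-locus expected hom
  e_hom_j[is.nan(e_hom_j)] <- 0

  obs <- !is.na(g)
  O <- rowSums(obs & g != 1L)
  L <- rowSums(obs)
  E <- obs %*% e_hom_j
  f <- as.numeric((O - E) / (L - E))
  low <- L < 2L
  if (any(low)) {
    warning(sum(low), " individual(s) with < 2 non-missing loci; F set NA")
    f[low] <- NA_real_
  }
  stats::setNames(f, gm$samples$iid)
}

#' Paired and one-sample t tests for diversity contrasts
#'
#' [paired_t()] runs the standard paired t test on per-locus `ho - he`
#' differences; [one_sample_t()] tests a mean against `mu0`. Both return
#' two-sided p-values and flag the degenerate zero-variance case instead of
#' erroring (`t = 0, p = 1` when all differences are zero).
#'
#' @param ho_vec,he_vec equal-length per-locus vectors.
#' @param values numeric vector.
#' @param mu0 null mean.
#' @return List with `t`, `p`, `df`, `mean_diff` (or `mean`), `degenerate`.
#' @export
paired_t <- function(ho_vec, he_vec) {
  if (length(ho_vec) != length(he_vec)) stop("vectors differ in length")
  if (length(ho_vec) < 2L) stop("need at least 2 pairs")
  d <- ho_vec - he_vec
  if (stats::sd(d) == 0) {
    return(list(t = if (all(d == 0)) 0 else NA_real_,
                p = if (all(d == 0)) 1 else NA_real_,
                df = length(d) - 1L, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(ho_vec, he_vec, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' @rdname paired_t
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::sd(values) == 0) {
    return(list(t = if (all(values == mu0)) 0 else NA_real_,
                p = if (all(values == mu0)) 1 else NA_real_,
                df = length(values) - 1L, mean = mean(values),
                degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = unname(tt$estimate),
       degenerate = FALSE)
}

#' LD-based effective population size
#'
#' Implements the Sved relationship between linkage disequilibrium and
#' effective population size: marker pairs within `max_dist_cm` are binned
#' by genetic distance `c` (Morgans); composite LD `r^2` is the squared
#' Pearson correlation of allele counts (missing calls mean-imputed), with
#' the sampling correction `r^2_adj = r^2 - 1/(2 n_ind)`. Each bin yields
#' `Ne_bin = (1/(4 c̄)) (1/r^2_adj - 1)`, read as the effective size about
#' `t = 1/(2 c̄)` generations ago (large distances = recent generations).
#' The reported `ne` is the harmonic mean of the bin estimates within the
#' recent-generation window `t <= max_gen`.
#'
#' @param gm a [genotype_matrix()] with genetic positions on its map.
#' @param max_dist_cm maximum pair distance in centimorgans.
#' @param n_bins number of equal-width distance bins.
#' @param max_gen recent-generation window for the summary estimate.
#' @param max_pairs cap on marker pairs (random subsample beyond it).
#' @return An object of class `ne_estimate`: `ne` (harmonic summary; `Inf`
#'   with `no_ld = TRUE` when no bin shows positive adjusted LD), `bins`
#'   (data.frame: `c_mean`, `generations`, `r2_adj`, `n_pairs`, `ne_bin`),
#'   `n_ind`.
#' @export
estimate_ne_ld <- function(gm, max_dist_cm = 10, n_bins = 10L,
                           max_gen = 50, max_pairs = 2e5) {
  validate_genotype_matrix(gm)
  n <- n_samples(gm)
  if (n < 2L) stop("need at least 2 individuals")

  # Candidate pairs per chromosome within the distance window. Chromosomes
  # and offsets are accumulated in lists (one allocation each) and markers
  # are thinned first when the full pair set would far exceed `max_pairs`.
  marker_use <- seq_len(n_markers(gm))
  approx_pairs <- function(use) {
    sum(vapply(split(gm$markers$cm[use], gm$markers$chrom[use]), function(cm) {
      if (length(cm) < 2L) return(0)
      length(cm) * min(length(cm) - 1,
                       max_dist_cm / max(stats::median(diff(sort(cm))), 1e-9))
    }, numeric(1))) / 2
  }
  ap <- approx_pairs(marker_use)
  if (ap > 4 * max_pairs) {
    marker_use <- sort(sample(marker_use,
                              ceiling(length(marker_use) *
                                        sqrt(4 * max_pairs / ap))))
  }
  acc_i <- list(); acc_j <- list()
  for (chr in unique(gm$markers$chrom[marker_use])) {
    idx <- marker_use[gm$markers$chrom[marker_use] == chr]
    idx <- idx[order(gm$markers$cm[idx])]
    cm <- gm$markers$cm[idx]
    if (length(idx) < 2L) next
    for (off in seq_len(length(idx) - 1L)) {
      d <- cm[-seq_len(off)] - cm[seq_len(length(idx) - off)]
      ok <- which(d <= max_dist_cm & d > 0)
      if (!length(ok)) break
      acc_i[[length(acc_i) + 1L]] <- idx[ok]
      acc_j[[length(acc_j) + 1L]] <- idx[ok + off]
    }
  }
  pair_i <- unlist(acc_i); pair_j <- unlist(acc_j)
  if (!length(pair_i)) stop("no marker pairs within max_dist_cm")
  if (length(pair_i) > max_pairs) {
    take <- sample.int(length(pair_i), max_pairs)
    pair_i <- pair_i[take]; pair_j <- pair_j[take]
  }

  # Standardize once (mean-impute missing), polymorphic markers only.
  X <- gm$calls
  mu <- colMeans(X, na.rm = TRUE)
  va <- apply(X, 2L, stats::var, na.rm = TRUE)
  usable <- !is.na(va) & va > 0
  keep <- usable[pair_i] & usable[pair_j]
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  if (!length(pair_i)) stop("no usable (polymorphic) marker pairs")
  X <- sweep(X, 2L, mu, `-`)
  X[is.na(X)] <- 0
  X <- sweep(X, 2L, sqrt(colSums(X^2)), `/`)

  r2 <- numeric(length(pair_i))
  for (st in seq(1L, length(pair_i), by = 50000L)) {
    en <- min(st + 49999L, length(pair_i))
    r2[st:en] <- colSums(X[, pair_i[st:en], drop = FALSE] *
                           X[, pair_j[st:en], drop = FALSE])^2
  }
  dist_m <- abs(gm$markers$cm[pair_i] - gm$markers$cm[pair_j]) / 100
  r2_adj <- r2 - 1 / (2 * n)

  edges <- seq(0, max_dist_cm / 100, length.out = n_bins + 1L)
  bin <- cut(dist_m, edges, include.lowest = TRUE, labels = FALSE)
  bins <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- which(bin == b)
    if (length(sel) < 2L) return(NULL)
    cbar <- mean(dist_m[sel])
    rb <- mean(r2_adj[sel])
    data.frame(c_mean = cbar, generations = 1 / (2 * cbar),
               r2_adj = rb, n_pairs = length(sel),
               ne_bin = if (rb > 0) (1 / (4 * cbar)) * (1 / rb - 1) else Inf)
  }))
  if (is.null(bins) || !nrow(bins)) stop("no usable distance bins")

  recent <- bins[bins$generations <= max_gen & is.finite(bins$ne_bin) &
                   bins$ne_bin > 0, , drop = FALSE]
  no_ld <- nrow(recent) == 0L
  ne <- if (no_ld) Inf else nrow(recent) / sum(1 / recent$ne_bin)
  structure(list(ne = ne, bins = bins, n_ind = n, no_ld = no_ld),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  if (x$no_ld) {
    cat("ne_estimate: no positive adjusted LD in the recent-generation",
        "window; Ne unbounded (very large)\n")
  } else {
    cat(sprintf("ne_estimate: Ne = %.3f (harmonic over %d bins, n = %d)\n",
                x$ne, nrow(x$bins), x$n_ind))
  }
  invisible(x)
}

#' Population diversity summary
#'
#' Aggregates [locus_stats()] into the population-level report: mean +/- SD
#' of every locus statistic, the MAF spectrum, PIC polymorphism classes
#' (low < 0.25, medium 0.25-0.5, high > 0.5), the proportion of polymorphic
#' markers, per-chromosome mean Shannon index, per-individual inbreeding F
#' with its one-sample t test, and the paired Ho vs He test.
#'
#' @param gm a (post-QC) [genotype_matrix()].
#' @param shi_base passed to [locus_stats()].
#' @param maf_threshold polymorphism threshold for PN.
#' @param ne optionally, a precomputed [estimate_ne_ld()] result (computed
#'   here when `NULL` and `compute_ne = TRUE`).
#' @param compute_ne set `FALSE` to skip the LD Ne estimate.
#' @return An object of class `diversity_summary`.
#' @export
diversity_summary <- function(gm, shi_base = c("e", "2"),
                              maf_threshold = 0.01, ne = NULL,
                              compute_ne = TRUE) {
  stats_df <- locus_stats(gm, shi_base = shi_base)
  msd <- function(x) c(mean = mean(x), sd = stats::sd(x))
  f <- individual_f(gm)
  fv <- f[!is.na(f)]
  pic_class <- cut(stats_df$pic, c(-Inf, 0.25, 0.5, Inf),
                   labels = c("low", "medium", "high"), right = FALSE)
  if (is.null(ne) && compute_ne) {
    ne <- tryCatch(estimate_ne_ld(gm), error = function(e) NULL)
  }
  structure(list(
    n_ind = n_samples(gm), n_loci = nrow(stats_df),
    means = rbind(maf = msd(stats_df$maf), ho = msd(stats_df$ho),
                  he = msd(stats_df$he), pic = msd(stats_df$pic),
                  shi = msd(stats_df$shi), f = msd(fv)),
    maf_spectrum = maf_spectrum(stats_df),
    pic_class_fractions = prop.table(table(pic_class)),
    pn = proportion_polymorphic(stats_df, maf_threshold),
    shi_by_chrom = tapply(stats_df$shi, stats_df$chrom, mean),
    f_values = f,
    ho_he_test = paired_t(stats_df$ho, stats_df$he),
    f_test = one_sample_t(fv, 0),
    ne = ne
  ), class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat("diversity_summary:", x$n_loci, "loci,", x$n_ind, "individuals\n")
  m <- x$means
  for (s in rownames(m)) {
    cat(sprintf("  %-4s %.3f +/- %.3f\n", toupper(s), m[s, "mean"],
                m[s, "sd"]))
  }
  cat(sprintf("  PN = %.3f | Ho vs He paired t: p = %.3g | F > 0: p = %.3g\n",
              x$pn, x$ho_he_test$p, x$f_test$p))
  if (!is.null(x$ne)) {
    cat(sprintf("  Ne (LD) = %.3f\n", x$ne$ne))
  }
  invisible(x)
}
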
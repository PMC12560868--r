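#' Runs-of-homozygosity scan parameters
#'
#' Sliding-window parameters of the scan; defaults are the documented
#' defaults of the standard SNP-array ROH caller: 50-SNP windows tolerating
#' 1 heterozygote and 5 missing calls, a 5% window hit threshold, and final
#' segment constraints of 100 SNPs, 1000 kb length, at most 50 kb/SNP
#' average spacing and a 1000 kb maximum internal gap.
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het_allowed heterozygotes tolerated per homozygous window.
#' @param window_missing_allowed missing calls tolerated per window.
#' @param window_hit_fraction minimum fraction of overlapping windows that
#'   must be homozygous for a SNP to be run-eligible.
#' @param min_snp minimum SNPs per reported segment.
#' @param min_length_kb minimum segment length.
#' @param min_density_kb_per_snp maximum average spacing within a segment.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a run.
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50L, window_het_allowed = 1L,
                       window_missing_allowed = 5L,
                       window_hit_fraction = 0.05,
                       min_snp = 100L, min_length_kb = 1000,
                       min_density_kb_per_snp = 50, max_gap_kb = 1000) {
  vals <- c(window_snp, window_het_allowed + 1, window_missing_allowed + 1,
            window_hit_fraction, min_snp, min_length_kb,
            min_density_kb_per_snp, max_gap_kb)
  if (any(vals <= 0)) stop("ROH parameters must be positive")
  structure(list(window_snp = as.integer(window_snp),
                 window_het_allowed = as.integer(window_het_allowed),
                 window_missing_allowed = as.integer(window_missing_allowed),
                 window_hit_fraction = window_hit_fraction,
                 min_snp = as.integer(min_snp),
                 min_length_kb = min_length_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp,
                 max_gap_kb = max_gap_kb),
            class = "roh_params")
}

# Run-eligible SNP flags for one genotype vector on one chromosome.
roh_eligible <- function(g, params) {
  s <- length(g)
  w <- params$window_snp
  if (s < w) return(rep(FALSE, s))
  het <- as.numeric(!is.na(g) & g == 1L)
  mis <- as.numeric(is.na(g))
  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(w + 1):(s + 1)] - cs[1:(s - w + 1)]
  }
  hom_win <- wsum(het) <= params$window_het_allowed &
    wsum(mis) <= params$window_missing_allowed
  nw <- s - w + 1L
  # Windows covering SNP i start in [max(1, i-w+1), min(i, nw)].
  cs <- c(0, cumsum(as.numeric(hom_win)))
  i <- seq_len(s)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  hits <- cs[hi + 1L] - cs[lo]
  hits / (hi - lo + 1L) >= params$window_hit_fraction
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome, a window of `window_snp` SNPs slides along
#' the map; a window is homozygous if it contains at most
#' `window_het_allowed` heterozygotes and `window_missing_allowed` missing
#' calls. Each SNP's hit rate is the fraction of overlapping windows that
#' are homozygous; SNPs at or above `window_hit_fraction` are run-eligible.
#' Maximal eligible stretches -- split where consecutive SNPs are more than
#' `max_gap_kb` apart -- are reported when they satisfy the `min_snp`,
#' `min_length_kb` and density constraints, with boundaries at the
#' outermost eligible SNPs.
#'
#' @param gm a [genotype_matrix()] whose markers are sorted by
#'   (chromosome, position); unsorted input is an error.
#' @param params a [roh_params()].
#' @return data.frame of class `roh_segments`: `iid`, `chrom`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_mb`.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  validate_genotype_matrix(gm)
  mk <- gm$markers
  chroms <- unique(mk$chrom)
  out <- list()
  for (chr in chroms) {
    idx <- which(mk$chrom == chr)
    bp <- mk$bp[idx]
    if (is.unsorted(bp)) {
      stop("markers on chromosome ", chr,
           " are not position-sorted; sort the map first")
    }
    gap_split <- c(FALSE, diff(bp) > params$max_gap_kb * 1000)
    for (si in seq_len(n_samples(gm))) {
      g <- gm$calls[si, idx]
      elig <- roh_eligible(g, params)
      if (!any(elig)) next
      # Runs of eligible SNPs, broken at oversized gaps.
      brk <- cumsum(!elig | gap_split)
      runs <- split(which(elig), brk[elig])
      for (rr in runs) {
        n_snps <- length(rr)
        if (n_snps < params$min_snp) next
        start <- bp[rr[1]]; end <- bp[rr[n_snps]]
        len_kb <- (end - start) / 1000
        if (len_kb < params$min_length_kb) next
        if (len_kb / n_snps > params$min_density_kb_per_snp) next
        out[[length(out) + 1L]] <- data.frame(
          iid = gm$samples$iid[si], chrom = chr,
          start_bp = start, end_bp = end, n_snps = n_snps,
          length_mb = (end - start) / 1e6, stringsAsFactors = FALSE)
      }
    }
  }
  segs <- if (length(out)) do.call(rbind, out) else
    data.frame(iid = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               n_snps = integer(0), length_mb = numeric(0))
  rownames(segs) <- NULL
  class(segs) <- c("roh_segments", "data.frame")
  segs
}

#' ROH-based genomic inbreeding coefficient
#'
#' `F_ROH,i` is the summed length of individual `i`'s segments divided by
#' the autosomal map length `L_auto` (sum over autosomes of last-minus-first
#' SNP position), so synthetic and real maps are handled uniformly.
#'
#' @param segments a [detect_roh()] result.
#' @param gm the [genotype_matrix()] the segments were called on.
#' @param n_autosomes autosome count defining the map denominator.
#' @return Named numeric vector of F_ROH per individual (0 for individuals
#'   without segments), in `[0, 1]`.
#' @export
f_roh <- function(segments, gm, n_autosomes = 29L) {
  mk <- gm$markers
  auto <- mk[is_autosome(mk$chrom, n_autosomes), ]
  if (!nrow(auto)) stop("no autosomal markers on the map")
  l_auto <- sum(tapply(auto$bp, auto$chrom, function(x) max(x) - min(x)))
  tot <- tapply(segments$end_bp - segments$start_bp, segments$iid, sum)
  f <- stats::setNames(rep(0, n_samples(gm)), gm$samples$iid)
  f[names(tot)] <- tot / l_auto
  pmin(f, 1)
}

#' Summaries of a ROH scan
#'
#' Per-individual counts and total lengths, segment-length class fractions,
#' per-chromosome counts, and F_ROH overall and by sex.
#'
#' @param segments a [detect_roh()] result.
#' @param gm the [genotype_matrix()] the segments were called on.
#' @param length_bins_mb segment-length class edges in Mb (last class open).
#' @param n_autosomes passed to [f_roh()].
#' @return An object of class `roh_summary`: `n_segments`, `per_individual`
#'   (data.frame `iid`, `sex`, `n_roh`, `total_mb`, `f_roh`),
#'   `length_class_fractions`, `per_chromosome` counts, `total_length_class_counts`
#'   (100 Mb classes of per-individual total length), `f_roh_by_sex`
#'   (mean +/- SD), `l_auto_mb`.
#' @export
roh_summaries <- function(segments, gm,
                          length_bins_mb = c(0, 5, 10, 15, 20),
                          n_autosomes = 29L) {
  f <- f_roh(segments, gm, n_autosomes = n_autosomes)
  per_ind <- data.frame(
    iid = gm$samples$iid, sex = gm$samples$sex,
    n_roh = 0L, total_mb = 0, f_roh = unname(f),
    stringsAsFactors = FALSE)
  if (nrow(segments)) {
    cnt <- table(segments$iid)
    tot <- tapply(segments$length_mb, segments$iid, sum)
    per_ind$n_roh[match(names(cnt), per_ind$iid)] <- as.integer(cnt)
    per_ind$total_mb[match(names(tot), per_ind$iid)] <- as.numeric(tot)
  }
  edges <- c(length_bins_mb, Inf)
  k <- length(edges) - 1L
  lab <- c(paste0(edges[seq_len(k - 1L)], "-", edges[1L + seq_len(k - 1L)]),
           paste0(">", edges[k]))
  len_class <- if (nrow(segments)) {
    cut(segments$length_mb, edges, labels = lab, right = FALSE)
  } else factor(character(0), levels = lab)
  per_chrom <- if (nrow(segments)) table(segments$chrom) else table(character(0))
  by_sex <- tapply(per_ind$f_roh, per_ind$sex, function(x) {
    c(mean = mean(x), sd = stats::sd(x), n = length(x))
  })
  tot_class <- table(cut(per_ind$total_mb,
                         c(seq(0, 1000, by = 100), Inf), right = FALSE))
  structure(list(
    n_segments = nrow(segments),
    per_individual = per_ind,
    length_class_fractions = if (nrow(segments)) prop.table(table(len_class))
                             else prop.table(table(len_class)) * 0,
    per_chromosome = per_chrom,
    total_length_class_counts = tot_class,
    f_roh_by_sex = by_sex,
    f_roh_mean = mean(per_ind$f_roh), f_roh_sd = stats::sd(per_ind$f_roh)
  ), class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat("roh_summary:", x$n_segments, "segments over",
      nrow(x$per_individual), "individuals\n")
  cat(sprintf("  F_ROH: %.4f +/- %.4f\n", x$f_roh_mean, x$f_roh_sd))
  if (x$n_segments > 0) {
    lc <- x$length_class_fractions
    cat("  length classes (Mb):",
        paste(names(lc), sprintf("%.1f%%", 100 * as.numeric(lc)),
              sep = " ", collapse = ", "), "\n")
  }
  invisible(x)
}
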
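#' Quality-control thresholds
#'
#' Thresholds for the sequential marker/sample filters. Defaults are the
#' standard SNP-array criteria for livestock diversity studies: autosomal
#' loci only, call rates of at least 0.90 for both markers and individuals,
#' an exact Hardy-Weinberg p-value of at least 1e-6, and a minor allele
#' frequency of at least 0.01.
#'
#' @param snp_call_rate_min minimum per-marker call rate.
#' @param sample_call_rate_min minimum per-individual call rate.
#' @param hwe_p_min minimum exact HWE p-value.
#' @param maf_min minimum minor allele frequency.
#' @param autosomes_only drop markers on X/Y/unplaced ("0") chromosomes?
#' @param n_autosomes number of autosomes defining the autosomal label set.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_min = 0.90,
                          sample_call_rate_min = 0.90,
                          hwe_p_min = 1e-6, maf_min = 0.01,
                          autosomes_only = TRUE, n_autosomes = 29L) {
  stopifnot(snp_call_rate_min >= 0, snp_call_rate_min <= 1,
            sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5)
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 sample_call_rate_min = sample_call_rate_min,
                 hwe_p_min = hwe_p_min, maf_min = maf_min,
                 autosomes_only = isTRUE(autosomes_only),
                 n_autosomes = as.integer(n_autosomes)),
            class = "qc_thresholds")
}

#' Per-marker and per-sample call rates
#'
#' Call rate is the non-missing fraction of genotypes (over samples for a
#' marker, over markers for a sample).
#'
#' @param gm a [genotype_matrix()].
#' @return Numeric vector in `[0, 1]`, named by marker id / sample iid.
#' @export
snp_call_rates <- function(gm) {
  if (n_samples(gm) < 1L) stop("need at least one sample")
  colMeans(!is.na(gm$calls))
}

#' @rdname snp_call_rates
#' @export
sample_call_rates <- function(gm) {
  if (n_markers(gm) < 1L) stop("need at least one marker")
  rowMeans(!is.na(gm$calls))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic genotype table: conditioning on the
#' observed allele counts, the p-value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count (no mid-p adjustment). Probabilities follow the
#' standard levene-haldane distribution
#' \eqn{P(n_{ab}) = \frac{2^{n_{ab}} n! \, n_a! \, n_b!}{n_{aa}! n_{ab}! n_{bb}! \, (2n)!}}
#' computed by recurrence for numerical stability.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (hom allele1, het, hom allele2).
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("negative genotype count")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("all genotype counts are zero")
  n_a <- 2 * n_hom1 + n_het              # minor-or-major; symmetric below
  n_minor <- min(n_a, 2 * n - n_a)
  # Attainable heterozygote counts share the parity of the minor allele count.
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- numeric(length(hets))
  # Unnormalized recurrence upward from the smallest attainable het count:
  # P(h + 2) / P(h) = 4 * n_aa(h) * n_bb(h) / ((h + 2) * (h + 1)).
  lp <- 0
  for (i in seq_along(hets)) {
    probs[i] <- lp
    h <- hets[i]
    if (i < length(hets)) {
      naa <- (n_minor - h) / 2
      nbb <- n - (h + n_minor) / 2       # (2n - n_minor - h) / 2
      lp <- lp + log(4 * naa * nbb) - log((h + 2) * (h + 1))
    }
  }
  probs <- exp(probs - max(probs))
  probs <- probs / sum(probs)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  min(1, sum(probs[probs <= probs[obs] * (1 + 1e-12)]))
}

# Vectorized HWE p over the markers of a genotype matrix.
hwe_exact_p_markers <- function(gm) {
  g <- gm$calls
  n2 <- colSums(!is.na(g) & g == 2L)
  n1 <- colSums(!is.na(g) & g == 1L)
  n0 <- colSums(!is.na(g) & g == 0L)
  out <- rep(NA_real_, ncol(g))
  ok <- (n0 + n1 + n2) > 0
  out[ok] <- vapply(which(ok), function(j) hwe_exact_p(n2[j], n1[j], n0[j]),
                    numeric(1))
  out
}

# Per-marker minor allele frequency over non-missing calls.
marker_maf <- function(gm) {
  p <- allele1_freq(gm)
  pmin(p, 1 - p)
}

#' Construct a QC accounting report
#'
#' Holds the per-filter marker removal counts under the first-filter-wins
#' attribution, so the accounting identity
#' `total - (sexchrom + callrate + hwe + maf) == retained` always holds.
#'
#' @param total_markers markers before any filter.
#' @param removed_sexchrom markers on sex chromosomes or unplaced scaffolds.
#' @param removed_snp_callrate markers under the call-rate threshold.
#' @param removed_hwe markers failing the exact HWE test.
#' @param removed_maf markers under the MAF threshold.
#' @param removed_samples individuals removed by the sample call-rate filter
#'   (reported separately; not part of the marker accounting).
#' @return An object of class `qc_report`; `retained_markers` is derived from
#'   the identity.
#' @export
qc_report <- function(total_markers, removed_sexchrom, removed_snp_callrate,
                      removed_hwe, removed_maf, removed_samples = 0L) {
  counts <- c(total_markers, removed_sexchrom, removed_snp_callrate,
              removed_hwe, removed_maf, removed_samples)
  if (any(counts < 0)) stop("negative count in QC report")
  retained <- total_markers - removed_sexchrom - removed_snp_callrate -
    removed_hwe - removed_maf
  if (retained < 0) stop("removal counts exceed total_markers")
  structure(list(
    total_markers = as.integer(total_markers),
    removed_sexchrom = as.integer(removed_sexchrom),
    removed_snp_callrate = as.integer(removed_snp_callrate),
    removed_hwe = as.integer(removed_hwe),
    removed_maf = as.integer(removed_maf),
    removed_samples = as.integer(removed_samples),
    retained_markers = as.integer(retained),
    pct = NULL
  ), class = "qc_report")
}

#' Populate display percentages of a QC report
#'
#' Removal percentages are computed against `total_markers` and truncated
#' (floored) at the displayed precision -- 2 decimals for the per-filter
#' categories, 1 decimal for the removed total -- so a removal fraction is
#' never overstated; the retained percentage is the complement of the floored
#' removed total. Exact fractions are stored alongside in `pct$exact`.
#'
#' @param report a [qc_report()].
#' @param digits decimals for the per-category display percentages.
#' @return The report with a `pct` element populated.
#' @export
qc_percentages <- function(report, digits = 2L) {
  stopifnot(inherits(report, "qc_report"))
  tot <- report$total_markers
  if (tot <= 0) stop("total_markers must be positive")
  cats <- c(sexchrom = report$removed_sexchrom,
            snp_callrate = report$removed_snp_callrate,
            hwe = report$removed_hwe, maf = report$removed_maf)
  removed_total <- sum(cats)
  report$pct <- list(
    categories = vapply(cats, pct_floor, numeric(1), total = tot,
                        digits = digits),
    removed_total = pct_floor(removed_total, tot, digits = 1L),
    retained = 100 - pct_floor(removed_total, tot, digits = 1L),
    exact = c(100 * cats / tot,
              removed_total = 100 * removed_total / tot,
              retained = 100 * report$retained_markers / tot)
  )
  report
}

#' @export
print.qc_report <- function(x, ...) {
  writeLines(render_qc_table(x))
  invisible(x)
}

#' Apply sequential quality control
#'
#' Filters are applied in a fixed order and every removed marker is counted
#' against the first filter that removes it, so the per-filter counts sum
#' exactly to `total - retained`:
#' 1. drop non-autosomal / unplaced markers (if `autosomes_only`);
#' 2. drop samples whose call rate over the remaining markers is below
#'    `sample_call_rate_min`;
#' 3. drop markers with call rate below `snp_call_rate_min`;
#' 4. drop markers with exact HWE p below `hwe_p_min`;
#' 5. drop markers with MAF below `maf_min` (on non-missing calls of the
#'    retained samples).
#'
#' @param gm a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (a [qc_report()] with percentages populated).
#' @export
apply_qc <- function(gm, thr = qc_thresholds()) {
  validate_genotype_matrix(gm)
  stopifnot(inherits(thr, "qc_thresholds"))
  total <- n_markers(gm)

  keep_m <- rep(TRUE, total)
  if (thr$autosomes_only) {
    keep_m <- is_autosome(gm$markers$chrom, thr$n_autosomes)
  }
  n_sex <- sum(!keep_m)
  cur <- gm[, which(keep_m)]

  scr <- sample_call_rates(cur)
  keep_s <- scr >= thr$sample_call_rate_min
  n_samp <- sum(!keep_s)
  cur <- cur[which(keep_s), ]

  if (n_samples(cur) == 0L) {
    warning("no samples survive the call-rate filter; ",
            "marker filters cannot be evaluated")
    report <- qc_percentages(qc_report(
      total_markers = total, removed_sexchrom = n_sex,
      removed_snp_callrate = 0L, removed_hwe = 0L, removed_maf = 0L,
      removed_samples = n_samp))
    return(list(genotypes = cur, report = report))
  }

  cr <- snp_call_rates(cur)
  pass_cr <- cr >= thr$snp_call_rate_min
  n_cr <- sum(!pass_cr)
  cur <- cur[, which(pass_cr)]

  hwe_p <- hwe_exact_p_markers(cur)
  pass_hwe <- is.na(hwe_p) | hwe_p >= thr$hwe_p_min
  n_hwe <- sum(!pass_hwe)
  cur <- cur[, which(pass_hwe)]

  maf <- marker_maf(cur)
  maf[is.nan(maf)] <- 0          # all-missing marker: no estimable MAF
  pass_maf <- maf >= thr$maf_min
  n_maf <- sum(!pass_maf)
  cur <- cur[, which(pass_maf)]

  if (n_markers(cur) == 0L) {
    warning("no markers survive quality control")
  }
  report <- qc_percentages(qc_report(
    total_markers = total, removed_sexchrom = n_sex,
    removed_snp_callrate = n_cr, removed_hwe = n_hwe, removed_maf = n_maf,
    removed_samples = n_samp
  ))
  list(genotypes = cur, report = report)
}
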
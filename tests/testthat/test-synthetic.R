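test_that("generation is deterministic for a fixed seed", {
  cfg <- sim_config(n_autosomal_markers = 2000, n_sex_markers = 100,
                    n_hwe_violators = 10, n_rare_loci = 20,
                    roh_per_individual = 1, seed = 3)
  h1 <- generate_herd(cfg)
  h2 <- generate_herd(cfg)
  expect_identical(h1$genotypes$calls, h2$genotypes$calls)
  expect_identical(h1$truth$planted_roh, h2$truth$planted_roh)
  expect_identical(h1$truth$sire_of, h2$truth$sire_of)
})

test_that("with no missingness and no violators, non-planted loci satisfy HWE", {
  cfg <- sim_config(n_bulls = 0, n_cows = 60, n_admixed = 0, n_families = 0,
                    n_autosomal_markers = 5000, n_sex_markers = 0,
                    panel_size = 0, n_hwe_violators = 0, n_rare_loci = 0,
                    missing_rate_marker = 0, low_quality_marker_frac = 0,
                    missing_rate_sample = 0, roh_per_individual = 0,
                    seed = 21)
  h <- generate_herd(cfg)
  expect_false(anyNA(h$genotypes$calls))
  g <- h$genotypes$calls
  pvals <- vapply(seq_len(ncol(g)), function(j) {
    hwe_exact_p(sum(g[, j] == 2), sum(g[, j] == 1), sum(g[, j] == 0))
  }, numeric(1))
  expect_gte(mean(pvals >= 1e-6), 0.99)
})

test_that("panel loci at frequency 1 force the maximum purity score", {
  cfg <- sim_config(n_bulls = 4, n_cows = 20, n_admixed = 4, n_families = 2,
                    n_autosomal_markers = 1000, n_sex_markers = 0,
                    panel_size = 25, purebred_panel_freq = 1.0,
                    admixed_panel_freq = 0.2,
                    missing_rate_marker = 0, low_quality_marker_frac = 0,
                    missing_rate_sample = 0, n_hwe_violators = 0,
                    n_rare_loci = 0, roh_per_individual = 0, seed = 8)
  h <- generate_herd(cfg)
  panel_cols <- match(h$truth$panel_truth_loci, h$genotypes$markers$id)
  pure_rows <- match(h$truth$purebred_ids, h$genotypes$samples$iid)
  scores <- rowSums(h$genotypes$calls[pure_rows, panel_cols])
  expect_true(all(scores == 2 * 25))
})

test_that("offspring are Mendelian-consistent with recorded sires", {
  cfg <- sim_config(n_bulls = 6, n_cows = 30, n_admixed = 0, n_families = 6,
                    n_autosomal_markers = 3000, n_sex_markers = 0,
                    panel_size = 20, n_hwe_violators = 15, n_rare_loci = 30,
                    missing_rate_marker = 0, low_quality_marker_frac = 0,
                    missing_rate_sample = 0, roh_per_individual = 0,
                    seed = 13)
  h <- generate_herd(cfg)
  g <- h$genotypes$calls
  for (cw in names(h$truth$sire_of)) {
    gc <- g[cw, ]; gs <- g[h$truth$sire_of[[cw]], ]
    opposing <- sum((gc == 0 & gs == 2) | (gc == 2 & gs == 0))
    expect_equal(opposing, 0)
  }
})

test_that("planted ROH are exactly homozygous before missingness", {
  cfg <- roh_test_config(seed = 4)
  h <- generate_herd(cfg)
  cfg0 <- roh_test_config(seed = 4)
  cfg0$missing_rate_marker <- 0
  h0 <- generate_herd(cfg0)
  mk <- h0$genotypes$markers
  pl <- h0$truth$planted_roh
  for (r in seq_len(min(nrow(pl), 50))) {
    idx <- which(mk$chrom == pl$chrom[r] & mk$bp >= pl$start_bp[r] &
                   mk$bp <= pl$end_bp[r])
    g <- h0$genotypes$calls[pl$iid[r], idx]
    expect_true(all(g %in% c(0L, 2L)))
  }
  # and every planted segment lies inside its chromosome's marker span
  for (chr in unique(pl$chrom)) {
    span <- range(mk$bp[mk$chrom == chr])
    d <- pl[pl$chrom == chr, ]
    expect_true(all(d$start_bp >= span[1] & d$end_bp <= span[2]))
  }
})

test_that("planted rare and HWE-violator loci have the designed signatures", {
  cfg <- sim_config(n_bulls = 6, n_cows = 54, n_admixed = 6, n_families = 4,
                    n_autosomal_markers = 2000, n_sex_markers = 0,
                    panel_size = 10, n_hwe_violators = 25, n_rare_loci = 40,
                    missing_rate_marker = 0, low_quality_marker_frac = 0,
                    missing_rate_sample = 0, roh_per_individual = 0,
                    seed = 31)
  h <- generate_herd(cfg)
  g <- h$genotypes$calls
  hwe_cols <- match(h$truth$hwe_violator_loci, h$genotypes$markers$id)
  expect_true(all(colSums(g[, hwe_cols] == 1) == 0))
  freq <- colMeans(g[, hwe_cols]) / 2
  # family sharing makes a few loci drift, but most stay intermediate
  expect_gte(mean(freq > 0.2 & freq < 0.8), 0.8)
  rare_cols <- match(h$truth$rare_loci, h$genotypes$markers$id)
  maf <- pmin(colMeans(g[, rare_cols]) / 2, 1 - colMeans(g[, rare_cols]) / 2)
  expect_true(all(maf > 0 & maf < 0.01))
})

test_that("Wright-Fisher founders sit at frequency 0.5 and tiny populations fix", {
  gm0 <- wright_fisher_drift(50, 0, 500, 200, seed = 5)
  p <- colMeans(gm0$calls) / 2
  # founder-pool + sampling noise: per-locus SD ~ 0.05, so assert on the
  # deviation distribution rather than every locus
  expect_lt(abs(mean(p) - 0.5), 0.02)
  expect_lt(mean(abs(p - 0.5)), 0.06)
  gm_fix <- wright_fisher_drift(2, 50, 300, 50, seed = 6)
  maf <- pmin(colMeans(gm_fix$calls) / 2, 1 - colMeans(gm_fix$calls) / 2)
  expect_gte(mean(maf == 0), 0.95)
  expect_identical(wright_fisher_drift(10, 5, 100, 20, seed = 7)$calls,
                   wright_fisher_drift(10, 5, 100, 20, seed = 7)$calls)
})
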
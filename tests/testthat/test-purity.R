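# Two perfectly separated clusters differing only at planted loci: the
# canonical fixture for PC1-loading recovery.
make_two_cluster_gm <- function(n_per = 10, n_planted = 20, n_noise = 80,
                                seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  planted <- rbind(matrix(2L, n_per, n_planted), matrix(0L, n_per, n_planted))
  noise <- matrix(rbinom(n * n_noise, 2, 0.5), n, n_noise)
  make_gm(cbind(planted, noise),
          bp = seq(1e5, by = 1e5, length.out = n_planted + n_noise))
}

test_that("PC1 contributions recover planted cluster loci and sum to 1", {
  gm <- make_two_cluster_gm()
  pca <- genotype_pca(gm, k = 3)
  expect_equal(sum(pca$pc1_contribution), 1, tolerance = 1e-9)
  expect_true(all(diff(pca$eigenvalues) <= 1e-8))
  top <- top_pc1_loci(pca, k = 20)
  expect_setequal(top, paste0("m", 1:20))
})

test_that("duplicated samples get identical PC1 scores; monomorphic loci load zero", {
  set.seed(4)
  base <- matrix(rbinom(8 * 30, 2, 0.4), 8, 30)
  base[, 30] <- 2L                     # monomorphic column
  gm <- make_gm(rbind(base, base), iid = sprintf("s%02d", 1:16))
  pca <- genotype_pca(gm, k = 2)
  expect_equal(pca$sample_scores[1:8, 1], pca$sample_scores[9:16, 1],
               ignore_attr = TRUE)
  expect_equal(pca$pc1_contribution[["m30"]], 0)
})

test_that("top_pc1_loci breaks exact ties by map position", {
  fake <- structure(list(
    pc1_contribution = c(m1 = 0.3, m2 = 0.4, m3 = 0.3),
    markers = data.frame(id = c("m1", "m2", "m3"), chrom = c("2", "1", "1"),
                         bp = c(100, 50, 500), stringsAsFactors = FALSE)
  ), class = "genotype_pca")
  expect_equal(top_pc1_loci(fake, k = 3), c("m2", "m3", "m1"))
  gm <- make_two_cluster_gm(n_per = 6, n_planted = 4, n_noise = 10)
  pca <- genotype_pca(gm, k = 2)
  expect_setequal(top_pc1_loci(pca, k = 4), paste0("m", 1:4))
  expect_setequal(top_pc1_loci(pca, k = 14), paste0("m", 1:14))
})

test_that("concordance classes follow the primary-allele-frequency thresholds", {
  gm <- make_gm(cbind(c(2L, 2L, 2L, 2L, 2L),    # p1 = 1.0 -> high
                      c(2L, 2L, 1L, 1L, 0L),    # p1 = 0.6 -> medium
                      c(1L, 1L, 1L, 1L, 1L),    # p1 = 0.5 tie -> allele1
                      c(0L, 0L, 0L, 0L, 1L),    # primary = allele2, 0.9
                      c(NA, NA, NA, NA, NA)))
  tab <- concordance_table(gm)
  expect_equal(tab$concordance_class[1:4],
               c("high", "medium", "medium", "high"))
  expect_equal(tab$primary_allele[1:4], c("A", "A", "A", "G"))
  expect_equal(tab$primary_freq[1:4], c(1, 0.6, 0.5, 0.9))
  expect_true(is.na(tab$concordance_class[5]))
})

test_that("concordance is invariant to allele-label swaps", {
  gm <- random_gm(n = 18, L = 40, seed = 6)
  tab1 <- concordance_table(gm)
  swapped <- gm
  poly <- swapped$markers$allele2 != "0"
  swapped$calls[, poly] <- 2L - swapped$calls[, poly]
  a1 <- swapped$markers$allele1[poly]
  swapped$markers$allele1[poly] <- swapped$markers$allele2[poly]
  swapped$markers$allele2[poly] <- a1
  tab2 <- concordance_table(swapped)
  expect_equal(tab1$primary_freq, tab2$primary_freq)
  expect_equal(tab1$concordance_class, tab2$concordance_class)
  expect_equal(tab1$primary_allele[poly], tab2$primary_allele[poly])
})

test_that("select_panel keeps the ordered intersection with high-concordance loci", {
  gm <- make_gm(cbind(c(2L, 2L, 2L), c(2L, 1L, 0L), c(2L, 2L, 2L)))
  tab <- concordance_table(gm)
  expect_equal(select_panel(c("m3", "m1"), tab)$marker_id, c("m3", "m1"))
  expect_equal(select_panel(c("m2", "m1"), tab)$marker_id, "m1")
  expect_warning(p <- select_panel("m2", tab), "empty panel")
  expect_equal(nrow(p), 0)
})

test_that("purity scores count primary-allele copies and rank deterministically", {
  gm <- make_gm(rbind(c(2L, 2L), c(1L, 2L), c(NA, NA), c(2L, 2L)),
                iid = c("d", "b", "c", "a"))
  tab <- concordance_table(gm)
  panel <- select_panel(c("m1", "m2"), tab)
  rk <- purity_scores(gm, panel, n_keep = 2)
  expect_equal(rk$score[rk$iid == "a"], 4)       # max = 2 x panel size
  expect_equal(rk$score[rk$iid == "c"], 0)       # all missing -> 0
  expect_equal(rk$iid, c("a", "d", "b", "c"))    # ties by id
  expect_equal(rk$iid[rk$selected], c("a", "d"))
})

test_that("screening recovers a planted purebred core without errors", {
  for (seed in c(2, 9, 27)) {
    cfg <- sim_config(n_bulls = 12, n_cows = 62, n_admixed = 14,
                      n_autosomal_markers = 4000, n_sex_markers = 0,
                      panel_size = 61, purebred_panel_freq = 0.95,
                      admixed_panel_freq = 0.2, n_hwe_violators = 0,
                      n_rare_loci = 0, roh_per_individual = 0, seed = seed)
    h <- generate_herd(cfg)
    qc <- apply_qc(h$genotypes)
    scr <- screen_purity(qc$genotypes, top_k = 100, n_keep = 60)
    expect_setequal(scr$selected_ids, h$truth$purebred_ids)
  }
})
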
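test_that("NJ reproduces the additive 4-taxon oracle exactly", {
  D <- matrix(c(0, 5, 9, 10,
                5, 0, 10, 11,
                9, 10, 0, 9,
                10, 11, 9, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_tree(D)
  expect_false(attr(tree, "negative_clamped"))
  # path lengths reproduce the additive input exactly
  C <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(C, D, tolerance = 1e-9)
  # known branch lengths: A:2 B:3 C:4 D:5 internal:3
  bl <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                        tree$edge[, 2])], tree$tip.label)
  expect_equal(bl[LETTERS[1:4]], c(A = 2, B = 3, C = 4, D = 5))
  expect_equal(sum(tree$edge.length), 2 + 3 + 4 + 5 + 3)
})

test_that("three leaves resolve by the closed form", {
  D <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(D)
  bl <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                        tree$edge[, 2])], tree$tip.label)
  expect_equal(bl[c("x", "y", "z")], c(x = 1, y = 3, z = 5))
})

test_that("NJ is consistent on random additive trees", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:12, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.5, 2))
    true <- ape::unroot(true)
    D <- ape::cophenetic.phylo(true)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(est), true), 0,
                 ignore_attr = TRUE)
    C <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_equal(C, D, tolerance = 1e-9)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  set.seed(42)
  for (rep in 1:3) {
    gm <- random_gm(n = 10, L = 300, missing_rate = 0, seed = rep + 50)
    D <- ibs_distance(gm)
    mine <- nj_tree(unclass(D))
    ref <- ape::nj(stats::as.dist(unclass(D)))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("tiny inputs give trivial trees with warnings; Newick round-trips", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_warning(tr <- nj_tree(D2), "fewer than 3")
  expect_setequal(tr$tip.label, c("a", "b"))
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  back <- ape::read.tree(text = nwk)
  expect_setequal(back$tip.label, tr$tip.label)
  # labels with spaces survive via the Newick underscore convention
  D3 <- matrix(c(0, 4, 6, 4, 0, 8, 6, 8, 0), 3, 3)
  rownames(D3) <- colnames(D3) <- c("bull one", "bull two", "cowX")
  tr3 <- nj_tree(D3)
  expect_setequal(tr3$tip.label, c("bull one", "bull two", "cowX"))
  back3 <- ape::read.tree(text = to_newick(tr3))
  expect_setequal(gsub("_", " ", back3$tip.label),
                  c("bull one", "bull two", "cowX"))
})

test_that("family assignment follows the threshold rule", {
  ids <- c("B1", "B2", "C1")
  G <- matrix(c(1, 0.3, 0.15,
                0.3, 1, 0.02,
                0.15, 0.02, 1), 3, 3, dimnames = list(ids, ids))
  class(G) <- c("square_matrix", "matrix")
  samples <- data.frame(iid = ids, sex = c("male", "male", "female"),
                        stringsAsFactors = FALSE)
  fa <- assign_families(G, samples, threshold = 0.1)
  expect_length(fa$families, 1)
  expect_setequal(fa$families[[1]]$bulls, c("B1", "B2"))
  expect_equal(fa$families[[1]]$cows, "C1")
  expect_length(fa$other_cows, 0)
})

test_that("below-threshold kinship yields singleton bull families and other cows", {
  ids <- c("B1", "B2", "B3", "C1", "C2")
  G <- diag(5) * 1
  dimnames(G) <- list(ids, ids)
  class(G) <- c("square_matrix", "matrix")
  samples <- data.frame(iid = ids,
                        sex = c("male", "male", "male", "female", "female"),
                        stringsAsFactors = FALSE)
  fa <- assign_families(G, samples)
  expect_length(fa$families, 3)
  expect_true(all(lengths(lapply(fa$families, `[[`, "bulls")) == 1))
  expect_setequal(fa$other_cows, c("C1", "C2"))
})

test_that("raising the threshold never moves a cow from other into a family", {
  gm <- random_gm(n = 25, L = 400, seed = 31)
  G <- grm(gm)
  samples <- gm$samples
  prev_other <- character(0)
  for (thr in c(0.05, 0.1, 0.2, 0.4)) {
    fa <- assign_families(G, samples, threshold = thr)
    expect_true(all(prev_other %in% fa$other_cows))
    prev_other <- fa$other_cows
  }
})

test_that("assignment is invariant to individual ordering", {
  gm <- random_gm(n = 20, L = 300, seed = 33)
  G <- grm(gm)
  fa1 <- assign_families(G, gm$samples, threshold = 0.08)
  perm <- sample(nrow(gm$samples))
  fa2 <- assign_families(G[perm, perm], gm$samples[perm, ], threshold = 0.08)
  expect_equal(fa1$membership[sort(names(fa1$membership))],
               fa2$membership[sort(names(fa2$membership))])
})

test_that("families recover planted half-sib truth on synthetic herds", {
  tot <- c(0, 0)
  for (seed in c(6, 13, 29)) {
    cfg <- sim_config(n_bulls = 10, n_cows = 40, n_admixed = 0,
                      n_families = 10, n_autosomal_markers = 4000,
                      n_sex_markers = 0, panel_size = 0,
                      n_hwe_violators = 0, n_rare_loci = 0,
                      roh_per_individual = 0, seed = seed)
    h <- generate_herd(cfg)
    G <- grm(h$genotypes)
    fa <- assign_families(G, h$genotypes$samples, threshold = 0.1)
    tot <- tot + family_match_rate(fa, h$truth, h$genotypes$samples$iid)
  }
  expect_gte(tot[1] / tot[2], 0.9)
})

test_that("bull lineages form connected subtrees in the NJ tree", {
  cfg <- sim_config(n_bulls = 12, n_cows = 0, n_admixed = 0, n_families = 3,
                    n_autosomal_markers = 3000, n_sex_markers = 0,
                    panel_size = 0, n_hwe_violators = 0, n_rare_loci = 0,
                    missing_rate_marker = 0, low_quality_marker_frac = 0,
                    missing_rate_sample = 0,
                    roh_per_individual = 0, seed = 44)
  # three sire lineages: clone-like groups via shared sires
  h <- generate_herd(cfg)
  g <- h$genotypes$calls
  # build 3 lineages of 4 half-sibs each from the first 3 bulls
  set.seed(44)
  L <- ncol(g)
  p <- colMeans(g) / 2
  lineage <- do.call(rbind, lapply(1:3, function(k) {
    t(vapply(1:4, function(i) {
      (runif(L) < g[k, ] / 2) + (runif(L) < rbinom(L, 2, p) / 2)
    }, numeric(L)))
  }))
  gm <- make_gm(lineage, chrom = h$genotypes$markers$chrom,
                bp = h$genotypes$markers$bp,
                iid = paste0("L", rep(1:3, each = 4), "_", rep(1:4, 3)))
  tree <- nj_tree(unclass(ibs_distance(gm)))
  for (k in 1:3) {
    tips <- paste0("L", k, "_", 1:4)
    # connectedness in the unrooted tree: monophyly after rooting outside
    out_tip <- paste0("L", (k %% 3) + 1, "_1")
    rooted <- ape::root(tree, outgroup = out_tip, resolve.root = TRUE)
    expect_true(ape::is.monophyletic(rooted, tips))
  }
})
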
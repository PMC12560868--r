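test_that("locus statistics match closed forms at reference frequencies", {
  # p = 0.5: 10 individuals, 5 het + reference homs give exact p
  gm <- make_gm(cbind(
    c(rep(2L, 5), rep(0L, 5)),                 # p = 0.5, ho = 0
    rep(1L, 10),                               # p = 0.5, all het
    c(rep(2L, 8), 1L, 1L),                     # p = 0.9
    rep(2L, 10),                               # p = 1 fixed
    c(rep(2L, 6), rep(1L, 4))                  # p = 0.8
  ))
  st <- locus_stats(gm)
  expect_equal(st$he[1], 0.5)
  expect_equal(st$pic[1], 0.375)
  expect_equal(st$shi[1], log(2))
  expect_equal(st$ho[2], 1)
  expect_equal(st$maf[4], 0)
  expect_equal(st$he[4], 0)
  expect_equal(st$pic[4], 0)
  expect_equal(st$shi[4], 0)
  expect_equal(st$pic[5], 1 - 0.68 - 2 * 0.64 * 0.04)   # 0.2688
  st2 <- locus_stats(gm, shi_base = "2")
  expect_equal(st2$shi[1], 1)
})

test_that("pic <= he with equality only at fixed loci; SHI symmetric, max at 0.5", {
  p <- seq(0.01, 0.99, by = 0.01)
  he <- 2 * p * (1 - p)
  pic <- 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2
  expect_true(all(pic <= he))
  expect_true(all(pic < he))
  shi <- -(p * log(p) + (1 - p) * log(1 - p))
  expect_equal(shi, rev(shi))
  expect_equal(which.max(shi), which(p == 0.5))
})

test_that("maf spectrum bins are half-open with a closed top bin", {
  st <- data.frame(maf = c(0.15, 0.15, 0.10, 0.20, 0.50, 0.05))
  sp <- maf_spectrum(st)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp[["[0.1,0.2)"]]), 3 / 6)
  expect_equal(unname(sp[["[0.2,0.3)"]]), 1 / 6)
  expect_equal(unname(sp[["[0.4,0.5]"]]), 1 / 6)
  expect_equal(unname(sp[["[0.05,0.1)"]]), 1 / 6)
  only <- maf_spectrum(data.frame(maf = rep(0.15, 9)))
  expect_equal(unname(only[["[0.1,0.2)"]]), 1)
})

test_that("proportion polymorphic counts loci above the MAF threshold", {
  st <- data.frame(maf = c(rep(0, 4), rep(0.3, 6)))
  expect_equal(proportion_polymorphic(st), 0.6)
  expect_equal(proportion_polymorphic(data.frame(maf = rep(0, 5))), 0)
  expect_equal(proportion_polymorphic(data.frame(maf = rep(0.3, 5))), 1)
})

test_that("individual F is near 0 for outbred data and 1 for full homozygotes", {
  set.seed(11)
  L <- 10000
  p <- runif(L, 0.1, 0.9)
  calls <- matrix(rbinom(200 * L, 2, rep(p, each = 200)), 200, L)
  gm <- make_gm(calls)
  f <- individual_f(gm)
  expect_lt(abs(mean(f)), 0.01)
  hom <- calls[1, ]
  hom[hom == 1L] <- 2L
  gm2 <- make_gm(rbind(hom, calls[2:50, ]))
  f2 <- individual_f(gm2)
  expect_equal(unname(f2[1]), 1, tolerance = 1e-10)
})

test_that("offspring of full-sib matings show F near 0.25", {
  set.seed(12)
  L <- 8000
  p <- runif(L, 0.2, 0.8)
  mate <- function(a, b) (runif(L) < a / 2) + (runif(L) < b / 2)
  inbred <- t(vapply(1:20, function(i) {
    gp1 <- rbinom(L, 2, p); gp2 <- rbinom(L, 2, p)   # grandparents
    sib1 <- mate(gp1, gp2); sib2 <- mate(gp1, gp2)
    mate(sib1, sib2)                                  # full-sib offspring
  }, numeric(L)))
  outbred <- matrix(rbinom(80 * L, 2, rep(p, each = 80)), 80, L)
  gm <- make_gm(rbind(inbred, outbred))
  f <- individual_f(gm)
  expect_lt(abs(mean(f[1:20]) - 0.25), 0.05)
})

test_that("paired and one-sample t tests handle degenerate and null cases", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  res <- paired_t(x, x)
  expect_true(res$degenerate)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  res0 <- one_sample_t(rep(0, 5))
  expect_true(res0$degenerate)
  expect_equal(res0$p, 1)
  set.seed(3)
  shifted <- paired_t(x + 0.5 + rnorm(4, sd = 1e-4), x)
  expect_lt(shifted$p, 1e-6)
  strong <- one_sample_t(rnorm(60, mean = 0.5, sd = 0.1))
  expect_lt(strong$p, 1e-6)
})

test_that("t tests hold their nominal type-I rate on null simulations", {
  set.seed(14)
  n_rep <- 200
  rej_paired <- rej_one <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    a <- rnorm(40); b <- a + rnorm(40)
    rej_paired[r] <- paired_t(a, b)$p < 0.05
    rej_one[r] <- one_sample_t(rnorm(60))$p < 0.01
  }
  expect_lt(mean(rej_paired), 0.11)      # nominal 0.05
  expect_lt(mean(rej_one), 0.05)         # nominal 0.01
})

test_that("Sved formula gives the textbook point value", {
  # a single pair at c = 0.5 Morgan with adjusted r2 = 0.25 -> Ne = 1.5
  n_ind <- 10
  r2_adj <- 0.25
  cbar <- 0.5
  expect_equal((1 / (4 * cbar)) * (1 / r2_adj - 1), 1.5)
})

test_that("LD-based Ne recovers a Wright-Fisher truth within a factor of 2", {
  nes <- vapply(1:8, function(s) {
    gm <- wright_fisher_drift(50, 30, 400, 100, seed = s)
    estimate_ne_ld(gm, max_dist_cm = 10, n_bins = 10)$ne
  }, numeric(1))
  med <- median(nes)
  expect_gt(med, 25)
  expect_lt(med, 100)
})

test_that("unlinked markers yield the no-LD flag or a very large Ne", {
  set.seed(15)
  L <- 300
  calls <- matrix(rbinom(100 * L, 2, 0.5), 100, L)
  gm <- make_gm(calls, chrom = rep(as.character(1:10), each = 30),
                bp = rep(seq(1e6, by = 1e6, length.out = 30), 10))
  est <- estimate_ne_ld(gm, max_dist_cm = 30, n_bins = 5)
  # residual sampling LD bounds the estimate away from any herd-scale value:
  # "very large" here means far beyond the sample size
  expect_true(est$no_ld || est$ne > 2 * n_samples(gm))
})
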
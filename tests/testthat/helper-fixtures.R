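# Shared fixtures and independent oracles, built in code at test time.

# Minimal genotype matrix from a calls matrix (markers on one chromosome by
# default, alleles A/G).
make_gm <- function(calls, chrom = NULL, bp = NULL, sex = NULL,
                    allele1 = "A", allele2 = "G", iid = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  chrom <- chrom %||% rep("1", L)
  bp <- bp %||% seq(1e5, by = 1e5, length.out = L)
  genotype_matrix(
    calls,
    data.frame(id = paste0("m", seq_len(L)), chrom = chrom, cm = bp / 1e6,
               bp = bp, allele1 = rep_len(allele1, L),
               allele2 = rep_len(allele2, L), stringsAsFactors = FALSE),
    data.frame(fid = "F", iid = iid %||% sprintf("s%02d", seq_len(n)),
               pat = "0", mat = "0",
               sex = sex %||% rep("unknown", n), phenotype = "-9",
               stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid genotype matrix for property tests.
random_gm <- function(n = 20, L = 50, missing_rate = 0.05, seed = 1) {
  set.seed(seed)
  p <- runif(L, 0.1, 0.9)
  calls <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  calls[runif(n * L) < missing_rate] <- NA
  pairs <- combn(c("A", "C", "G", "T"), 2)
  pick <- sample(ncol(pairs), L, replace = TRUE)
  make_gm(calls, chrom = sample(c(as.character(1:5), "X"), L, replace = TRUE),
          bp = sample.int(1e7, L),
          sex = sample(c("male", "female"), n, replace = TRUE),
          allele1 = pairs[1, pick], allele2 = pairs[2, pick])
}

# Independent brute-force oracle for the exact HWE test: explicit
# conditional probabilities of every attainable heterozygote count via
# log-factorials (no recurrence shared with the implementation).
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nb <- 2 * n - na
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (na - h) / 2
    nbb <- (nb - h) / 2
    h * log(2) + lfactorial(n) + lfactorial(na) + lfactorial(nb) -
      lfactorial(naa) - lfactorial(h) - lfactorial(nbb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_het]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Merge overlapping planted intervals of one individual/chromosome (two
# overlapping autozygous plants form one autozygous stretch).
merge_planted <- function(df) {
  out <- list()
  for (key in unique(paste(df$iid, df$chrom))) {
    d <- df[paste(df$iid, df$chrom) == key, ]
    d <- d[order(d$start_bp), ]
    cur <- d[1, , drop = FALSE]
    if (nrow(d) > 1) {
      for (r in 2:nrow(d)) {
        if (d$start_bp[r] <= cur$end_bp) {
          cur$end_bp <- max(cur$end_bp, d$end_bp[r])
        } else {
          out[[length(out) + 1L]] <- cur
          cur <- d[r, , drop = FALSE]
        }
      }
    }
    out[[length(out) + 1L]] <- cur
  }
  do.call(rbind, out)
}

# Fraction of merged planted segments recovered with reciprocal overlap
# >= `min_overlap` by a detected segment set.
planted_recovery <- function(segs, planted, min_overlap = 0.9) {
  pl <- merge_planted(planted)
  hit <- 0L
  for (r in seq_len(nrow(pl))) {
    s <- segs[segs$iid == pl$iid[r] & segs$chrom == pl$chrom[r], ]
    if (!nrow(s)) next
    ov <- pmin(s$end_bp, pl$end_bp[r]) - pmax(s$start_bp, pl$start_bp[r])
    rec <- ov / pmax(s$end_bp - s$start_bp, pl$end_bp[r] - pl$start_bp[r])
    if (any(rec >= min_overlap)) hit <- hit + 1L
  }
  c(hit = hit, total = nrow(pl))
}

# Small dense-map herd configuration for ROH tests (25 kb spacing).
roh_test_config <- function(seed, roh_per_individual = 2,
                            roh_length_range_bp = c(5e6, 1e7)) {
  sim_config(
    n_bulls = 4, n_cows = 16, n_admixed = 0, n_families = 4,
    n_autosomal_markers = 20000, n_sex_markers = 0,
    n_chromosomes = 10, chrom_length_bp = 5e7,
    panel_size = 0, n_hwe_violators = 0, n_rare_loci = 0,
    missing_rate_marker = 0.002, low_quality_marker_frac = 0,
    missing_rate_sample = 0,
    roh_per_individual = roh_per_individual,
    roh_length_range_bp = roh_length_range_bp, seed = seed
  )
}

# Fraction of truth-sired cows assigned to their sire's family.
family_match_rate <- function(assignment, truth, ids) {
  memb <- assignment$membership
  cows <- intersect(names(truth$sire_of), ids)
  tot <- 0L; ok <- 0L
  for (cw in cows) {
    sire <- truth$sire_of[[cw]]
    if (!(sire %in% ids)) next
    tot <- tot + 1L
    if (memb[cw] != "other" && memb[cw] == memb[sire]) ok <- ok + 1L
  }
  c(ok = ok, total = tot)
}
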
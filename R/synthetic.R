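#' Simulation configuration for synthetic herds
#'
#' Bundles every knob of the synthetic herd generator. Defaults emulate the
#' conserved dairy-cattle herd the pipeline is designed for: 74 genotyped
#' animals (12 bulls, 62 cows) on a ~95k bovine SNP array (29 autosomes plus
#' X/Y/unplaced markers), a purebred core of 60 with 14 admixed outliers, a
#' 61-locus near-fixed purity panel, half-sib families from 10 sires, loci
#' violating Hardy-Weinberg equilibrium, rare single-carrier loci, a
#' low-quality marker stratum driving call-rate failures, and planted
#' autozygous segments giving a mean F_ROH near 0.09.
#'
#' @param n_bulls,n_cows counts of males/females genotyped.
#' @param n_admixed number of admixed outlier cows (the remaining animals form
#'   the purebred core).
#' @param n_autosomal_markers,n_sex_markers marker counts; sex markers are
#'   labelled `"X"`, `"Y"` and `"0"` (unplaced) in a 3:1:1 split.
#' @param n_chromosomes number of autosomes (cattle: 29).
#' @param chrom_length_bp autosome length in base pairs; marker density is
#'   `n_autosomal_markers / (n_chromosomes * chrom_length_bp)`.
#' @param panel_size number of purity-panel truth loci.
#' @param purebred_panel_freq target `allele1` frequency of panel loci among
#'   purebred founders (enforced by exact allele counts; offspring inherit, so
#'   the realized purebred frequency matches up to Mendelian sampling and is
#'   exact at 1.0).
#' @param admixed_panel_freq target panel-locus frequency among admixed
#'   individuals (exact allele counts, floored).
#' @param admixed_background_frac fraction of non-panel autosomal loci at
#'   which admixed individuals draw from an independent (diverged) allele
#'   frequency.
#' @param missing_rate_marker baseline per-marker missing-call rate.
#' @param low_quality_marker_frac,low_quality_missing_rate fraction of markers
#'   assigned an elevated missing rate, emulating assay failures that push
#'   markers under a 0.90 call-rate threshold.
#' @param missing_rate_sample per-sample missing-call rate (combined with the
#'   marker rate as independent events).
#' @param n_hwe_violators loci generated with zero heterozygotes at allele
#'   frequency ~0.5 (grossly violating Hardy-Weinberg equilibrium).
#' @param n_rare_loci loci with exactly one heterozygous carrier
#'   (MAF = 1/(2N) < 0.01 for herds of 51+ animals).
#' @param n_families number of half-sib sire families; the first
#'   `n_families` bulls act as sires of the purebred cows.
#' @param roh_per_individual mean number of planted autozygous segments per
#'   individual (Poisson).
#' @param roh_length_range_bp length range (uniform) of planted segments.
#' @param seed integer seed; all randomness in [generate_herd()] flows from a
#'   single stream seeded with it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_bulls = 12L, n_cows = 62L, n_admixed = 14L,
                       n_autosomal_markers = 90349L, n_sex_markers = 4907L,
                       n_chromosomes = 29L, chrom_length_bp = 1e8,
                       panel_size = 61L,
                       purebred_panel_freq = 0.95, admixed_panel_freq = 0.20,
                       admixed_background_frac = 0.20,
                       missing_rate_marker = 0.005,
                       low_quality_marker_frac = 0.09,
                       low_quality_missing_rate = 0.20,
                       missing_rate_sample = 0.002,
                       n_hwe_violators = 70L, n_rare_loci = 3300L,
                       n_families = 10L,
                       roh_per_individual = 29.5,
                       roh_length_range_bp = c(1e6, 1.6e7),
                       seed = 1L) {
  cfg <- list(
    n_bulls = as.integer(n_bulls), n_cows = as.integer(n_cows),
    n_admixed = as.integer(n_admixed),
    n_autosomal_markers = as.integer(n_autosomal_markers),
    n_sex_markers = as.integer(n_sex_markers),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = chrom_length_bp,
    panel_size = as.integer(panel_size),
    purebred_panel_freq = purebred_panel_freq,
    admixed_panel_freq = admixed_panel_freq,
    admixed_background_frac = admixed_background_frac,
    missing_rate_marker = missing_rate_marker,
    low_quality_marker_frac = low_quality_marker_frac,
    low_quality_missing_rate = low_quality_missing_rate,
    missing_rate_sample = missing_rate_sample,
    n_hwe_violators = as.integer(n_hwe_violators),
    n_rare_loci = as.integer(n_rare_loci),
    n_families = as.integer(n_families),
    roh_per_individual = roh_per_individual,
    roh_length_range_bp = roh_length_range_bp,
    seed = as.integer(seed)
  )
  probs <- c(cfg$purebred_panel_freq, cfg$admixed_panel_freq,
             cfg$admixed_background_frac, cfg$missing_rate_marker,
             cfg$low_quality_marker_frac, cfg$low_quality_missing_rate,
             cfg$missing_rate_sample)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$purebred_panel_freq < 0.9) {
    stop("purebred_panel_freq must be in [0.9, 1.0]")
  }
  if (cfg$admixed_panel_freq > 0.5) {
    stop("admixed_panel_freq must be in [0.0, 0.5]")
  }
  n_special <- cfg$panel_size + cfg$n_hwe_violators + cfg$n_rare_loci
  if (n_special > cfg$n_autosomal_markers) {
    stop("panel_size + n_hwe_violators + n_rare_loci (", n_special,
         ") exceeds n_autosomal_markers (", cfg$n_autosomal_markers, ")")
  }
  if (cfg$n_admixed > cfg$n_cows) stop("n_admixed exceeds n_cows")
  if (cfg$n_families > cfg$n_bulls) stop("n_families exceeds n_bulls")
  if (cfg$roh_length_range_bp[1] > cfg$roh_length_range_bp[2]) {
    stop("roh_length_range_bp must be increasing")
  }
  structure(cfg, class = "sim_config")
}

# Evenly split `total` markers across chromosome labels.
split_counts <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

build_marker_map <- function(cfg) {
  counts <- split_counts(cfg$n_autosomal_markers, cfg$n_chromosomes)
  chroms <- rep(as.character(seq_len(cfg$n_chromosomes)), counts)
  bp <- unlist(lapply(counts, function(k) {
    sort(sample.int(cfg$chrom_length_bp, k))
  }))
  if (cfg$n_sex_markers > 0L) {
    sx <- split_counts(cfg$n_sex_markers, 5L)
    sex_counts <- c(X = sx[1] + sx[2] + sx[3], Y = sx[4], `0` = sx[5])
    chroms <- c(chroms, rep(names(sex_counts), sex_counts))
    bp <- c(bp, unlist(lapply(sex_counts, function(k) {
      sort(sample.int(cfg$chrom_length_bp, k))
    })))
  }
  pairs <- utils::combn(c("A", "C", "G", "T"), 2)   # columns already sorted
  pick <- sample.int(ncol(pairs), length(chroms), replace = TRUE)
  data.frame(
    id = paste0("SNP", chroms, "_", unlist(lapply(
      rle(chroms)$lengths, seq_len))),
    chrom = chroms, cm = bp / 1e6, bp = bp,
    allele1 = pairs[1, pick], allele2 = pairs[2, pick],
    stringsAsFactors = FALSE
  )
}

# Genotypes with an exact allele-1 copy count: ceiling(2n * freq) copies
# distributed uniformly over 2n slots (floor for `ceil = FALSE`).
exact_freq_genotypes <- function(n, freq, ceil = TRUE) {
  copies <- if (ceil) ceiling(2 * n * freq) else floor(2 * n * freq)
  slots <- sample(c(rep(1L, copies), rep(0L, 2L * n - copies)))
  slots[seq(1L, 2L * n, 2L)] + slots[seq(2L, 2L * n, 2L)]
}

# Mendelian transmission: one allele from each unphased parent genotype.
mendelian_offspring <- function(sire_g, dam_g) {
  (stats::runif(length(sire_g)) < sire_g / 2) +
    (stats::runif(length(dam_g)) < dam_g / 2)
}

#' Generate a synthetic herd with planted ground truth
#'
#' Builds a genotyped herd whose structure is fully recorded: a purebred core
#' with near-fixed panel loci, admixed outliers diverged at the panel (and a
#' fraction of background loci), paternal half-sib families bred from a
#' recorded sire and an unobserved dam, Hardy-Weinberg-violating loci (zero
#' heterozygotes at intermediate frequency), rare single-carrier loci,
#' sex-chromosome/unplaced markers, planted autozygous segments (exactly
#' homozygous before missingness is injected), and per-marker/per-sample
#' missingness. Every planted feature is returned in the truth record so
#' downstream stages can be tested for parameter recovery.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (class `herd_truth`: `purebred_ids`, `admixed_ids`,
#'   `panel_truth_loci`, `family_of`, `sire_of`, `planted_roh`).
#' @export
generate_herd <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  markers <- build_marker_map(cfg)
  L <- nrow(markers)
  auto_idx <- which(is_autosome(markers$chrom, cfg$n_chromosomes))

  special <- sample(auto_idx, cfg$panel_size + cfg$n_hwe_violators +
                      cfg$n_rare_loci)
  panel_idx <- special[seq_len(cfg$panel_size)]
  hwe_idx <- special[cfg$panel_size + seq_len(cfg$n_hwe_violators)]
  rare_idx <- special[cfg$panel_size + cfg$n_hwe_violators +
                        seq_len(cfg$n_rare_loci)]
  background_idx <- setdiff(auto_idx, special)
  diverged_idx <- sample(background_idx,
                         round(cfg$admixed_background_frac *
                                 length(background_idx)))

  p <- stats::runif(L, 0.05, 0.95)      # baseline allele1 frequencies

  bull_ids <- sprintf("BULL_%03d", seq_len(cfg$n_bulls))
  cow_ids <- sprintf("COW_%03d", seq_len(cfg$n_cows))
  ids <- c(bull_ids, cow_ids)
  n <- length(ids)
  admixed_ids <- if (cfg$n_admixed > 0L) utils::tail(cow_ids, cfg$n_admixed)
                 else character(0)
  purebred_cow_ids <- setdiff(cow_ids, admixed_ids)
  purebred_ids <- c(bull_ids, purebred_cow_ids)

  sire_ids <- bull_ids[seq_len(cfg$n_families)]
  family_labels <- sprintf("FAM_%02d", seq_len(cfg$n_families))
  has_fams <- cfg$n_families > 0L && length(purebred_cow_ids) > 0L
  sire_of <- if (has_fams) {
    stats::setNames(sample(sire_ids, length(purebred_cow_ids),
                           replace = TRUE), purebred_cow_ids)
  } else stats::setNames(character(0), character(0))
  family_of <- if (has_fams) {
    c(stats::setNames(family_labels, sire_ids),
      stats::setNames(family_labels[match(sire_of, sire_ids)],
                      names(sire_of)))
  } else stats::setNames(character(0), character(0))

  # Founders: all bulls plus, under family structure, one unobserved dam
  # per purebred cow; without families the purebred cows are founders
  # themselves.
  n_dams <- if (has_fams) length(purebred_cow_ids) else 0L
  founder_cows <- if (has_fams) character(0) else purebred_cow_ids
  n_founders <- cfg$n_bulls + n_dams + length(founder_cows)
  Fg <- matrix(stats::rbinom(n_founders * L, 2L,
                             rep(p, each = n_founders)),
               nrow = n_founders, ncol = L)
  for (j in panel_idx) {
    Fg[, j] <- exact_freq_genotypes(n_founders, cfg$purebred_panel_freq)
  }
  if (length(hwe_idx)) {
    Fg[, hwe_idx] <- 2L * matrix(
      stats::rbinom(n_founders * length(hwe_idx), 1L, 0.5),
      nrow = n_founders)
  }

  calls <- matrix(0L, nrow = n, ncol = L, dimnames = list(ids, markers$id))
  calls[bull_ids, ] <- Fg[seq_len(cfg$n_bulls), , drop = FALSE]
  if (length(founder_cows)) {
    calls[founder_cows, ] <-
      Fg[cfg$n_bulls + n_dams + seq_along(founder_cows), , drop = FALSE]
  }

  # Purebred cows: Mendelian offspring of their sire and a private dam.
  if (n_dams > 0L) {
    sire_rows <- Fg[match(sire_of, bull_ids), , drop = FALSE]
    dam_rows <- Fg[cfg$n_bulls + seq_len(n_dams), , drop = FALSE]
    off <- matrix(
      (stats::runif(n_dams * L) < sire_rows / 2) +
        (stats::runif(n_dams * L) < dam_rows / 2),
      nrow = n_dams)
    # HWE-violator loci: offspring take the sire's homozygote class (the dam
    # is implicitly of the same class), preserving both the zero-het design
    # and Mendelian consistency.
    if (length(hwe_idx)) off[, hwe_idx] <- sire_rows[, hwe_idx]
    calls[purebred_cow_ids, ] <- off
  }

  # Admixed outliers: an exotic background diverged at panel loci and at a
  # recorded fraction of background loci.
  if (cfg$n_admixed > 0L) {
    m <- cfg$n_admixed
    p_adm <- p
    p_adm[diverged_idx] <- stats::runif(length(diverged_idx), 0.05, 0.95)
    Ag <- matrix(stats::rbinom(m * L, 2L, rep(p_adm, each = m)), nrow = m)
    for (j in panel_idx) {
      Ag[, j] <- exact_freq_genotypes(m, cfg$admixed_panel_freq, ceil = FALSE)
    }
    if (length(hwe_idx)) {
      Ag[, hwe_idx] <- 2L * matrix(
        stats::rbinom(m * length(hwe_idx), 1L, 0.5), nrow = m)
    }
    calls[admixed_ids, ] <- Ag
  }

  # Planted autozygous segments: one haplotype drawn per segment, doubled.
  n_seg <- stats::rpois(n, cfg$roh_per_individual)
  planted <- vector("list", sum(n_seg))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(n_seg[i])) {
      chrom <- as.character(sample.int(cfg$n_chromosomes, 1L))
      on_chr <- which(markers$chrom == chrom)
      span <- range(markers$bp[on_chr])
      len <- stats::runif(1, cfg$roh_length_range_bp[1],
                          cfg$roh_length_range_bp[2])
      start <- floor(stats::runif(1, span[1], max(span[1] + 1,
                                                  span[2] - len)))
      end <- min(span[2], floor(start + len))
      cover <- on_chr[markers$bp[on_chr] >= start & markers$bp[on_chr] <= end]
      if (length(cover)) {
        hap <- stats::rbinom(length(cover), 1L, p[cover])
        calls[i, cover] <- 2L * hap
      }
      k <- k + 1L
      planted[[k]] <- data.frame(iid = ids[i], chrom = chrom,
                                 start_bp = start, end_bp = end,
                                 stringsAsFactors = FALSE)
    }
  }
  planted_roh <- if (k > 0L) do.call(rbind, planted[seq_len(k)]) else
    data.frame(iid = character(0), chrom = character(0),
               start_bp = numeric(0), end_bp = numeric(0))

  # Rare loci: everyone homozygous for allele1 except a single het carrier
  # (applied after ROH planting so the MAF guarantee survives).
  if (length(rare_idx)) {
    calls[, rare_idx] <- 2L
    carriers <- sample.int(n, length(rare_idx), replace = TRUE)
    calls[cbind(carriers, rare_idx)] <- 1L
  }

  # Missingness: baseline + low-quality marker stratum, combined with the
  # per-sample rate as independent events.
  rate_m <- rep(cfg$missing_rate_marker, L)
  n_lq <- round(cfg$low_quality_marker_frac * L)
  if (n_lq > 0L) {
    rate_m[sample.int(L, n_lq)] <- cfg$low_quality_missing_rate
  }
  if (any(rate_m > 0) || cfg$missing_rate_sample > 0) {
    pm <- 1 - outer(rep(1 - cfg$missing_rate_sample, n), 1 - rate_m)
    calls[stats::runif(n * L) < pm] <- NA_integer_
  }

  samples <- data.frame(
    fid = "HERD", iid = ids,
    pat = ifelse(ids %in% names(sire_of), sire_of[ids], "0"),
    mat = "0",
    sex = c(rep("male", cfg$n_bulls), rep("female", cfg$n_cows)),
    phenotype = "-9", stringsAsFactors = FALSE
  )
  truth <- structure(list(
    purebred_ids = purebred_ids,
    admixed_ids = admixed_ids,
    panel_truth_loci = markers$id[panel_idx],
    hwe_violator_loci = markers$id[hwe_idx],
    rare_loci = markers$id[rare_idx],
    family_of = family_of,
    sire_of = sire_of,
    planted_roh = planted_roh
  ), class = "herd_truth")

  list(genotypes = genotype_matrix(calls, markers, samples), truth = truth)
}

#' @export
print.herd_truth <- function(x, ...) {
  cat("herd_truth:", length(x$purebred_ids), "purebred,",
      length(x$admixed_ids), "admixed individuals\n")
  cat("  panel loci:", length(x$panel_truth_loci),
      "| HWE violators:", length(x$hwe_violator_loci),
      "| rare loci:", length(x$rare_loci), "\n")
  cat("  families:", length(unique(x$family_of)),
      "| planted ROH segments:", nrow(x$planted_roh), "\n")
  invisible(x)
}

#' Serialize a herd truth record
#'
#' Writes the planted ground truth as tabular TSV sidecars plus a JSON
#' manifest, so simulated datasets remain self-describing on disk.
#'
#' @param truth a `herd_truth` record from [generate_herd()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the manifest path.
#' @export
write_herd_truth <- function(truth, dir, prefix = "herd") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(what) file.path(dir, paste0(prefix, "_", what, ".tsv"))
  ind <- data.frame(
    iid = c(truth$purebred_ids, truth$admixed_ids),
    status = c(rep("purebred", length(truth$purebred_ids)),
               rep("admixed", length(truth$admixed_ids))),
    stringsAsFactors = FALSE
  )
  ind$family <- ifelse(ind$iid %in% names(truth$family_of),
                       truth$family_of[ind$iid], NA)
  ind$sire <- ifelse(ind$iid %in% names(truth$sire_of),
                     truth$sire_of[ind$iid], NA)
  utils::write.table(ind, path("individuals"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  loci <- data.frame(
    marker_id = c(truth$panel_truth_loci, truth$hwe_violator_loci,
                  truth$rare_loci),
    role = c(rep("panel", length(truth$panel_truth_loci)),
             rep("hwe_violator", length(truth$hwe_violator_loci)),
             rep("rare", length(truth$rare_loci))),
    stringsAsFactors = FALSE
  )
  utils::write.table(loci, path("loci"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$planted_roh, path("planted_roh"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- file.path(dir, paste0(prefix, "_truth_manifest.json"))
  jsonlite::write_json(
    list(individuals = path("individuals"), loci = path("loci"),
         planted_roh = path("planted_roh"),
         counts = list(purebred = length(truth$purebred_ids),
                       admixed = length(truth$admixed_ids),
                       panel = length(truth$panel_truth_loci),
                       planted_roh = nrow(truth$planted_roh))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Forward-in-time Wright-Fisher drift simulator
#'
#' Simulates biallelic markers through `n_generations` of random mating in a
#' constant population of `n_effective` diploids, starting from founder allele
#' frequency 0.5 at every locus. Markers are arranged on `n_chromosomes`
#' chromosomes with constant spacing, recombining at the Haldane map distance
#' within chromosomes and independently across them, so linked markers
#' accumulate the linkage disequilibrium that the LD-based Ne estimator reads
#' out. A final round of random mating produces `n_sampled` offspring.
#'
#' @param n_effective diploid population size (>= 2).
#' @param n_generations generations of drift (0 returns founder offspring).
#' @param n_markers total marker count.
#' @param n_sampled individuals in the returned sample.
#' @param seed integer seed.
#' @param n_chromosomes chromosomes the markers are split across.
#' @param spacing_cm inter-marker spacing in centimorgans.
#' @return A [genotype_matrix()] (alleles `"A"`/`"C"`, `allele1 = "A"`
#'   counted; founder frequency 0.5).
#' @export
wright_fisher_drift <- function(n_effective, n_generations, n_markers,
                                n_sampled, seed, n_chromosomes = 5L,
                                spacing_cm = 0.5) {
  if (n_effective < 2) stop("n_effective must be >= 2")
  set.seed(as.integer(seed))
  N <- as.integer(n_effective)
  L <- as.integer(n_markers)
  counts <- split_counts(L, n_chromosomes)
  chrom <- rep(as.character(seq_len(n_chromosomes)), counts)
  within_pos <- unlist(lapply(counts, seq_len))
  d_morgan <- spacing_cm / 100
  # Recombination fraction between adjacent markers; chromosome breaks are
  # free recombination.
  r <- ifelse(chrom[-1L] == chrom[-L],
              0.5 * (1 - exp(-2 * d_morgan)), 0.5)

  gametes <- function(H, pid) {
    m <- length(pid)
    h1 <- H[2L * pid - 1L, , drop = FALSE]
    h2 <- H[2L * pid, , drop = FALSE]
    sw <- matrix(stats::runif(m * (L - 1L)) <
                   matrix(r, nrow = m, ncol = L - 1L, byrow = TRUE),
                 nrow = m)
    state <- cbind(stats::rbinom(m, 1L, 0.5),
                   matrix(0L, nrow = m, ncol = L - 1L))
    state <- (state[, 1L] + cbind(0L, t(apply(sw, 1L, cumsum)))) %% 2L
    h1 * (1L - state) + h2 * state
  }

  H <- matrix(stats::rbinom(2L * N * L, 1L, 0.5), nrow = 2L * N)
  if (n_generations > 0) {
    for (g in seq_len(n_generations)) {
      gamA <- gametes(H, sample.int(N, N, replace = TRUE))
      gamB <- gametes(H, sample.int(N, N, replace = TRUE))
      H2 <- matrix(0L, nrow = 2L * N, ncol = L)
      H2[seq(1L, 2L * N, 2L), ] <- gamA
      H2[seq(2L, 2L * N, 2L), ] <- gamB
      H <- H2
    }
  }
  calls <- gametes(H, sample.int(N, n_sampled, replace = TRUE)) +
    gametes(H, sample.int(N, n_sampled, replace = TRUE))
  storage.mode(calls) <- "integer"

  markers <- data.frame(
    id = paste0("WF", chrom, "_", within_pos),
    chrom = chrom, cm = (within_pos - 1L) * spacing_cm,
    bp = (within_pos - 1L) * spacing_cm * 1e6 + 1,
    allele1 = "A", allele2 = "C", stringsAsFactors = FALSE
  )
  samples <- data.frame(
    fid = "WF", iid = sprintf("WF_%04d", seq_len(n_sampled)),
    pat = "0", mat = "0", sex = "unknown", phenotype = "-9",
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, markers, samples)
}
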
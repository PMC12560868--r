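#' Read PLINK text PED/MAP files
#'
#' Parses a whitespace-delimited PLINK text fileset into a
#' [genotype_matrix()]. Genotypes are recoded as counts of `allele1`, the
#' alphabetically smaller of the two allele characters observed at each
#' marker, so the encoding does not depend on row order. A `"0 0"` pair is
#' missing; half-missing pairs (e.g. `"A 0"`) are treated as missing and
#' reported through a warning with the affected pair count.
#'
#' @param ped_path path to the PED file (6 leading columns
#'   `FID IID PAT MAT SEX PHENO`, then two allele columns per marker).
#' @param map_path path to the MAP file (4 columns `CHR SNP CM BP`).
#' @return A [genotype_matrix()].
#' @seealso [write_ped_map()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_tok)
  if (any(nf != 4L)) {
    stop("MAP line ", which(nf != 4L)[1], " has ", nf[nf != 4L][1],
         " fields; expected 4 (CHR SNP CM BP)")
  }
  mm <- matrix(unlist(map_tok), ncol = 4L, byrow = TRUE)
  markers <- data.frame(
    id = mm[, 2], chrom = mm[, 1],
    cm = as.numeric(mm[, 3]), bp = as.numeric(mm[, 4]),
    allele1 = NA_character_, allele2 = NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(markers$id)) {
    stop("duplicate marker id in MAP: ",
         markers$id[duplicated(markers$id)][1])
  }
  L <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "[ \t]+")
  want <- 6L + 2L * L
  nf <- lengths(ped_tok)
  if (any(nf != want)) {
    bad <- which(nf != want)[1]
    stop("PED row ", bad, " (", ped_tok[[bad]][2] %||% "?", ") has ",
         nf[bad], " fields; expected ", want, " for ", L, " markers")
  }
  n <- length(ped_tok)
  pm <- matrix(unlist(ped_tok), nrow = n, byrow = TRUE)
  samples <- data.frame(
    fid = pm[, 1], iid = pm[, 2], pat = pm[, 3], mat = pm[, 4],
    sex = decode_sex(pm[, 5]), phenotype = pm[, 6],
    stringsAsFactors = FALSE
  )

  A1 <- pm[, 6L + 2L * seq_len(L) - 1L, drop = FALSE]
  A2 <- pm[, 6L + 2L * seq_len(L), drop = FALSE]
  half <- xor(A1 == "0", A2 == "0")
  if (any(half)) {
    warning(sum(half), " half-missing genotype pair(s) treated as missing")
    A1[half] <- "0"
    A2[half] <- "0"
  }
  A1[A1 == "0"] <- NA
  A2[A2 == "0"] <- NA

  # Column-wise allele canonicalization, vectorized: the per-column min and
  # max character over both allele slots; any residual character proves a
  # third allele.
  stack <- rbind(A1, A2)
  cmin <- do.call(pmin, c(as.data.frame(t(stack), stringsAsFactors = FALSE),
                          na.rm = TRUE))
  cmax <- do.call(pmax, c(as.data.frame(t(stack), stringsAsFactors = FALSE),
                          na.rm = TRUE))
  cmin <- as.character(cmin)
  cmax <- as.character(cmax)
  lo <- matrix(cmin, nrow = 2L * n, ncol = L, byrow = TRUE)
  hi <- matrix(cmax, nrow = 2L * n, ncol = L, byrow = TRUE)
  extra <- !is.na(stack) & stack != lo & stack != hi
  if (any(extra)) {
    j <- which(colSums(extra) > 0)[1]
    stop("marker ", markers$id[j], " has more than 2 distinct alleles")
  }

  all_missing <- is.na(cmin)
  markers$allele1 <- ifelse(all_missing, "0", cmin)
  markers$allele2 <- ifelse(all_missing | cmin == cmax, "0", cmax)

  a1 <- matrix(markers$allele1, nrow = n, ncol = L, byrow = TRUE)
  calls <- (A1 == a1) + (A2 == a1)
  storage.mode(calls) <- "integer"
  genotype_matrix(calls, markers, samples)
}

#' Write PLINK text PED/MAP files
#'
#' Serializes a [genotype_matrix()] to the standard whitespace-delimited text
#' fileset. Missing calls are written as `"0 0"`; a monomorphic marker
#' (recorded `allele2 == "0"`) is written homozygous for `allele1`.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  validate_genotype_matrix(gm)
  mk <- gm$markers
  map <- paste(mk$chrom, mk$id, format(mk$cm, trim = TRUE, scientific = FALSE),
               format(mk$bp, trim = TRUE, scientific = FALSE))
  writeLines(map, map_path)

  n <- n_samples(gm)
  L <- n_markers(gm)
  geno_txt <- character(0)
  if (L > 0L) {
    a1 <- matrix(mk$allele1, nrow = n, ncol = L, byrow = TRUE)
    a2 <- matrix(mk$allele2, nrow = n, ncol = L, byrow = TRUE)
    g <- gm$calls
    pair <- matrix("0 0", nrow = n, ncol = L)
    i2 <- !is.na(g) & g == 2L
    i1 <- !is.na(g) & g == 1L
    i0 <- !is.na(g) & g == 0L
    pair[i2] <- paste(a1[i2], a1[i2])
    pair[i1] <- paste(a1[i1], a2[i1])
    pair[i0] <- paste(a2[i0], a2[i0])
    geno_txt <- apply(pair, 1L, paste, collapse = " ")
  }
  s <- gm$samples
  lead <- paste(s$fid, s$iid, s$pat %||% "0", s$mat %||% "0",
                encode_sex(s$sex), s$phenotype %||% "-9")
  if (L > 0L) {
    writeLines(paste(lead, geno_txt), ped_path)
  } else {
    writeLines(lead, ped_path)
  }
  invisible(list(ped = ped_path, map = map_path))
}
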
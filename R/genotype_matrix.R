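#' Genotype matrix container
#'
#' The central data structure of the pipeline: an individuals x markers matrix
#' of allele counts together with the marker map and the sample sheet. Each
#' call counts copies of `allele1` at that marker, so entries are 0, 1, 2 or
#' `NA` (missing). `allele1` is always the alphabetically smaller of the two
#' observed allele characters, which makes the encoding invariant to the order
#' in which individuals appear in a PED file; frequency-based primary/secondary
#' allele roles are derived downstream and never stored here.
#'
#' @param calls integer matrix, `n_samples` x `n_markers`, entries in
#'   `{0, 1, 2, NA}` counting copies of `allele1`.
#' @param markers data.frame with columns `id`, `chrom` (character labels
#'   `"1"`..`"29"`, `"X"`, `"Y"`, `"0"`), `cm` (genetic position,
#'   centimorgans), `bp` (1-based physical position), `allele1`, `allele2`
#'   (single characters; `allele2 == "0"` marks a monomorphic locus).
#' @param samples data.frame with columns `fid`, `iid`, `pat`, `mat`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`) and `phenotype` (opaque string).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  gm <- structure(
    list(calls = calls, markers = markers, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  rownames(gm$calls) <- samples$iid
  colnames(gm$calls) <- markers$id
  gm
}

#' Validate a genotype matrix
#'
#' Checks dimensions, call coding, marker-id uniqueness and the monomorphic
#' convention (a marker with `allele2 == "0"` may only carry calls 2 or `NA`).
#'
#' @param gm a [genotype_matrix()].
#' @return `gm`, invisibly; errors on any violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  need_m <- c("id", "chrom", "cm", "bp", "allele1", "allele2")
  if (!all(need_m %in% names(gm$markers))) {
    stop("markers must have columns: ", paste(need_m, collapse = ", "))
  }
  need_s <- c("fid", "iid", "sex")
  if (!all(need_s %in% names(gm$samples))) {
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  }
  if (nrow(gm$calls) != nrow(gm$samples)) {
    stop("calls has ", nrow(gm$calls), " rows but sample sheet has ",
         nrow(gm$samples))
  }
  if (ncol(gm$calls) != nrow(gm$markers)) {
    stop("calls has ", ncol(gm$calls), " columns but marker map has ",
         nrow(gm$markers))
  }
  if (anyDuplicated(gm$markers$id)) {
    stop("duplicate marker ids: ",
         paste(utils::head(gm$markers$id[duplicated(gm$markers$id)], 3),
               collapse = ", "))
  }
  key <- paste(gm$samples$fid, gm$samples$iid)
  if (anyDuplicated(key)) stop("duplicate (fid, iid) sample keys")
  bad <- gm$calls[!is.na(gm$calls) & !(gm$calls %in% 0:2)]
  if (length(bad)) stop("calls outside {0,1,2,NA}: ", bad[1])
  if (any(gm$markers$bp < 0)) stop("negative physical positions")
  mono <- which(gm$markers$allele2 == "0")
  if (length(mono)) {
    sub <- gm$calls[, mono, drop = FALSE]
    if (any(!is.na(sub) & sub != 2L)) {
      stop("monomorphic marker (allele2 == \"0\") carries a call other than 2")
    }
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "individuals x",
      ncol(x$calls), "markers\n")
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(x$calls))))
  sx <- table(x$samples$sex)
  cat("  sex:", paste(names(sx), sx, sep = "=", collapse = ", "), "\n")
  chroms <- unique(x$markers$chrom)
  cat("  chromosomes:", length(chroms),
      paste0("(", paste(utils::head(chroms[order(chrom_rank(chroms))], 6),
                        collapse = ","),
             if (length(chroms) > 6) ",..." else "", ")"), "\n")
  invisible(x)
}

#' Number of samples / markers
#' @param gm a [genotype_matrix()].
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_markers <- function(gm) ncol(gm$calls)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (integer, logical, or iid character vector).
#' @param j marker index (integer, logical, or marker-id character vector).
#' @param ... unused.
#' @return the subsetted `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$samples$iid)
  if (is.character(j)) j <- match(j, x$markers$id)
  if (anyNA(i)) stop("unknown sample id in subset")
  if (anyNA(j)) stop("unknown marker id in subset")
  genotype_matrix(
    x$calls[i, j, drop = FALSE],
    x$markers[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

# Per-marker allele1 frequency over non-missing calls (NaN if all missing).
allele1_freq <- function(gm) {
  colMeans(gm$calls, na.rm = TRUE) / 2
}

# Encode sex integers from PED column 5.
decode_sex <- function(code) {
  out <- rep("unknown", length(code))
  out[code == "1"] <- "male"
  out[code == "2"] <- "female"
  out
}

encode_sex <- function(sex) {
  unname(c(male = "1", female = "2", unknown = "0")[sex])
}
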
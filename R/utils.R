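# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
is_autosome <- function(chrom, n_autosomes = 29L) {
  chrom %in% as.character(seq_len(n_autosomes))
}

# Sort key for chromosome labels: numeric autosomes first in numeric order,
# then X, Y, and "0"/unplaced last.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.integer(chrom))
  rank <- ifelse(!is.na(num) & num > 0L, num,
    ifelse(chrom == "X", 1000L, ifelse(chrom == "Y", 1001L, 1002L))
  )
  rank
}

# Thousands-separated integer rendering ("78,460").
format_count <- function(x) {
  formatC(x, format = "d", big.mark = ",")
}

# Percentage of a count against a total, truncated (floored) at `digits`
# decimals. Truncation guarantees a removal percentage is never overstated.
pct_floor <- function(count, total, digits = 2L) {
  floor(100 * count / total * 10^digits) / 10^digits
}

# Deterministic seed derivation for sub-streams, kept under 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483587L
}
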
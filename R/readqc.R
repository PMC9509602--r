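#' Extract enzyme reads
#'
#' Keeps reads that look like genuine BcgI-digested fragments: exactly 32 bp
#' with the recognition core in place — CGA at positions 11-13 and TGC at
#' 20-22 (1-based) in either orientation.  `N` matches nothing.  Reads of any
#' other length, or without the core, are discarded (and counted by
#' [qc_filter()] upstream totals); input order is preserved.
#'
#' @param reads a read set.
#' @return the subset of `reads` that are enzyme reads.
#' @export
extract_enzyme_reads <- function(reads) {
  reads <- as_read_set(reads)
  keep <- is_enzyme_read(reads$sequence)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  as_read_set(out)
}

is_enzyme_read <- function(sequence) {
  ok_len <- nchar(sequence) == BCGI_TAG_LEN
  core <- substring(sequence, 11L, 22L)
  fwd <- grepl("^CGA[ACGT]{6}TGC$", core)
  rev <- grepl("^GCA[ACGT]{6}TCG$", core)
  ok_len & (fwd | rev)
}

#' Quality-filter enzyme reads
#'
#' Applies the two clean-read criteria: remove reads with more than 8%
#' unknown (`N`) bases, and remove reads with more than 20% low-quality
#' bases, where low quality means Phred `Q <= 20` (Phred+33 encoding).  Both
#' thresholds are strict (a read at exactly 8% or 20% survives).
#'
#' @param reads a read set (enzyme reads).
#' @return list with `reads` (the survivors, order preserved) and `report`,
#'   a one-row data frame with `n_in`, `n_clean`, `removed_n_frac`,
#'   `removed_lowq` (reads failing the respective filter; a read failing both
#'   is counted under the N filter).
#' @export
qc_filter <- function(reads) {
  reads <- as_read_set(reads)
  n <- nchar(reads$sequence)
  n_N <- nchar(reads$sequence) - nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  qual_ok <- grepl("^[!-~]*$", reads$quality)
  if (any(!qual_ok)) {
    stop_invalid("malformed quality string for read '%s'",
                 reads$read_id[which(!qual_ok)[1L]])
  }
  frac_lowq <- vapply(reads$quality, function(q) {
    qv <- utf8ToInt(q) - 33L
    mean(qv <= 20L)
  }, numeric(1), USE.NAMES = FALSE)
  if (nrow(reads) == 0L) frac_lowq <- numeric(0)
  fail_n <- n_N / n > 0.08
  fail_q <- frac_lowq > 0.20
  keep <- !fail_n & !fail_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(
    reads = as_read_set(out),
    report = data.frame(
      n_in = nrow(reads),
      n_clean = sum(keep),
      removed_n_frac = sum(fail_n),
      removed_lowq = sum(fail_q & !fail_n)
    )
  )
}

#' Raw-to-clean QC summary for one sample
#'
#' Runs enzyme-read extraction followed by quality filtering and reports the
#' raw/enzyme/clean totals and fractions.
#'
#' @param reads a raw read set.
#' @return list with `reads` (clean reads) and `report` (one-row data frame:
#'   `n_raw`, `n_enzyme`, `n_clean`, `fraction_enzyme`, `fraction_clean`).
#' @export
qc_sample <- function(reads) {
  reads <- as_read_set(reads)
  enzyme <- extract_enzyme_reads(reads)
  res <- qc_filter(enzyme)
  list(
    reads = res$reads,
    report = data.frame(
      n_raw = nrow(reads),
      n_enzyme = nrow(enzyme),
      n_clean = nrow(res$reads),
      fraction_enzyme = if (nrow(reads) > 0L) nrow(enzyme) / nrow(reads) else 0,
      fraction_clean = if (nrow(reads) > 0L) nrow(res$reads) / nrow(reads) else 0
    )
  )
}
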
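#' @importFrom stats rbinom rnorm runif sd median quantile predict
#' @importFrom utils head read.table write.table
NULL

BCGI_TAG_LEN <- 32L
BCGI_CORE_OFFSET <- 11L  # 1-based start of the CGA half-site within a tag

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet `A/C/G/T/N`.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical orientation of a tag
#'
#' A 32-bp tag and its reverse complement name the same double-stranded
#' fragment; the canonical form is the lexicographically smaller of the two,
#' so that tags match regardless of the strand they were read from.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of canonical sequences.
#' @export
canonical_tag <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# Derive a named per-stage seed from one master seed.  Keeps all derived
# seeds in the 32-bit integer range.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
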
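#' Read and write read sets as FASTQ
#'
#' A read set is a data frame with columns `read_id`, `sequence` and
#' `quality` (Phred+33 strings, same length as the sequence).  These helpers
#' round-trip that representation through standard FASTQ files.
#'
#' @param reads data frame with columns `read_id`, `sequence`, `quality`.
#' @param path file path.
#' @return `read_fastq` returns a read-set data frame; `write_fastq` returns
#'   `path` invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- as_read_set(reads)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  read_set(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}

#' Construct and validate a read set
#'
#' @param read_id,sequence,quality equal-length character vectors.
#' @return data frame of class `read_set`.
#' @export
read_set <- function(read_id, sequence, quality) {
  as_read_set(data.frame(
    read_id = as.character(read_id),
    sequence = as.character(sequence),
    quality = as.character(quality),
    stringsAsFactors = FALSE
  ))
}

as_read_set <- function(x) {
  need <- c("read_id", "sequence", "quality")
  if (!all(need %in% names(x))) {
    stop_invalid("a read set needs columns %s", paste(need, collapse = ", "))
  }
  bad <- nchar(x$sequence) != nchar(x$quality)
  if (any(bad)) {
    stop_invalid("sequence/quality length mismatch for read '%s'",
                 x$read_id[which(bad)[1L]])
  }
  class(x) <- c("read_set", "data.frame")
  x
}

#' Write genomes as FASTA
#'
#' @param genomes named character vector (species_id -> DNA sequence).
#' @param path file path.
#' @export
write_genomes_fasta <- function(genomes, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genomes), path)
  invisible(path)
}

#' @rdname write_genomes_fasta
#' @export
read_genomes_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read and write taxonomy tables as TSV
#'
#' Columns: `species_id`, `genus`, `phylum`.
#'
#' @param tax taxonomy data frame.
#' @param path file path.
#' @export
write_taxonomy <- function(tax, path) {
  write.table(tax[, c("species_id", "genus", "phylum")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character")
}

#' Write an abundance matrix (taxa x samples) as TSV
#'
#' @param mat numeric matrix, rows = taxa, columns = samples.
#' @param path file path.
#' @export
write_profile_tsv <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}
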
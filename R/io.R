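# Plain-text format I/O.  FASTA/FASTQ go through Biostrings; newick through
# ape; PHYLIP (relaxed) and partition tables are simple enough to write here.

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings returning/accepting plain named character
#' vectors, which is how sequences travel through this package.
#'
#' @param x Named character vector of sequences.
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Read and write FASTQ
#'
#' FASTQ records are handled as a tibble with `id`, `bases` and a `qualities`
#' list-column of integer Phred scores, matching the read-filter interface.
#'
#' @param reads Tibble with columns `id`, `bases`, `qualities`.
#' @param path File path (`.gz` supported on read).
#' @param encoding `"phred33"` or `"phred64"`.
#' @return `read_fastq()` returns such a tibble.
#' @export
write_fastq <- function(reads, path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  off <- if (encoding == "phred33") 33L else 64L
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reads))) {
    q <- reads$qualities[[i]]
    writeLines(c(paste0("@", reads$id[i]), reads$bases[i], "+",
                 intToUtf8(q + off)), con)
  }
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64")) {
  encoding <- match.arg(encoding)
  off <- if (encoding == "phred33") 33L else 64L
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  idx <- seq(1L, length(lines), by = 4L)
  tibble::tibble(
    id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
    bases = toupper(lines[idx + 1L]),
    qualities = lapply(lines[idx + 3L], function(s) utf8ToInt(s) - off)
  )
}

#' Write a relaxed-PHYLIP alignment and a partition table
#'
#' @param aln Named character vector of equal-width aligned sequences.
#' @param path Output path.
#' @export
write_phylip <- function(aln, path) {
  stopifnot(length(unique(nchar(aln))) == 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(aln), nchar(aln[[1L]])), con)
  writeLines(sprintf("%s  %s", names(aln), unname(aln)), con)
  invisible(path)
}

#' @param partitions Tibble with `family_id`, `start`, `end` (1-based,
#'   inclusive), as produced by [concatenate_alignments()].
#' @rdname write_phylip
#' @export
write_partitions <- function(partitions, path) {
  writeLines(sprintf("%s = %d-%d", partitions$family_id,
                     partitions$start, partitions$end), path)
  invisible(path)
}
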
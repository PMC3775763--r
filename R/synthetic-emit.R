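#' Degrade coding sequences into transcripts and sequencing reads
#'
#' Emulates the imperfection of real transcriptome data: each input CDS is
#' truncated by `missing_fraction` of its length (removed from a random end),
#' and paired-end reads are sampled uniformly from the surviving transcripts
#' with configurable per-base low-quality and N-substitution rates.  A truth
#' map records exactly what was removed so downstream filters can be scored.
#'
#' @param cds Named character vector of coding sequences.  Names of the form
#'   `"<taxon>|<family>|g<copy>"` (or `"<taxon>|g<copy>"`) are parsed into
#'   the truth map.
#' @param missing_fraction Fraction of each transcript removed (scalar or
#'   per-sequence vector, `0 <= f < 1`).
#' @param read_pairs Total number of read pairs to sample (0 = none).
#' @param read_length Read length in bp (default 90).
#' @param low_quality_rate Fraction of read bases assigned the low quality
#'   score (Q2); the rest get Q38.
#' @param n_rate Fraction of read bases replaced by `N`.
#' @param encoding `"phred33"` (default) or `"phred64"` quality encoding for
#'   written FASTQ.
#' @param out_dir Optional directory; when given, writes `transcripts.fasta`,
#'   `reads_1.fastq`, `reads_2.fastq` and `truth_map.tsv` there.
#' @param seed Integer seed.
#' @return List with `transcripts` (named character vector), `reads` (tibble:
#'   `id`, `mate`, `bases`, `qualities` list-column of integer Phred scores),
#'   `truth` (tibble: `taxon`, `family_id`, `gene_id`, `copy_index`,
#'   `masked_fraction`, `original_length`, `kept_length`) and `files`
#'   (paths, or `NULL`).
#' @export
degrade_and_emit <- function(cds, missing_fraction = 0, read_pairs = 0,
                             read_length = 90, low_quality_rate = 0.02,
                             n_rate = 0.002, encoding = c("phred33", "phred64"),
                             out_dir = NULL, seed = NULL) {
  encoding <- match.arg(encoding)
  if (any(missing_fraction < 0 | missing_fraction >= 1))
    stop("missing_fraction must be in [0, 1)")
  mf <- rep_len(missing_fraction, length(cds))
  local_seed(seed, {
    lens <- nchar(cds)
    keep <- pmax(1L, as.integer(round(lens * (1 - mf))))
    from_start <- stats::runif(length(cds)) < 0.5
    transcripts <- vapply(seq_along(cds), function(i) {
      if (keep[i] >= lens[i]) return(cds[[i]])
      if (from_start[i]) substr(cds[[i]], 1L, keep[i])
      else substr(cds[[i]], lens[i] - keep[i] + 1L, lens[i])
    }, character(1))
    names(transcripts) <- names(cds)

    ids <- strsplit(names(cds), "|", fixed = TRUE)
    truth <- tibble::tibble(
      taxon = vapply(ids, `[`, character(1), 1L),
      family_id = vapply(ids, function(x) if (length(x) >= 3) x[2] else NA_character_, character(1)),
      gene_id = names(cds),
      copy_index = vapply(ids, function(x) {
        g <- x[length(x)]
        if (grepl("^g[0-9]+", g)) as.integer(sub("^g", "", sub("\\..*$", "", g))) else NA_integer_
      }, integer(1)),
      masked_fraction = 1 - keep / lens,
      original_length = as.integer(lens),
      kept_length = keep
    )

    reads <- emit_read_pairs(transcripts, read_pairs, read_length,
                             low_quality_rate, n_rate)

    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa <- file.path(out_dir, "transcripts.fasta")
      write_fasta(transcripts, fa)
      f1 <- file.path(out_dir, "reads_1.fastq")
      f2 <- file.path(out_dir, "reads_2.fastq")
      write_fastq(reads[reads$mate == 1L, ], f1, encoding)
      write_fastq(reads[reads$mate == 2L, ], f2, encoding)
      tm <- file.path(out_dir, "truth_map.tsv")
      utils::write.table(truth, tm, sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(transcripts = fa, reads_1 = f1, reads_2 = f2, truth_map = tm)
    }
    list(transcripts = transcripts, reads = reads, truth = truth, files = files)
  })
}

emit_read_pairs <- function(transcripts, read_pairs, read_length,
                            low_quality_rate, n_rate) {
  empty <- tibble::tibble(id = character(0), mate = integer(0),
                          bases = character(0), qualities = list())
  if (read_pairs <= 0) return(empty)
  lens <- nchar(transcripts)
  usable <- which(lens >= read_length)
  if (length(usable) < length(transcripts))
    warning(sprintf("%d transcript(s) shorter than read_length skipped",
                    length(transcripts) - length(usable)))
  if (length(usable) == 0) return(empty)
  w <- lens[usable] / sum(lens[usable])
  pick <- sample(usable, read_pairs, replace = TRUE, prob = w)
  rows <- vector("list", 2L * read_pairs)
  for (k in seq_len(read_pairs)) {
    i <- pick[k]
    L <- lens[i]
    insert <- min(L, 2L * read_length + 20L)
    start <- sample.int(L - insert + 1L, 1L)
    frag <- substr(transcripts[[i]], start, start + insert - 1L)
    r1 <- substr(frag, 1L, read_length)
    r2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(frag, insert - read_length + 1L, insert))))
    for (m in 1:2) {
      b <- if (m == 1) r1 else r2
      bb <- strsplit(b, "", fixed = TRUE)[[1L]]
      nn <- stats::runif(read_length) < n_rate
      bb[nn] <- "N"
      q <- ifelse(stats::runif(read_length) < low_quality_rate, 2L, 38L)
      q[nn] <- 2L
      rows[[2L * (k - 1L) + m]] <- tibble::tibble(
        id = sprintf("read%06d", k), mate = m,
        bases = paste0(bb, collapse = ""), qualities = list(as.integer(q)))
    }
  }
  dplyr::bind_rows(rows)
}
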
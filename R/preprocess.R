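#' Quality-filter sequencing reads
#'
#' Applies the pre-assembly read screen: a read is discarded when it has more
#' than `max_low_quality_bases` bases at or below `quality_threshold`, or
#' when more than `max_n_fraction` of its bases are `N`.  With the defaults
#' (Q7, 40 bases, 20%) this reproduces the conventional Illumina screen of
#' "more than 40 low-quality bases or more than 20% N" on 90 bp reads; the
#' Phred threshold is exposed rather than an encoding-specific ASCII value,
#' with `encoding` handled at FASTQ read time ([read_fastq()]).
#'
#' @param reads Tibble with columns `id`, `bases`, `qualities` (list-column
#'   of integer Phred scores), as from [read_fastq()].
#' @param quality_threshold A base is "low quality" when its Phred score is
#'   `<=` this value (default 7).
#' @param max_low_quality_bases Maximum tolerated count of low-quality bases
#'   (default 40; strictly more discards the read).
#' @param max_n_fraction Maximum tolerated N fraction (default 0.20; strictly
#'   more discards the read).
#' @return List with `kept` (tibble, input order preserved) and `discarded`
#'   (tibble with a `reason` column: `"low_quality"` or `"n_content"`).
#' @examples
#' r <- tibble::tibble(id = "r1", bases = strrep("A", 90),
#'                     qualities = list(rep(38L, 90)))
#' filter_reads(r)$kept$id
#' @export
filter_reads <- function(reads, quality_threshold = 7,
                         max_low_quality_bases = 40, max_n_fraction = 0.20) {
  stopifnot(all(c("id", "bases", "qualities") %in% names(reads)))
  if (max_n_fraction < 0 || max_n_fraction > 1) stop("max_n_fraction must be in [0,1]")
  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    b <- reads$bases[i]; q <- reads$qualities[[i]]
    if (nchar(b) != length(q))
      stop(sprintf("malformed record '%s': %d bases but %d quality scores",
                   reads$id[i], nchar(b), length(q)))
    n_low <- sum(q <= quality_threshold)
    n_N <- lengths(regmatches(b, gregexpr("N", b, fixed = TRUE)))
    if (n_low > max_low_quality_bases) reason[i] <- "low_quality"
    else if (n_N / nchar(b) > max_n_fraction) reason[i] <- "n_content"
  }
  keep <- is.na(reason)
  list(kept = reads[keep, , drop = FALSE],
       discarded = dplyr::mutate(reads[!keep, , drop = FALSE],
                                 reason = reason[!keep]))
}

#' Length-filter assembled contigs
#'
#' Retains contigs at least `min_length` bp long (inclusive), preserving
#' input order.
#'
#' @param transcripts Named character vector of contig sequences.
#' @param min_length Minimum retained length in bp (default 150).
#' @return Named character vector of the retained contigs.
#' @export
filter_contigs <- function(transcripts, min_length = 150) {
  transcripts[nchar(transcripts) >= min_length]
}

#' Collapse highly similar transcripts
#'
#' Greedy longest-first clustering used to remove putative alternative
#' splice forms: transcripts are visited in decreasing length (ties by name),
#' and one is dropped when its best local alignment to an already-kept
#' representative has percent identity `>= identity_threshold` over at least
#' `min_self_coverage` of its own length.
#'
#' @param transcripts Named character vector of nucleotide sequences.
#' @param identity_threshold Identity fraction (default 0.95).
#' @param min_self_coverage Fraction of the shorter transcript that must be
#'   covered by the alignment (default 0.8).
#' @return Named character vector of representatives, in input order.
#' @export
collapse_redundant <- function(transcripts, identity_threshold = 0.95,
                               min_self_coverage = 0.8) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0,1]")
  if (length(transcripts) <= 1L) return(transcripts)
  ord <- order(-nchar(transcripts), names(transcripts))
  reps <- character(0)
  for (i in ord) {
    s <- transcripts[[i]]
    redundant <- FALSE
    for (r in reps) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), Biostrings::DNAString(transcripts[[r]]),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -3),
        gapOpening = 5, gapExtension = 2)
      span <- Biostrings::nchar(Biostrings::pattern(al))
      if (span / nchar(s) >= min_self_coverage &&
          Biostrings::pid(al) / 100 >= identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) reps <- c(reps, names(transcripts)[i])
  }
  transcripts[intersect(names(transcripts), reps)]
}

#' Extract a coding region from a transcript
#'
#' Translates all six reading frames, takes the open reading frames between
#' stop codons, aligns each locally to the reference proteins, and defines
#' the CDS from the highest-scoring (ORF, reference) pair whose score reaches
#' `min_score`.  This is the annotation step that turns assembled transcripts
#' into in-frame coding sequences with a defined translation.
#'
#' @param transcript A single nucleotide string (may be named).
#' @param reference_proteins Named character vector of reference protein
#'   sequences.
#' @param min_score Minimum local alignment raw score (BLOSUM62, gap open 11,
#'   extend 1) for a CDS call (default 60).
#' @param min_orf_aa Minimum ORF length considered, in residues (default 15).
#' @return A one-row tibble (`transcript_id`, `ref_id`, `strand`, `frame`,
#'   `start`, `end` 1-based inclusive on the input strand, `cds`, `protein`,
#'   `score`) or `NULL` when nothing reaches `min_score`.
#' @export
extract_cds <- function(transcript, reference_proteins, min_score = 60,
                        min_orf_aa = 15) {
  if (length(reference_proteins) == 0) stop("reference proteome is empty")
  tid <- names(transcript) %||% "transcript"
  s <- unname(transcript[[1L]])
  if (nchar(s) < 3) {
    warning("transcript shorter than one codon; no CDS")
    return(NULL)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  refs <- Biostrings::AAStringSet(reference_proteins)

  best <- NULL
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    L <- nchar(seqs)
    for (f in 0:2) {
      n_cod <- (L - f) %/% 3
      if (n_cod < min_orf_aa) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(seqs, f + 1L, f + 3L * n_cod)),
        if.fuzzy.codon = "solve", no.init.codon = TRUE))
      # ORFs = maximal stop-free stretches
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1L]]
      offset <- 0L
      for (p in pieces) {
        start_aa <- offset + 1L
        offset <- offset + nchar(p) + 1L
        if (nchar(p) < min_orf_aa) next
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAStringSet(rep(p, length(refs))), refs,
          type = "local", substitutionMatrix = mat,
          gapOpening = 11, gapExtension = 1)
        sc <- Biostrings::score(al)
        j <- which.max(sc)
        if (sc[j] >= min_score && (is.null(best) || sc[j] > best$score)) {
          rng <- Biostrings::pattern(al[j])
          a1 <- start_aa + Biostrings::start(rng) - 1L
          a2 <- start_aa + Biostrings::end(rng) - 1L
          nt1 <- f + 3L * (a1 - 1L) + 1L     # on current strand
          nt2 <- f + 3L * a2
          if (strand == "-") { tmp <- nt1; nt1 <- L - nt2 + 1L; nt2 <- L - tmp + 1L }
          cds_nt <- if (strand == "+") substr(s, nt1, nt2) else
            as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(substr(s, nt1, nt2))))
          best <- tibble::tibble(
            transcript_id = tid, ref_id = names(reference_proteins)[j],
            strand = strand, frame = f + 1L, start = nt1, end = nt2,
            cds = cds_nt, protein = substr(p, Biostrings::start(rng),
                                           Biostrings::end(rng)),
            score = sc[j])
        }
      }
    }
  }
  best
}
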
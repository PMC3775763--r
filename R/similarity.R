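#' Local protein alignment score
#'
#' Optimal Smith-Waterman local alignment with affine gaps (default
#' BLOSUM62, gap open 11 / extend 1 -- the classic protein-search defaults),
#' reported as a similarity hit: raw score plus the aligned span length on
#' each sequence.  If no positive-scoring local alignment exists the score
#' is 0 with empty spans.
#'
#' @param a,b Protein sequences (single strings, may be named).
#' @param substitution_matrix Scoring matrix (default `BLOSUM62`).
#' @param gap_open,gap_extend Affine gap parameters: a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @return One-row tibble: `query`, `subject`, `raw_score`,
#'   `qalnlen`, `salnlen`, `evalue` (`NA`; the in-house aligner reports raw
#'   scores only).
#' @export
local_align_protein <- function(a, b, substitution_matrix = NULL,
                                gap_open = 11, gap_extend = 1) {
  if (nchar(a[[1L]]) == 0 || nchar(b[[1L]]) == 0) stop("empty sequence")
  mat <- substitution_matrix %||% blosum62()
  for (s in c(a[[1L]], b[[1L]])) {
    bad <- setdiff(strsplit(s, "", fixed = TRUE)[[1L]], rownames(mat))
    if (length(bad))
      stop("residue(s) not covered by the substitution matrix: ",
           paste(unique(bad), collapse = ", "))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a[[1L]]), Biostrings::AAString(b[[1L]]),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    sc <- 0; qlen <- 0L; slen <- 0L
  } else {
    qlen <- Biostrings::width(Biostrings::pattern(al))
    slen <- Biostrings::width(Biostrings::subject(al))
  }
  tibble::tibble(query = names(a) %||% "a", subject = names(b) %||% "b",
                 raw_score = sc, qalnlen = as.integer(qlen),
                 salnlen = as.integer(slen), evalue = NA_real_)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' All-vs-all protein similarity
#'
#' Computes similarity hits for every pair of proteins with the in-house
#' local aligner.  Scores are symmetric (one alignment per unordered pair,
#' reported in both directions) and self-hits are always retained -- they are
#' required to normalise H-scores.  Cross-hits below `min_raw_score` are
#' dropped.  For larger data sets use [blast_all_vs_all()], which preserves
#' E-value semantics.
#'
#' @param proteins Named character vector (>= 2 sequences).
#' @param min_raw_score Raw-score retention threshold for cross-hits
#'   (default 50).
#' @inheritParams local_align_protein
#' @return Tibble of hits (`query`, `subject`, `raw_score`, `qalnlen`,
#'   `salnlen`, `evalue`), both directions of every retained pair plus all
#'   self-hits.
#' @export
all_vs_all <- function(proteins, min_raw_score = 50,
                       substitution_matrix = NULL,
                       gap_open = 11, gap_extend = 1) {
  if (length(proteins) < 2) stop("need at least 2 proteins")
  if (is.null(names(proteins))) stop("proteins must be named")
  ids <- names(proteins)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      h <- local_align_protein(proteins[i], proteins[j],
                               substitution_matrix, gap_open, gap_extend)
      if (i == j) {
        rows[[length(rows) + 1L]] <- h
      } else if (h$raw_score >= min_raw_score) {
        rows[[length(rows) + 1L]] <- h
        rows[[length(rows) + 1L]] <- tibble::tibble(
          query = h$subject, subject = h$query, raw_score = h$raw_score,
          qalnlen = h$salnlen, salnlen = h$qalnlen, evalue = NA_real_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Read a tabular similarity file
#'
#' Parses the standard 12-column tabular hit format (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore), optionally extended with a 13th raw-score
#' column (`-outfmt "6 std score"`).  Without the 13th column the raw score
#' is recovered from the bit score via the default gapped BLOSUM62 statistics
#' (lambda 0.267, K 0.041).  Aligned span lengths are computed from the
#' coordinate columns.  Rows with E-value above `max_evalue` are dropped,
#' except self-hits, which are always kept; if a gene referenced by a
#' retained cross-hit has no self-hit the H-score is undefined and an error
#' is raised.  Multiple HSPs per pair are reduced to the best raw score.
#'
#' @param path Path to the tabular file.
#' @param max_evalue E-value retention threshold (default 1e-5).
#' @return Tibble of hits as in [all_vs_all()].
#' @export
read_similarity_table <- function(path, max_evalue = 1e-5) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield != 12L & nfield != 13L)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected 12 or 13 fields, got %d",
                 bad[1L], nfield[bad[1L]]))
  f <- function(k) vapply(parts, `[`, character(1), k)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(f(k)))
    if (anyNA(v)) {
      ln <- which(is.na(v))[1L]
      stop(sprintf("malformed row at line %d: non-numeric field %d", ln, k))
    }
    v
  }
  hits <- tibble::tibble(
    query = f(1), subject = f(2),
    qalnlen = as.integer(abs(num(8) - num(7)) + 1),
    salnlen = as.integer(abs(num(10) - num(9)) + 1),
    evalue = num(11),
    raw_score = if (all(nfield == 13L)) num(13)
                else round((num(12) * log(2) + log(0.041)) / 0.267))
  hits <- hits[hits$evalue <= max_evalue | hits$query == hits$subject, ]
  hits <- dplyr::slice_max(dplyr::group_by(hits, .data$query, .data$subject),
                           .data$raw_score, n = 1, with_ties = FALSE)
  hits <- dplyr::ungroup(hits)
  genes <- unique(c(hits$query, hits$subject))
  selfs <- hits$query[hits$query == hits$subject]
  missing <- setdiff(genes, selfs)
  if (length(missing))
    stop("self-hit missing for gene(s): ", paste(missing, collapse = ", "),
         " -- H-scores are undefined without self scores")
  hits[, c("query", "subject", "raw_score", "qalnlen", "salnlen", "evalue")]
}

#' All-vs-all similarity via the blastp binary
#'
#' Convenience wrapper for large gene sets: builds a combined protein
#' database, runs `blastp` all-vs-all at `max_evalue`, and ingests the
#' 13-column tabular output through [read_similarity_table()].  Any gene
#' whose self-hit is absent from the BLAST output (rare, but possible with
#' very short sequences) gets one computed by the in-house aligner.
#'
#' @param proteins Named character vector of protein sequences.
#' @param max_evalue E-value threshold passed to blastp (default 1e-5).
#' @param threads Number of blastp threads.
#' @return Tibble of hits as in [all_vs_all()].
#' @export
blast_all_vs_all <- function(proteins, max_evalue = 1e-5, threads = 1) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stop("blastp/makeblastdb not found on PATH; use all_vs_all() instead")
  td <- tempfile("blastavs")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "prot.fasta")
  write_fasta(proteins, fa)
  db <- file.path(td, "db")
  out <- file.path(td, "hits.tsv")
  system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db),
          stdout = FALSE, stderr = FALSE)
  status <- system2("blastp",
                    c("-query", fa, "-db", db, "-evalue", format(max_evalue),
                      "-seg", "no", "-num_threads", threads,
                      "-outfmt", shQuote("6 std score"), "-out", out),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) stop("blastp failed with status ", status)
  lines <- readLines(out)
  # ensure every queried gene has a self-hit before parsing
  parts <- strsplit(lines, "\t", fixed = TRUE)
  selfs <- unique(vapply(parts[vapply(parts, function(p) p[1] == p[2],
                                      logical(1))], `[`, character(1), 1L))
  for (g in setdiff(names(proteins), selfs)) {
    h <- local_align_protein(proteins[g], proteins[g])
    lines <- c(lines, paste(g, g, 100, h$qalnlen, 0, 0, 1, h$qalnlen, 1,
                            h$salnlen, 0, h$raw_score / 2, h$raw_score,
                            sep = "\t"))
  }
  writeLines(lines, out)
  read_similarity_table(out, max_evalue)
}
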
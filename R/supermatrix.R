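#' Back-translate an aligned protein block to codons
#'
#' Expands every residue column of a protein alignment to the source codon
#' and every gap to `---`, producing the matched nucleotide block analysed
#' alongside the amino-acid block (the 3:1 width relation between the two
#' supermatrices follows from this step).
#'
#' @param aligned_proteins Named character vector (equal-width protein
#'   alignment).
#' @param cds Named character vector of unaligned coding sequences; each
#'   must translate exactly to its ungapped protein row.
#' @return Named character vector: codon alignment of width
#'   `3 * protein width`.
#' @export
backtranslate <- function(aligned_proteins, cds) {
  missing <- setdiff(names(aligned_proteins), names(cds))
  if (length(missing)) stop("no CDS for: ", paste(missing, collapse = ", "))
  translations <- translate_cds(cds[names(aligned_proteins)])
  out <- vapply(names(aligned_proteins), function(nm) {
    prot <- aligned_proteins[[nm]]
    s <- cds[[nm]]
    ung <- gsub("-", "", prot, fixed = TRUE)
    tr <- translations[[nm]]
    if (!identical(unname(tr), ung)) {
      # report the first disagreeing residue
      t1 <- strsplit(unname(tr), "")[[1L]]; t2 <- strsplit(ung, "")[[1L]]
      pos <- if (length(t1) != length(t2)) min(length(t1), length(t2)) + 1L
             else which(t1 != t2)[1L]
      stop(sprintf("CDS of '%s' does not translate to its protein row (first mismatch at residue %d)",
                   nm, pos))
    }
    chars <- strsplit(prot, "", fixed = TRUE)[[1L]]
    cod <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") cod[i] <- "---"
      else { cod[i] <- substr(s, 3L * k + 1L, 3L * k + 3L); k <- k + 1L }
    }
    paste0(cod, collapse = "")
  }, character(1))
  names(out) <- names(aligned_proteins)
  out
}

#' Per-family alignment object
#'
#' Bundles a family's aligned protein and codon blocks.
#'
#' @param family_id Family identifier.
#' @param aa Named character vector: aligned protein block (names = taxa).
#' @param nt Named character vector: aligned codon block, width `3 * aa`.
#' @return A `gene_alignment` list.
#' @export
gene_alignment <- function(family_id, aa, nt) {
  stopifnot(identical(sort(names(aa)), sort(names(nt))),
            all(nchar(nt) == 3L * nchar(aa)))
  structure(list(family_id = family_id, aa = aa, nt = nt[names(aa)]),
            class = "gene_alignment")
}

#' Align a single-copy family and back-translate it
#'
#' Convenience step from a family's coding sequences to a [gene_alignment()]:
#' translate, progressively align the proteins, back-translate.  Row names
#' are reduced to the taxon (the part of the gene id before the first `|`).
#'
#' @param cds Named character vector of the family members' CDS (names are
#'   gene ids of the form `taxon|...`).
#' @param family_id Family identifier.
#' @inheritParams progressive_align
#' @return A `gene_alignment`.
#' @export
align_family <- function(cds, family_id, substitution_matrix = NULL,
                         gap_open = 11, gap_extend = 1) {
  prots <- translate_cds(cds)
  aa <- progressive_align(prots, substitution_matrix, gap_open, gap_extend)
  nt <- backtranslate(aa, cds)
  names(aa) <- sub("\\|.*$", "", names(aa))
  names(nt) <- sub("\\|.*$", "", names(nt))
  gene_alignment(family_id, aa, nt)
}

#' Filter genes by per-taxon missing data
#'
#' Drops any gene in which some taxon exceeds `max_missing_fraction` of
#' missing data (alignment gaps plus wholly absent taxa; ambiguity characters
#' count as present).  With the default 0.5 a gene is retained only when
#' every taxon contributes at least half of the alignment -- the filter that
#' reduces a full gene set to the low-missing-data core used for inference.
#' `quantifier = "mean"` instead averages the missing fraction over taxa.
#'
#' @param gene_alignments List of [gene_alignment()] objects.
#' @param taxa Character vector of all taxa that should be present.
#' @param max_missing_fraction Per-taxon tolerated missing fraction,
#'   inclusive (default 0.5).
#' @param quantifier `"any"` (drop if any taxon exceeds; default) or
#'   `"mean"`.
#' @return List with `retained` (list of gene alignments) and `dropped`
#'   (tibble `family_id`, `worst_taxon`, `missing_fraction`).
#' @export
filter_genes_by_missing <- function(gene_alignments, taxa,
                                    max_missing_fraction = 0.5,
                                    quantifier = c("any", "mean")) {
  quantifier <- match.arg(quantifier)
  drop_log <- list()
  retained <- list()
  for (ga in gene_alignments) {
    frac <- missing_fraction_by_taxon(ga, taxa)
    stat <- if (quantifier == "any") max(frac) else mean(frac)
    if (stat > max_missing_fraction) {
      drop_log[[length(drop_log) + 1L]] <- tibble::tibble(
        family_id = ga$family_id,
        worst_taxon = names(frac)[which.max(frac)],
        missing_fraction = max(frac))
    } else retained[[length(retained) + 1L]] <- ga
  }
  list(retained = retained,
       dropped = dplyr::bind_rows(drop_log) %||% tibble::tibble())
}

missing_fraction_by_taxon <- function(ga, taxa) {
  w <- nchar(ga$aa[[1L]])
  vapply(stats::setNames(taxa, taxa), function(tx) {
    if (!tx %in% names(ga$aa)) return(1)
    row <- ga$aa[[tx]]
    (nchar(row) - nchar(gsub("[-?]", "", row))) / w
  }, numeric(1))
}

#' Concatenate gene alignments into a supermatrix
#'
#' Concatenates the retained genes in lexicographic `family_id` order into
#' matched nucleotide and amino-acid supermatrices with a partition table.
#' Taxa absent from a gene are filled with gaps across that partition, so
#' every row spans the full width; total nucleotide width is exactly three
#' times the amino-acid width.
#'
#' @param gene_alignments List of [gene_alignment()] objects (>= 1).
#' @param taxa Character vector of taxa forming the rows.
#' @return A `supermatrix`: list with `taxa`, `nt` and `aa` (named character
#'   vectors) and `partitions` (tibble `family_id`, `aa_start`, `aa_end`,
#'   `nt_start`, `nt_end`; 1-based inclusive).
#' @export
concatenate_alignments <- function(gene_alignments, taxa) {
  if (length(gene_alignments) == 0) stop("no gene alignments")
  ids <- vapply(gene_alignments, `[[`, character(1), "family_id")
  gene_alignments <- gene_alignments[order(ids)]
  aa_rows <- stats::setNames(rep("", length(taxa)), taxa)
  nt_rows <- aa_rows
  parts <- list()
  aa_pos <- 0L
  for (ga in gene_alignments) {
    if (anyDuplicated(names(ga$aa)))
      stop("duplicate taxon row within gene ", ga$family_id)
    w <- nchar(ga$aa[[1L]])
    for (tx in taxa) {
      aa_rows[tx] <- paste0(aa_rows[tx],
                            if (tx %in% names(ga$aa)) ga$aa[[tx]]
                            else strrep("-", w))
      nt_rows[tx] <- paste0(nt_rows[tx],
                            if (tx %in% names(ga$nt)) ga$nt[[tx]]
                            else strrep("-", 3L * w))
    }
    parts[[length(parts) + 1L]] <- tibble::tibble(
      family_id = ga$family_id,
      aa_start = aa_pos + 1L, aa_end = aa_pos + w,
      nt_start = 3L * aa_pos + 1L, nt_end = 3L * (aa_pos + w))
    aa_pos <- aa_pos + w
  }
  structure(list(taxa = taxa, nt = nt_rows, aa = aa_rows,
                 partitions = dplyr::bind_rows(parts)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa, %d genes, %d nt / %d aa positions\n",
              length(x$taxa), nrow(x$partitions), nchar(x$nt[[1L]]),
              nchar(x$aa[[1L]])))
  invisible(x)
}
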
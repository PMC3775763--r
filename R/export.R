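# Tabular exports/imports for the pipeline's intermediate artifacts.

#' Write similarity hits, graphs and families as TSV
#'
#' Plain-text interchange for the ortholog-detection artifacts: the
#' canonical hits table (`query`, `subject`, `raw_score`, `qalnlen`,
#' `salnlen`, `evalue`), the H-score graph as an edge list (`from`, `to`,
#' `h`), and gene families in long form (`family_id`, `taxon`, `gene_id`).
#'
#' @param hits Hit tibble ([all_vs_all()], [read_similarity_table()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param graph An `ortholog_graph` from [build_graph()].
#' @rdname write_hits_tsv
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "ortholog_graph"))
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param families Family tibble from [cluster_families()].
#' @rdname write_hits_tsv
#' @export
write_families_tsv <- function(families, path) {
  long <- dplyr::bind_rows(lapply(seq_len(nrow(families)), function(i)
    tibble::tibble(family_id = families$family_id[i],
                   taxon = families$taxa[[i]],
                   gene_id = families$members[[i]])))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Orthogroup count matrix
#'
#' @param families Family tibble from [cluster_families()].
#' @param taxa Taxa forming the columns (default: all observed).
#' @return Integer matrix (family x taxon) of gene counts.
#' @export
family_count_matrix <- function(families, taxa = NULL) {
  taxa <- taxa %||% sort(unique(unlist(families$taxa)))
  m <- t(vapply(families$taxa, function(tx)
    as.integer(table(factor(tx, levels = taxa))), integer(length(taxa))))
  dimnames(m) <- list(families$family_id, taxa)
  m
}

#' Read a calibration table
#'
#' Parses the plain-text calibration format: one row per calibration with
#' tab-separated fields `clade` (comma-separated taxon list, or `root`),
#' `mean_ma`, `sd_ma`, `type` (`stem` or `crown`), with a header line.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `clade` (list), `mean`, `sd`, `type`, as
#'   consumed by [strict_clock_date()].
#' @export
read_calibrations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clade", "mean_ma", "sd_ma", "type")
  if (!all(need %in% names(df)))
    stop("calibration file must have columns: ", paste(need, collapse = ", "))
  tibble::tibble(
    clade = lapply(strsplit(df$clade, ","), trimws),
    mean = as.numeric(df$mean_ma),
    sd = as.numeric(df$sd_ma),
    type = df$type)
}

#' Write a dated tree with posterior mean ages
#'
#' Writes the rooted topology in Newick with each internal node labelled by
#' its posterior mean age (Ma) and branch lengths set to the implied mean
#' durations.
#'
#' @param dt A `dated_tree` from [strict_clock_date()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dated_tree <- function(dt, path) {
  stopifnot(inherits(dt, "dated_tree"))
  tree <- dt$tree
  ntip <- ape::Ntip(tree)
  ages <- numeric(ntip + tree$Nnode)
  est <- dt$estimates[dt$estimates$parameter != "rate", ]
  ages[est$node] <- est$mean
  tree$edge.length <- ages[tree$edge[, 1L]] - ages[tree$edge[, 2L]]
  tree$node.label <- sprintf("%.2f", ages[(ntip + 1L):(ntip + tree$Nnode)])
  ape::write.tree(tree, path)
  invisible(path)
}

#' Export posterior samples of a dated tree
#'
#' @param dt A `dated_tree`.
#' @param path Output path (TSV, one row per kept sample).
#' @return The path, invisibly.
#' @export
write_posterior_tsv <- function(dt, path) {
  stopifnot(inherits(dt, "dated_tree"))
  utils::write.table(dt$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
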
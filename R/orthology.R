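#' H-score: normalised pairwise similarity
#'
#' The edge weight of the ortholog graph: the raw cross-alignment score of
#' two genes scaled by the larger of their self-alignment scores,
#' `raw_ab * 100 / max(raw_aa, raw_bb)`, clamped to `[0, 100]`.  A gene
#' against itself scores 100; unrelated genes score 0.
#'
#' @param raw_ab Raw cross score (>= 0).
#' @param raw_aa,raw_bb Raw self scores (> 0).
#' @return Numeric H-score in `[0, 100]` (vectorised).
#' @examples
#' h_score(50, 100, 200)  # 25
#' h_score(250, 250, 250) # 100
#' @export
h_score <- function(raw_ab, raw_aa, raw_bb) {
  if (any(raw_aa <= 0) || any(raw_bb <= 0))
    stop("self scores must be positive")
  if (any(raw_ab < 0)) stop("cross score must be >= 0")
  pmin(100, pmax(0, raw_ab * 100 / pmax(raw_aa, raw_bb)))
}

#' Build the H-score-weighted ortholog graph
#'
#' Turns a similarity hit table into an undirected gene graph.  Directed raw
#' scores are symmetrised as the maximum over the two directions; an edge
#' (a, b) is created only when the aligned span is strictly longer than a
#' third of each gene's length and the H-score is strictly greater than
#' `min_h`.  Self-hits must be present for every gene in a cross-hit.
#'
#' @param hits Hit tibble ([all_vs_all()], [read_similarity_table()]).
#' @param protein_lengths Named integer vector of protein lengths; when
#'   `NULL`, lengths are taken from each gene's self-hit span.
#' @param min_mutual_coverage Coverage fraction that must be strictly
#'   exceeded on both genes (default 1/3).
#' @param min_h H-score that must be strictly exceeded (default 5).
#' @return An `ortholog_graph`: list with `nodes` (tibble `gene`, `taxon`)
#'   and `edges` (tibble `from`, `to`, `h`, with `from < to`).
#' @export
build_graph <- function(hits, protein_lengths = NULL,
                        min_mutual_coverage = 1 / 3, min_h = 5) {
  selfs <- hits[hits$query == hits$subject, ]
  self_score <- stats::setNames(selfs$raw_score, selfs$query)
  cross <- hits[hits$query != hits$subject, ]
  genes <- unique(c(hits$query, hits$subject))
  missing <- setdiff(unique(c(cross$query, cross$subject)), names(self_score))
  if (length(missing))
    stop("missing self-hit for gene(s): ", paste(missing, collapse = ", "))
  if (is.null(protein_lengths))
    protein_lengths <- stats::setNames(pmax(selfs$qalnlen, selfs$salnlen),
                                       selfs$query)

  nodes <- tibble::tibble(gene = sort(genes),
                          taxon = sub("\\|.*$", "", sort(genes)))
  if (nrow(cross) == 0)
    return(structure(list(nodes = nodes,
                          edges = tibble::tibble(from = character(0),
                                                 to = character(0),
                                                 h = numeric(0))),
                     class = "ortholog_graph"))

  a <- pmin(cross$query, cross$subject)
  b <- pmax(cross$query, cross$subject)
  key <- paste(a, b, sep = "\r")
  # per unordered pair keep the directed hit with the larger raw score
  # (symmetrised score); its spans provide the coverage test
  ord <- order(key, -cross$raw_score, cross$query)
  cross <- cross[ord, ]
  first <- !duplicated(key[ord])
  cross <- cross[first, ]
  la <- protein_lengths[cross$query]
  lb <- protein_lengths[cross$subject]
  h <- h_score(cross$raw_score, self_score[cross$query],
               self_score[cross$subject])
  keep <- cross$qalnlen > la * min_mutual_coverage &
    cross$salnlen > lb * min_mutual_coverage & h > min_h
  edges <- tibble::tibble(from = pmin(cross$query, cross$subject)[keep],
                          to = pmax(cross$query, cross$subject)[keep],
                          h = unname(h[keep]))
  structure(list(nodes = nodes, edges = edges), class = "ortholog_graph")
}

#' Cluster the ortholog graph into gene families
#'
#' Constrained average-linkage agglomeration: starting from singletons, the
#' pair of clusters with the highest average linkage (mean H-score over all
#' cross pairs, absent edges counting 0) is merged, provided the merge is
#' admissible: average linkage strictly above `min_h` and, in the default
#' `"merge"` mode, the merged cluster's edge density (realised edges over
#' `k(k-1)/2`) strictly above `min_density`.  Two-gene clusters always have
#' density 1 when their edge exists.  Ties are broken by the
#' lexicographically smallest pair of cluster ids (a cluster's id is its
#' smallest gene id), making the result order-independent.  In `"post"`
#' mode the density rule is applied after clustering instead, dissolving
#' failing families into singletons.
#'
#' @param graph An `ortholog_graph` from [build_graph()].
#' @param min_density Edge density that must be strictly exceeded
#'   (default 1/3).
#' @param min_h Average linkage that must be strictly exceeded (default 5).
#' @param density_mode `"merge"` (check at every merge; default) or `"post"`.
#' @return Tibble with one row per family: `family_id`, `size`, `members`
#'   (list of gene ids), `taxa` (list), `edge_density`, `mean_h`.
#' @export
cluster_families <- function(graph, min_density = 1 / 3, min_h = 5,
                             density_mode = c("merge", "post")) {
  density_mode <- match.arg(density_mode)
  stopifnot(inherits(graph, "ortholog_graph"))
  g <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                     vertices = graph$nodes$gene)
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    clusters <- c(clusters,
                  agglomerate_component(members, graph$edges, min_density,
                                        min_h, density_mode))
  }
  # deterministic family ids: order by smallest member gene id
  key <- vapply(clusters, function(cl) min(cl), character(1))
  clusters <- clusters[order(key)]
  edges <- graph$edges
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- sort(clusters[[i]])
    k <- length(cl)
    within <- edges$from %in% cl & edges$to %in% cl
    dens <- if (k < 2) 1 else sum(within) / (k * (k - 1) / 2)
    tibble::tibble(family_id = sprintf("FAM%05d", i), size = k,
                   members = list(cl),
                   taxa = list(sub("\\|.*$", "", cl)),
                   edge_density = dens,
                   mean_h = if (k < 2) NA_real_ else
                     sum(edges$h[within]) / (k * (k - 1) / 2))
  })
  dplyr::bind_rows(rows)
}

# Average-linkage agglomeration within one connected component.
agglomerate_component <- function(members, edges, min_density, min_h,
                                  density_mode) {
  k <- length(members)
  if (k == 1L) return(list(members))
  members <- sort(members)
  idx <- stats::setNames(seq_len(k), members)
  H <- matrix(0, k, k)
  A <- matrix(FALSE, k, k)          # adjacency (edge exists)
  sel <- edges$from %in% members & edges$to %in% members
  ei <- idx[edges$from[sel]]; ej <- idx[edges$to[sel]]
  H[cbind(ei, ej)] <- H[cbind(ej, ei)] <- edges$h[sel]
  A[cbind(ei, ej)] <- A[cbind(ej, ei)] <- TRUE

  cl <- as.list(seq_len(k))          # clusters as index vectors
  repeat {
    n_cl <- length(cl)
    if (n_cl == 1L) break
    best <- NULL
    for (p in seq_len(n_cl - 1L)) {
      for (q in (p + 1L):n_cl) {
        ip <- cl[[p]]; iq <- cl[[q]]
        link <- mean(H[ip, iq, drop = FALSE])
        if (link <= min_h) next
        if (density_mode == "merge") {
          m <- c(ip, iq)
          dens <- mean(A[m, m][upper.tri(diag(length(m)))])
          if (length(m) > 2L && dens <= min_density) next
          if (length(m) == 2L && !A[ip, iq]) next
        }
        ids <- sort(c(min(members[ip]), min(members[iq])))
        cand <- list(link = link, p = p, q = q, ids = ids)
        if (is.null(best) || cand$link > best$link ||
            (cand$link == best$link &&
             (cand$ids[1] < best$ids[1] ||
              (cand$ids[1] == best$ids[1] && cand$ids[2] < best$ids[2]))))
          best <- cand
      }
    }
    if (is.null(best)) break
    cl[[best$p]] <- c(cl[[best$p]], cl[[best$q]])
    cl[[best$q]] <- NULL
  }
  if (density_mode == "post") {
    out <- list()
    for (ip in cl) {
      m <- length(ip)
      dens <- if (m < 2) 1 else mean(A[ip, ip][upper.tri(diag(m))])
      if (m > 2L && dens <= min_density)
        out <- c(out, as.list(ip))      # dissolve
      else out <- c(out, list(ip))
    }
    cl <- out
  }
  lapply(cl, function(ip) members[ip])
}

#' Select one-to-one single-copy families
#'
#' Retains the families in which every required taxon is represented by
#' exactly one gene -- the 1:1 orthologs that are concatenated for
#' species-tree inference.
#'
#' @param families Family tibble from [cluster_families()].
#' @param required_taxa Character vector of taxa that must each contribute
#'   exactly one gene.
#' @return The retained subset of `families`, with a `single_copy` column
#'   set to `TRUE`.
#' @export
select_single_copy <- function(families, required_taxa) {
  if (length(required_taxa) == 0) stop("required_taxa must be non-empty")
  ok <- vapply(families$taxa, function(tx) {
    cnt <- table(factor(tx, levels = required_taxa))
    all(cnt == 1L) && length(tx) == length(required_taxa)
  }, logical(1))
  dplyr::mutate(families[ok, , drop = FALSE], single_copy = TRUE)
}
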
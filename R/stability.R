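#' Gene-subsampling topology-stability protocol
#'
#' For each gene count `N` on a grid, repeatedly draws a uniform random set
#' of `N` genes (without replacement within a draw), concatenates them,
#' builds a tree and compares its unrooted topology with a reference; draws
#' are repeated until the topologies match, and the number of draws needed
#' ("repeats until match") is recorded.  Each accepted tree also receives
#' fast bootstrap supports.  Averaged over `trees_per_N` slots this measures
#' how concentrated the phylogenetic signal is: repeats fall and supports
#' rise as `N` grows.
#'
#' @param gene_alignments List of [gene_alignment()] objects (the gene pool).
#' @param reference Reference topology (`phylo`, same taxa).
#' @param N_grid Integer vector of gene counts (default `seq(10, 220, 10)`,
#'   truncated to the pool size).
#' @param trees_per_N Accepted trees per N (default 30).
#' @param max_attempts_per_slot Draw cap per slot; a slot that exhausts it is
#'   recorded as censored at the cap (default 1000).
#' @param builder Tree builder for the replicate trees: `"fastml"`
#'   (NJ start + NNI under JC; default), `"nj"`, or `"ml"` (full GTR+Gamma
#'   search).
#' @param bootstrap_builder Builder used inside the bootstrap of each
#'   accepted tree: `"nj"` (default; distance bootstrap, cheap enough to
#'   run at every slot) or `"ml"`.
#' @param bootstrap_replicates Bootstrap replicates per accepted tree
#'   (default 50; 0 skips supports).
#' @param seed Integer seed.
#' @return A tibble (`jackknife_table`): `N`, `slot`, `repeats`, `censored`,
#'   `mean_support`, `supports` (list column).
#' @export
gene_jackknife <- function(gene_alignments, reference,
                           N_grid = seq(10, 220, by = 10), trees_per_N = 30,
                           max_attempts_per_slot = 1000,
                           builder = c("fastml", "nj", "ml"),
                           bootstrap_builder = c("nj", "ml"),
                           bootstrap_replicates = 50, seed = NULL) {
  builder <- match.arg(builder)
  bootstrap_builder <- match.arg(bootstrap_builder)
  n_genes <- length(gene_alignments)
  taxa <- sort(unique(unlist(lapply(gene_alignments, function(g) names(g$aa)))))
  if (any(N_grid > n_genes)) stop("N_grid values exceed the number of genes")
  if (!setequal(reference$tip.label, taxa))
    stop("reference topology must cover the same taxa as the gene pool")
  local_seed(seed, {
    rows <- list()
    for (N in N_grid) {
      for (slot in seq_len(trees_per_N)) {
        attempt <- 0L
        accepted <- NULL
        while (attempt < max_attempts_per_slot) {
          attempt <- attempt + 1L
          pick <- sample.int(n_genes, N)
          sm <- concatenate_alignments(gene_alignments[pick], taxa)
          tr <- build_replicate_tree(sm$nt, builder)
          if (rf_distance(tr, reference) == 0L) {
            accepted <- list(tree = tr, nt = sm$nt)
            break
          }
        }
        censored <- is.null(accepted)
        supports <- numeric(0)
        if (!censored && bootstrap_replicates > 0) {
          bs <- bootstrap_support(accepted$nt, builder = bootstrap_builder,
                                  n_replicates = bootstrap_replicates,
                                  fit = if (bootstrap_builder == "ml")
                                    attr(accepted$tree, "fit") else NULL,
                                  seed = sample.int(1e8, 1))
          supports <- bs$support$support
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          N = N, slot = slot,
          repeats = if (censored) max_attempts_per_slot else attempt,
          censored = censored,
          mean_support = if (length(supports)) mean(supports) else NA_real_,
          supports = list(supports))
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("jackknife_table", class(out))
    out
  })
}

build_replicate_tree <- function(nt, builder) {
  if (builder == "nj") return(nj_builder(nt))
  fit <- ml_search(nt, gamma = builder == "ml",
                   optimize_model = builder == "ml", rearrangement = "NNI")
  tr <- fit$tree
  attr(tr, "fit") <- fit
  tr
}

#' Summarise a jackknife table per N
#'
#' @param jk A `jackknife_table` from [gene_jackknife()].
#' @return Tibble: `N`, `mean_repeats`, `mean_support`, `n_censored`.
#' @export
jackknife_summary <- function(jk) {
  dplyr::summarise(dplyr::group_by(jk, .data$N),
                   mean_repeats = mean(.data$repeats),
                   mean_support = mean(.data$mean_support, na.rm = TRUE),
                   n_censored = sum(.data$censored), .groups = "drop")
}

#' Count gene trees matching a reference topology
#'
#' How many individual gene trees have exactly the reference (unrooted)
#' topology -- typically a minority even when the concatenated tree is
#' identical to the reference and fully supported.
#'
#' @param gene_trees List of `phylo` objects (may be named by gene).
#' @param reference Reference topology covering the shared leaf set.
#' @return List with `matching` (count of RF-0 trees), `total` (comparable
#'   trees), `excluded` (names/indices of trees whose leaf set differs) and
#'   `rf` (tibble of per-gene RF distances).
#' @export
count_matching_gene_trees <- function(gene_trees, reference) {
  nm <- names(gene_trees) %||% as.character(seq_along(gene_trees))
  comparable <- vapply(gene_trees, function(t)
    setequal(t$tip.label, reference$tip.label), logical(1))
  rf <- vapply(gene_trees[comparable], function(t)
    rf_distance(t, reference), integer(1))
  list(matching = sum(rf == 0L), total = sum(comparable),
       excluded = nm[!comparable],
       rf = tibble::tibble(gene = nm[comparable], rf = unname(rf)))
}
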
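#' Simulate gene families inside a species tree
#'
#' Evolves each family as a single gene copy entering at the species-tree
#' root and undergoing a linear birth-death process of gene duplication and
#' loss along the species branches; at every speciation node each surviving
#' copy is inherited by both daughter lineages.  Duplication nodes are
#' labelled `D`, speciation nodes `S`.  A family is single-copy when every
#' taxon carries exactly one surviving gene -- the ground truth against which
#' ortholog detection is scored.
#'
#' @param tree Ultrametric species tree (`phylo`), e.g. from
#'   [simulate_species_tree()].
#' @param n_families Number of independent families to simulate.
#' @param dup_rate,loss_rate Duplication / loss rates per gene lineage per
#'   unit time (>= 0).
#' @param seed Integer seed.
#' @return A tibble with one row per family: `family_id`, `n_genes`,
#'   `single_copy` (flag), `counts` (list of per-taxon gene counts),
#'   `gene_tree` (list of `phylo` or `NULL` for < 2 genes) and `rec`
#'   (list; internal recursive form consumed by [simulate_codon_sequences()]).
#' @examples
#' sp <- simulate_species_tree(6, seed = 1)
#' fam <- simulate_gene_families(sp, 10, dup_rate = 0, loss_rate = 0, seed = 2)
#' all(fam$single_copy)
#' @export
simulate_gene_families <- function(tree, n_families, dup_rate = 5e-4,
                                   loss_rate = 1.5e-4, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  taxa <- tree$tip.label
  sp_rec <- phylo_to_rec(tree)
  local_seed(seed, {
    fams <- lapply(seq_len(n_families), function(i) {
      rec <- prune_rec(sim_family_rec(sp_rec, sp_rec$age, dup_rate, loss_rate))
      rec <- label_gene_copies(rec)
      labs <- collect_tip_labels(rec)
      cnt <- table(factor(sub("\\|.*$", "", labs), levels = taxa))
      counts <- as.integer(cnt); names(counts) <- taxa
      tibble::tibble(
        family_id = sprintf("F%04d", i),
        n_genes = length(labs),
        single_copy = all(counts == 1L),
        counts = list(counts),
        gene_tree = list(if (count_tips(rec) >= 2) rec_to_phylo(rec) else NULL),
        rec = list(rec)
      )
    })
    dplyr::bind_rows(fams)
  })
}

# One gene lineage running down the species branch that leads to `sp_node`,
# entering at age t_in.  Returns a rec node or NULL (lost).
sim_family_rec <- function(sp_node, t_in, dup_rate, loss_rate) {
  rate <- dup_rate + loss_rate
  t <- t_in
  repeat {
    wait <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (t - wait <= sp_node$age) break
    t <- t - wait
    if (stats::runif(1) < loss_rate / rate) return(NULL)      # loss
    # duplication: two independent continuations from age t
    left  <- sim_family_rec(sp_node, t, dup_rate, loss_rate)
    right <- sim_family_rec(sp_node, t, dup_rate, loss_rate)
    if (is.null(left)) return(right)
    if (is.null(right)) return(left)
    return(list(label = "", age = t, dup = TRUE, children = list(left, right)))
  }
  if (is.null(sp_node$children)) {                            # reached a taxon
    return(list(label = sp_node$label, age = 0, dup = FALSE, children = NULL))
  }
  kids <- Filter(Negate(is.null), lapply(sp_node$children, function(d)
    sim_family_rec(d, sp_node$age, dup_rate, loss_rate)))
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  list(label = "", age = sp_node$age, dup = FALSE, children = kids)
}

# rename tips "<taxon>" -> "<taxon>|g<k>" with k counting copies per taxon
label_gene_copies <- function(rec) {
  if (is.null(rec)) return(NULL)
  counter <- new.env(parent = emptyenv())
  walk <- function(nd) {
    if (is.null(nd$children)) {
      k <- (get0(nd$label, envir = counter, ifnotfound = 0L)) + 1L
      assign(nd$label, k, envir = counter)
      nd$label <- sprintf("%s|g%d", nd$label, k)
      return(nd)
    }
    nd$children <- lapply(nd$children, walk)
    nd
  }
  walk(rec)
}
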
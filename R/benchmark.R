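#' Simulate a full synthetic phylogenomics benchmark
#'
#' Chains the generators into the standard validation data set: a dated
#' species tree, gene families with duplication/loss, and codon sequences
#' per family, with gene ids qualified as `"<taxon>|<family>|g<copy>"`.
#' This is the ground-truth bundle against which ortholog recovery, topology
#' recovery and the stability protocol are scored.
#'
#' @param n_taxa Number of taxa (default 15).
#' @param n_families Number of gene families (default 300).
#' @param n_codons Codons per gene (default 200).
#' @param dup_rate,loss_rate Gene duplication/loss rates per lineage per
#'   unit time (defaults 5e-4 / 1.5e-4, giving roughly a third multi-copy
#'   or incomplete families on a 100-unit-deep 15-taxon tree).
#' @param root_age Species-tree root age (default 100).
#' @param rate Substitution rate, substitutions/site/time (default 0.002).
#' @param rate_sdlog Lognormal spread of per-gene rate multipliers
#'   (default 0.3).
#' @param model A [codon_model()].
#' @param species_tree Optional fixed species tree (`phylo`), e.g.
#'   [benchmark_species_tree()]; overrides `n_taxa`/`root_age`.
#' @param seed Integer seed.
#' @return List with `species_tree`, `families` (tibble from
#'   [simulate_gene_families()] plus list-columns `cds` and `alignment`),
#'   `cds` (named vector over all genes), `proteins` (their translations)
#'   and `single_copy_ids` (character vector of truly single-copy families).
#' @export
simulate_benchmark <- function(n_taxa = 15, n_families = 300, n_codons = 200,
                               dup_rate = 5e-4, loss_rate = 1.5e-4,
                               root_age = 100, rate = 0.002, rate_sdlog = 0.3,
                               model = codon_model(), species_tree = NULL,
                               seed = 1) {
  sp <- species_tree %||% simulate_species_tree(n_taxa, root_age = root_age,
                                                seed = child_seed(seed, 1))
  fam <- simulate_gene_families(sp, n_families, dup_rate, loss_rate,
                                seed = child_seed(seed, 2))
  mults <- local_seed(child_seed(seed, 3),
                      stats::rlnorm(n_families, 0, rate_sdlog))
  cds_all <- character(0)
  fam$cds <- vector("list", nrow(fam))
  fam$alignment <- vector("list", nrow(fam))
  for (i in seq_len(nrow(fam))) {
    rec <- fam$rec[[i]]
    if (is.null(rec) || fam$n_genes[i] == 0) next
    sim <- simulate_codon_sequences(rec, n_codons, model, rate = rate,
                                    rate_multiplier = mults[i],
                                    seed = child_seed(seed, 100 + i))
    qualify <- function(nms) vapply(strsplit(nms, "|", fixed = TRUE),
      function(p) sprintf("%s|%s|%s", p[1], fam$family_id[i], p[2]),
      character(1))
    names(sim$cds) <- qualify(names(sim$cds))
    names(sim$alignment) <- qualify(names(sim$alignment))
    fam$cds[[i]] <- sim$cds
    fam$alignment[[i]] <- sim$alignment
    cds_all <- c(cds_all, sim$cds)
  }
  list(species_tree = sp, families = fam, cds = cds_all,
       proteins = translate_cds(cds_all),
       single_copy_ids = fam$family_id[fam$single_copy])
}

#' Fixed benchmark species tree
#'
#' A fixed, dated, ultrametric 15-taxon species tree used by the validation
#' benchmarks: root at 90 Ma (a grape-family-like depth), five major clades,
#' most internal edges 10 Ma or longer, plus two short (1.5 Ma) internal
#' edges mimicking a rapid radiation -- the part of the backbone that needs
#' tens of genes to resolve.  Using a fixed tree makes the topology-recovery and
#' stability benchmarks reproducible and independent of the vagaries of
#' random tree shapes, whose arbitrarily short internal edges no method
#' could resolve.
#'
#' @return An ultrametric `phylo` with tips `T01`..`T15`.
#' @examples
#' max(node_ages(benchmark_species_tree()))  # 90
#' @export
benchmark_species_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((T01:10,T02:10):10,T03:20):20,((T04:8,T05:8):17,",
    "(T06:23.5,T07:23.5):1.5):15):30,(((T08:15,T09:15):15,T10:30):25,",
    "((T11:33.5,T12:33.5):1.5,T13:35):20):15):20,(T14:45,T15:45):45);"))
}

#' Simulate the topology-stability gene pool
#'
#' The gene pool used by the gene-jackknife benchmark: `n_genes` genes of
#' `n_codons` codons, a fraction of which evolve on NNI-perturbed copies of
#' the species tree (gene-tree discordance of the kind incomplete lineage
#' sorting produces around short internal edges) while the rest follow the
#' species tree.  Gene lengths are kept short so that small gene subsamples
#' genuinely risk missing the short backbone edges -- the regime the
#' repeats-until-match statistic is designed to expose.
#'
#' @param n_genes Pool size (default 70).
#' @param n_codons Codons per gene (default 100).
#' @param frac_discordant Fraction of genes on perturbed topologies
#'   (default 0.4).
#' @param nni_moves NNI moves applied to each discordant gene's tree
#'   (default 2).
#' @param rate Substitution rate, subs/site/Ma (default 0.002).
#' @param species_tree Dated species tree (default
#'   [benchmark_species_tree()]).
#' @param model A [codon_model()].
#' @param seed Integer seed.
#' @return List with `genes` (list of [gene_alignment()]), `gene_trees`
#'   (list of `phylo` the genes actually evolved on), `discordant`
#'   (logical vector) and `species_tree`.
#' @export
simulate_stability_pool <- function(n_genes = 70, n_codons = 100,
                                    frac_discordant = 0.4, nni_moves = 2,
                                    rate = 0.002,
                                    species_tree = benchmark_species_tree(),
                                    model = codon_model(), seed = 1) {
  n_noisy <- round(n_genes * frac_discordant)
  genes <- vector("list", n_genes)
  gene_trees <- vector("list", n_genes)
  discordant <- seq_len(n_genes) <= n_noisy
  for (i in seq_len(n_genes)) {
    tr <- if (discordant[i])
      perturb_tree_nni(species_tree, n_moves = nni_moves,
                       seed = child_seed(seed, i))
    else species_tree
    sim <- simulate_codon_sequences(tr, n_codons, model, rate = rate,
                                    seed = child_seed(seed, 1000 + i))
    gid <- sprintf("G%03d", i)
    names(sim$cds) <- paste0(names(sim$cds), "|", gid)
    genes[[i]] <- align_family(sim$cds, gid)
    gene_trees[[i]] <- tr
  }
  names(genes) <- names(gene_trees) <-
    sprintf("G%03d", seq_len(n_genes))
  list(genes = genes, gene_trees = gene_trees, discordant = discordant,
       species_tree = species_tree)
}
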
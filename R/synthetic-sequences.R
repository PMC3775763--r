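#' Simulate codon sequences along a gene tree
#'
#' Evolves in-frame coding sequence along a dated gene tree under the
#' stop-free mutation-level codon model of [codon_model()].  The root
#' sequence is drawn from the stationary distribution (no stop codons, so
#' translation is always defined), and substitutions are applied branch by
#' branch via exact transition matrices.  Branch lengths in expected
#' nucleotide substitutions per site are `time * rate * rate_multiplier`.
#'
#' An optional whole-genome duplication (`wgd = list(age =, retained_fraction =)`)
#' duplicates every lineage alive at the stated age; each extra copy is
#' retained with the given probability and carries an independently evolved
#' copy of the subtree below, its tips suffixed `.w`.  An optional codon-level
#' deletion process (`indel_rate`, geometric lengths with mean
#' `mean_indel_codons`) removes codons from descendants while the true
#' alignment keeps their columns as gaps.
#'
#' @param gene_tree A dated gene tree: a `phylo` (time-scaled, e.g. from
#'   [simulate_gene_families()]), or the `rec` form stored by that function.
#' @param n_codons Number of codons (>= 1).
#' @param model A [codon_model()].
#' @param rate Substitution rate in expected nucleotide substitutions per
#'   site per unit time (default `0.002`, i.e. 2 substitutions/site per 1000
#'   time units -- a plant-nuclear-gene-like rate when time is in Ma).
#' @param rate_multiplier Per-gene rate scaling factor.
#' @param wgd Optional `list(age =, retained_fraction =)`.
#' @param indel_rate Deletion events per codon per unit time (default 0).
#' @param mean_indel_codons Mean deletion length in codons.
#' @param seed Integer seed.
#' @return A list with `cds` (named character vector of unaligned coding
#'   sequences), `alignment` (named character vector, gapped, equal width
#'   `3 * n_codons`), and `tree` (the possibly WGD-expanded `phylo`, or
#'   `NULL` when fewer than two genes exist).
#' @export
simulate_codon_sequences <- function(gene_tree, n_codons, model = codon_model(),
                                     rate = 0.002, rate_multiplier = 1,
                                     wgd = NULL, indel_rate = 0,
                                     mean_indel_codons = 3, seed = NULL) {
  if (n_codons < 1) stop("n_codons must be >= 1")
  stopifnot(inherits(model, "codon_model"))
  rec <- if (inherits(gene_tree, "phylo")) phylo_to_rec(gene_tree) else gene_tree
  if (is.null(rec)) stop("empty gene tree")
  local_seed(seed, {
    if (!is.null(wgd)) {
      if (is.null(wgd$age) || is.null(wgd$retained_fraction))
        stop("wgd needs fields age and retained_fraction")
      rec <- insert_wgd(rec, wgd$age, wgd$retained_fraction)
    }
    states0 <- sample.int(length(model$codons), n_codons, replace = TRUE,
                          prob = model$pi)
    out <- new.env(parent = emptyenv())
    evolve <- function(nd, states, t_parent) {
      b <- (t_parent - nd$age) * rate * rate_multiplier
      if (b > 0) {
        P <- codon_transition(model, b)
        cumP <- t(apply(P, 1L, cumsum))
        alive <- which(!is.na(states))
        u <- stats::runif(length(alive))
        # inverse-CDF draw, vectorised across sites
        states[alive] <- rowSums(u > cumP[states[alive], , drop = FALSE]) + 1L
      }
      if (indel_rate > 0) {
        n_ev <- stats::rpois(1, indel_rate * max(t_parent - nd$age, 0) * n_codons)
        for (k in seq_len(n_ev)) {
          len <- stats::rgeom(1, 1 / mean_indel_codons) + 1L
          start <- sample.int(n_codons, 1)
          states[start:min(n_codons, start + len - 1L)] <- NA_integer_
        }
      }
      if (is.null(nd$children)) {
        assign(nd$label, states, envir = out)
      } else {
        for (ch in nd$children) evolve(ch, states, nd$age)
      }
    }
    evolve(rec, states0, rec$age)
    labs <- collect_tip_labels(rec)
    aln <- vapply(labs, function(l) {
      st <- get(l, envir = out)
      cods <- ifelse(is.na(st), "---", model$codons[st])
      paste0(cods, collapse = "")
    }, character(1))
    cds <- gsub("-", "", aln, fixed = TRUE)
    list(cds = cds, alignment = aln,
         tree = if (count_tips(rec) >= 2) rec_to_phylo(rec) else NULL)
  })
}

# Duplicate every lineage crossing `age`; each new copy (an independent
# replica of the subtree below the crossing point) is kept with probability
# `retained`; its tips get a ".w" suffix.
insert_wgd <- function(rec, age, retained) {
  if (age >= rec$age) {
    # duplication above the root: duplicate the whole tree
    if (stats::runif(1) < retained) {
      copy <- suffix_tips(rec, ".w")
      return(list(label = "", age = age, dup = TRUE, children = list(rec, copy)))
    }
    return(rec)
  }
  walk <- function(nd) {
    if (is.null(nd$children)) return(nd)
    nd$children <- lapply(nd$children, function(ch) {
      ch <- walk(ch)
      if (ch$age < age && age < nd$age) {
        if (stats::runif(1) < retained) {
          copy <- suffix_tips(ch, ".w")
          return(list(label = "", age = age, dup = TRUE,
                      children = list(ch, copy)))
        }
      }
      ch
    })
    nd
  }
  walk(rec)
}

suffix_tips <- function(rec, suf) {
  if (is.null(rec$children)) { rec$label <- paste0(rec$label, suf); return(rec) }
  rec$children <- lapply(rec$children, suffix_tips, suf = suf)
  rec
}
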
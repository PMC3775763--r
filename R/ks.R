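# Nei-Gojobori (1986) synonymous/nonsynonymous divergence.

GENETIC_CODE_TBL <- local({
  gc <- Biostrings::GENETIC_CODE
  gc
})

codon_aa <- function(codon) unname(GENETIC_CODE_TBL[codon])

# per-codon synonymous site count: for each position the fraction of the
# three single-nucleotide changes that are synonymous; changes to stop codons
# count as nonsynonymous (sites renormalised to 3 per codon)
ng_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa <- codon_aa(codon)
  if (is.na(aa) || aa == "*") return(c(S = 0, N = 0))
  s <- 0; n <- 0
  for (p in 1:3) {
    for (b in setdiff(nts, substr(codon, p, p))) {
      alt <- codon
      substr(alt, p, p) <- b
      alt_aa <- codon_aa(alt)
      if (!is.na(alt_aa) && alt_aa == aa && alt_aa != "*") s <- s + 1
      else n <- n + 1
    }
  }
  tot <- s + n
  c(S = 3 * s / tot, N = 3 * n / tot)
}

# synonymous/nonsynonymous differences between two codons, averaged over
# equally weighted mutational pathways; pathways through stop codons are
# excluded (falling back to all pathways if every one is blocked)
ng_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(Sd = 0, Nd = 0))
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  perms <- if (length(pos) == 1L) list(pos) else
    if (length(pos) == 2L) list(pos, rev(pos)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
             function(o) pos[o])
  path_counts <- list()
  for (perm in perms) {
    cur <- c1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in perm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- codon_aa(cur); a2 <- codon_aa(nxt)
      if (is.na(a2) || a2 == "*") blocked <- TRUE
      if (!is.na(a1) && !is.na(a2) && a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1L]] <-
      list(sd = sd, nd = nd, blocked = blocked)
  }
  open <- Filter(function(x) !x$blocked, path_counts)
  use <- if (length(open)) open else path_counts
  c(Sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    Nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

#' Synonymous and nonsynonymous divergence of a CDS pair
#'
#' Nei-Gojobori estimator: synonymous (S) and nonsynonymous (N) site counts
#' from codon degeneracy averaged over both sequences, difference counts
#' averaged over equally parsimonious substitution pathways (stop-codon
#' pathways excluded), and Jukes-Cantor correction
#' `Ks = -3/4 log(1 - 4/3 * Sd/S)`.  Pairs with `Sd/S >= 3/4` are saturated
#' and flagged.  Codon pairs containing gaps or ambiguities are dropped.
#' When the two CDS differ in length they are first aligned through their
#' protein translations and back-translated.
#'
#' @param cds1,cds2 Coding sequences (lengths divisible by 3).
#' @return One-row tibble: `ks`, `ka`, `S`, `N`, `Sd`, `Nd`, `n_codons`,
#'   `saturated` (`ks`/`ka` are `NA` when saturated or undefined).
#' @export
ks_pair <- function(cds1, cds2) {
  if (nchar(cds1[[1L]]) %% 3L || nchar(cds2[[1L]]) %% 3L)
    stop("CDS lengths must be divisible by 3")
  s1 <- unname(cds1[[1L]]); s2 <- unname(cds2[[1L]])
  if (nchar(s1) != nchar(s2)) {
    p <- progressive_align(c(a = translate_cds(c(x = s1))[[1L]],
                             b = translate_cds(c(x = s2))[[1L]]))
    n1 <- backtranslate(p["a"], c(a = s1))
    n2 <- backtranslate(p["b"], c(b = s2))
    s1 <- n1[[1L]]; s2 <- n2[[1L]]
  }
  cods1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  cods2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  ok <- grepl("^[ACGT]{3}$", cods1) & grepl("^[ACGT]{3}$", cods2) &
    codon_aa(cods1) != "*" & codon_aa(cods2) != "*"
  cods1 <- cods1[ok]; cods2 <- cods2[ok]
  if (length(cods1) == 0)
    return(tibble::tibble(ks = NA_real_, ka = NA_real_, S = 0, N = 0,
                          Sd = 0, Nd = 0, n_codons = 0L, saturated = FALSE))
  sites1 <- colSums(do.call(rbind, lapply(cods1, ng_sites)))
  sites2 <- colSums(do.call(rbind, lapply(cods2, ng_sites)))
  S <- (sites1[["S"]] + sites2[["S"]]) / 2
  N <- (sites1[["N"]] + sites2[["N"]]) / 2
  d <- colSums(do.call(rbind, Map(ng_diffs, cods1, cods2)))
  Sd <- d[["Sd"]]; Nd <- d[["Nd"]]
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  saturated <- is.na(pS) || pS >= 3 / 4
  ks <- if (!saturated && !is.na(pS)) -3 / 4 * log(1 - 4 / 3 * pS) else NA_real_
  ka <- if (!is.na(pN) && pN < 3 / 4) -3 / 4 * log(1 - 4 / 3 * pN) else NA_real_
  tibble::tibble(ks = ks, ka = ka, S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codons = length(cods1), saturated = saturated)
}

#' Per-taxon Ks distributions of paralog pairs
#'
#' Computes Nei-Gojobori Ks for every within-taxon paralog pair implied by
#' the gene families (families with >= 2 genes in a taxon) and bins the
#' values per taxon.  A secondary concentration of Ks values (a "peak") is
#' the classic footprint of an ancient whole-genome duplication shared by
#' the sampled paralogs.
#'
#' @param cds Named character vector of all coding sequences (gene ids of
#'   the form `taxon|...`).
#' @param families Family tibble ([cluster_families()]) or a list of
#'   character vectors of gene ids.
#' @param bin_width Histogram bin width in Ks units (default 0.05).
#' @param max_ks Values above this (or saturated pairs) are excluded from
#'   the histogram (default 3).
#' @return List with `pairs` (tibble: `taxon`, `gene1`, `gene2`, `ks`,
#'   `ka`, `saturated`) and `histogram` (tibble: `taxon`, `bin_lo`,
#'   `bin_hi`, `count`).
#' @export
ks_distribution <- function(cds, families, bin_width = 0.05, max_ks = 3) {
  fam_members <- if (is.data.frame(families)) families$members else families
  rows <- list()
  for (mem in fam_members) {
    taxa <- sub("\\|.*$", "", mem)
    for (tx in unique(taxa[duplicated(taxa)])) {
      genes <- mem[taxa == tx]
      prs <- utils::combn(genes, 2L)
      for (c_i in seq_len(ncol(prs))) {
        g1 <- prs[1L, c_i]; g2 <- prs[2L, c_i]
        if (!g1 %in% names(cds) || !g2 %in% names(cds)) next
        kp <- ks_pair(cds[g1], cds[g2])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          taxon = tx, gene1 = g1, gene2 = g2,
          ks = kp$ks, ka = kp$ka, saturated = kp$saturated)
      }
    }
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(taxon = character(0), gene1 = character(0),
                   gene2 = character(0), ks = numeric(0), ka = numeric(0),
                   saturated = logical(0))
  usable <- pairs[!is.na(pairs$ks) & !pairs$saturated & pairs$ks <= max_ks, ]
  breaks <- seq(0, max_ks, by = bin_width)
  hist_tbl <- if (nrow(usable)) {
    dplyr::bind_rows(lapply(split(usable, usable$taxon), function(df) {
      ct <- table(cut(df$ks, breaks, include.lowest = TRUE, right = FALSE))
      tibble::tibble(taxon = df$taxon[1L],
                     bin_lo = breaks[-length(breaks)],
                     bin_hi = breaks[-1L],
                     count = as.integer(ct))
    }))
  } else tibble::tibble(taxon = character(0), bin_lo = numeric(0),
                        bin_hi = numeric(0), count = integer(0))
  list(pairs = pairs, histogram = hist_tbl)
}

#' Expected synonymous divergence per unit branch length
#'
#' For a [codon_model()], the expected number of synonymous substitutions
#' per synonymous site accumulated per unit branch length (branch lengths
#' being expected nucleotide substitutions per site): the stationary
#' synonymous substitution flux divided by the stationary Nei-Gojobori
#' synonymous site fraction.  Multiplying by the total path length between
#' two sequences gives the model-true dS that [ks_pair()] estimates.
#'
#' @param model A [codon_model()].
#' @return Numeric scalar (dS per unit branch length).
#' @export
codon_ds_per_unit <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  codons <- model$codons
  aa <- codon_aa(codons)
  flux_s <- 0
  for (i in seq_along(codons)) {
    syn <- aa == aa[i]
    syn[i] <- FALSE
    flux_s <- flux_s + model$pi[i] * sum(model$Q[i, syn])
  }
  sbar <- sum(model$pi * vapply(codons, function(cd) ng_sites(cd)[["S"]],
                                numeric(1)))
  # Q carries 3 expected substitutions per codon per unit branch length, so
  # flux_s is already per codon per unit branch length
  unname(flux_s / sbar)
}
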
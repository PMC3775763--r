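#' Neighbor-joining tree
#'
#' Standard NJ agglomeration on a symmetric distance matrix, with any
#' negative branch length clamped to zero and the deficit shifted to the
#' sister edge so path lengths are preserved as far as possible.
#'
#' @param D Symmetric distance matrix (zero diagonal, `n >= 3`) or `dist`.
#' @return Unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(as.dist(D))
  clamp_negative_edges(tr)
}

clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1L]
    p <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == p), e)
    if (length(sisters)) {
      s <- sisters[1L]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

# ---------------------------------------------------------------------------
# Fitch parsimony

MISSING_CHARS <- c("-", "?", "N", "X")

#' Fitch parsimony score
#'
#' Minimum number of unordered state changes over the tree, summed across
#' sites (Fitch's bottom-up pass on bitmask state sets).  Gaps and other
#' missing symbols (`- ? N X`) are wildcards compatible with every state.
#'
#' @param tree `phylo` whose tip labels match the alignment names.
#' @param alignment Named character vector of equal-width sequences.
#' @return Integer change count.
#' @export
fitch_score <- function(tree, alignment) {
  if (is.null(tree$tip.label) || ape::Ntip(tree) < 2)
    stop("tree has no tip labels")
  extra <- setdiff(tree$tip.label, names(alignment))
  miss <- setdiff(names(alignment), tree$tip.label)
  if (length(extra) || length(miss))
    stop("tree/alignment leaf mismatch; tree-only: ",
         paste(extra, collapse = ","), " alignment-only: ",
         paste(miss, collapse = ","))
  m <- aln_to_matrix(alignment[tree$tip.label])
  alphabet <- sort(setdiff(unique(as.vector(m)), MISSING_CHARS))
  full <- bitwShiftL(1L, length(alphabet)) - 1L
  code <- stats::setNames(bitwShiftL(1L, seq_along(alphabet) - 1L), alphabet)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  npat <- ncol(m)
  masks <- matrix(0L, npat, nnode)
  for (i in seq_len(ntip)) {
    v <- code[m[i, ]]
    v[is.na(v)] <- full
    masks[, i] <- v
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  score <- integer(npat)
  seen <- integer(nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    if (seen[p] == 0L) {
      masks[, p] <- masks[, ch]
    } else {
      inter <- bitwAnd(masks[, p], masks[, ch])
      un <- bitwOr(masks[, p], masks[, ch])
      empty <- inter == 0L
      score <- score + as.integer(empty)
      masks[, p] <- ifelse(empty, un, inter)
    }
    seen[p] <- seen[p] + 1L
  }
  sum(score)
}

#' Heuristic maximum-parsimony search
#'
#' Random stepwise-addition starting trees followed by branch-swapping hill
#' climbing under the Fitch criterion; all distinct equally-best topologies
#' encountered are retained.  `swap = "nni"` scans all nearest-neighbor
#' interchanges; `"spr"`/`"tbr"` add rounds of subtree pruning-regrafting
#' proposals (the TBR variant restarts SPR from the improved tree and is a
#' documented simplification of full tree-bisection-reconnection, adequate
#' at the tree sizes this package targets).
#'
#' @param alignment Named character vector of equal-width sequences
#'   (>= 4 taxa).
#' @param n_random_additions Number of random-addition starting trees.
#' @param swap `"nni"`, `"spr"` or `"tbr"`.
#' @param max_rounds Cap on swap rounds per start.
#' @param seed Integer seed.
#' @return List with `trees` (multiPhylo of equally-best topologies) and
#'   `score` (their shared Fitch score).
#' @export
mp_search <- function(alignment, n_random_additions = 10,
                      swap = c("nni", "spr", "tbr"), max_rounds = 50,
                      seed = NULL) {
  swap <- match.arg(swap)
  taxa <- names(alignment)
  if (length(taxa) < 4) stop("need at least 4 taxa")
  local_seed(seed, {
    best_trees <- list()
    best_score <- Inf
    for (rep in seq_len(n_random_additions)) {
      tr <- stepwise_addition(alignment, sample(taxa))
      sc <- fitch_score(tr, alignment)
      res <- swap_hill_climb(tr, sc, alignment, swap, max_rounds)
      if (res$score < best_score) {
        best_score <- res$score
        best_trees <- res$trees
      } else if (res$score == best_score) {
        best_trees <- c(best_trees, res$trees)
      }
    }
    best_trees <- unique_topologies(best_trees)
    list(trees = structure(best_trees, class = "multiPhylo"),
         score = best_score)
  })
}

stepwise_addition <- function(alignment, order_taxa) {
  tr <- ape::unroot(ape::read.tree(
    text = sprintf("(%s,%s,%s);", order_taxa[1], order_taxa[2], order_taxa[3])))
  tr$edge.length <- rep(1, nrow(tr$edge))
  for (tx in order_taxa[-(1:3)]) {
    cand <- lapply(seq_len(nrow(tr$edge)), function(e)
      phytools::bind.tip(tr, tx, edge.length = 1, where = tr$edge[e, 2L],
                         position = tr$edge.length[e] / 2))
    sub <- alignment[c(tr$tip.label, tx)]
    scores <- vapply(cand, function(ct) fitch_score(ct, sub), numeric(1))
    tr <- cand[[which.min(scores)]]
  }
  tr
}

swap_hill_climb <- function(tr, sc, alignment, swap, max_rounds) {
  equal_best <- list(tr)
  for (round in seq_len(max_rounds)) {
    improved <- FALSE
    # nni() returns a compressed multiPhylo (shared TipLabel attribute);
    # uncompress so every tree carries its own labels
    neigh <- as.list(ape::.uncompressTipLabel(phangorn::nni(tr)))
    if (swap %in% c("spr", "tbr")) {
      extra <- lapply(seq_len(20L), function(i) phangorn::rSPR(tr, moves = 1))
      neigh <- c(neigh, extra)
    }
    scores <- vapply(neigh, function(nt) fitch_score(nt, alignment), numeric(1))
    jbest <- which.min(scores)
    if (scores[jbest] < sc) {
      sc <- scores[jbest]
      tr <- neigh[[jbest]]
      equal_best <- list(tr)
      improved <- TRUE
    } else {
      ties <- which(scores == sc)
      if (length(ties)) equal_best <- c(equal_best, neigh[ties])
    }
    if (!improved) break
  }
  list(trees = unique_topologies(equal_best), score = sc)
}

unique_topologies <- function(trees) {
  if (length(trees) <= 1) return(trees)
  keys <- vapply(trees, function(t) paste(sort(split_keys(t)), collapse = ";"),
                 character(1))
  trees[!duplicated(keys)]
}

# ---------------------------------------------------------------------------
# GTR + Gamma likelihood

#' GTR substitution model
#'
#' @param exch Six exchangeabilities (`AC`, `AG`, `AT`, `CG`, `CT`, `GT`).
#' @param base_freq Base frequencies summing to 1.
#' @param gamma_shape Discrete-Gamma shape (`NULL` = rate homogeneity).
#' @param n_cat Number of Gamma rate categories (default 4).
#' @return A `gtr_model` with the normalised rate matrix (mean rate 1) and
#'   its eigendecomposition.
#' @export
gtr_model <- function(exch = c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1),
                      base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      gamma_shape = NULL, n_cat = 4L) {
  nts <- c("A", "C", "G", "T")
  exch <- exch[c("AC", "AG", "AT", "CG", "CT", "GT")]
  base_freq <- base_freq[nts]
  if (anyNA(exch) || any(exch <= 0)) stop("invalid exchangeabilities")
  if (anyNA(base_freq) || abs(sum(base_freq) - 1) > 1e-9 || any(base_freq <= 0))
    stop("base frequencies must be positive and sum to 1")
  Q <- matrix(0, 4, 4, dimnames = list(nts, nts))
  Q["A", "C"] <- Q["C", "A"] <- exch[["AC"]]
  Q["A", "G"] <- Q["G", "A"] <- exch[["AG"]]
  Q["A", "T"] <- Q["T", "A"] <- exch[["AT"]]
  Q["C", "G"] <- Q["G", "C"] <- exch[["CG"]]
  Q["C", "T"] <- Q["T", "C"] <- exch[["CT"]]
  Q["G", "T"] <- Q["T", "G"] <- exch[["GT"]]
  Q <- Q * rep(base_freq, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(base_freq * diag(Q))
  Q <- Q / mu
  sp <- sqrt(base_freq)
  B <- (Q * sp) / rep(sp, each = 4)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  rates <- if (is.null(gamma_shape)) 1 else
    phangorn::discrete.gamma(gamma_shape, n_cat)
  structure(list(exch = exch, base_freq = base_freq, gamma_shape = gamma_shape,
                 n_cat = if (is.null(gamma_shape)) 1L else as.integer(n_cat),
                 rates = rates, Q = Q,
                 eig_values = eig$values, eig_left = eig$vectors / sp,
                 eig_right = t(eig$vectors * sp)), class = "gtr_model")
}

gtr_transition <- function(model, t) {
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 1e-300] <- 1e-300
  P
}

IUPAC_ROWS <- local({
  nts <- c("A", "C", "G", "T")
  amb <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = nts, `-` = nts, `?` = nts, X = nts)
  out <- t(vapply(amb, function(s) as.numeric(nts %in% s), numeric(4)))
  colnames(out) <- nts
  out
})

#' GTR(+Gamma) log-likelihood by the pruning algorithm
#'
#' Felsenstein's pruning over the tree, with a discrete-Gamma rate mixture
#' when the model carries a shape parameter.  Gaps and IUPAC ambiguities
#' enter as partial likelihood 1 over their compatible states.
#'
#' @param tree `phylo` with branch lengths (substitutions/site).
#' @param alignment Named character vector of equal-width nucleotide
#'   sequences covering the tree's tips.
#' @param model A [gtr_model()].
#' @return Log-likelihood (numeric scalar).
#' @export
gtr_loglik <- function(tree, alignment, model = gtr_model()) {
  stopifnot(inherits(model, "gtr_model"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!all(tree$tip.label %in% names(alignment)))
    stop("alignment does not cover all tips")
  m <- aln_to_matrix(alignment[tree$tip.label])
  pat <- compress_patterns(m)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  tipL <- lapply(seq_len(ntip), function(i) {
    rows <- IUPAC_ROWS[match(pat$m[i, ], rownames(IUPAC_ROWS)), , drop = FALSE]
    rows[is.na(rows[, 1L]), ] <- 1
    rows
  })
  npat <- ncol(pat$m)
  sitelik <- numeric(npat)
  for (r in model$rates) {
    L <- vector("list", nnode)
    for (i in seq_len(ntip)) L[[i]] <- tipL[[i]]
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      P <- gtr_transition(model, tr$edge.length[e] * r)
      contrib <- L[[ch]] %*% t(P)
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    root <- tr$edge[nrow(tr$edge), 1L]
    sitelik <- sitelik + as.vector(L[[root]] %*% model$base_freq) / length(model$rates)
  }
  sum(pat$w * log(sitelik))
}

compress_patterns <- function(m) {
  key <- apply(m, 2L, paste0, collapse = "")
  tab <- table(key)[unique(key)]
  first <- !duplicated(key)
  list(m = m[, first, drop = FALSE], w = as.numeric(table(key)[key[first]]))
}

# ---------------------------------------------------------------------------
# ML search, bootstrap, topology utilities

aln_to_phyDat <- function(alignment) {
  phangorn::phyDat(aln_to_matrix(alignment), type = "DNA")
}

#' Maximum-likelihood tree search
#'
#' NJ starting tree on ML distances, then joint optimisation of branch
#' lengths, GTR parameters and a 4-category discrete Gamma with
#' nearest-neighbor-interchange rearrangements until no improvement --
#' the deterministic Gamma stand-in for rate-category (CAT-style)
#' approximations.  Backed by phangorn's optimiser.
#'
#' @param alignment Named character vector of nucleotide sequences
#'   (>= 4 taxa).
#' @param gamma Use a 4-category discrete Gamma (default TRUE).
#' @param optimize_model Optimise exchangeabilities/base frequencies
#'   (default TRUE; otherwise Jukes-Cantor).
#' @param rearrangement `"NNI"` (default), `"stochastic"` or `"none"`.
#' @param start Optional starting `phylo`.
#' @param seed Integer seed (stochastic rearrangement only).
#' @return An `ml_fit`: list with `tree` (unrooted, branch lengths),
#'   `loglik`, `model` (fitted [gtr_model()]) and the underlying `pml` fit.
#' @export
ml_search <- function(alignment, gamma = TRUE, optimize_model = TRUE,
                      rearrangement = "NNI", start = NULL, seed = NULL) {
  if (length(alignment) < 4) stop("need at least 4 taxa")
  dat <- aln_to_phyDat(alignment)
  local_seed(seed, {
    tr <- start %||% nj_tree(as.matrix(jc_distance(dat)))
    tr <- ape::unroot(tr)
    tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
    fit <- phangorn::pml(tr, dat, k = if (gamma) 4L else 1L)
    fit <- quiet(phangorn::optim.pml(
      fit, model = if (optimize_model) "GTR" else "JC",
      optGamma = gamma, optBf = optimize_model, optQ = optimize_model,
      optEdge = TRUE, rearrangement = rearrangement,
      control = phangorn::pml.control(trace = 0)))
    model <- gtr_model(
      exch = stats::setNames(fit$Q, c("AC", "AG", "AT", "CG", "CT", "GT")),
      base_freq = stats::setNames(fit$bf, c("A", "C", "G", "T")),
      gamma_shape = if (gamma) fit$shape else NULL, n_cat = 4L)
    structure(list(tree = fit$tree, loglik = fit$logLik, model = model,
                   pml = fit), class = "ml_fit")
  })
}

quiet <- function(expr) {
  out <- NULL
  invisible(utils::capture.output(out <- suppressMessages(expr)))
  out
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("ML tree: %d tips, log-likelihood %.3f\n",
              ape::Ntip(x$tree), x$loglik))
  invisible(x)
}

#' One-row model summary of an ML fit
#'
#' @param x An `ml_fit`.
#' @param ... Unused.
#' @return One-row tibble: `loglik`, `n_tip`, `gamma_shape`, `tree_length`.
#' @importFrom generics glance
#' @export glance
#' @export
#' @method glance ml_fit
glance.ml_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_tip = ape::Ntip(x$tree),
                 gamma_shape = x$model$gamma_shape %||% NA_real_,
                 tree_length = sum(x$tree$edge.length))
}

#' Fast nonparametric bootstrap support
#'
#' Site-resampling bootstrap in the rapid style: every replicate restarts
#' from the full-data tree and is refined with NNI only, model parameters
#' held at their full-data estimates.  Support for each internal edge of the
#' full-data tree is the percentage of replicate trees containing its
#' bipartition.
#'
#' @param alignment Named character vector of nucleotide sequences.
#' @param builder `"ml"` (default), `"mp"` or `"nj"`.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param fit Optional precomputed `ml_fit` for the full data (saves the
#'   initial search).
#' @param seed Integer seed.
#' @return List with `tree` (best full-data tree, node labels = support),
#'   `support` (tibble: one row per internal edge, `split` and `support`),
#'   and `replicates` (multiPhylo).
#' @export
bootstrap_support <- function(alignment, builder = c("ml", "mp", "nj"),
                              n_replicates = 100, fit = NULL, seed = NULL) {
  builder <- match.arg(builder)
  width <- ncol(aln_to_matrix(alignment))
  local_seed(seed, {
    if (builder == "ml") {
      fit <- fit %||% ml_search(alignment)
      best <- fit$tree
    } else if (builder == "nj") {
      best <- nj_builder(alignment)
    } else {
      best <- mp_search(alignment, n_random_additions = 5,
                        seed = sample.int(1e8, 1))$trees[[1L]]
    }
    m <- aln_to_matrix(alignment)
    reps <- vector("list", n_replicates)
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(width, width, replace = TRUE)
      res <- m[, idx, drop = FALSE]
      if (builder == "mp") res <- matrix_to_aln(res)
      reps[[b]] <- switch(builder,
        ml = {
          dat <- aln_to_phyDat(res)
          f <- phangorn::pml(best, dat, k = fit$model$n_cat,
                             shape = fit$model$gamma_shape %||% 1,
                             bf = fit$pml$bf, Q = fit$pml$Q)
          f <- quiet(phangorn::optim.pml(
            f, optEdge = TRUE, rearrangement = "NNI",
            control = phangorn::pml.control(trace = 0)))
          f$tree
        },
        nj = nj_builder(res),
        mp = mp_search(res, n_random_additions = 2,
                       seed = sample.int(1e8, 1))$trees[[1L]])
    }
    reps <- structure(reps, class = "multiPhylo")
    support_tbl <- split_support(best, reps)
    best_lab <- annotate_support(best, support_tbl)
    list(tree = best_lab, support = support_tbl, replicates = reps)
  })
}

# JC-corrected Hamming distances (fast start-tree distances)
jc_distance <- function(dat) {
  p <- phangorn::dist.hamming(dat)
  p[p >= 0.745] <- 0.745          # keep the correction finite
  -3 / 4 * log(1 - 4 / 3 * p)
}

nj_builder <- function(alignment) {
  db <- ape::as.DNAbin(aln_to_matrix(alignment))
  d <- ape::dist.dna(db, model = "JC69", pairwise.deletion = TRUE)
  d[!is.finite(d)] <- max(d[is.finite(d)], 1) * 2
  nj_tree(as.matrix(d))
}

# canonical split keys (internal, non-trivial bipartitions); works on rooted
# and unrooted representations alike (complementary sides canonicalised,
# trivial splits dropped, duplicates removed)
split_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  labs <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (s in pp) {
    side <- sort(tree$tip.label[s])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (!(labs[1L] %in% side)) side <- setdiff(labs, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

split_support <- function(best, replicates) {
  keys <- split_keys(best)
  if (length(keys) == 0)
    return(tibble::tibble(split = character(0), support = numeric(0)))
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (rt in replicates) {
    rk <- split_keys(rt)
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1
  }
  tibble::tibble(split = keys,
                 support = 100 * unname(counts) / length(replicates))
}

# write supports onto node labels of the (rooted representation of the) tree
annotate_support <- function(tree, support_tbl) {
  ntip <- ape::Ntip(tree)
  labs <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  node_lab <- rep("", tree$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(tree$tip.label[pp[[k]]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (!(labs[1L] %in% side)) side <- setdiff(labs, side)
    key <- paste(side, collapse = "|")
    j <- match(key, support_tbl$split)
    if (!is.na(j)) node_lab[k] <- format(round(support_tbl$support[j]))
  }
  tree$node.label <- node_lab
  tree
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the internal bipartition sets of
#' two unrooted trees on the same leaves; 0 means identical topology.
#'
#' @param t1,t2 `phylo` objects with identical leaf sets.
#' @return Integer distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  k1 <- split_keys(t1); k2 <- split_keys(t2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Check topological identity
#' @inheritParams rf_distance
#' @return TRUE when the unrooted topologies are identical.
#' @export
topologies_equal <- function(t1, t2) rf_distance(t1, t2) == 0L

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree `phylo`.
#' @param outgroup Tip label.
#' @return Rooted `phylo` with two children at the root.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' not in tree")
  tip <- match(outgroup, tree$tip.label)
  e <- which(tree$edge[, 2L] == tip)
  phytools::reroot(tree, tip, position = tree$edge.length[e] / 2)
}
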
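FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' Extract 4-fold degenerate sites
#'
#' Returns the third codon positions of the columns where, in every taxon,
#' the codon is ungapped, unambiguous and belongs to a 4-fold degenerate
#' codon family (its first two bases determine the amino acid: Leu CTx,
#' Val GTx, Ser TCx, Pro CCx, Thr ACx, Ala GCx, Arg CGx, Gly GGx).  Strict
#' intersection over taxa guarantees the retained positions are synonymous
#' everywhere on the tree, making them the standard near-neutral site class
#' for molecular dating.
#'
#' @param nt_alignment Codon-partitioned nucleotide alignment (named
#'   character vector, width divisible by 3) or a `supermatrix` (its `nt`
#'   slot is used).
#' @return Named character vector of third-position sites (possibly width 0).
#' @export
fourfold_sites <- function(nt_alignment) {
  if (inherits(nt_alignment, "supermatrix")) nt_alignment <- nt_alignment$nt
  w <- unique(nchar(nt_alignment))
  if (length(w) != 1L) stop("rows differ in width")
  if (w %% 3L != 0L) stop("alignment width not divisible by 3")
  m <- aln_to_matrix(nt_alignment)
  n_cod <- w %/% 3L
  keep <- logical(n_cod)
  third <- matrix("", nrow(m), n_cod, dimnames = list(rownames(m), NULL))
  for (k in seq_len(n_cod)) {
    cols <- (3L * (k - 1L) + 1L):(3L * k)
    block <- m[, cols, drop = FALSE]
    ok <- all(block %in% c("A", "C", "G", "T")) &&
      all(paste0(block[, 1L], block[, 2L]) %in% FOURFOLD_PREFIXES)
    if (ok) {
      keep[k] <- TRUE
      third[, k] <- block[, 3L]
    }
  }
  if (!any(keep)) {
    out <- stats::setNames(rep("", nrow(m)), rownames(m))
    return(out)
  }
  matrix_to_aln(third[, keep, drop = FALSE])
}

#' Strict-clock Bayesian node dating
#'
#' Metropolis-Hastings sampling of internal node ages and a single clock
#' rate on a fixed rooted topology.  The likelihood is the pruning-algorithm
#' likelihood of the 4-fold degenerate site matrix with branch lengths
#' `rate * duration`; the prior combines normal calibration densities on
#' calibrated nodes, uniform-within-constraints ages elsewhere and a diffuse
#' lognormal on the rate.  Node-age proposals are sliding windows reflected
#' into the (child, parent) interval; the rate uses a multiplicative scale
#' move.  Proposal scales adapt toward ~30% acceptance during burn-in and
#' are fixed afterwards.  With zero data the posterior reproduces the prior,
#' which is the first sanity check to run on any calibration set.
#'
#' @param tree Rooted binary `phylo` topology (branch lengths ignored).
#' @param aln_4d Named character vector of 4-fold degenerate sites
#'   ([fourfold_sites()]); zero-width or `NULL` gives a prior-only run.
#' @param calibrations Tibble/data.frame with columns `clade` (list column
#'   of taxon vectors, or the string `"root"`), `mean`, `sd` (Ma) and `type`
#'   (`"crown"` = the clade's MRCA, `"stem"` = its parent node).
#' @param model A [gtr_model()] for the site likelihood (default
#'   Jukes-Cantor).
#' @param steps Total MCMC iterations (default 20000).
#' @param burnin Discarded iterations (default `steps %/% 4`).
#' @param thin Keep every `thin`-th sample (default 10).
#' @param rate_prior_meanlog,rate_prior_sdlog Lognormal prior on the clock
#'   rate, substitutions/site/Ma (defaults log(0.002), 2 -- diffuse around
#'   typical plant nuclear rates).
#' @param root_max Upper bound for the root age when the root itself is not
#'   calibrated (default 4x the largest calibration mean).
#' @param seed Integer seed.
#' @return A `dated_tree`: list with `tree` (input topology), `samples`
#'   (tibble of kept iterations: node ages in Ma and `rate`), `estimates`
#'   (tibble: `node`, `mean`, `lwr`, `upr` 95% credible interval),
#'   `acceptance` (named rates) and `node_map` (internal node -> tip set).
#' @export
strict_clock_date <- function(tree, aln_4d, calibrations,
                              model = gtr_model(), steps = 20000,
                              burnin = steps %/% 4, thin = 10,
                              rate_prior_meanlog = log(0.002),
                              rate_prior_sdlog = 2,
                              root_max = NULL, seed = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  if (is.null(calibrations) || nrow(calibrations) == 0)
    stop("at least one calibration is required")
  if (any(calibrations$sd <= 0)) stop("calibration sd must be positive")

  # resolve calibrated nodes (internal node numbers, ape convention)
  cal_node <- integer(nrow(calibrations))
  for (i in seq_len(nrow(calibrations))) {
    cl <- calibrations$clade[[i]]
    ty <- calibrations$type[i] %||% "crown"
    if (identical(cl, "root") || identical(cl[[1L]], "root")) {
      cal_node[i] <- ntip + 1L
      next
    }
    if (!all(cl %in% tree$tip.label))
      stop("calibration clade has taxa not in the tree: ",
           paste(setdiff(cl, tree$tip.label), collapse = ", "))
    mrca <- if (length(cl) == 1L) match(cl, tree$tip.label)
            else ape::getMRCA(tree, cl)
    nd <- if (identical(ty, "stem")) {
      pe <- which(tree$edge[, 2L] == mrca)
      if (length(pe) == 0) stop("stem calibration on the root clade; use clade='root'")
      tree$edge[pe, 1L]
    } else {
      if (length(cl) == 1L) stop("crown calibration needs >= 2 taxa")
      mrca
    }
    cal_node[i] <- nd
  }
  cal_mean <- stats::setNames(calibrations$mean, cal_node)
  cal_sd <- stats::setNames(calibrations$sd, cal_node)
  root_max <- root_max %||% (4 * max(calibrations$mean))

  # topology bookkeeping
  tr <- ape::reorder.phylo(tree, "postorder")
  parent_of <- integer(ntip + nnode)
  parent_of[tr$edge[, 2L]] <- tr$edge[, 1L]
  children_of <- split(tr$edge[, 2L], tr$edge[, 1L])
  internal <- (ntip + 1L):(ntip + nnode)
  root <- ntip + 1L

  prior_only <- is.null(aln_4d) || length(aln_4d) == 0 ||
    unique(nchar(aln_4d))[1L] == 0
  loglik_fn <- if (prior_only) function(ages, rate) 0 else
    make_clock_loglik(tr, aln_4d, model, ntip)

  log_prior <- function(ages, rate) {
    lp <- stats::dlnorm(rate, rate_prior_meanlog, rate_prior_sdlog, log = TRUE)
    for (nd in internal) {
      upper <- if (nd == root) root_max else ages[parent_of[nd]]
      lower <- max(ages[children_of[[as.character(nd)]]], 0)
      if (ages[nd] <= lower || ages[nd] >= upper) return(-Inf)
      key <- as.character(nd)
      if (key %in% names(cal_mean))
        lp <- lp + stats::dnorm(ages[nd], cal_mean[[key]], cal_sd[[key]], log = TRUE)
    }
    lp
  }

  local_seed(seed, {
    # initial state: calibrated means where available, else evenly spaced
    ages <- numeric(ntip + nnode)
    depth_order <- rev(unique(tr$edge[, 1L]))       # root first in preorder
    ages[root] <- cal_mean[[as.character(root)]] %||% (root_max / 2)
    for (nd in depth_order) {
      if (nd == root) next
      key <- as.character(nd)
      up <- ages[parent_of[nd]]
      ages[nd] <- if (key %in% names(cal_mean))
        min(cal_mean[[key]], up * 0.95) else up * 0.7
    }
    rate <- exp(rate_prior_meanlog)
    scales <- c(age = max(1, ages[root] / 20), rate = 0.3)
    acc <- c(age = 0, rate = 0); try_n <- c(age = 0, rate = 0)
    lp <- log_prior(ages, rate)
    ll <- loglik_fn(ages, rate)
    keep_iter <- seq(burnin + 1L, steps, by = thin)
    samples <- matrix(NA_real_, length(keep_iter), nnode + 1L)
    colnames(samples) <- c(paste0("node", internal), "rate")
    srow <- 0L

    for (it in seq_len(steps)) {
      for (nd in internal) {
        upper <- if (nd == root) root_max else ages[parent_of[nd]]
        lower <- max(ages[children_of[[as.character(nd)]]], 0)
        prop <- reflect(ages[nd] + stats::runif(1, -scales["age"], scales["age"]),
                        lower, upper)
        old <- ages[nd]; ages[nd] <- prop
        lp2 <- log_prior(ages, rate); ll2 <- loglik_fn(ages, rate)
        try_n["age"] <- try_n["age"] + 1
        if (log(stats::runif(1)) < (lp2 + ll2) - (lp + ll)) {
          lp <- lp2; ll <- ll2; acc["age"] <- acc["age"] + 1
        } else ages[nd] <- old
      }
      u <- stats::runif(1, -scales["rate"], scales["rate"])
      rate2 <- rate * exp(u)
      lp2 <- log_prior(ages, rate2); ll2 <- loglik_fn(ages, rate2)
      try_n["rate"] <- try_n["rate"] + 1
      if (log(stats::runif(1)) < (lp2 + ll2) - (lp + ll) + u) {
        rate <- rate2; lp <- lp2; ll <- ll2; acc["rate"] <- acc["rate"] + 1
      }
      if (it <= burnin && it %% 100L == 0L) {      # adapt toward ~0.3
        for (mv in c("age", "rate")) {
          r <- acc[mv] / max(try_n[mv], 1)
          scales[mv] <- scales[mv] * exp(0.5 * (r - 0.3))
        }
        acc[] <- 0; try_n[] <- 0
      }
      if (it %in% keep_iter) {
        srow <- srow + 1L
        samples[srow, ] <- c(ages[internal], rate)
      }
    }
    est <- tibble::tibble(
      node = c(internal, NA_integer_),
      parameter = colnames(samples),
      mean = colMeans(samples),
      lwr = apply(samples, 2L, stats::quantile, 0.025),
      upr = apply(samples, 2L, stats::quantile, 0.975))
    node_map <- lapply(stats::setNames(internal, paste0("node", internal)),
                       function(nd) sort(tree$tip.label[tips_below(tr, nd, ntip)]))
    structure(list(tree = tree,
                   samples = tibble::as_tibble(samples),
                   estimates = est,
                   acceptance = acc / pmax(try_n, 1),
                   node_map = node_map), class = "dated_tree")
  })
}

reflect <- function(x, lower, upper) {
  if (upper <= lower) return(lower)
  span <- upper - lower
  y <- (x - lower) %% (2 * span)
  lower + ifelse(y > span, 2 * span - y, y)
}

tips_below <- function(tr, node, ntip) {
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    if (nd <= ntip) out <- c(out, nd)
    else stack <- c(stack, kids[[as.character(nd)]])
  }
  out
}

# Pruning likelihood as a closure over precomputed patterns; branch lengths
# recomputed from ages at each call.
make_clock_loglik <- function(tr, aln, model, ntip) {
  m <- aln_to_matrix(aln[tr$tip.label])
  pat <- compress_patterns(m)
  tipL <- lapply(seq_len(ntip), function(i) {
    rows <- IUPAC_ROWS[match(pat$m[i, ], rownames(IUPAC_ROWS)), , drop = FALSE]
    rows[is.na(rows[, 1L]), ] <- 1
    rows
  })
  edges <- tr$edge
  nnode_all <- ntip + tr$Nnode
  w <- pat$w
  bf <- model$base_freq
  function(ages, rate) {
    L <- vector("list", nnode_all)
    for (i in seq_len(ntip)) L[[i]] <- tipL[[i]]
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L]; ch <- edges[e, 2L]
      b <- (ages[p] - ages[ch]) * rate
      if (b < 0) return(-Inf)
      P <- gtr_transition(model, b)
      contrib <- L[[ch]] %*% t(P)
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    root <- edges[nrow(edges), 1L]
    sl <- as.vector(L[[root]] %*% bf)
    if (any(sl <= 0)) return(-Inf)
    sum(w * log(sl))
  }
}

#' @export
print.dated_tree <- function(x, ...) {
  root <- x$estimates[x$estimates$parameter ==
                        paste0("node", ape::Ntip(x$tree) + 1L), ]
  cat(sprintf("dated tree: %d internal nodes; root age %.1f (%.1f-%.1f)\n",
              length(x$node_map), root$mean, root$lwr, root$upr))
  invisible(x)
}
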
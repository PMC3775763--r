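# Independent oracles used to cross-check the package's implementations.
# These are deliberately written from scratch (plain dynamic programming /
# exhaustive enumeration / closed forms) and share no code with the package
# internals they check.

# --- brute-force local alignment (Smith-Waterman, affine gaps) -------------
# Gap of length L costs gap_open + L * gap_ext (BLAST convention, matching
# Biostrings' gapOpening/gapExtension semantics).
oracle_local_align <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- brute-force global alignment score (Needleman-Wunsch, affine) ---------
oracle_global_align <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext,
                     Y[i - 1, j] - gap_open - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext,
                     X[i, j - 1] - gap_open - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive Fitch oracle ------------------------------------------------
# Minimum change count by enumerating every assignment of internal states.
oracle_parsimony <- function(tree, alignment) {
  states <- c("A", "C", "G", "T")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  m <- do.call(rbind, strsplit(alignment[tree$tip.label], ""))
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))  # assignments
  total <- 0
  for (site in seq_len(ncol(m))) {
    obs <- m[, site]
    # missing symbols may take any state: enumerate tip possibilities too
    tip_opts <- lapply(obs, function(ch) {
      if (ch %in% states) match(ch, states) else 1:4
    })
    best <- Inf
    tip_grid <- as.matrix(expand.grid(tip_opts))
    for (tg in seq_len(nrow(tip_grid))) {
      tipstate <- tip_grid[tg, ]
      full <- cbind(matrix(tipstate, nrow(grid), ntip, byrow = TRUE), grid)
      changes <- rowSums(
        matrix(full[cbind(rep(seq_len(nrow(grid)), nrow(tree$edge)),
                          rep(tree$edge[, 1], each = nrow(grid)))] !=
               full[cbind(rep(seq_len(nrow(grid)), nrow(tree$edge)),
                          rep(tree$edge[, 2], each = nrow(grid)))],
               nrow(grid), nrow(tree$edge)))
      best <- min(best, min(changes))
    }
    total <- total + best
  }
  total
}

# --- two-taxon GTR likelihood via an independent matrix exponential --------
oracle_two_taxon_loglik <- function(seq1, seq2, d_total, exch, base_freq) {
  nts <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(nts, nts))
  Q["A", "C"] <- Q["C", "A"] <- exch[["AC"]]
  Q["A", "G"] <- Q["G", "A"] <- exch[["AG"]]
  Q["A", "T"] <- Q["T", "A"] <- exch[["AT"]]
  Q["C", "G"] <- Q["G", "C"] <- exch[["CG"]]
  Q["C", "T"] <- Q["T", "C"] <- exch[["CT"]]
  Q["G", "T"] <- Q["T", "G"] <- exch[["GT"]]
  Q <- Q * rep(base_freq, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(base_freq * diag(Q))
  P <- as.matrix(Matrix::expm(Q * d_total))
  s1 <- strsplit(seq1, "")[[1L]]; s2 <- strsplit(seq2, "")[[1L]]
  sum(log(base_freq[s1] * P[cbind(s1, s2)]))
}

# --- misc helpers -----------------------------------------------------------
random_protein <- function(n) {
  paste0(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n, replace = TRUE),
         collapse = "")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

phydat_to_chr <- function(dat) {
  ch <- as.character(dat)
  toupper(stats::setNames(apply(ch, 1L, paste0, collapse = ""), rownames(ch)))
}

blosum <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
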
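#' Mutation-level codon substitution model
#'
#' Builds a reversible 61-state codon rate matrix from a nucleotide GTR
#' parameterisation.  Codons differing at exactly one position exchange at
#' rate `exch[xy] * base_freq[y]`; stop codons (TAA, TAG, TGA, standard code)
#' are excluded from the state space, so no substitution can create a stop
#' and translation stays well defined.  The matrix is scaled so that one unit
#' of branch length equals one expected nucleotide substitution per site
#' (three per codon) at stationarity.
#'
#' The stationary distribution is proportional to the product of the position
#' base frequencies, renormalised over the 61 sense codons; because of the
#' stop-codon exclusion its nucleotide marginals differ slightly from
#' `base_freq`.  Use [codon_stationary()] for the exact marginals.
#'
#' @param exch Named numeric vector of the six GTR exchangeabilities
#'   (`AC`, `AG`, `AT`, `CG`, `CT`, `GT`), all positive.
#' @param base_freq Named numeric vector of the four base frequencies
#'   (`A`, `C`, `G`, `T`), summing to 1.
#' @param omega Nonsynonymous/synonymous rate ratio (default 0.2, moderate
#'   purifying selection typical of conserved nuclear genes; 1 = neutral).
#'   Does not change the stationary distribution.
#' @return An object of class `codon_model`: the codon list, rate matrix `Q`,
#'   stationary codon frequencies `pi`, and the eigendecomposition used for
#'   transition probabilities.
#' @examples
#' m <- codon_model()
#' sum(m$pi)                      # 1
#' range(rowSums(m$Q))            # ~0 (rates balance)
#' @export
codon_model <- function(exch = c(AC = 1, AG = 2, AT = 1, CG = 1, CT = 2, GT = 1),
                        base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        omega = 0.2) {
  nts <- c("A", "C", "G", "T")
  exch <- exch[c("AC", "AG", "AT", "CG", "CT", "GT")]
  base_freq <- base_freq[nts]
  if (anyNA(exch) || any(exch <= 0)) stop("exchangeabilities must be positive and named AC..GT")
  if (anyNA(base_freq) || any(base_freq < 0) || abs(sum(base_freq) - 1) > 1e-8)
    stop("base frequencies must be named A,C,G,T and sum to 1")

  codons <- sense_codons()
  n <- length(codons)
  cod_mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))

  # symmetric nucleotide exchangeability lookup
  ex <- matrix(0, 4, 4, dimnames = list(nts, nts))
  ex["A", "C"] <- ex["C", "A"] <- exch[["AC"]]
  ex["A", "G"] <- ex["G", "A"] <- exch[["AG"]]
  ex["A", "T"] <- ex["T", "A"] <- exch[["AT"]]
  ex["C", "G"] <- ex["G", "C"] <- exch[["CG"]]
  ex["C", "T"] <- ex["T", "C"] <- exch[["CT"]]
  ex["G", "T"] <- ex["T", "G"] <- exch[["GT"]]

  if (omega <= 0) stop("omega must be positive")
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  Q <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(cod_mat[i, ] != cod_mat[j, ])
      if (length(diff) == 1L) {
        x <- cod_mat[i, diff]; y <- cod_mat[j, diff]
        Q[i, j] <- ex[x, y] * base_freq[[y]] *
          (if (aa[i] == aa[j]) 1 else omega)
      }
    }
  }
  pi_cod <- apply(cod_mat, 1L, function(cd) prod(base_freq[cd]))
  pi_cod <- pi_cod / sum(pi_cod)
  names(pi_cod) <- codons

  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi_cod * diag(Q))      # expected substitutions per codon per unit
  Q <- Q * (3 / mu)                 # 1 unit = 1 expected substitution / nt site

  # reversible eigendecomposition for fast transition matrices
  sp <- sqrt(pi_cod)
  B <- (Q * sp) / rep(sp, each = n)            # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  structure(list(
    exch = exch, base_freq = base_freq, omega = omega,
    codons = codons, Q = Q, pi = pi_cod,
    eig_values = eig$values,
    eig_left = eig$vectors / sp,        # diag(1/sqrt(pi)) %*% V
    eig_right = t(eig$vectors * sp)     # t(V) %*% diag(sqrt(pi))
  ), class = "codon_model")
}

# The 61 sense codons of the standard genetic code, in fixed order.
sense_codons <- function() {
  nts <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
  all64 <- sort(all64)
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

# P(t) = exp(Qt) for a codon_model; rows index the parent state.
codon_transition <- function(model, t) {
  if (t < 0) stop("branch length must be >= 0")
  n <- length(model$codons)
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model$codons, model$codons)
  P
}

#' Stationary nucleotide frequencies of a codon model
#'
#' Marginal base frequencies implied by the stationary codon distribution,
#' overall and per codon position.  These differ from the input `base_freq`
#' because stop codons are excluded from the state space.
#'
#' @param model A [codon_model()].
#' @return A list with `overall` (length-4 named vector) and `by_position`
#'   (3 x 4 matrix).
#' @export
codon_stationary <- function(model) {
  stopifnot(inherits(model, "codon_model"))
  cod_mat <- do.call(rbind, strsplit(model$codons, "", fixed = TRUE))
  nts <- c("A", "C", "G", "T")
  by_pos <- sapply(nts, function(nt)
    sapply(1:3, function(p) sum(model$pi[cod_mat[, p] == nt])))
  rownames(by_pos) <- paste0("pos", 1:3)
  list(overall = colMeans(by_pos), by_position = by_pos)
}

#' Translate in-frame coding sequence
#'
#' @param cds A character vector of nucleotide strings, each of length
#'   divisible by 3.
#' @return Character vector of amino-acid strings (`*` for stops, `X` for
#'   ambiguous codons).
#' @export
translate_cds <- function(cds) {
  if (any(nchar(cds) %% 3 != 0)) stop("CDS length not divisible by 3")
  out <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                            if.fuzzy.codon = "solve",
                                            no.init.codon = TRUE))
  names(out) <- names(cds)
  out
}
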
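## GY94-style codon substitution model over the 61 sense codons.
## Instantaneous rates: q_ij = 0 for codon pairs differing at >1 position;
## otherwise q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous].
## The matrix is time-reversible with stationary distribution pi, which
## permits a symmetric eigendecomposition for fast matrix exponentials.

## Precompute the sparse single-step structure once per session: for each
## ordered sense-codon pair differing at exactly one position, whether the
## change is a transition and whether it is nonsynonymous.
.codon_pair_structure <- function() {
  diffs <- matrix(0L, N_SENSE, N_SENSE)
  ts <- matrix(FALSE, N_SENSE, N_SENSE)
  nonsyn <- matrix(FALSE, N_SENSE, N_SENSE)
  for (p in 1:3) {
    same_other <- TRUE
    for (q in setdiff(1:3, p))
      same_other <- same_other & outer(SENSE_NT[, q], SENSE_NT[, q], "==")
    differ_p <- outer(SENSE_NT[, p], SENSE_NT[, p], "!=")
    one <- same_other & differ_p
    diffs[one] <- diffs[one] + 1L
    tr <- outer(SENSE_NT[, p], SENSE_NT[, p], is_transition)
    ts[one & tr] <- TRUE
  }
  single <- diffs == 1L
  nonsyn <- outer(SENSE_AA, SENSE_AA, "!=")
  list(single = single, transition = ts, nonsyn = nonsyn & single)
}
.PAIRS <- .codon_pair_structure()

#' GY94 codon rate matrix
#'
#' Build the 61x61 instantaneous rate matrix with transition/transversion
#' ratio `kappa`, nonsynonymous/synonymous ratio `omega` and stationary
#' codon frequencies `pi`. When `scale = TRUE` the matrix is normalized so
#' that the expected substitution rate \eqn{-\sum_i \pi_i q_{ii}} equals 1,
#' i.e. branch lengths are in expected substitutions per codon.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Stationary codon frequencies (61-vector summing to 1).
#' @param scale Normalize mean rate to 1?
#' @return 61x61 rate matrix with zero row sums.
#' @export
codon_rate_matrix <- function(kappa, omega, pi = equal_codon_freqs(),
                              scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0)
  .check_codon_freqs(pi)
  Q <- matrix(0, N_SENSE, N_SENSE, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  Q[.PAIRS$single] <- 1
  Q[.PAIRS$transition] <- Q[.PAIRS$transition] * kappa
  Q[.PAIRS$nonsyn] <- Q[.PAIRS$nonsyn] * omega
  Q <- Q * rep(pi, each = N_SENSE) # q_ij ~ pi_j
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

## Mean substitution rate (-sum pi_i q_ii) of an *unscaled* matrix; used to
## normalize site-class mixtures by their average rate.
.mean_rate <- function(kappa, omega, pi) {
  Q <- codon_rate_matrix(kappa, omega, pi, scale = FALSE)
  -sum(pi * diag(Q))
}

## Symmetric eigendecomposition of a reversible Q. Returns a closure-free
## list from which P(t) = U diag(exp(lambda t)) Uinv is assembled.
codon_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * (sp / rep(sp, each = length(sp))) # diag(sp) Q diag(1/sp), S = t(S)
  S <- (S + t(S)) / 2 # symmetrize against round-off
  e <- eigen(S, symmetric = TRUE)
  U <- e$vectors / sp          # diag(1/sp) V
  Uinv <- t(e$vectors * sp)    # t(V) diag(sp)
  list(values = e$values, U = U, Uinv = Uinv)
}

## Transition probability matrix from an eigendecomposition.
codon_probs <- function(eig, t) {
  if (t < 0) stop("negative branch length")
  if (t == 0) return(diag(length(eig$values)))
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  # numerical cleanup: tiny negatives from round-off
  P[P < 0] <- 0
  P
}

#' Discretize a beta distribution into equal-probability rate classes
#'
#' Used by the M7 and M8 site models: the beta(p, q) distribution of omega
#' on (0, 1) is represented by `k` categories of equal probability, each at
#' the median of its probability slice.
#'
#' @param p,q Beta shape parameters (> 0).
#' @param k Number of categories.
#' @return Numeric vector of `k` omega values in (0, 1).
#' @export
beta_omega_classes <- function(p, q, k = 10) {
  stopifnot(p > 0, q > 0, k >= 1)
  stats::qbeta((seq_len(k) - 0.5) / k, p, q)
}
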
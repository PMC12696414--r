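# GY94 rate matrices, transition probabilities and the dN/dS
# decomposition. The heavy lifting (matrix build, spectral exponential)
# is done in compiled code; these wrappers validate and document the
# conventions.

#' Build a GY94 codon rate matrix
#'
#' Instantaneous rates between sense codons `i -> j` differing at exactly
#' one position are `pi_j * kappa^[transition] * omega^[nonsynonymous]`;
#' all multi-step rates are zero. The matrix is scaled so the expected
#' substitution rate at stationarity is 1, making branch lengths expected
#' substitutions per codon under that branch class's own omega.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega dN/dS for this branch class (>= 0)
#' @param pi stationary codon frequencies: positive 61-vector summing to 1
#'   (use [empirical_codon_freqs()], whose pseudo-count guarantees
#'   positivity).
#' @return 61 x 61 rate matrix with zero row sums.
#' @examples
#' Q <- build_rate_matrix(kappa = 2, omega = 0.1)
#' max(abs(rowSums(Q)))  # ~ 0
#' @export
build_rate_matrix <- function(kappa, omega, pi = uniform_codon_freqs()) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa > 0,
            is.numeric(omega), length(omega) == 1, omega >= 0)
  pi <- check_codon_freqs(pi)
  ct <- codon_tables()
  Q <- cpp_build_Q(kappa, omega, pi, ct$adj, ct$ts, ct$nonsyn)
  dimnames(Q) <- list(ct$codons, ct$codons)
  Q
}

#' Transition probability matrix P = exp(Qt)
#'
#' Computed by spectral decomposition of the pi-symmetrized generator
#' (exact for a reversible Q); tiny negative entries from round-off are
#' clamped to zero.
#'
#' @param Q rate matrix from [build_rate_matrix()]
#' @param t branch length (>= 0, expected substitutions per codon)
#' @param pi the stationary frequencies `Q` was built with
#' @return 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(Q, t, pi = uniform_codon_freqs()) {
  if (!is.numeric(t) || length(t) != 1 || t < 0)
    stop("branch length t must be a single non-negative number")
  pi <- check_codon_freqs(pi)
  eg <- cpp_eigen_system(Q, pi)
  P <- cpp_transition(eg$left, eg$right, eg$values, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Uniform sense-codon frequencies
#' @return 61-vector of 1/61, named by codon.
#' @export
uniform_codon_freqs <- function() {
  ct <- codon_tables()
  stats::setNames(rep(1 / 61, 61), ct$codons)
}

check_codon_freqs <- function(pi) {
  if (length(pi) != 61) stop("codon frequencies must have length 61")
  if (any(pi <= 0)) stop("codon frequencies must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-8) stop("codon frequencies must sum to 1")
  pi / sum(pi)
}

#' Empirical codon frequencies of an alignment
#'
#' Observed sense-codon proportions with a pseudo-count of 0.5 added to
#' every sense codon before normalization, so no frequency is ever zero
#' (the package's stand-in for Codeml's empirical codon-frequency
#' convention).
#'
#' @param aln a `codon_alignment`
#' @param pseudo pseudo-count per codon (default 0.5)
#' @return named 61-vector summing to 1.
#' @export
empirical_codon_freqs <- function(aln, pseudo = 0.5) {
  ct <- codon_tables()
  st <- aln_state_matrix(aln)
  counts <- tabulate(st[!is.na(st)], nbins = 61) + pseudo
  stats::setNames(counts / sum(counts), ct$codons)
}

#' Decompose a branch class into dN, dS and their ratio
#'
#' Expected nonsynonymous flux `rho_N = sum over nonsynonymous pairs of
#' pi_i q_ij` (synonymous likewise) under the class's scaled Q; the
#' nonsynonymous/synonymous opportunity proportions come from the same Q
#' rebuilt with omega = 1. Then `dN = t * rho_N / propN`, `dS = t * rho_S
#' / propS`; the ratio reproduces the class omega whenever dS > 0.
#'
#' @param kappa,omega,pi model parameters for the branch class
#' @param t branch length (>= 0)
#' @return list with `dN`, `dS`, `ratio` (`ratio = omega` when `t = 0`,
#'   where the decomposition is the 0/0 limit).
#' @examples
#' d <- decompose_dnds(kappa = 2, omega = 0.5, t = 0.3)
#' d$ratio  # 0.5
#' @export
decompose_dnds <- function(kappa, omega, t, pi = uniform_codon_freqs()) {
  stopifnot(t >= 0)
  ct <- codon_tables()
  pi <- check_codon_freqs(pi)
  flux <- function(w) {
    Q <- cpp_build_Q(kappa, w, pi, ct$adj, ct$ts, ct$nonsyn)
    F <- pi * Q            # pi_i q_ij, rowwise
    rN <- sum(F[ct$nonsyn == 1])
    rS <- sum(F[ct$adj == 1 & ct$nonsyn == 0])
    c(N = rN, S = rS)
  }
  f <- flux(omega)
  opp <- flux(1)
  propN <- opp["N"] / sum(opp)
  propS <- opp["S"] / sum(opp)
  dN <- t * f[["N"]] / propN
  dS <- t * f[["S"]] / propS
  ratio <- if (t == 0 || f[["S"]] == 0) omega else dN / dS
  list(dN = unname(dN), dS = unname(dS), ratio = unname(ratio))
}
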
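# Rate matrices, transition probabilities, pruning likelihood and the
# dN/dS decomposition.

test_that("GY94 generator is a proper reversible rate matrix", {
  set.seed(42)
  for (rep in 1:3) {
    pi <- stats::setNames(rdirichlet1(61), codon_tables()$codons)
    kappa <- stats::runif(1, 0.5, 5)
    omega <- stats::runif(1, 0.01, 3)
    Q <- build_rate_matrix(kappa, omega, pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    # detailed balance pi_i q_ij = pi_j q_ji
    F <- pi * Q
    expect_lt(max(abs(F - t(F))), 1e-14)
    # unit expected rate at stationarity
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-10)
  }
  ct <- codon_tables()
  Q0 <- build_rate_matrix(2, 0, uniform_codon_freqs())
  expect_true(all(Q0[ct$nonsyn == 1] == 0))
})

test_that("transition matrices satisfy identity, semigroup and ergodic limits", {
  set.seed(7)
  pi <- stats::setNames(rdirichlet1(61), codon_tables()$codons)
  Q <- build_rate_matrix(2.3, 0.4, pi)
  P0 <- transition_matrix(Q, 0, pi)
  expect_lt(max(abs(P0 - diag(61))), 1e-12)
  P1 <- transition_matrix(Q, 0.17, pi)
  P2 <- transition_matrix(Q, 0.31, pi)
  P12 <- transition_matrix(Q, 0.48, pi)
  expect_lt(max(abs(P1 %*% P2 - P12)), 1e-8)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
  Pinf <- transition_matrix(Q, 500, pi)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-6)
  expect_error(transition_matrix(Q, -0.1, pi), "non-negative")
})

test_that("empirical codon frequencies are pseudo-counted proportions", {
  ct <- codon_tables()
  aln <- codon_alignment(c(a = strrep("AAA", 50), b = strrep("AAA", 50)))
  pi <- empirical_codon_freqs(aln)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_equal(unname(pi["AAA"]), (100 + 0.5) / (100 + 61 * 0.5))
  expect_true(all(pi > 0))
  other <- pi[names(pi) != "AAA"]
  expect_true(all(abs(other - other[1]) < 1e-15))
  # uniform usage is recovered at large n
  set.seed(11)
  s <- paste(sample(ct$codons, 10000, replace = TRUE), collapse = "")
  pi2 <- empirical_codon_freqs(codon_alignment(c(x = s)))
  expect_lt(max(abs(pi2 - 1 / 61)), 0.01)
})

test_that("pruning equals closed forms and brute-force marginalization", {
  pi <- uniform_codon_freqs()
  om <- c(background = 0.3, mono_terminal = 0.7, het_terminal = 0.1)

  # single tip at t = 0: lnL = log pi_c
  phy1 <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "t1",
                         Nnode = 1L, edge.length = 0),
                    class = "phylo")
  tr1 <- labeled_tree(phy1, c(t1 = "monoecious"))
  a1 <- codon_alignment(c(t1 = "ATG"))
  expect_equal(log_likelihood(tr1, a1, 2, om, pi = pi),
               log(pi[["ATG"]]), tolerance = 1e-12)

  # 3-taxon, 2 sites vs brute force over 61^2 internal assignments
  tr <- three_taxon_tree()
  aln <- codon_alignment(c(t1 = "ATGAAA", t2 = "ATGAAG", t3 = "ATAGAA"))
  ll <- log_likelihood(tr, aln, 2, om, pi = pi)
  bf <- brute_force_loglik_3tax(tr, aln, 2, om, pi)
  expect_lt(abs(ll - bf), 1e-10)

  # missing data: N codon = uniform partial likelihood, still matches
  aln_na <- codon_alignment(c(t1 = "ATGAAA", t2 = "ATGNNN", t3 = "AT-GAA"))
  ll_na <- log_likelihood(tr, aln_na, 2, om, pi = pi)
  bf_na <- brute_force_loglik_3tax(tr, aln_na, 2, om, pi)
  expect_lt(abs(ll_na - bf_na), 1e-10)
})

test_that("site independence and taxon-order invariance hold", {
  tr <- three_taxon_tree()
  pi <- uniform_codon_freqs()
  om <- c(background = 0.2, mono_terminal = 0.5, het_terminal = 0.1)
  a1 <- codon_alignment(c(t1 = "ATG", t2 = "ACG", t3 = "ATA"))
  a2 <- codon_alignment(c(t1 = "ATGATG", t2 = "ACGACG", t3 = "ATAATA"))
  expect_equal(2 * log_likelihood(tr, a1, 2, om, pi = pi),
               log_likelihood(tr, a2, 2, om, pi = pi), tolerance = 1e-9)
  shuf <- codon_alignment(c(t3 = "ATA", t1 = "ATG", t2 = "ACG"))
  expect_equal(log_likelihood(tr, a1, 2, om, pi = pi),
               log_likelihood(tr, shuf, 2, om, pi = pi), tolerance = 1e-12)
  bad <- codon_alignment(c(t1 = "ATG", t2 = "ACG", t9 = "ATA"))
  expect_error(log_likelihood(tr, bad, 2, om, pi = pi), "mismatch")
})

test_that("dN/dS decomposition reproduces the class omega", {
  set.seed(3)
  for (rep in 1:5) {
    kappa <- stats::runif(1, 0.5, 6)
    omega <- stats::runif(1, 0.02, 4)
    t <- stats::runif(1, 0.05, 2)
    pi <- stats::setNames(rdirichlet1(61), codon_tables()$codons)
    d <- decompose_dnds(kappa, omega, t, pi)
    expect_equal(d$ratio, omega, tolerance = 1e-6)
  }
  neutral <- decompose_dnds(2, 1, 0.5)
  expect_equal(neutral$dN, neutral$dS, tolerance = 1e-10)
  zero <- decompose_dnds(2, 0.3, 0)
  expect_identical(c(zero$dN, zero$dS), c(0, 0))
  expect_equal(zero$ratio, 0.3)
})
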
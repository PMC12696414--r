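# The codon-evolution simulator and its artifact injectors.

test_that("labeled trees have the expected branch classes and guards", {
  cfg <- sim_config(n_taxa_mono = 4, n_taxa_het = 4)
  tr <- build_labeled_tree(cfg)
  expect_equal(length(tr$phy$tip.label), 8)
  counts <- table(partition_branches(tr))
  expect_equal(unname(counts[c("mono_terminal", "het_terminal",
                               "background")]),
               c(4L, 4L, 6L), ignore_attr = TRUE)
  expect_error(build_labeled_tree(sim_config(n_taxa_mono = 1,
                                             n_taxa_het = 1)),
               "at least 3 taxa")
  # seeded determinism of the random-yule shape
  y1 <- build_labeled_tree(sim_config(tree_shape = "random-yule", seed = 7))
  y2 <- build_labeled_tree(sim_config(tree_shape = "random-yule", seed = 7))
  expect_identical(ape::write.tree(y1$phy), ape::write.tree(y2$phy))
})

test_that("zero branch lengths copy the root to every tip", {
  cfg <- sim_config(terminal_bl = 0, internal_bl = 0, n_codons = 40,
                    seed = 5)
  tr <- build_labeled_tree(cfg)
  aln <- simulate_alignment(tr, cfg)
  expect_equal(length(unique(unclass(aln))), 1L)
})

test_that("simulated codon frequencies converge to the stationary ones", {
  set.seed(19)
  pi <- stats::setNames(rdirichlet1(61, alpha = 8), codon_tables()$codons)
  cfg <- sim_config(n_taxa_mono = 4, n_taxa_het = 4, terminal_bl = 20,
                    internal_bl = 20, n_codons = 10000, codon_freqs = pi,
                    seed = 23)
  tr <- build_labeled_tree(cfg)
  aln <- simulate_alignment(tr, cfg)
  st <- aln_states_by_tip(aln, tr$phy$tip.label)
  freq <- tabulate(st, nbins = 61) / length(st)
  tv <- 0.5 * sum(abs(freq - pi))
  expect_lt(tv, 0.02)
})

test_that("neutral evolution matches the brute-force flux opportunity", {
  # short branches so nearly all tip-pair differences are single events;
  # the expected nonsynonymous fraction of single-position differences is
  # the relative nonsynonymous flux of Q at omega = 1
  ct <- codon_tables()
  pi <- uniform_codon_freqs()
  cfg <- sim_config(n_taxa_mono = 2, n_taxa_het = 2, terminal_bl = 0.02,
                    internal_bl = 0, n_codons = 30000, seed = 31,
                    omega_by_class = c(background = 1, mono_terminal = 1,
                                       het_terminal = 1))
  tr <- build_labeled_tree(cfg)
  aln <- simulate_alignment(tr, cfg)
  st <- aln_states_by_tip(aln, tr$phy$tip.label)
  Q <- build_rate_matrix(2, 1, pi)
  F <- pi * Q
  rhoN <- sum(F[ct$nonsyn == 1])
  rhoS <- sum(F[ct$adj == 1 & ct$nonsyn == 0])
  n_nonsyn <- n_syn <- 0
  for (a in 1:3) for (b in (a + 1):4) {
    diff <- which(st[a, ] != st[b, ])
    for (s in diff) {
      i <- st[a, s]; j <- st[b, s]
      if (ct$adj[i, j] == 1) {
        if (ct$nonsyn[i, j] == 1) n_nonsyn <- n_nonsyn + 1
        else n_syn <- n_syn + 1
      }
    }
  }
  phat <- n_nonsyn / (n_nonsyn + n_syn)
  expect_gt(n_nonsyn + n_syn, 500)
  expect_lt(abs(phat - rhoN / (rhoN + rhoS)), 0.05)
})

test_that("monoecious tips accumulate more amino-acid change when their omega is higher", {
  wins <- 0
  for (seed in 1:3) {
    cfg <- sim_config(n_codons = 200, seed = seed,
                      omega_by_class = c(background = 0.1,
                                         mono_terminal = 0.5,
                                         het_terminal = 0.02))
    tr <- build_labeled_tree(cfg)
    aln <- simulate_alignment(tr, cfg)
    aa <- vapply(unclass(aln), function(s)
      paste(seqinr::translate(strsplit(tolower(s), "")[[1]]), collapse = ""),
      character(1))
    aam <- do.call(rbind, strsplit(aa, ""))
    cons <- apply(aam, 2, function(col) names(which.max(table(col))))
    mism <- apply(aam, 1, function(r) sum(r != cons))
    mono <- grepl("^mono", names(aa))
    if (mean(mism[mono]) > mean(mism[!mono])) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("k < 1 compresses every test-branch category omega toward 1", {
  set.seed(4)
  for (rep in 1:20) {
    w <- sort(stats::runif(3, 0.01, 5))
    k <- stats::runif(1, 0.05, 0.99)
    off <- w != 1
    expect_true(all(abs(w[off]^k - 1) < abs(w[off] - 1)))
  }
})

test_that("artifact injection is a seeded no-op-or-exact transformation", {
  cfg <- sim_config(n_codons = 30, seed = 2)
  tr <- build_labeled_tree(cfg)
  aln <- simulate_alignment(tr, cfg)
  expect_identical(unclass(inject_artifacts(aln, cfg)), unclass(aln))

  cfg_amb <- sim_config(n_codons = 30, seed = 2, ambiguity_injection = 0.1)
  a1 <- inject_artifacts(aln, cfg_amb)
  a2 <- inject_artifacts(aln, cfg_amb)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(aln)))
  # originals only edited at injected positions, injected rows appended last
  cfg_cont <- sim_config(n_codons = 30, seed = 2,
                         contamination = list(n = 2, prob = 0.5))
  a3 <- inject_artifacts(aln, cfg_cont)
  expect_equal(length(a3), length(aln) + 2)
  expect_identical(unclass(a3)[seq_along(aln)], unclass(aln))
  expect_error(sim_config(contamination = list(n = 1, prob = 1.5)),
               "\\[0, 1\\]")
})

test_that("an injected divergent row lands at the closed-form z-score", {
  base <- strrep("ATGGCCAAA", 20)
  aln <- codon_alignment(stats::setNames(rep(base, 10), paste0("s", 1:10)))
  cfg <- sim_config(seed = 9, contamination = list(n = 1, prob = 0.5))
  inj <- inject_artifacts(aln, cfg)
  z <- divergence_zscore_filter(inj)$report
  zdiv <- z$z[z$taxon == "divergent_1"]
  expect_equal(zdiv, 10 / sqrt(11), tolerance = 1e-10)
  expect_true(z$removed[z$taxon == "divergent_1"])
})

test_that("fixtures round-trip and have deterministic checksums", {
  cfg <- sim_config(n_codons = 25, seed = 13, tree_shape = "random-yule")
  ds <- simulate_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture(ds, d1)
  m2 <- write_fixture(ds, d2)
  expect_identical(m1$md5, m2$md5)
  back <- read_fixture(d1)
  expect_identical(unclass(back$alignment), unclass(ds$alignment))
  expect_identical(ape::write.tree(back$tree$phy),
                   ape::write.tree(ds$tree$phy))
  expect_identical(back$traits[names(ds$traits)], ds$traits)
  expect_equal(back$truth$n_codons, cfg$n_codons)
  expect_equal(back$truth$seed, cfg$seed)
  ds$alignment <- structure(character(0), class = "codon_alignment")
  expect_error(write_fixture(ds, d1), "empty alignment")
})
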
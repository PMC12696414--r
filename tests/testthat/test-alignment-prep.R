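# The ortholog-retention and alignment-cleaning rules.

test_that("isoform selection prefers presence, then length, then id", {
  expect_identical(select_isoform(c(A = 20, B = 25)), "B")
  expect_identical(select_isoform(c(A = 10)), "A")
  expect_identical(select_isoform(c(A = 10, B = 10),
                                  c(A = 300, B = 450)), "B")
  expect_identical(select_isoform(c(B = 10, A = 10),
                                  c(A = 300, B = 300)), "A")
  expect_error(select_isoform(numeric(0)), "no isoforms")
})

test_that("coverage filter applies the ceiling rule per life-cycle group", {
  mono_sp <- paste0("m", 1:15)
  het_sp <- paste0("h", 1:15)
  traits <- stats::setNames(c(rep("monoecious", 15), rep("heteroecious", 15)),
                            c(mono_sp, het_sp))
  mk <- function(taxa) codon_alignment(
    stats::setNames(rep("ATGAAA", length(taxa)), taxa))
  alns <- list(
    ok_8_8 = mk(c(mono_sp[1:8], het_sp[1:8])),
    short_7_15 = mk(c(mono_sp[1:7], het_sp)),
    full = mk(c(mono_sp, het_sp)))
  kept <- coverage_filter(alns, traits)
  expect_setequal(names(kept), c("ok_8_8", "full"))
  expect_identical(attr(kept, "removed"), "short_7_15")
  bad <- list(x = mk(c("m1", "unknown_sp")))
  expect_error(coverage_filter(bad, traits), "unknown_sp")
})

test_that("codon-gappy trimming keeps species-specific gaps only", {
  rows <- rep("ATGAAATTT", 10)
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- paste0("s", 1:10)
  m[1, 4:6] <- "-"            # codon column 2: 1 gapped row -> kept
  m[3:4, 7:9] <- "-"          # codon column 3: 2 gapped rows -> removed
  aln <- cyclerelax:::aln_from_matrix(m)
  trimmed <- trim_codon_gappy(aln)
  expect_equal(n_codons(trimmed), 2L)
  expect_equal(attr(trimmed, "removed_codons"), 1L)
  expect_identical(substr(unclass(trimmed)[["s1"]], 1, 6), "ATG---")
  # no gaps -> identity; and trimming is idempotent
  clean <- codon_alignment(stats::setNames(rows, paste0("s", 1:10)))
  expect_identical(c(unclass(trim_codon_gappy(clean))), c(unclass(clean)))
  twice <- trim_codon_gappy(trimmed)
  expect_identical(c(unclass(twice)), c(unclass(trimmed)))
  expect_equal(attr(twice, "removed_codons"), 0L)
})

test_that("ambiguity homogenization maps IUPAC letters to N", {
  expect_identical(unclass(homogenize_ambiguities(
    codon_alignment(c(x = "ATR")))[["x"]]), "ATN")
  expect_identical(unclass(homogenize_ambiguities(
    codon_alignment(c(x = "WSKMWS")))[["x"]]), "NNNNNN")
  clean <- codon_alignment(c(x = "ACGT-N"))
  expect_identical(unclass(homogenize_ambiguities(clean)), unclass(clean))
  expect_error(codon_alignment(c(x = "AZG")), "illegal character")
})

test_that("consensus takes the modal base with alphabetical ties", {
  aln <- codon_alignment(c(a = "AAC", b = "ACC", c = "CCA"))
  # cols: {A,A,C}->A, {A,C,C}->C, {C,C,A}->C
  expect_identical(consensus_sequence(aln), "ACC")
  tie <- codon_alignment(c(a = "AAA", b = "CAA"))     # col1 tie A/C -> A
  expect_identical(substr(consensus_sequence(tie), 1, 1), "A")
  five <- codon_alignment(stats::setNames(rep("ATGCCC", 5), paste0("s", 1:5)))
  expect_identical(consensus_sequence(five), "ATGCCC")
  allgap <- codon_alignment(c(a = "A--", b = "A--"))
  expect_identical(consensus_sequence(allgap), "ANN")
})

test_that("divergence z-filter removes only what its closed form allows", {
  base <- strrep("ATGGCCAAATTTGGG", 8)    # 120 nt
  half_div <- paste0(strrep("TGCATGCATGCATGC", 4), substr(base, 61, 120))

  # n = 11: max attainable z = 10/sqrt(11) > 2.5 -> removed
  a11 <- codon_alignment(stats::setNames(c(rep(base, 10), half_div),
                                         c(paste0("s", 1:10), "odd")))
  r11 <- divergence_zscore_filter(a11)
  expect_true(r11$report$removed[r11$report$taxon == "odd"])
  expect_equal(sum(r11$report$removed), 1L)
  expect_equal(max(abs(r11$report$z)), 10 / sqrt(11), tolerance = 1e-10)
  expect_equal(length(r11$alignment), 10L)

  # n = 6: max attainable z = 5/sqrt(6) < 2.5 -> provably nothing removable
  a6 <- codon_alignment(stats::setNames(c(rep(base, 5), half_div),
                                        c(paste0("s", 1:5), "odd")))
  r6 <- divergence_zscore_filter(a6)
  expect_false(any(r6$report$removed))
  expect_equal(max(abs(r6$report$z)), 5 / sqrt(6), tolerance = 1e-10)

  # identical rows: sd = 0, all z defined as 0
  same <- codon_alignment(stats::setNames(rep(base, 4), paste0("s", 1:4)))
  rs <- divergence_zscore_filter(same)
  expect_true(all(rs$report$z == 0))
  expect_false(any(rs$report$removed))

  # < 3 rows: skipped with a warning
  two <- codon_alignment(c(a = base, b = half_div))
  expect_warning(rtwo <- divergence_zscore_filter(two), "skipped")
  expect_true(attr(rtwo$report, "skipped"))
  expect_equal(length(rtwo$alignment), 2L)

  # idempotence on the n = 11 fixture: survivors are identical, so a
  # second pass removes nothing
  r11b <- divergence_zscore_filter(r11$alignment)
  expect_false(any(r11b$report$removed))
})

test_that("clean simulated data passes the z-filter untouched", {
  for (seed in 1:5) {
    cfg <- sim_config(n_codons = 120, seed = seed)
    tr <- build_labeled_tree(cfg)
    aln <- simulate_alignment(tr, cfg)
    out <- prep_alignment(aln)
    expect_equal(out$report$sequences_removed, 0L)
    expect_equal(length(out$alignment), length(aln))
  }
})

test_that("the prep pipeline reports reconciling counts", {
  base <- strrep("ATGGCCAAATTTGGG", 8)
  half_div <- paste0(strrep("TGCATGCATGCATGC", 4), substr(base, 61, 120))
  m <- do.call(rbind, strsplit(c(rep(base, 10), half_div), ""))
  rownames(m) <- c(paste0("s", 1:10), "odd")
  m[1, 1:3] <- "-"
  m[2:3, 4:6] <- "-"
  m[5, 7] <- "R"
  aln <- cyclerelax:::aln_from_matrix(m)
  out <- prep_alignment(aln)
  expect_equal(out$report$n_sequences_in, 11L)
  expect_equal(out$report$codon_columns_removed, 1L)
  expect_equal(out$report$sequences_removed, 1L)
  expect_equal(out$report$removal_fraction, 1 / 11)
  expect_false(grepl("R", paste(unclass(out$alignment), collapse = "")))
})
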
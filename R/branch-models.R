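# The Codeml-style stage: per-ortholog M0 (two dN/dS ratios: all
# terminal branches vs background) and M1 (three ratios: monoecious
# terminal, heteroecious terminal, background) fits, the 1-df likelihood
# ratio test, BH correction across orthologs, and direction summaries.

#' Fit the two- and three-ratio branch models for one ortholog
#'
#' @param tree a `labeled_tree` with both life cycles among its tips
#' @param aln a `codon_alignment`
#' @param pi codon frequencies (default empirical, shared by both fits)
#' @return list with elements `M0` and `M1`, both `codon_fit` objects
#'   sharing codon frequencies and branch lengths.
#' @export
fit_branch_models <- function(tree, aln, pi = NULL) {
  cls <- unique(branch_classes(tree))
  if (!all(c("mono_terminal", "het_terminal") %in% cls))
    stop("unsupported design: both life cycles must be present among tips")
  if (is.null(pi)) pi <- empirical_codon_freqs(aln)
  m0 <- fit_codon_model(tree, aln, "M0", pi = pi)
  list(M0 = m0, M1 = fit_codon_model(tree, aln, "M1", pi = pi, init = m0))
}

#' Likelihood ratio test
#'
#' `stat = 2 (lnL1 - lnL0)`, clamped at zero against round-off, compared
#' to the upper tail of a chi-square distribution.
#'
#' @param lnL0,lnL1 log-likelihoods of the null and alternative model
#' @param df degrees of freedom (> 0)
#' @return list with `stat` and `p`.
#' @examples
#' lrt(-1000, -998.0793)$p  # ~ 0.05
#' @export
lrt <- function(lnL0, lnL1, df = 1) {
  if (df <= 0) stop("df must be positive")
  if (lnL1 < lnL0 - 1e-4)
    warning("alternative lnL below null lnL by more than tolerance")
  stat <- max(0, 2 * (lnL1 - lnL0))
  list(stat = stat, p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`p_(i) * m / i` with enforced monotonicity,
#' capped at 1), preserving input order. `NA` entries (non-converged
#' fits) are passed through as `NA` and do not count toward `m`.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed)
#' @return adjusted vector, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Run the branch-model stage over a batch of orthologs
#'
#' Fits M0 and M1 per ortholog, runs the 1-df LRT, BH-adjusts across the
#' converged orthologs, and calls the dN/dS direction from the M1
#' estimates.
#'
#' @param alignments named list of `codon_alignment`s
#' @param tree a `labeled_tree` (shared) or a named list of trees
#' @param alpha significance cutoff on adjusted p (default 0.05)
#' @return data frame of class `ortholog_tests`: one row per ortholog
#'   with lnL_M0, lnL_M1, the three M1 ratios, stat, p, p_adj, direction.
#' @export
run_branch_stage <- function(alignments, tree, alpha = 0.05) {
  one <- function(id) {
    tr <- if (inherits(tree, "labeled_tree")) tree else tree[[id]]
    fits <- fit_branch_models(tr, alignments[[id]])
    test <- lrt(fits$M0$lnL, fits$M1$lnL)
    om <- fits$M1$params$omega_by_class
    conv <- fits$M0$converged && fits$M1$converged
    data.frame(ortholog_id = id,
               lnL_M0 = fits$M0$lnL, lnL_M1 = fits$M1$lnL,
               omega_back = om[["background"]],
               omega_mono = om[["mono_terminal"]],
               omega_het = om[["het_terminal"]],
               stat = test$stat,
               p = if (conv) test$p else NA_real_,
               converged = conv,
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(names(alignments), one))
  res$p_adj <- bh_adjust(res$p)
  res$direction <- ifelse(res$omega_mono > res$omega_het, "mono_higher",
                          ifelse(res$omega_mono < res$omega_het,
                                 "het_higher", "equal"))
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  class(res) <- c("ortholog_tests", "data.frame")
  res
}

#' Summarize dN/dS directions among significant orthologs
#'
#' Counts orthologs significant at `alpha` on BH-adjusted p, split by
#' whether the M1 monoecious terminal ratio exceeds the heteroecious one,
#' and reports per-class medians of the M1 estimates among the
#' significant set.
#'
#' @param results an `ortholog_tests` data frame (BH-adjusted)
#' @param alpha adjusted-p cutoff (default 0.05)
#' @return list with `n_total`, `n_significant`, `n_mono_higher`,
#'   `n_het_higher`, `prop_mono_higher`, and `median_omega` (named:
#'   mono_terminal, het_terminal, background).
#' @export
summarize_directions <- function(results, alpha = 0.05) {
  if (is.null(results) || nrow(results) == 0)
    return(list(n_total = 0L, n_significant = 0L, n_mono_higher = 0L,
                n_het_higher = 0L, prop_mono_higher = NA_real_,
                median_omega = c(mono_terminal = NA_real_,
                                 het_terminal = NA_real_,
                                 background = NA_real_)))
  sig <- !is.na(results$p_adj) & results$p_adj < alpha
  s <- results[sig, , drop = FALSE]
  n_mono <- sum(s$direction == "mono_higher")
  n_het <- sum(s$direction == "het_higher")
  list(n_total = nrow(results), n_significant = sum(sig),
       n_mono_higher = n_mono, n_het_higher = n_het,
       prop_mono_higher = if (sum(sig)) n_mono / sum(sig) else NA_real_,
       median_omega = c(
         mono_terminal = stats::median(s$omega_mono),
         het_terminal = stats::median(s$omega_het),
         background = stats::median(s$omega_back)))
}
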
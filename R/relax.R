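# RELAX-style selection-intensity testing. A three-category site model
# (omega1 <= omega2 <= omega3 with proportions p) is shared by reference
# and unclassified branches; test branches use omega^k. The null fixes
# the selection-intensity parameter k = 1, the alternative frees it;
# the LRT has one degree of freedom. k < 1 compresses the test-branch
# omega distribution toward 1 (relaxed selection), k > 1 pushes it away
# (intensified selection).

#' Assign RELAX branch sets
#'
#' Terminal branches of the tested life cycle become test branches, the
#' other terminal branches are the reference set, and all internal
#' branches are unclassified: they share the reference omega distribution
#' (k = 1) and contribute to the likelihood without test-specific
#' parameters.
#'
#' @param tree a `labeled_tree` with both life cycles present
#' @param test_class `"mono_terminal"` or `"het_terminal"`
#' @return character vector over edges with values `test`, `reference`,
#'   `unclassified`, plus a `counts` attribute.
#' @export
assign_relax_branches <- function(tree,
                                  test_class = c("mono_terminal",
                                                 "het_terminal")) {
  test_class <- match.arg(test_class)
  cls <- branch_classes(tree)
  if (!all(c("mono_terminal", "het_terminal") %in% cls))
    stop("both life cycles must be present among tips")
  out <- ifelse(cls == test_class, "test",
                ifelse(cls == "background", "unclassified", "reference"))
  structure(out, counts = table(out))
}

# stick-breaking proportions from two logits
.props_from_logits <- function(a) {
  p1 <- stats::plogis(a[1])
  p2 <- (1 - p1) * stats::plogis(a[2])
  c(p1, p2, 1 - p1 - p2)
}
.logits_from_props <- function(p) {
  c(stats::qlogis(p[1]), stats::qlogis(p[2] / (1 - p[1])))
}

#' Evaluate the RELAX mixture log-likelihood at fixed parameters
#'
#' Reference and unclassified branches use the category omegas directly;
#' test branches use `omega^k`. Setting `k = 1` gives the null model's
#' likelihood surface.
#'
#' @param tree a `labeled_tree`
#' @param aln a `codon_alignment`
#' @param test_class which terminal branches are the test set
#' @param omega,props site-category omegas and proportions (same length)
#' @param kappa transition/transversion ratio
#' @param k selection-intensity exponent on test branches
#' @param pi codon frequencies (default empirical)
#' @return the log-likelihood.
#' @export
relax_loglik <- function(tree, aln, test_class, omega, props, kappa, k = 1,
                         pi = NULL) {
  stopifnot(length(omega) == length(props),
            abs(sum(props) - 1) < 1e-8, k >= 0)
  pd <- pruning_data(tree, aln, pi)
  is_test <- pd$edge_class == test_class
  omega_cat <- t(vapply(seq_along(omega), function(cc)
    ifelse(is_test, omega[cc]^k, omega[cc]), numeric(length(is_test))))
  mixture_loglik(pd, kappa, omega_cat, props)
}

#' Fit the RELAX null and alternative models for one ortholog
#'
#' Both fits share the three-category site model (categories drawn once
#' per site, shared across branches) and estimate the category omegas,
#' their proportions and kappa; the alternative additionally frees the
#' selection-intensity exponent k applied to test branches. Category
#' omegas are bounded to \[1e-4, 20\] and reported sorted (the likelihood
#' is invariant to jointly permuting categories and proportions).
#'
#' @param tree a `labeled_tree`
#' @param aln a `codon_alignment`
#' @param test_class which terminal branches are tested
#' @param pi codon frequencies (default empirical)
#' @return object of class `relax_fit`: test_class, `omega` (sorted),
#'   `props`, `kappa`, `k`, `lnL_null`, `lnL_alt`, `stat`, `p`,
#'   `converged`, `n_evals`.
#' @export
fit_relax <- function(tree, aln, test_class = c("mono_terminal",
                                                "het_terminal"),
                      pi = NULL) {
  test_class <- match.arg(test_class)
  assign_relax_branches(tree, test_class)   # validates the design
  pd <- pruning_data(tree, aln, pi)
  is_test <- pd$edge_class == test_class    # postorder, matching pd$edge
  lb <- log(.OMEGA_BOUNDS)
  kb <- log(.KAPPA_BOUNDS)
  xb <- log(.K_BOUNDS)

  unpack <- function(p, free_k) {
    list(omega = exp(clamp(p[1:3], lb[1], lb[2])),
         props = .props_from_logits(clamp(p[4:5], -12, 12)),
         kappa = exp(clamp(p[6], kb[1], kb[2])),
         k = if (free_k) exp(clamp(p[7], xb[1], xb[2])) else 1)
  }
  objective <- function(free_k) function(p) {
    q <- unpack(p, free_k)
    if (any(q$props < 1e-8)) return(-Inf)
    om <- rbind(ref = q$omega, test = q$omega^q$k)
    omega_cat <- t(vapply(1:3, function(cc)
      ifelse(is_test, om["test", cc], om["ref", cc]),
      numeric(length(is_test))))
    mixture_loglik(pd, q$kappa, omega_cat, q$props)
  }

  null_starts <- list(
    c(log(c(0.02, 0.3, 1.5)), .logits_from_props(c(0.7, 0.25, 0.05)), log(2)),
    c(log(c(0.05, 0.5, 2.0)), .logits_from_props(c(0.5, 0.4, 0.1)), log(2)),
    c(log(c(0.01, 0.1, 1.0)), .logits_from_props(c(1, 1, 1) / 3), log(2)))
  null_opt <- multistart_maximize(objective(FALSE), null_starts,
                                  explore_maxit = 90, polish_maxit = 500)
  # warm-start the alternative at the null optimum (k = 1) so
  # lnL_alt >= lnL_null holds by construction
  alt_starts <- lapply(c(1, 0.5, 2), function(k0)
    c(null_opt$par, log(k0)))
  alt_opt <- multistart_maximize(objective(TRUE), alt_starts,
                                 explore_maxit = 60, polish_maxit = 350)

  qa <- unpack(alt_opt$par, TRUE)
  ord <- order(qa$omega)
  q0 <- unpack(null_opt$par, FALSE)
  ord0 <- order(q0$omega)
  test <- lrt(null_opt$lnL, alt_opt$lnL)
  structure(list(test_class = test_class,
                 omega = qa$omega[ord], props = qa$props[ord],
                 kappa = qa$kappa, k = qa$k,
                 null_omega = q0$omega[ord0], null_props = q0$props[ord0],
                 null_kappa = q0$kappa,
                 lnL_null = null_opt$lnL, lnL_alt = alt_opt$lnL,
                 stat = test$stat, p = test$p,
                 converged = null_opt$converged && alt_opt$converged,
                 n_evals = null_opt$n_evals + alt_opt$n_evals),
            class = "relax_fit")
}

#' @export
print.relax_fit <- function(x, ...) {
  cat(sprintf("relax_fit [test = %s]: k = %.4f, LRT stat = %.4f, p = %.4g\n",
              x$test_class, x$k, x$stat, x$p))
  cat(sprintf("  site categories: omega = (%s), props = (%s)\n",
              paste(sprintf("%.4f", x$omega), collapse = ", "),
              paste(sprintf("%.3f", x$props), collapse = ", ")))
  cat(sprintf("  lnL null = %.4f, alt = %.4f%s\n", x$lnL_null, x$lnL_alt,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
logLik.relax_fit <- function(object, ...) {
  structure(object$lnL_alt, df = 7, class = "logLik")
}

#' Classify a RELAX fit
#'
#' `relaxed` when the adjusted p is below `alpha` and k < 1,
#' `intensified` when it is below `alpha` and k > 1, otherwise `null`.
#' A significant fit with k exactly 1 (a measure-zero tie) is classified
#' `null` with a warning.
#'
#' @param fit a `relax_fit` (or a list with `k`)
#' @param p_adj the BH-adjusted p-value for this ortholog's test family
#' @param alpha cutoff (default 0.05)
#' @return one of `"null"`, `"relaxed"`, `"intensified"`.
#' @export
classify_relax <- function(fit, p_adj, alpha = 0.05) {
  if (is.na(p_adj) || p_adj >= alpha) return("null")
  if (fit$k < 1) return("relaxed")
  if (fit$k > 1) return("intensified")
  warning("significant test with k exactly 1; classified null")
  "null"
}

#' Run one RELAX test family over a batch of orthologs
#'
#' Fits null and alternative per ortholog for the given test class,
#' BH-adjusts across the family's converged tests, and classifies each
#' ortholog.
#'
#' @param alignments named list of `codon_alignment`s
#' @param tree a `labeled_tree` (shared) or named list of trees
#' @param test_class which terminal branches are tested
#' @param alpha adjusted-p cutoff
#' @return data frame: ortholog_id, k, lnL_null, lnL_alt, stat, p,
#'   p_adj, verdict.
#' @export
run_relax_stage <- function(alignments, tree,
                            test_class = c("mono_terminal", "het_terminal"),
                            alpha = 0.05) {
  test_class <- match.arg(test_class)
  fits <- lapply(names(alignments), function(id) {
    tr <- if (inherits(tree, "labeled_tree")) tree else tree[[id]]
    fit_relax(tr, alignments[[id]], test_class)
  })
  res <- data.frame(
    ortholog_id = names(alignments),
    k = vapply(fits, `[[`, numeric(1), "k"),
    lnL_null = vapply(fits, `[[`, numeric(1), "lnL_null"),
    lnL_alt = vapply(fits, `[[`, numeric(1), "lnL_alt"),
    stat = vapply(fits, `[[`, numeric(1), "stat"),
    p = ifelse(vapply(fits, `[[`, logical(1), "converged"),
               vapply(fits, `[[`, numeric(1), "p"), NA_real_),
    stringsAsFactors = FALSE)
  res$p_adj <- bh_adjust(res$p)
  res$verdict <- vapply(seq_along(fits), function(i)
    classify_relax(fits[[i]], res$p_adj[i], alpha), character(1))
  class(res) <- c("relax_tests", "data.frame")
  res
}

#' Cross-classify RELAX verdicts against each other and the branch-model
#' results
#'
#' Builds the 3 x 3 verdict table of the monoecious-test (M_M) family
#' against the heteroecious-test (M_H) family, counts the three
#' supporting categories (relaxed-in-mono AND intensified-in-het;
#' relaxed-in-mono only; intensified-in-het only), and, when branch-model
#' results are supplied, the congruence of the supporting set with the
#' M1-significant mono-higher orthologs.
#'
#' @param mm,mh data frames from [run_relax_stage()] for the two
#'   families (same ortholog universe)
#' @param codeml optional `ortholog_tests` data frame from
#'   [run_branch_stage()]
#' @return object of class `cross_classification`: list with `table`
#'   (3 x 3), `supporting` (named counts), `n_supporting`,
#'   `congruence` (count or NA), `verdicts` (per-ortholog data frame).
#' @export
cross_classify <- function(mm, mh, codeml = NULL) {
  if (!setequal(mm$ortholog_id, mh$ortholog_id))
    stop("ortholog universes differ: ",
         paste(union(setdiff(mm$ortholog_id, mh$ortholog_id),
                     setdiff(mh$ortholog_id, mm$ortholog_id)),
               collapse = ", "))
  mh <- mh[match(mm$ortholog_id, mh$ortholog_id), ]
  lv <- c("null", "relaxed", "intensified")
  vm <- factor(mm$verdict, levels = lv)
  vh <- factor(mh$verdict, levels = lv)
  tab <- table(M_M = vm, M_H = vh)
  supporting <- c(
    relaxed_mono_intensified_het = sum(vm == "relaxed" & vh == "intensified"),
    relaxed_mono_only = sum(vm == "relaxed" & vh == "null"),
    intensified_het_only = sum(vm == "null" & vh == "intensified"))
  supp_ids <- mm$ortholog_id[(vm == "relaxed" & vh %in% c("intensified", "null")) |
                               (vm == "null" & vh == "intensified")]
  congruence <- NA_integer_
  if (!is.null(codeml)) {
    cand <- codeml$ortholog_id[codeml$significant &
                                 codeml$direction == "mono_higher"]
    congruence <- length(intersect(supp_ids, cand))
  }
  structure(list(table = tab, supporting = supporting,
                 n_supporting = sum(supporting),
                 supporting_ids = supp_ids,
                 congruence = congruence,
                 verdicts = data.frame(ortholog_id = mm$ortholog_id,
                                       verdict_M_M = as.character(vm),
                                       verdict_M_H = as.character(vh),
                                       stringsAsFactors = FALSE)),
            class = "cross_classification")
}

#' @export
print.cross_classification <- function(x, ...) {
  cat("RELAX cross-classification (rows M_M, cols M_H):\n")
  print(x$table)
  cat("supporting categories:\n")
  for (nm in names(x$supporting))
    cat(sprintf("  %-30s %d\n", nm, x$supporting[[nm]]))
  if (!is.na(x$congruence))
    cat("congruence with mono-higher branch-model set:", x$congruence, "\n")
  invisible(x)
}
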
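# Maximum-likelihood fitting of the branch and selection-intensity codon
# models. All positive parameters are optimized on the log scale with box
# bounds (omega in [1e-4, 20], kappa in [0.1, 50], k in [0.05, 20]);
# category proportions use a stick-breaking logit. Each model runs a
# short Nelder-Mead exploration from >= 3 grid starts and polishes the
# best, which keeps fits deterministic for fixed inputs.

.OMEGA_BOUNDS <- c(1e-4, 20)
.KAPPA_BOUNDS <- c(0.1, 50)
.K_BOUNDS <- c(0.05, 20)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Generic multi-start Nelder-Mead maximizer over an unconstrained vector.
# fn returns the log-likelihood; returns the best optimum with an
# evaluation count and a fixed-point convergence flag.
multistart_maximize <- function(fn, starts, explore_maxit = 100,
                                polish_maxit = 400, reltol = 1e-9) {
  n_evals <- 0L
  neg <- function(p) {
    n_evals <<- n_evals + 1L
    v <- fn(p)
    if (!is.finite(v)) 1e10 else -v
  }
  runs <- lapply(starts, function(s) {
    tryCatch(stats::optim(s, neg, method = "Nelder-Mead",
                          control = list(maxit = explore_maxit,
                                         reltol = 1e-8)),
             error = function(e) NULL)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs) || all(!vapply(runs, function(r) is.finite(r$value),
                                   logical(1))))
    return(list(par = starts[[1]], lnL = -Inf, converged = FALSE,
                n_evals = n_evals))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  pol <- stats::optim(best$par, neg, method = "Nelder-Mead",
                      control = list(maxit = polish_maxit, reltol = reltol))
  # fixed-point check: restarting from the optimum should not improve
  pol2 <- stats::optim(pol$par, neg, method = "Nelder-Mead",
                       control = list(maxit = 150, reltol = reltol))
  if (pol2$value < pol$value) pol <- pol2
  list(par = pol$par, lnL = -pol$value,
       converged = pol$convergence == 0 || abs(pol2$value - pol$value) < 1e-6,
       n_evals = n_evals)
}

new_codon_fit <- function(model_id, params, lnL, n_free, converged, n_evals) {
  structure(list(model_id = model_id, params = params, lnL = lnL,
                 n_free_params = n_free, converged = converged,
                 n_evals = n_evals),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon_fit [%s]: lnL = %.4f (%d free parameters%s)\n",
              x$model_id, x$lnL, x$n_free_params,
              if (x$converged) "" else ", NOT converged"))
  om <- x$params$omega_by_class
  if (!is.null(om))
    cat("  omega: ", paste(sprintf("%s = %.4f", names(om), om),
                           collapse = ", "), "\n", sep = "")
  cat(sprintf("  kappa = %.3f\n", x$params$kappa))
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$n_free_params, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  p <- object$params
  c(p$omega_by_class, kappa = p$kappa,
    if (!is.null(p[["k"]])) c(k = p[["k"]]))
}

#' Fit a branch codon model by maximum likelihood
#'
#' `model = "M0"` estimates one dN/dS shared by all terminal branches and
#' one for the background; `model = "M1"` splits the terminal ratio by
#' life cycle (monoecious vs heteroecious terminal branches). kappa is
#' estimated jointly; codon frequencies are fixed at their empirical
#' (pseudo-counted) values; branch lengths are fixed at the input tree's
#' values.
#'
#' @param tree a `labeled_tree` with both life cycles among its tips for
#'   `"M1"`
#' @param aln a `codon_alignment`
#' @param model `"M0"` (two ratios) or `"M1"` (three ratios)
#' @param pi codon frequencies; default empirical from `aln`
#' @param init optional extra start (a `codon_fit`, typically the nested
#'   M0 fit, used to warm-start M1 in addition to the grid starts)
#' @return a `codon_fit` with elements `model_id`, `params` (kappa,
#'   `omega_by_class`, pi), `lnL`, `n_free_params`, `converged`,
#'   `n_evals`.
#' @export
fit_codon_model <- function(tree, aln, model = c("M0", "M1"), pi = NULL,
                            init = NULL) {
  model <- match.arg(model)
  pd <- pruning_data(tree, aln, pi)
  classes <- unique(pd$edge_class)
  if (model == "M1") {
    if (!all(c("mono_terminal", "het_terminal") %in% classes))
      stop("M1 requires both monoecious and heteroecious terminal branches")
  }
  lb <- log(.OMEGA_BOUNDS)
  kb <- log(.KAPPA_BOUNDS)
  n_om <- if (model == "M0") 2L else 3L

  to_omega <- function(p) exp(clamp(p[seq_len(n_om)], lb[1], lb[2]))
  to_kappa <- function(p) exp(clamp(p[n_om + 1L], kb[1], kb[2]))
  edge_omega <- function(om) {
    if (model == "M0") {
      cls <- ifelse(pd$edge_class == "background", "background", "terminal")
      unname(c(terminal = om[1], background = om[2])[cls])
    } else {
      unname(c(mono_terminal = om[1], het_terminal = om[2],
               background = om[3])[pd$edge_class])
    }
  }
  fn <- function(p) {
    om <- to_omega(p)
    sum(pd$weights *
          pattern_loglik(pd, to_kappa(p), edge_omega(om)))
  }
  starts <- lapply(c(0.05, 0.2, 1.0), function(w)
    c(rep(log(w), n_om), log(2)))
  if (!is.null(init) && inherits(init, "codon_fit") && model == "M1" &&
      init$model_id == "M0") {
    om0 <- init$params$omega_by_class
    starts <- c(list(log(c(om0[["terminal"]], om0[["terminal"]],
                           om0[["background"]], init$params$kappa))),
                starts)
  }
  opt <- multistart_maximize(fn, starts)
  om <- to_omega(opt$par)
  names(om) <- if (model == "M0") c("terminal", "background") else
    c("mono_terminal", "het_terminal", "background")
  new_codon_fit(model, list(kappa = to_kappa(opt$par), omega_by_class = om,
                            pi = pd$pi),
                opt$lnL, n_free = n_om + 1L, opt$converged, opt$n_evals)
}
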
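# GO over-representation testing: hypergeometric upper tail per term,
# BH correction over the tested terms. The background is restricted to
# annotated genes, matching an annotated-orthologs background definition.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from
#' a universe of `N` of which `K` carry the term. Computed in log space
#' via the survival function of the hypergeometric distribution.
#'
#' @param k observed number of candidate genes with the term
#' @param K background genes with the term
#' @param n candidate-set size
#' @param N background size
#' @return the upper-tail probability (1 when k = 0).
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("invalid hypergeometric bounds: need 0 <= k <= min(K, n), K,n <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Read a gene-to-GO annotation map from TSV
#'
#' @param path TSV with columns `gene_id`, `go_id` and optionally
#'   `namespace`
#' @return named list: gene id -> character vector of GO term ids.
#' @export
read_go_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_id") %in% names(df)))
    stop("annotation map needs columns gene_id, go_id")
  bad <- !grepl("^GO:\\d{7}$", df$go_id)
  if (any(bad))
    stop("malformed GO ids: ", paste(utils::head(unique(df$go_id[bad]), 3),
                                     collapse = ", "))
  split(df$go_id, df$gene_id)
}

#' GO term over-representation test
#'
#' One hypergeometric upper-tail test per GO term present in at least one
#' candidate gene (and carried by at least `min_term_size` background
#' genes), BH-corrected over the tested terms. Unannotated genes are
#' excluded from both the background size N and the candidate size n.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of `background`)
#' @param background character vector of background gene ids
#' @param annot named list gene id -> GO term ids (see [read_go_map()])
#' @param alpha significance cutoff on adjusted p (default 0.05)
#' @param min_term_size smallest background term size tested (default 2)
#' @return data frame sorted by `p_adj`: term, k, K, n, N, p, p_adj,
#'   significant.
#' @export
enrich <- function(candidates, background, annot, alpha = 0.05,
                   min_term_size = 2L) {
  outside <- setdiff(candidates, background)
  if (length(outside))
    stop("candidates not in background: ", paste(outside, collapse = ", "))
  bg <- intersect(background, names(annot))
  cand <- intersect(candidates, bg)
  N <- length(bg)
  n <- length(cand)
  if (n == 0)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  term_by_gene <- annot[bg]
  Ktab <- table(unlist(term_by_gene, use.names = FALSE))
  ktab <- table(unlist(annot[cand], use.names = FALSE))
  terms <- names(ktab)[Ktab[names(ktab)] >= min_term_size]
  p <- vapply(terms, function(tm)
    hypergeom_upper_tail(as.integer(ktab[[tm]]), as.integer(Ktab[[tm]]),
                         n, N), numeric(1))
  out <- data.frame(term = terms, k = as.integer(ktab[terms]),
                    K = as.integer(Ktab[terms]), n = n, N = N,
                    p = unname(p), stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(out$p_adj, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out$significant <- out$p_adj < alpha
  out
}
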
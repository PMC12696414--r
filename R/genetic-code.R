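# Standard-code codon tables shared by the whole package.
# State space is the 61 sense codons; stops are excluded and can never
# be emitted or read as states.

.codon_cache <- new.env(parent = emptyenv())

#' Codon tables for the standard genetic code
#'
#' Returns the package's shared codon bookkeeping: the 61 sense codons,
#' their amino-acid translations, and the 61 x 61 structural masks used by
#' the GY94 rate matrix (single-position adjacency, transition vs
#' transversion at the differing position, nonsynonymous change).
#'
#' @return A list with elements `codons` (character 61), `aa` (character
#'   61), `adj`, `ts`, `nonsyn` (61 x 61 0/1 matrices), and `stops`.
#' @examples
#' ct <- codon_tables()
#' length(ct$codons)  # 61
#' @export
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  bases <- c("T", "C", "A", "G")
  codons <- sort(as.vector(outer(outer(bases, bases, paste0), bases, paste0)))
  aa <- vapply(codons, function(cd) {
    seqinr::translate(strsplit(tolower(cd), "")[[1]])
  }, character(1))
  sense <- aa != "*"
  stops <- codons[!sense]
  codons <- codons[sense]
  aa <- aa[sense]
  n <- length(codons)
  stopifnot(n == 61L)

  cmat <- do.call(rbind, strsplit(codons, ""))
  purine <- cmat %in% c("A", "G")
  dim(purine) <- dim(cmat)

  adj <- ts <- nonsyn <- matrix(0, n, n, dimnames = list(codons, codons))
  for (pos in 1:3) {
    same_other <- outer(cmat[, -pos][, 1], cmat[, -pos][, 1], "==") &
      outer(cmat[, -pos][, 2], cmat[, -pos][, 2], "==")
    diff_here <- outer(cmat[, pos], cmat[, pos], "!=")
    pair <- same_other & diff_here
    adj[pair] <- 1
    is_ts <- outer(purine[, pos], purine[, pos], "==")
    ts[pair & is_ts] <- 1
  }
  nonsyn[outer(aa, aa, "!=") & adj == 1] <- 1
  diag(adj) <- diag(ts) <- diag(nonsyn) <- 0

  .codon_cache$tab <- list(codons = codons, aa = aa, adj = adj, ts = ts,
                           nonsyn = nonsyn, stops = stops)
  .codon_cache$tab
}

#' Map codon strings to sense-codon state indices
#'
#' Codons containing gaps, `N`, or any IUPAC ambiguity letter — and stop
#' codons, which are not part of the state space — map to `NA` (treated as
#' missing data, i.e. a uniform partial likelihood).
#'
#' @param x character vector of 3-letter codon strings
#' @return integer vector of indices into `codon_tables()$codons`, `NA`
#'   for unresolvable codons.
#' @keywords internal
codon_index <- function(x) {
  ct <- codon_tables()
  match(toupper(x), ct$codons)
}
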
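# CodonAlignment: an in-frame CDS alignment over A/C/G/T, IUPAC
# ambiguity letters, N and '-'.

.IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
.LEGAL_CHARS <- c("A", "C", "G", "T", "N", "-", .IUPAC_AMBIG)

#' Construct a codon alignment
#'
#' @param seqs named character vector of equal-length nucleotide strings;
#'   length must be a multiple of 3. Names are the taxon ids.
#' @return An object of class `codon_alignment`: a named character vector
#'   with the class attribute set, validated on construction.
#' @examples
#' aln <- codon_alignment(c(a = "ATGAAA", b = "ATGAAG"))
#' n_codons(aln)
#' @export
codon_alignment <- function(seqs) {
  if (length(seqs) == 0) stop("alignment must contain at least one sequence")
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("all sequences must be named with taxon ids")
  if (anyDuplicated(names(seqs)))
    stop("duplicated taxon ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1) stop("all rows must have equal length")
  if (len %% 3 != 0) stop("alignment length ", len, " is not a multiple of 3")
  bad <- regexpr(sprintf("[^%s-]", paste(setdiff(.LEGAL_CHARS, "-"),
                                         collapse = "")),
                 seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal character '%s' in sequence '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), names(seqs)[i], bad[i]))
  }
  structure(seqs, class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa, %d codons (%d nt)\n",
              length(x), n_codons(x), nchar(x[[1]])))
  show <- utils::head(unclass(x), 5)
  for (i in seq_along(show))
    cat(sprintf("  %-15s %s%s\n", names(show)[i],
                substr(show[i], 1, 48),
                if (nchar(show[i]) > 48) "..." else ""))
  if (length(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Number of codon columns in an alignment
#' @param aln a `codon_alignment`
#' @export
n_codons <- function(aln) nchar(unclass(aln)[[1]]) %/% 3L

#' Alignment as a character matrix (taxa x nucleotide columns)
#' @param aln a `codon_alignment`
#' @keywords internal
aln_char_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Rebuild a codon alignment from a character matrix
#' @keywords internal
aln_from_matrix <- function(m) {
  codon_alignment(stats::setNames(apply(m, 1, paste, collapse = ""),
                                  rownames(m)))
}

#' Alignment as a matrix of codon strings (taxa x codon columns)
#' @keywords internal
aln_codon_matrix <- function(aln) {
  s <- unclass(aln)
  nc <- n_codons(aln)
  starts <- 3L * (seq_len(nc) - 1L) + 1L
  m <- vapply(s, function(row) substring(row, starts, starts + 2L),
              character(nc))
  m <- t(matrix(m, nrow = nc, dimnames = list(NULL, names(aln))))
  m
}

#' Alignment as integer codon states (taxa x codon columns)
#'
#' Codons with gaps, N, ambiguity letters, or stop codons become `NA`
#' (missing data).
#' @keywords internal
aln_state_matrix <- function(aln) {
  cm <- aln_codon_matrix(aln)
  st <- codon_index(cm)
  dim(st) <- dim(cm)
  rownames(st) <- rownames(cm)
  st
}

#' Read a codon alignment from an aligned FASTA file
#'
#' @param path FASTA file with equal-length, in-frame sequences.
#' @return a `codon_alignment`
#' @export
read_codon_fasta <- function(path) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  codon_alignment(stats::setNames(toupper(unlist(recs)), names(recs)))
}

#' Write a codon alignment to FASTA
#'
#' @param aln a `codon_alignment`
#' @param path output file
#' @export
write_codon_fasta <- function(aln, path) {
  seqinr::write.fasta(as.list(unclass(aln)), names = names(aln),
                      file.out = path, nbchar = 60)
  invisible(path)
}
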
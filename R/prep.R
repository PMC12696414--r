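# Ortholog-retention and alignment-cleaning rules: isoform selection,
# per-life-cycle coverage filtering, codon-aware gappy trimming,
# ambiguity homogenization, and the consensus z-score divergence filter.

#' Alignment-preparation configuration
#'
#' @param min_group_fraction minimum fraction of each life-cycle group
#'   that must be present for an ortholog to be retained (default 0.5;
#'   "at least" a fraction of a count rounds up).
#' @param gappy_max_gapped a codon column is removed when at least this
#'   many rows are gapped in it (default 2: gappyness >= 2/n, keeping
#'   only species-specific gaps).
#' @param z_interval retained z-score interval for the divergence filter.
#' @param divergence_denominator `"comparable"` (sites where the row has
#'   an unambiguous base; default) or `"all"` (every alignment column).
#' @param sd_denominator `"sample"` (n - 1; default) or `"population"`.
#' @return object of class `prep_config`
#' @export
prep_config <- function(min_group_fraction = 0.5, gappy_max_gapped = 2L,
                        z_interval = c(-2.5, 2.5),
                        divergence_denominator = c("comparable", "all"),
                        sd_denominator = c("sample", "population")) {
  stopifnot(min_group_fraction > 0, min_group_fraction <= 1,
            gappy_max_gapped >= 1,
            length(z_interval) == 2, z_interval[1] < z_interval[2])
  structure(list(min_group_fraction = min_group_fraction,
                 gappy_max_gapped = as.integer(gappy_max_gapped),
                 z_interval = z_interval,
                 divergence_denominator = match.arg(divergence_denominator),
                 sd_denominator = match.arg(sd_denominator)),
            class = "prep_config")
}

#' Select the representative isoform of an ortholog
#'
#' Retains the isoform identified in the most query species; ties are
#' broken by greater sequence length, then by lexicographically smallest
#' isoform id.
#'
#' @param isoform_presence named numeric vector: isoform id -> number of
#'   species it was identified in
#' @param isoform_lengths optional named numeric vector of lengths,
#'   used only for tie-breaking
#' @return the selected isoform id.
#' @examples
#' select_isoform(c(A = 20, B = 25))  # "B"
#' @export
select_isoform <- function(isoform_presence, isoform_lengths = NULL) {
  if (length(isoform_presence) == 0) stop("no isoforms supplied")
  ids <- names(isoform_presence)
  if (is.null(ids)) stop("isoform_presence must be named")
  len <- if (is.null(isoform_lengths)) rep(0, length(ids)) else
    isoform_lengths[ids]
  len[is.na(len)] <- 0
  ord <- order(-isoform_presence, -len, ids)
  ids[ord[1]]
}

#' Filter orthologs on per-life-cycle species coverage
#'
#' Retains orthologs present in at least
#' `ceiling(min_group_fraction * group size)` species of EACH life-cycle
#' group.
#'
#' @param alignments named list of `codon_alignment` objects
#' @param traits named trait vector covering every taxon that occurs
#' @param config a [prep_config()]
#' @param group_sizes named total group sizes (default: tabulated from
#'   `traits`)
#' @return the retained sub-list, with attribute `removed` naming the
#'   dropped orthologs.
#' @export
coverage_filter <- function(alignments, traits, config = prep_config(),
                            group_sizes = table(traits)) {
  need <- ceiling(config$min_group_fraction * group_sizes)
  keep <- vapply(alignments, function(aln) {
    taxa <- names(aln)
    unknown <- setdiff(taxa, names(traits))
    if (length(unknown))
      stop("taxon missing from trait table: ",
           paste(unknown, collapse = ", "))
    have <- table(factor(traits[taxa], levels = names(group_sizes)))
    all(have >= need)
  }, logical(1))
  structure(alignments[keep], removed = names(alignments)[!keep])
}

# gapped-row count per codon column ('-' at any of its 3 positions)
.codon_gap_counts <- function(m) {
  nc <- ncol(m) %/% 3L
  vapply(seq_len(nc), function(j) {
    cols <- 3L * (j - 1L) + 1:3
    sum(apply(m[, cols, drop = FALSE] == "-", 1, any))
  }, numeric(1))
}

#' Trim gappy codon columns
#'
#' Removes whole codon columns in which the number of gapped sequences is
#' at least `gappy_max_gapped` (default 2, i.e. gappyness >= 2/n), so
#' only species-specific gaps survive. A sequence is gapped in a codon
#' column if any of its three positions is `-`; the reading frame is
#' always preserved.
#'
#' @param aln a `codon_alignment`
#' @param config a [prep_config()]
#' @return trimmed `codon_alignment` with attribute `removed_codons`.
#' @export
trim_codon_gappy <- function(aln, config = prep_config()) {
  m <- aln_char_matrix(aln)
  gc <- .codon_gap_counts(m)
  drop <- gc >= config$gappy_max_gapped
  if (!any(drop)) return(structure(aln, removed_codons = 0L))
  keep_nt <- rep(!drop, each = 3L)
  out <- aln_from_matrix(m[, keep_nt, drop = FALSE])
  structure(out, removed_codons = sum(drop))
}

#' Replace IUPAC ambiguity codes with N
#'
#' Every ambiguity letter (R, Y, S, W, K, M, B, D, H, V) becomes `N`;
#' A/C/G/T, `N` and `-` are unchanged. Illegal characters are rejected
#' with their position (by the alignment constructor).
#'
#' @param aln a `codon_alignment`
#' @return homogenized `codon_alignment`.
#' @examples
#' homogenize_ambiguities(codon_alignment(c(x = "ATR")))  # "ATN"
#' @export
homogenize_ambiguities <- function(aln) {
  s <- unclass(aln)
  s[] <- chartr(paste(.IUPAC_AMBIG, collapse = ""),
                strrep("N", length(.IUPAC_AMBIG)), s)
  codon_alignment(s)
}

#' Consensus sequence of an alignment
#'
#' Per column, the most common nucleotide among A/C/G/T, ignoring gaps
#' and N; ties are broken alphabetically; columns with no unambiguous
#' base give `N`.
#'
#' @param aln a `codon_alignment`
#' @return single character string.
#' @export
consensus_sequence <- function(aln) {
  m <- aln_char_matrix(aln)
  bases <- c("A", "C", "G", "T")
  cons <- apply(m, 2, function(col) {
    tab <- table(factor(col[col %in% bases], levels = bases))
    if (sum(tab) == 0) return("N")
    names(tab)[which.max(tab)]     # which.max takes the first = alphabetical
  })
  paste(cons, collapse = "")
}

#' Divergence z-score filter
#'
#' Each row's divergence rate is its mismatch count against the consensus
#' over its comparable sites (columns where the row has an unambiguous
#' base; set `divergence_denominator = "all"` in the config for the
#' all-columns convention). Rows whose z-score — (d - mean d) / sd(d),
#' sample sd by default — falls outside `z_interval` are removed. With
#' fewer than 3 rows the filter is skipped with a warning; with sd = 0
#' nothing is removed.
#'
#' @param aln a `codon_alignment`
#' @param config a [prep_config()]
#' @return list with `alignment` (filtered) and `report` (a data frame
#'   with divergence, z and removed flags, plus attributes `mean`, `sd`,
#'   `skipped`).
#' @export
divergence_zscore_filter <- function(aln, config = prep_config()) {
  m <- aln_char_matrix(aln)
  if (nrow(m) < 3) {
    warning("fewer than 3 sequences: divergence filter skipped")
    rep <- data.frame(taxon = rownames(m), divergence = NA_real_,
                      z = NA_real_, removed = FALSE)
    attr(rep, "skipped") <- TRUE
    return(list(alignment = aln, report = rep))
  }
  cons <- strsplit(consensus_sequence(aln), "")[[1]]
  bases <- c("A", "C", "G", "T")
  d <- apply(m, 1, function(row) {
    comparable <- row %in% bases
    denom <- if (config$divergence_denominator == "comparable")
      sum(comparable) else length(row)
    if (denom == 0) return(0)
    sum(comparable & row != cons) / denom
  })
  mu <- mean(d)
  sdv <- if (config$sd_denominator == "sample") stats::sd(d) else
    sqrt(mean((d - mu)^2))
  z <- if (is.na(sdv) || sdv == 0) rep(0, length(d)) else (d - mu) / sdv
  removed <- z < config$z_interval[1] | z > config$z_interval[2]
  rep <- data.frame(taxon = rownames(m), divergence = d, z = z,
                    removed = removed, row.names = NULL)
  attr(rep, "mean") <- mu
  attr(rep, "sd") <- sdv
  attr(rep, "skipped") <- FALSE
  out <- if (any(removed))
    aln_from_matrix(m[!removed, , drop = FALSE]) else aln
  list(alignment = out, report = rep)
}

#' Run the fixed cleaning pipeline on one ortholog alignment
#'
#' Stage order is fixed: codon-gappy trimming, ambiguity homogenization,
#' then the divergence z-score filter. (Isoform selection and coverage
#' filtering operate across orthologs, before this point.) Stages only
#' remove rows or columns; no surviving base is edited except by
#' ambiguity homogenization.
#'
#' @param aln a `codon_alignment`
#' @param config a [prep_config()]
#' @return list with `alignment` and `report` (per-stage removal counts
#'   plus the divergence report).
#' @export
prep_alignment <- function(aln, config = prep_config()) {
  n0 <- length(aln)
  trimmed <- trim_codon_gappy(aln, config)
  homog <- homogenize_ambiguities(trimmed)
  zf <- divergence_zscore_filter(homog, config)
  list(alignment = zf$alignment,
       report = list(n_sequences_in = n0,
                     codon_columns_removed = attr(trimmed, "removed_codons"),
                     sequences_removed = sum(zf$report$removed),
                     removal_fraction = sum(zf$report$removed) / n0,
                     divergence = zf$report))
}
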
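# LabeledTree: a rooted phylogeny (ape "phylo") whose tips carry a
# life-cycle trait. Terminal branches inherit the class of their tip
# (mono_terminal / het_terminal); internal branches are background.

.TRAITS <- c("monoecious", "heteroecious")

#' Construct a labeled tree
#'
#' @param phy a rooted, binary `ape::phylo` with branch lengths (expected
#'   substitutions per codon).
#' @param traits named character vector mapping every tip label to
#'   `"monoecious"` or `"heteroecious"`.
#' @return object of class `labeled_tree`: list with elements `phy` and
#'   `traits`.
#' @export
labeled_tree <- function(phy, traits) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape 'phylo' tree")
  if (is.null(phy$edge.length)) stop("tree must have branch lengths")
  if (any(phy$edge.length < 0)) stop("branch lengths must be non-negative")
  missing <- setdiff(phy$tip.label, names(traits))
  if (length(missing))
    stop("tips missing from trait table: ", paste(missing, collapse = ", "))
  traits <- traits[phy$tip.label]
  bad <- !traits %in% .TRAITS
  if (any(bad))
    stop("unknown trait value(s): ", paste(unique(traits[bad]), collapse = ", "),
         " (expected monoecious/heteroecious)")
  structure(list(phy = phy, traits = traits), class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  tab <- table(x$traits)
  cat(sprintf("labeled_tree: %d tips (%s), %d edges\n",
              length(x$phy$tip.label),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$phy$edge)))
  invisible(x)
}

#' Branch classes of a labeled tree
#'
#' Assigns every edge of the tree to a branch class: terminal branches get
#' `mono_terminal` or `het_terminal` from their tip's life-cycle trait and
#' all internal branches are `background`.
#'
#' @param tree a `labeled_tree`
#' @return character vector, one class per row of `tree$phy$edge`.
#' @export
branch_classes <- function(tree) {
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  cls <- rep("background", nrow(phy$edge))
  term <- child <= ntip
  tr <- tree$traits[phy$tip.label[child[term]]]
  cls[term] <- ifelse(tr == "monoecious", "mono_terminal", "het_terminal")
  cls
}

#' Partition tree branches by life-cycle class
#'
#' The branch partition behind the two- and three-ratio branch models:
#' terminal branches are classed by the life cycle of the species they
#' lead to, and every internal branch is background.
#'
#' @param tree a `labeled_tree`, or an `ape::phylo` if `traits` is given.
#' @param traits optional named trait vector (used when `tree` is a bare
#'   `phylo`).
#' @return object of class `branch_partition`: character vector of classes
#'   (one per edge) with a `counts` attribute.
#' @examples
#' tr <- build_labeled_tree(sim_config(n_taxa_mono = 4, n_taxa_het = 4))
#' table(partition_branches(tr))
#' @export
partition_branches <- function(tree, traits = NULL) {
  if (!inherits(tree, "labeled_tree")) {
    if (is.null(traits)) stop("traits required when tree is not labeled")
    tree <- labeled_tree(tree, traits)
  }
  cls <- branch_classes(tree)
  structure(cls, counts = table(cls), class = "branch_partition")
}

#' Read a labeled tree from Newick + trait TSV
#'
#' @param newick_path rooted Newick file with branch lengths
#' @param traits_path TSV with columns `species_id`, `life_cycle`
#' @export
read_labeled_tree <- function(newick_path, traits_path) {
  phy <- ape::read.tree(newick_path)
  traits <- read_trait_table(traits_path)
  labeled_tree(phy, traits)
}

#' Read a species-to-life-cycle trait table
#'
#' @param path TSV with columns `species_id` and `life_cycle`
#' @return named character vector
#' @export
read_trait_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "life_cycle") %in% names(df)))
    stop("trait table needs columns species_id, life_cycle")
  stats::setNames(df$life_cycle, df$species_id)
}

#' Write a trait table as TSV
#' @param traits named character vector
#' @param path output TSV
#' @export
write_trait_table <- function(traits, path) {
  utils::write.table(
    data.frame(species_id = names(traits), life_cycle = unname(traits)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
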
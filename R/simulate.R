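# Seeded codon-evolution simulator. Generates labeled trees, codon
# alignments evolved under branch-class-specific omega (optionally a
# three-category site model with a selection-intensity exponent k on test
# branches), plus artifact injectors (divergent sequences, gap columns,
# ambiguity codes) that exercise every cleaning filter.

#' Simulation configuration
#'
#' Defaults are the study conditions the downstream tests assume: a
#' balanced 8-tip tree (4 monoecious + 4 heteroecious), kappa = 2, uniform
#' sense-codon frequencies, and per-class dN/dS set to the reported
#' per-class medians (monoecious terminal 0.1116, background 0.0849,
#' heteroecious terminal 0.0605).
#'
#' @param n_taxa_mono,n_taxa_het numbers of monoecious / heteroecious tips
#' @param tree_shape `"balanced"` (total tips must be a power of 2) or
#'   `"random-yule"`
#' @param terminal_bl,internal_bl branch lengths, expected substitutions
#'   per codon under the branch's own class omega
#' @param n_codons alignment length in codons (>= 1)
#' @param kappa transition/transversion ratio (> 0)
#' @param codon_freqs positive 61-vector summing to 1
#' @param omega_by_class named vector with entries `background`,
#'   `mono_terminal`, `het_terminal` (all >= 0)
#' @param relax_scenario optional list
#'   `list(omega = c(w1 <= w2 <= w3), props = p (sums to 1), k, test_class)`;
#'   site categories are drawn once at the root and held fixed across
#'   branches, and branches of `test_class` use `omega^k`.
#' @param contamination optional list `list(n, prob)`: append `n`
#'   divergent copies with per-site substitution probability `prob`
#' @param gap_injection optional list of `list(codon, rows)` entries:
#'   gap out codon column `codon` in the given row indices
#' @param ambiguity_injection per-site probability of replacing a base
#'   with a random IUPAC ambiguity letter
#' @param seed integer seed; every simulation is reproducible from
#'   (config, seed)
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_taxa_mono = 4, n_taxa_het = 4,
                       tree_shape = c("balanced", "random-yule"),
                       terminal_bl = 0.2, internal_bl = 0.1,
                       n_codons = 400, kappa = 2,
                       codon_freqs = uniform_codon_freqs(),
                       omega_by_class = c(background = 0.0849,
                                          mono_terminal = 0.1116,
                                          het_terminal = 0.0605),
                       relax_scenario = NULL,
                       contamination = NULL,
                       gap_injection = NULL,
                       ambiguity_injection = 0,
                       seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa_mono >= 0, n_taxa_het >= 0, n_codons >= 1, kappa > 0,
            terminal_bl >= 0, internal_bl >= 0,
            ambiguity_injection >= 0, ambiguity_injection <= 1)
  codon_freqs <- check_codon_freqs(codon_freqs)
  req <- c("background", "mono_terminal", "het_terminal")
  if (!all(req %in% names(omega_by_class)))
    stop("omega_by_class needs entries: ", paste(req, collapse = ", "))
  if (any(omega_by_class < 0)) stop("omega values must be >= 0")
  if (!is.null(relax_scenario)) {
    rs <- relax_scenario
    stopifnot(length(rs$omega) == length(rs$props))
    if (is.unsorted(rs$omega)) stop("relax_scenario$omega must be sorted")
    if (abs(sum(rs$props) - 1) > 1e-12)
      stop("relax_scenario$props must sum to 1")
    if (any(rs$props < 0) || any(rs$omega < 0))
      stop("relax_scenario values must be non-negative")
    if (is.null(rs$k) || rs$k < 0) stop("relax_scenario$k must be >= 0")
    if (is.null(rs$test_class)) rs$test_class <- "mono_terminal"
    relax_scenario <- rs
  }
  if (!is.null(contamination)) {
    if (is.null(contamination$prob) || contamination$prob < 0 ||
        contamination$prob > 1)
      stop("contamination probability must lie in [0, 1]")
    if (is.null(contamination$n) || contamination$n < 0)
      stop("contamination n must be >= 0")
  }
  structure(list(n_taxa_mono = n_taxa_mono, n_taxa_het = n_taxa_het,
                 tree_shape = tree_shape, terminal_bl = terminal_bl,
                 internal_bl = internal_bl, n_codons = as.integer(n_codons),
                 kappa = kappa, codon_freqs = codon_freqs,
                 omega_by_class = omega_by_class,
                 relax_scenario = relax_scenario,
                 contamination = contamination,
                 gap_injection = gap_injection,
                 ambiguity_injection = ambiguity_injection,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a labeled tree for a simulation configuration
#'
#' Tips are named `mono_i` / `het_i` and interleaved along the tip order
#' so both life cycles are spread across the tree (multiple apparent
#' transitions, as in the aphid phylogeny). Terminal branches get
#' `terminal_bl`, internal branches `internal_bl`.
#'
#' @param config a [sim_config()]
#' @return a `labeled_tree`
#' @export
build_labeled_tree <- function(config) {
  n <- config$n_taxa_mono + config$n_taxa_het
  if (n < 3) stop("invalid configuration: need at least 3 taxa in total")
  phy <- if (config$tree_shape == "balanced") {
    if (log2(n) %% 1 != 0)
      stop("balanced shape needs a power-of-2 number of tips")
    ape::stree(n, type = "balanced")
  } else {
    set.seed(config$seed)
    ape::rphylo(n, birth = 1, death = 0)
  }
  ntip <- length(phy$tip.label)
  phy$edge.length <- ifelse(phy$edge[, 2] <= ntip,
                            config$terminal_bl, config$internal_bl)
  lab <- character(n)
  take_mono <- rep(c(TRUE, FALSE), length.out = n)
  n_m <- config$n_taxa_mono
  if (sum(take_mono) > n_m) take_mono[which(take_mono)[-seq_len(n_m)]] <- FALSE
  if (sum(take_mono) < n_m) take_mono[which(!take_mono)[seq_len(n_m - sum(take_mono))]] <- TRUE
  lab[take_mono] <- paste0("mono_", seq_len(sum(take_mono)))
  lab[!take_mono] <- paste0("het_", seq_len(sum(!take_mono)))
  phy$tip.label <- lab
  traits <- stats::setNames(ifelse(take_mono, "monoecious", "heteroecious"),
                            lab)
  labeled_tree(phy, traits)
}

# omega applying on one edge for one site category, honoring the
# relax scenario's k exponent on its test branches.
.sim_edge_omega <- function(config, cls) {
  rs <- config$relax_scenario
  if (is.null(rs)) return(rep(config$omega_by_class[[cls]], 1))
  w <- rs$omega
  if (cls == rs$test_class) w <- w^rs$k
  w
}

#' Simulate a codon alignment on a labeled tree
#'
#' The root sequence is drawn from `codon_freqs`; each branch evolves
#' sites with `P = exp(Q t)` under that branch class's omega (or, in a
#' relax scenario, the site category's omega, raised to `k` on test
#' branches; categories are drawn once at the root and held fixed). Stop
#' codons are never produced — they are outside the state space.
#'
#' @param tree a `labeled_tree`
#' @param config a [sim_config()]
#' @return a `codon_alignment` over the tree's tips.
#' @export
simulate_alignment <- function(tree, config) {
  set.seed(config$seed)
  ct <- codon_tables()
  phy <- ape::reorder.phylo(tree$phy, "cladewise")   # preorder traversal
  cls <- branch_classes(labeled_tree(phy, tree$traits))
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  nsites <- config$n_codons
  pi <- config$codon_freqs

  rs <- config$relax_scenario
  ncat <- if (is.null(rs)) 1L else length(rs$omega)
  site_cat <- if (ncat == 1L) rep(1L, nsites) else
    sample.int(ncat, nsites, replace = TRUE, prob = rs$props)

  states <- matrix(NA_integer_, nnode, nsites)
  states[root, ] <- sample.int(61L, nsites, replace = TRUE, prob = pi)

  classes_present <- unique(cls)
  miss <- setdiff(classes_present, names(config$omega_by_class))
  if (length(miss))
    stop("configuration error: branch class without omega: ",
         paste(miss, collapse = ", "))

  # cache P by (class, category, t)
  Pcache <- new.env(parent = emptyenv())
  getP <- function(cl, cat, t) {
    key <- paste(cl, cat, t)
    if (!is.null(Pcache[[key]])) return(Pcache[[key]])
    w <- .sim_edge_omega(config, cl)[cat]
    Q <- cpp_build_Q(config$kappa, w, pi, ct$adj, ct$ts, ct$nonsyn)
    eg <- cpp_eigen_system(Q, pi)
    P <- cpp_transition(eg$left, eg$right, eg$values, t)
    P <- P / rowSums(P)
    Pcache[[key]] <- P
    P
  }

  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    t <- phy$edge.length[e]
    parent <- states[par, ]
    child <- parent
    if (t > 0) {
      for (cat in unique(site_cat)) {
        P <- getP(cls[e], cat, t)
        idx <- which(site_cat == cat)
        for (s in unique(parent[idx])) {
          here <- idx[parent[idx] == s]
          child[here] <- sample.int(61L, length(here), replace = TRUE,
                                    prob = P[s, ])
        }
      }
    }
    states[ch, ] <- child
  }

  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(row)
    paste(ct$codons[row], collapse = ""))
  codon_alignment(stats::setNames(seqs, phy$tip.label))
}

#' Inject cleaning-filter artifacts into an alignment
#'
#' Appends `contamination$n` divergent copies of the first row (per-site
#' substitution to a random different base with probability
#' `contamination$prob`), gaps out whole codon columns per the
#' `gap_injection` plan, and replaces bases with random IUPAC ambiguity
#' letters at rate `ambiguity_injection`. Original rows are never edited
#' except by the explicit gap/ambiguity plans; with all plans empty the
#' alignment is returned unchanged.
#'
#' @param aln a `codon_alignment`
#' @param config a [sim_config()]
#' @return a `codon_alignment`
#' @export
inject_artifacts <- function(aln, config) {
  set.seed(config$seed + 10657L)
  m <- aln_char_matrix(aln)
  cont <- config$contamination
  if (!is.null(cont) && cont$n > 0) {
    for (i in seq_len(cont$n)) {
      row <- m[1, ]
      hit <- stats::runif(length(row)) < cont$prob & row %in% c("A", "C", "G", "T")
      row[hit] <- vapply(row[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      m <- rbind(m, row)
      rownames(m)[nrow(m)] <- paste0("divergent_", i)
    }
  }
  for (plan in config$gap_injection) {
    cols <- 3L * (plan$codon - 1L) + 1:3
    m[plan$rows, cols] <- "-"
  }
  if (config$ambiguity_injection > 0) {
    hit <- matrix(stats::runif(length(m)) < config$ambiguity_injection,
                  nrow(m)) & m %in% c("A", "C", "G", "T")
    dim(hit) <- dim(m)
    m[hit] <- sample(.IUPAC_AMBIG, sum(hit), replace = TRUE)
  }
  aln_from_matrix(m)
}

#' Simulate a full dataset (tree, alignment, traits, truth)
#'
#' @param config a [sim_config()]
#' @return object of class `sim_dataset` with elements `alignment`,
#'   `tree`, `traits`, `truth` (the config used).
#' @export
simulate_dataset <- function(config) {
  tree <- build_labeled_tree(config)
  aln <- simulate_alignment(tree, config)
  aln <- inject_artifacts(aln, config)
  structure(list(alignment = aln, tree = tree, traits = tree$traits,
                 truth = config),
            class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Emits `alignment.fasta`, `tree.nwk`, `traits.tsv` and `truth.json`
#' into `out_dir` and returns a manifest of files with md5 checksums.
#'
#' @param dataset a `sim_dataset`
#' @param out_dir writable output directory (created if absent)
#' @return data frame with columns `file`, `md5`.
#' @export
write_fixture <- function(dataset, out_dir) {
  if (length(dataset$alignment) == 0)
    stop("refusing to write an empty alignment")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir,
                     c("alignment.fasta", "tree.nwk", "traits.tsv",
                       "truth.json"))
  write_codon_fasta(dataset$alignment, paths[1])
  ape::write.tree(dataset$tree$phy, paths[2])
  write_trait_table(dataset$traits, paths[3])
  truth <- dataset$truth
  truth$codon_freqs <- as.list(truth$codon_freqs)
  truth$omega_by_class <- as.list(truth$omega_by_class)
  jsonlite::write_json(unclass(truth), paths[4], auto_unbox = TRUE,
                       digits = NA, null = "null")
  data.frame(file = basename(paths),
             md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir the fixture directory
#' @return a list with `alignment`, `tree`, `traits`, `truth`.
#' @export
read_fixture <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  tree <- read_labeled_tree(file.path(dir, "tree.nwk"),
                            file.path(dir, "traits.tsv"))
  list(alignment = read_codon_fasta(file.path(dir, "alignment.fasta")),
       tree = tree, traits = tree$traits, truth = truth)
}
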
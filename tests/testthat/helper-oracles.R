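# Independent oracles and small fixture builders shared across tests.

# Rooted 3-taxon tree ((t1,t2),t3) with chosen branch lengths and traits.
three_taxon_tree <- function(t1 = 0.2, t2 = 0.3, t12 = 0.15, t3 = 0.4) {
  phy <- ape::read.tree(
    text = sprintf("((t1:%g,t2:%g):%g,t3:%g);", t1, t2, t12, t3))
  labeled_tree(phy, c(t1 = "monoecious", t2 = "heteroecious",
                      t3 = "monoecious"))
}

# Brute-force log-likelihood for the 3-taxon tree by explicit summation
# over all 61 x 61 assignments of the two internal nodes. Deliberately
# naive; independent of the pruning recursion.
brute_force_loglik_3tax <- function(tree, aln, kappa, omega_by_class, pi) {
  ct <- codon_tables()
  phy <- tree$phy
  cls <- branch_classes(tree)
  E <- phy$edge
  P <- lapply(seq_len(nrow(E)), function(e) {
    Q <- build_rate_matrix(kappa, omega_by_class[[cls[e]]], pi)
    transition_matrix(Q, phy$edge.length[e], pi)
  })
  st <- aln_states_by_tip(aln, phy$tip.label)
  root <- length(phy$tip.label) + 1L
  total <- 0
  for (s in seq_len(ncol(st))) {
    acc <- 0
    for (r in 1:61) {
      for (u in 1:61) {
        pr <- pi[r]
        for (e in seq_len(nrow(E))) {
          par <- E[e, 1]; ch <- E[e, 2]
          from <- if (par == root) r else u
          pr <- pr * if (ch <= 3) {
            tipst <- st[ch, s]
            if (is.na(tipst)) sum(P[[e]][from, ]) else P[[e]][from, tipst]
          } else P[[e]][from, u]
        }
        acc <- acc + pr
      }
    }
    total <- total + log(acc)
  }
  total
}

# Brute-force likelihood for the 4-taxon tree ((t1,t2),(t3,t4)):
# enumerates all 61^3 internal assignments (root r, cherry nodes u, v);
# the innermost v sum is carried out as an explicit term-by-term vector
# sum. Independent of the pruning recursion.
brute_force_loglik_4tax <- function(tree, aln, kappa, omega_by_class, pi) {
  phy <- tree$phy
  cls <- branch_classes(tree)
  E <- phy$edge
  P <- lapply(seq_len(nrow(E)), function(e) {
    Q <- build_rate_matrix(kappa, omega_by_class[[cls[e]]], pi)
    transition_matrix(Q, phy$edge.length[e], pi)
  })
  findP <- function(par, ch) P[[which(E[, 1] == par & E[, 2] == ch)]]
  st <- aln_states_by_tip(aln, phy$tip.label)
  root <- 5L
  u_node <- E[E[, 2] == 1L, 1]   # cherry above t1/t2
  v_node <- E[E[, 2] == 3L, 1]   # cherry above t3/t4
  Pru <- findP(root, u_node); Prv <- findP(root, v_node)
  Pu1 <- findP(u_node, 1L); Pu2 <- findP(u_node, 2L)
  Pv3 <- findP(v_node, 3L); Pv4 <- findP(v_node, 4L)
  total <- 0
  for (s in seq_len(ncol(st))) {
    acc <- 0
    vterm <- Pv3[, st[3, s]] * Pv4[, st[4, s]]   # one entry per v
    for (r in 1:61) for (u in 1:61) {
      left <- pi[r] * Pru[r, u] * Pu1[u, st[1, s]] * Pu2[u, st[2, s]]
      acc <- acc + left * sum(Prv[r, ] * vterm)
    }
    total <- total + log(acc)
  }
  total
}

# tip-ordered codon state matrix (rows follow `tips`)
aln_states_by_tip <- function(aln, tips) {
  cm <- do.call(rbind, lapply(unclass(aln)[tips], function(s) {
    nc <- nchar(s) %/% 3
    starts <- 3 * (seq_len(nc) - 1) + 1
    cyclerelax:::codon_index(substring(s, starts, starts + 2))
  }))
  rownames(cm) <- tips
  cm
}

# Exact hypergeometric upper tail by combinatorial summation.
hyper_upper_exact <- function(k, K, n, N) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Dirichlet draw for random codon frequencies.
rdirichlet1 <- function(n, alpha = 5) {
  x <- stats::rgamma(n, alpha)
  x / sum(x)
}
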
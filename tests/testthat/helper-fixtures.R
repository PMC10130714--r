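# Shared helpers for the test suite: small random instances with known
# structure, and a brute-force PD implementation independent of the
# package's edge-matrix machinery.

# random ultrametric tree via the package's own Yule generator would be
# circular for tree tests, so use ape's independent coalescent simulator
randomUltrametricTree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n, tip.label = sprintf("t%02d", seq_len(n)))
  validateTimeTree(tree)
}

# random PresenceGrid over a tree's tips; every species guaranteed >= 1 cell
randomGrid <- function(tree, nCellsWanted = 6, seed = 1, fill = 0.4) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  P <- matrix(as.numeric(stats::runif(nCellsWanted * n) < fill),
              nCellsWanted, n,
              dimnames = list(sprintf("c%02d", seq_len(nCellsWanted)),
                              tree$tip.label))
  for (j in which(colSums(P) == 0)) P[sample.int(nCellsWanted, 1), j] <- 1
  coords <- data.frame(lat = seq(8.5, by = 1, length.out = nCellsWanted),
                       lon = rep(76, nCellsWanted))
  PresenceGrid(P, coords)
}

# brute-force rooted PD: total length of the induced root-anchored subtree,
# built by walking tip-to-root paths on the raw edge matrix
bruteForcePD <- function(tree, species) {
  if (length(species) == 0) return(0)
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  used <- logical(nrow(tree$edge))
  for (s in species) {
    node <- match(s, tree$tip.label)
    repeat {
      e <- match(node, child)
      if (is.na(e) || used[e]) break
      used[e] <- TRUE
      node <- parent[e]
    }
  }
  sum(tree$edge.length[used])
}

# brute-force PE: every used branch contributes length / (number of cells
# where any of its descendant tips occurs)
bruteForcePE <- function(tree, P) {
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  nEdge <- nrow(tree$edge)
  descend <- function(node) {
    if (node <= ape::Ntip(tree)) return(tree$tip.label[node])
    unlist(lapply(child[parent == node], descend))
  }
  tipsOf <- lapply(seq_len(nEdge), function(e) descend(child[e]))
  out <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    sp <- colnames(P)[P[i, ] > 0]
    for (e in seq_len(nEdge)) {
      hit <- intersect(tipsOf[[e]], colnames(P))
      if (length(intersect(hit, sp)) == 0) next
      rng <- sum(apply(P[, hit, drop = FALSE] > 0, 1, any))
      out[i] <- out[i] + tree$edge.length[e] / rng
    }
  }
  out
}
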
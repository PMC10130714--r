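#' Slice an ultrametric tree at an evolutionary depth
#'
#' A "lineage" at depth t is a branch of the tree that crosses t, using the
#' half-open convention childAge <= t < parentAge. Each lineage carries the
#' set of extant species descending from it; at any one depth these sets
#' partition the tip set. At the exact root age (where no branch crosses,
#' since the root has no parent branch) the branches incident to the root
#' are returned, so basal splits that coincide with the root age are still
#' representable as the root's child lineages.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param t slicing depth in Myr, 0 <= t <= root age.
#' @param tol numeric fuzz (relative to root age) used when comparing ages.
#' @return a [LineageSlice-class] object.
#' @examples
#' fx <- makeToyFixture()
#' lineageCount(sliceLineages(fx$tree, 1.5))  # 2 lineages: {A,B} and {C}
#' @export
sliceLineages <- function(tree, t, tol = 1e-8) {
  T <- rootAge(tree)
  eps <- tol * max(T, 1)
  if (t < -eps || t > T + eps)
    stop(sprintf("slice depth %g outside [0, root age %g]", t, T))
  bt <- branchTable(tree)
  if (abs(t - T) <= eps) {
    rootNode <- ape::Ntip(tree) + 1L
    keep <- which(bt$parent == rootNode)
  } else {
    keep <- which(bt$childAge <= t + eps & bt$parentAge > t + eps)
  }
  etm <- .edgeTipMatrix(tree)
  tips <- lapply(keep, function(e) tree$tip.label[etm[e, ]])
  lin <- bt[keep, c("edge", "parentAge", "childAge")]
  lin$nTips <- lengths(tips)
  rownames(lin) <- NULL
  new("LineageSlice", depth = t, lineages = lin, tips = tips)
}

#' Lineage-through-time counts
#'
#' Number of branches of the extant tree crossing each requested past time
#' point; non-increasing as the depth grows, equal to the tip count at t = 0
#' and to the number of root children at t = root age.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param times numeric vector of depths in Myr, all within [0, root age].
#' @return integer vector of lineage counts, one per time.
#' @export
lttCounts <- function(tree, times) {
  vapply(times, function(t) lineageCount(sliceLineages(tree, t)), integer(1))
}
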
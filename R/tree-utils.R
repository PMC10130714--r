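#' @importFrom ape read.tree write.tree Ntip Nnode
NULL

#' Root age of an ultrametric tree
#'
#' Age is measured backward from the present: extant tips sit at age 0 and
#' the root at the maximum root-to-tip path length (in the tree's branch
#' length unit, Myr throughout this package).
#'
#' @param tree an ape `phylo` object with branch lengths.
#' @return the root age (max root-to-tip distance).
#' @export
rootAge <- function(tree) {
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Node ages of a time-calibrated tree
#'
#' @param tree an ape `phylo` object with branch lengths.
#' @return numeric vector of ages (Myr before present) indexed by node id
#'   (tips first, then internal nodes, ape convention).
#' @export
nodeAges <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' Validate a time-calibrated ultrametric phylogeny
#'
#' Checks that the tree is rooted, binary-or-multifurcating with a single
#' root, has non-negative branch lengths, unique tip labels, and is
#' ultrametric: all root-to-tip path lengths equal within a relative
#' tolerance. Trees failing the tolerance are rejected, not rescaled.
#'
#' @param tree an ape `phylo` object.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return the tree, invisibly, if valid; otherwise an error naming the
#'   worst-offending tip.
#' @export
validateTimeTree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  # a phylo object has exactly one parentless node; a basal polytomy is a
  # legitimate rooted shape for a time tree, so ape::is.rooted (which would
  # reject it) is deliberately not used here
  if (length(setdiff(tree$edge[, 1], tree$edge[, 2])) != 1)
    stop("tree must have exactly one root")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  T <- max(depths)
  dev <- abs(depths - T)
  if (T > 0 && max(dev) / T > tol) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric within relative tolerance %g: tip '%s' has root-to-tip path %.8g vs root age %.8g",
      tol, tree$tip.label[worst], depths[worst], T))
  }
  invisible(tree)
}

#' Read a time-calibrated tree from a Newick file
#'
#' Parses a Newick file (branch lengths mandatory, internal labels optional
#' and preserved) and validates it with [validateTimeTree()].
#'
#' @param path path to a Newick file.
#' @param tol relative ultrametricity tolerance passed to [validateTimeTree()].
#' @return a validated `phylo` object.
#' @export
readTimeTree <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  off <- .newickSyntaxOffset(txt)
  if (!is.na(off))
    stop(sprintf("malformed Newick in '%s' near character offset %d", path, off))
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop(sprintf("malformed Newick in '%s' (offset <= %d)", path, nchar(txt)))
  validateTimeTree(tree, tol = tol)
  tree
}

# first character offset at which the parenthesis structure of a Newick
# string is provably broken, or NA if balanced and ';'-terminated
.newickSyntaxOffset <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  if (!grepl(";", txt)) return(length(chars))
  NA_integer_
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @param digits significant digits for branch lengths (default 12, enough
#'   for lossless round-trips of simulated trees).
#' @export
writeTimeTree <- function(tree, path, digits = 12) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Branch bookkeeping table
#'
#' One row per edge with parent/child node ids, branch length, and the ages
#' (Myr before present) of both end nodes.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return data.frame with columns edge, parent, child, length, parentAge,
#'   childAge.
#' @export
branchTable <- function(tree) {
  ages <- nodeAges(tree)
  data.frame(
    edge      = seq_len(nrow(tree$edge)),
    parent    = tree$edge[, 1],
    child     = tree$edge[, 2],
    length    = tree$edge.length,
    parentAge = ages[tree$edge[, 1]],
    childAge  = ages[tree$edge[, 2]]
  )
}

# logical nEdge x nTip incidence: does tip j descend from edge e (i.e. from
# the child node of e)? Computed by one postorder sweep.
.edgeTipMatrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  nodeTips <- matrix(FALSE, ntip + nnode, ntip)
  nodeTips[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    nodeTips[p, ] <- nodeTips[p, ] | nodeTips[ch, ]
  }
  out <- nodeTips[tree$edge[, 2], , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

#' Induced subtree spanning a species set and the root
#'
#' Returns the subtree made of all branches on the paths from the named tips
#' to the global root. Branch lengths are preserved and degree-2 internal
#' nodes are NOT collapsed, so the root path is retained; this is the
#' subtree whose total branch length is rooted Faith's PD.
#'
#' @param tree a `phylo` object.
#' @param species character vector of tip labels (non-empty subset).
#' @return a `phylo` object (possibly containing degree-2 nodes).
#' @export
inducedSubtree <- function(tree, species) {
  species <- unique(as.character(species))
  if (length(species) == 0) stop("species set must be non-empty")
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  etm <- .edgeTipMatrix(tree)
  keep <- which(rowSums(etm[, species, drop = FALSE]) > 0)
  ntip <- ape::Ntip(tree)
  rootNode <- ntip + 1L
  edges <- tree$edge[keep, , drop = FALSE]
  keptTips <- sort(match(species, tree$tip.label))
  keptInternal <- sort(setdiff(unique(c(edges)), keptTips))
  # new ids: tips 1..k in original tip order, then root, then other internals
  keptInternal <- c(rootNode, setdiff(keptInternal, rootNode))
  newId <- integer(ntip + tree$Nnode)
  newId[keptTips] <- seq_along(keptTips)
  newId[keptInternal] <- length(keptTips) + seq_along(keptInternal)
  out <- list(
    edge        = cbind(newId[edges[, 1]], newId[edges[, 2]]),
    edge.length = tree$edge.length[keep],
    tip.label   = tree$tip.label[keptTips],
    Nnode       = length(keptInternal)
  )
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  out
}

#' Total branch length of a tree
#'
#' @param tree a `phylo` object.
#' @return sum of all branch lengths.
#' @export
totalTreeLength <- function(tree) sum(tree$edge.length)
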
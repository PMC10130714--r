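# Partitioning PD among named clades (family / superorder level).

# Map each clade label to the set of tree edges it owns: every edge whose
# descendant tip set lies entirely inside the clade's membership. For a
# monophyletic clade this is the MRCA subtree plus the stem edge subtending
# the MRCA; deep branches shared between clades belong to no one and are
# reported as "unassigned".
.cladeEdgeSets <- function(tree, cladeMap, level, species,
                           dropSingletons = TRUE) {
  stopifnot(all(c("species", level) %in% names(cladeMap)))
  labels <- stats::setNames(as.character(cladeMap[[level]]), cladeMap$species)
  unlabeled <- setdiff(species, names(labels)[!is.na(labels) & labels != ""])
  if (length(unlabeled))
    stop("species without a '", level, "' label: ",
         paste(unlabeled, collapse = ", "))
  byClade <- split(names(labels)[names(labels) %in% species],
                   labels[names(labels) %in% species])
  if (dropSingletons) {
    single <- lengths(byClade) < 2
    if (any(single)) {
      message("excluding ", sum(single), " single-species clade(s) at level '",
              level, "': ", paste(names(byClade)[single], collapse = ", "))
      byClade <- byClade[!single]
    }
  }
  etm <- .edgeTipMatrix(tree)
  inGrid <- colnames(etm) %in% species
  lapply(byClade, function(members) {
    inClade <- colnames(etm) %in% members
    # edge owned by the clade: descends to >= 1 member and, among species in
    # the analysis, to members only
    which(rowSums(etm[, inClade, drop = FALSE]) > 0 &
          rowSums(etm[, inGrid & !inClade, drop = FALSE]) == 0)
  })
}

#' Clade contributions to PD per latitudinal bin
#'
#' For each 1-degree (by default) latitudinal bin, the branch lengths of the
#' bin's induced subtree are attributed to clades: a branch belongs to a
#' clade when all its descendant species (among those analysed) are members.
#' Branches ancestral to several clades — the root spine — are reported as
#' an explicit "unassigned" category rather than pro-rated. Single-species
#' clades are excluded by default.
#'
#' @param tree a validated ultrametric `phylo` object.
#' @param pg a [PresenceGrid-class].
#' @param cladeMap data.frame with columns `species` and the clade label
#'   column named by `level` (e.g. `family`, `superorder`).
#' @param level which clade column of `cladeMap` to use.
#' @param width bin width in degrees (default 1).
#' @param dropSingletons exclude clades with a single extant species
#'   (default TRUE).
#' @return long data.frame: bin, binMid, clade, PD, proportion. Proportions
#'   sum to 1 within each non-empty bin (unassigned included).
#' @export
cladePDByBin <- function(tree, pg, cladeMap, level = "superorder",
                         width = 1, dropSingletons = TRUE) {
  sets <- .cladeEdgeSets(tree, cladeMap, level, speciesNames(pg),
                         dropSingletons = dropSingletons)
  al <- .alignTree(tree, pg)
  binned <- binByLatitude(pg, width = width)
  lower <- attr(binned, "lower"); mid <- attr(binned, "mid")
  lat <- latitudes(pg)
  assigned <- sort(unique(unlist(sets)))
  rows <- list()
  for (k in seq_len(nrow(binned))) {
    cells <- which(floor(lat / width) * width == lower[k])
    present <- which(colSums(al$present[cells, , drop = FALSE]) > 0)
    if (length(present) == 0) next
    contrib <- vapply(sets, function(e)
      sum(al$bt$length[intersect(present, e)]), numeric(1))
    un <- sum(al$bt$length[setdiff(present, assigned)])
    vals <- c(contrib, unassigned = un)
    rows[[length(rows) + 1]] <- data.frame(
      bin = rownames(binned)[k], binMid = mid[k],
      clade = names(vals), PD = unname(vals),
      proportion = unname(vals) / sum(vals))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clade contributions to PD by region and evolutionary depth
#'
#' For each latitudinal region and depth t, branch lengths of the region's
#' induced subtree are truncated below t (only the portion of each branch
#' older than t counts) and attributed to clades as in [cladePDByBin()].
#' At t = 0 this reproduces the binwise totals aggregated over the region;
#' near the root age contributions vanish and proportions are flagged NA.
#'
#' @inheritParams cladePDByBin
#' @param depths numeric vector of depths in Myr (default every 10 Myr from
#'   0 up to the root age).
#' @param regions named list of latitude intervals `c(min, max)`; a cell
#'   belongs to a region when min < lat <= max. Defaults to a
#'   southern/central/northern split at 13 and 15.5 degrees N (approximate
#'   Palghat and Goa gaps).
#' @return long data.frame: region, depth, clade, PD, proportion, note
#'   (non-NA for empty regions or zero-PD depth rows).
#' @export
cladePDByDepth <- function(tree, pg, cladeMap, level = "superorder",
                           depths = NULL,
                           regions = list(southern = c(-Inf, 13),
                                          central  = c(13, 15.5),
                                          northern = c(15.5, Inf)),
                           dropSingletons = TRUE) {
  T <- rootAge(tree)
  if (is.null(depths)) depths <- seq(0, T, by = 10)
  sets <- .cladeEdgeSets(tree, cladeMap, level, speciesNames(pg),
                         dropSingletons = dropSingletons)
  al <- .alignTree(tree, pg)
  lat <- latitudes(pg)
  assigned <- sort(unique(unlist(sets)))
  rows <- list()
  for (rn in names(regions)) {
    cells <- which(lat > regions[[rn]][1] & lat <= regions[[rn]][2])
    if (length(cells) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        region = rn, depth = NA_real_, clade = NA_character_,
        PD = NA_real_, proportion = NA_real_, note = "empty region")
      next
    }
    present <- which(colSums(al$present[cells, , drop = FALSE]) > 0)
    for (t in depths) {
      trunc <- pmax(0, al$bt$parentAge - pmax(al$bt$childAge, t))
      contrib <- vapply(sets, function(e)
        sum(trunc[intersect(present, e)]), numeric(1))
      un <- sum(trunc[setdiff(present, assigned)])
      vals <- c(contrib, unassigned = un)
      tot <- sum(vals)
      rows[[length(rows) + 1]] <- data.frame(
        region = rn, depth = t, clade = names(vals), PD = unname(vals),
        proportion = if (tot > 0) unname(vals) / tot else NA_real_,
        note = if (tot > 0) NA_character_ else "no branch length above this depth")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
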
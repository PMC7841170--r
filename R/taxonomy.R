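# Taxonomy handling: a small rooted tree over the panel taxa, lowest common
# ancestor queries, and the "Bovinae/Ovis"-style composite labels used when a
# peptide is compatible with several taxa.

TAXON_RANKS <- c("species", "genus", "subfamily", "family", "infraorder", "root")

#' Read a taxonomy table
#'
#' Three-column tab-separated file: `name`, `rank`, `parent` (empty or `NA`
#' for the root). Validates that there is a single root, that every parent
#' resolves, and that rank strictly coarsens along every leaf-to-root path.
#'
#' @param path File path.
#' @return data.frame with columns `name`, `rank`, `parent`.
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  validate_taxonomy(tx)
}

#' Validate a taxonomy data frame
#' @param tx data.frame with `name`, `rank`, `parent`.
#' @return The validated data.frame (invisibly usable as a taxonomy).
#' @export
validate_taxonomy <- function(tx) {
  stopifnot(all(c("name", "rank", "parent") %in% names(tx)))
  if (anyDuplicated(tx$name)) stop("duplicate taxon names")
  if (!all(tx$rank %in% TAXON_RANKS)) {
    stop("unknown rank(s): ", paste(setdiff(tx$rank, TAXON_RANKS), collapse = ", "))
  }
  roots <- tx$name[is.na(tx$parent)]
  if (length(roots) != 1L) stop("taxonomy must have exactly one root")
  unresolved <- setdiff(stats::na.omit(tx$parent), tx$name)
  if (length(unresolved)) {
    stop("unresolved parent(s): ", paste(unresolved, collapse = ", "))
  }
  rank_ord <- match(tx$rank, TAXON_RANKS)
  for (i in seq_len(nrow(tx))) {
    p <- tx$parent[i]
    if (!is.na(p) && rank_ord[match(p, tx$name)] <= rank_ord[i]) {
      stop(sprintf("rank does not coarsen from %s to parent %s", tx$name[i], p))
    }
  }
  tx
}

# path from a taxon up to (and including) the root
lineage <- function(taxon, tx) {
  i <- match(taxon, tx$name)
  if (is.na(i)) stop(sprintf("unknown taxon '%s'", taxon))
  path <- character()
  while (!is.na(i)) {
    path <- c(path, tx$name[i])
    i <- match(tx$parent[i], tx$name)
  }
  path
}

#' Lowest common ancestor of a taxon set
#'
#' @param taxa Non-empty character vector of taxon names.
#' @param tx Taxonomy data.frame ([read_taxonomy()]).
#' @return List with `name` and `rank` of the deepest node ancestral to every
#'   taxon (a singleton set returns the taxon itself).
#' @export
lca <- function(taxa, tx) {
  taxa <- unique(taxa)
  if (length(taxa) == 0L) stop("empty taxon set")
  paths <- lapply(taxa, lineage, tx = tx)
  common <- Reduce(intersect, paths)
  # intersect preserves the order of the first path (leaf -> root), so the
  # first common element is the deepest shared node
  node <- common[1]
  list(name = node, rank = tx$rank[match(node, tx$name)])
}

# leaf taxa of the panel that descend from (or are) a node
descendant_leaves <- function(node, tx, leaves) {
  leaves[vapply(leaves, function(l) node %in% lineage(l, tx), logical(1))]
}

#' Composite taxon label
#'
#' Collapses a compatible-taxa set to the shortest description used in
#' reporting: each maximal taxonomy node whose panel leaves are all in the
#' set replaces its leaves, and the parts are joined with `/` in fixed panel
#' order. `{Bos, Bubalus, Ovis}` becomes `"Bovinae/Ovis"` when Bovinae covers
#' exactly Bos and Bubalus in the panel.
#'
#' @param taxa Compatible taxon names (subset of `panel_taxa`).
#' @param tx Taxonomy data.frame.
#' @param panel_taxa All leaf taxa present in the panel, in fixed panel order.
#' @return Character scalar label.
#' @export
label_taxa <- function(taxa, tx, panel_taxa) {
  taxa <- intersect(panel_taxa, taxa)  # fixed panel order
  if (length(taxa) == 0L) stop("no panel taxa to label")
  remaining <- taxa
  parts <- character()
  while (length(remaining)) {
    leaf <- remaining[1]
    # deepest-to-root walk: take the highest ancestor still fully compatible
    best <- leaf
    for (anc in lineage(leaf, tx)[-1]) {
      dl <- descendant_leaves(anc, tx, panel_taxa)
      if (all(dl %in% taxa)) best <- anc else break
    }
    parts <- c(parts, best)
    remaining <- setdiff(remaining, descendant_leaves(best, tx, panel_taxa))
  }
  paste(parts, collapse = "/")
}
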
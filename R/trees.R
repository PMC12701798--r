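## Conversion of the package's nested-node trees to ape "phylo" objects and
## Newick files. Branch lengths are in generations; leaf labels are cell ids
## (cell_<site>_<index>); internal labels carry clone ids where known.

#' Convert a cell lineage tree to an ape phylo object
#'
#' @param tree A `cell_lineage_tree` (needs at least 2 leaves).
#' @return An object of class `phylo` with branch lengths in generations and
#'   internal node labels `clone_<id>` at clone subtree roots.
#' @export
lineage_to_phylo <- function(tree) {
  .nodes_to_phylo(tree$root)
}

.nodes_to_phylo <- function(root) {
  n_leaf <- 0L
  n_int <- 0L
  count <- function(node) {
    if (!length(node$children)) n_leaf <<- n_leaf + 1L
    else {
      n_int <<- n_int + 1L
      for (ch in node$children) count(ch)
    }
  }
  count(root)
  if (n_leaf < 2L)
    stop("phylo conversion needs at least 2 leaves; use write_newick()")

  tip_label <- character(n_leaf)
  node_label <- character(n_int)
  edges <- matrix(0L, n_leaf + n_int - 1L, 2L)
  elen <- numeric(nrow(edges))
  tip_i <- 0L
  int_i <- 0L
  edge_i <- 0L

  assign_num <- function(node) {
    if (!length(node$children)) {
      tip_i <<- tip_i + 1L
      tip_label[tip_i] <<- node$label
      tip_i
    } else {
      int_i <<- int_i + 1L
      my <- n_leaf + int_i
      node_label[int_i] <<- if (!is.na(node$clone_root))
        paste0("clone_", node$clone_root) else ""
      for (ch in node$children) {
        child_num <- assign_num(ch)
        edge_i <<- edge_i + 1L
        edges[edge_i, ] <<- c(my, child_num)
        elen[edge_i] <<- ch$time - node$time
      }
      my
    }
  }
  assign_num(root)

  phy <- structure(list(edge = edges, edge.length = elen,
                        tip.label = tip_label, node.label = node_label,
                        Nnode = n_int), class = "phylo")
  phy
}

#' Convert a clone tree to an ape phylo object
#'
#' Clone-tree leaves become tips labeled `clone_<id>`; internal (possibly
#' observed) clones become labeled internal nodes. Singleton internal nodes
#' (an observed clone with a single kept child) are preserved.
#'
#' @param clone_tree A [build_clone_tree()] result.
#' @return A `phylo` object, branch lengths in generations.
#' @export
clone_tree_to_phylo <- function(clone_tree) {
  nested <- .clone_tree_nested(clone_tree)
  .nodes_to_phylo(nested)
}

.clone_tree_nested <- function(ct) {
  children_of <- split(ct$nodes[!is.na(ct$parent)],
                       ct$parent[!is.na(ct$parent)])
  build <- function(cid) {
    kids <- children_of[[as.character(cid)]]
    node <- .new_lineage_node(time = ct$birth_gen[[as.character(cid)]],
                              clone_root = cid)
    node$label <- paste0("clone_", cid)
    if (length(kids)) node$children <- lapply(kids, build)
    node
  }
  build(ct$root)
}

#' Write a tree to a Newick file
#'
#' Uses [ape::write.tree()]; degenerate trees with fewer than two leaves are
#' written as a minimal Newick string directly.
#'
#' @param tree A `cell_lineage_tree`, `clone_tree`, or `phylo` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "phylo")) {
    ape::write.tree(tree, file = path)
    return(invisible(path))
  }
  nested <- if (inherits(tree, "clone_tree")) .clone_tree_nested(tree)
            else tree$root
  n_leaf <- 0L
  count <- function(node) {
    if (!length(node$children)) n_leaf <<- n_leaf + 1L
    else for (ch in node$children) count(ch)
  }
  count(nested)
  if (n_leaf < 2L) {
    lab <- if (!length(nested$children)) nested$label else {
      ch <- nested$children[[1L]]
      paste0("(", ch$label, ":", ch$time - nested$time, ")", nested$label)
    }
    writeLines(paste0(lab, ";"), path)
  } else {
    ape::write.tree(.nodes_to_phylo(nested), file = path)
  }
  invisible(path)
}

#' Export per-edge event annotations of a lineage tree
#'
#' One row per event on an edge, keyed by the child node's id in a preorder
#' numbering (leaves carry their cell id instead).
#'
#' @param tree A `cell_lineage_tree`.
#' @return Data frame with columns `node`, `time`, `kind`, `generation`,
#'   `strand_id`, `region`, `offset`, `start`, `length`, `arm`, `origin`.
#' @export
edge_event_table <- function(tree) {
  rows <- list()
  counter <- 0L
  walk <- function(node) {
    counter <<- counter + 1L
    id <- if (!length(node$children)) node$label else paste0("node_", counter)
    for (ev in node$events) {
      rows[[length(rows) + 1L]] <<- data.frame(
        node = id, time = node$time, kind = ev$kind,
        generation = if (is.null(ev$generation)) NA_real_ else ev$generation,
        strand_id = if (is.null(ev$strand_id)) NA_integer_ else ev$strand_id,
        region = if (is.null(ev$region)) NA_integer_ else ev$region,
        offset = if (is.null(ev$offset)) NA_real_ else ev$offset,
        start = if (is.null(ev$start)) NA_integer_ else ev$start,
        length = if (is.null(ev$length)) NA_integer_ else ev$length,
        arm = if (is.null(ev$arm)) NA_integer_ else ev$arm,
        origin = if (is.null(ev$origin)) NA_character_ else ev$origin)
    }
    for (ch in node$children) walk(ch)
  }
  walk(tree$root)
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = character(0), time = numeric(0),
                      kind = character(0), generation = numeric(0),
                      strand_id = integer(0), region = integer(0),
                      offset = numeric(0), start = integer(0),
                      length = integer(0), arm = integer(0),
                      origin = character(0))
  rownames(out) <- NULL
  out
}
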
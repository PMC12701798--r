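## Stage 2 ("down-up-down"): sample cells from the final populations, trace
## the clone tree backwards, resolve it to a binary single-cell lineage with
## a coalescent over the recorded clone sizes, then add passenger mutations
## in a top-down traversal.

#' Sample observed cells from the final populations
#'
#' Cells are drawn per site with clone probabilities proportional to the
#' final clone sizes at that site (multinomial sampling).
#'
#' @param record A `tumor_record` from [run_forward()].
#' @param n_per_site Integer vector of sample sizes, one per site (a scalar
#'   is recycled); must not exceed any site's final population.
#' @return Data frame with columns `cell_id` (`cell_<site>_<index>`), `site`
#'   and `clone_id`.
#' @export
sample_observed_cells <- function(record, n_per_site) {
  n_sites <- ncol(record$counts)
  n_per_site <- rep_len(as.integer(n_per_site), n_sites)
  rows <- list()
  for (s in seq_len(n_sites)) {
    n <- n_per_site[s]
    if (n == 0L) next
    cc <- record$counts[, s]
    N <- sum(cc)
    if (n > N)
      stop("cannot sample ", n, " cells from site ", s,
           " holding only ", N, " cells")
    live <- which(cc > 0L)
    tab <- as.integer(stats::rmultinom(1L, n, cc[live]))
    rows[[s]] <- data.frame(
      cell_id = sprintf("cell_%d_%d", s, seq_len(n)),
      site = s,
      clone_id = rep(live, tab))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = character(0), site = integer(0),
                      clone_id = integer(0))
  rownames(out) <- NULL
  out
}

#' Build the clone tree of the observed clones
#'
#' Takes the union of root paths of the observed clones through the clone
#' registry's parent pointers, then contracts unobserved, non-branching
#' intermediate clones into edges; the contracted clones' founding events
#' are concatenated onto the edge in birth order. Edge lengths are
#' differences of birth generations. If the founder itself is unobserved and
#' non-branching it is contracted too, so a single observed clone yields a
#' single-node tree carrying its whole driver history on the root edge.
#'
#' @param sample_df Sample assignment from [sample_observed_cells()].
#' @param record The `tumor_record`.
#' @return An object of class `clone_tree` with fields `nodes` (kept clone
#'   ids), `parent` (named; `NA` for the root), `edge_events` (named list of
#'   ordered driver events on the edge into each node, including the root's
#'   own root-path events), `birth_gen`, `weights` (clones x sites sampled
#'   cell counts), `root`, and `final_gen`.
#' @export
build_clone_tree <- function(sample_df, record) {
  if (!nrow(sample_df)) stop("empty sample: no observed clones")
  parent_of <- vapply(record$clones, function(cl)
    if (is.na(cl$parent)) NA_integer_ else cl$parent, integer(1))
  birth_of <- vapply(record$clones, `[[`, integer(1), "birth_gen")

  observed <- sort(unique(sample_df$clone_id))
  closure <- integer(0)
  for (c0 in observed) {
    c <- c0
    while (!is.na(c) && !(c %in% closure)) {
      closure <- c(closure, c)
      c <- parent_of[c]
    }
  }
  closure <- sort(closure)

  kids <- split(closure[!is.na(parent_of[closure])],
                parent_of[closure[!is.na(parent_of[closure])]])
  n_children <- vapply(as.character(closure),
                       function(k) length(kids[[k]]), integer(1))
  keep <- closure[closure %in% observed | n_children[as.character(closure)] >= 2L]
  ## the topmost kept node is the root; everything above it is contracted in
  keep_set <- keep

  climb <- function(c) {
    ## walk from c's registry parent up to the nearest kept ancestor,
    ## collecting contracted clones' founding events top-down
    evs <- list()
    p <- parent_of[c]
    chain <- integer(0)
    while (!is.na(p) && !(p %in% keep_set)) {
      chain <- c(p, chain)
      p <- parent_of[p]
    }
    for (cc in chain) {
      ev <- record$clones[[cc]]$event
      if (!is.null(ev)) evs[[length(evs) + 1L]] <- ev
    }
    own <- record$clones[[c]]$event
    if (!is.null(own)) evs[[length(evs) + 1L]] <- own
    list(parent = p, events = evs)
  }

  parent <- stats::setNames(rep(NA_integer_, length(keep)), keep)
  edge_events <- stats::setNames(vector("list", length(keep)), keep)
  for (c in keep) {
    cl <- climb(c)
    parent[as.character(c)] <- cl$parent
    edge_events[[as.character(c)]] <- cl$events
  }
  root <- keep[is.na(parent[as.character(keep)])]
  if (length(root) != 1L) stop("internal error: clone tree is not rooted")

  n_sites <- ncol(record$counts)
  weights <- matrix(0L, length(keep), n_sites,
                    dimnames = list(as.character(keep), NULL))
  tab <- table(factor(sample_df$clone_id, levels = keep), sample_df$site)
  weights[, as.integer(colnames(tab))] <- as.integer(tab)

  structure(list(nodes = keep, parent = parent, edge_events = edge_events,
                 birth_gen = stats::setNames(birth_of[keep], keep),
                 weights = weights, root = root,
                 final_gen = record$generations),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", length(x$nodes), "nodes, root clone", x$root,
      ", ", sum(x$weights), "sampled cells\n")
  invisible(x)
}

## ---- coalescent resolution ------------------------------------------------

.new_lineage_node <- function(time, label = NA_character_, children = list(),
                              clone_root = NA_integer_) {
  list(time = time, label = label, children = children,
       events = list(), clone_root = clone_root)
}

#' Resolve lineages within one clone by a discrete-generation coalescent
#'
#' Walking backwards from the latest entry generation towards the clone's
#' birth generation, the `j` lineages active at generation `t` coalesce
#' pairwise with probability `choose(j, 2) / N(t)` per generation, with at
#' most one merger per generation; whenever `N(t) < j` a merger is forced.
#' Lineages surviving to the birth generation are merged there, at the
#' clone's founding cell.
#'
#' @param entering List of entering lineages; each element is a list with a
#'   `node` (a lineage-tree node: sampled cell leaf or a resolved child-clone
#'   subtree root) and an `entry_gen`.
#' @param sizes Numeric vector of the clone's recorded total size per
#'   generation, indexed so that `sizes[t + 1]` is the size at generation
#'   `t` (as returned by [clone_size_series()]).
#' @param birth_gen The clone's birth generation.
#' @return The single lineage node subtending all entering lineages (with
#'   `time` >= `birth_gen`).
#' @export
resolve_within_clone <- function(entering, sizes, birth_gen) {
  stopifnot(length(entering) >= 1L)
  if (length(entering) == 1L) return(entering[[1L]]$node)
  entry <- vapply(entering, `[[`, numeric(1), "entry_gen")
  nodes <- lapply(entering, `[[`, "node")
  N_at <- function(t) {
    i <- t + 1
    if (i < 1 || i > length(sizes) || is.na(sizes[i]) || sizes[i] < 1)
      stop("record-integrity error: clone size missing at generation ", t)
    sizes[i]
  }

  active <- list()
  pending <- order(entry, decreasing = TRUE)
  pi <- 1L
  t <- max(entry)
  repeat {
    while (pi <= length(pending) && entry[pending[pi]] >= t) {
      active[[length(active) + 1L]] <- nodes[[pending[pi]]]
      pi <- pi + 1L
    }
    j <- length(active)
    if (t <= birth_gen) break
    if (j >= 2L) {
      N <- N_at(t)
      p <- min(1, choose(j, 2) / N)
      if (N < j || stats::runif(1L) < p) {
        pair <- sample.int(j, 2L)
        merged <- .new_lineage_node(time = t,
                                    children = active[pair])
        active <- c(active[-pair], list(merged))
      }
    }
    t <- t - 1L
  }
  ## forced merges at the founding cell
  while (length(active) >= 2L) {
    pair <- sample.int(length(active), 2L)
    merged <- .new_lineage_node(time = birth_gen, children = active[pair])
    active <- c(active[-pair], list(merged))
  }
  active[[1L]]
}

#' Assemble the binary single-cell lineage tree
#'
#' Resolves every clone of the clone tree with
#' [resolve_within_clone()] (its own sampled cells, entering at the final
#' generation, plus the founder lineages of its child clones, entering at
#' their birth generations) and grafts the subtrees along the clone-tree
#' edges. Driver events of each clone-tree edge are attached to the edge
#' above the corresponding subtree root.
#'
#' @param clone_tree A [build_clone_tree()] result.
#' @param record The `tumor_record`.
#' @param sample_df The sample assignment the clone tree was built from.
#' @return An object of class `cell_lineage_tree` with fields `root` (nested
#'   node list: `time`, `label`, `children`, `events`, `clone_root`),
#'   `final_gen`, `n_leaves` and `layout`. Node times are absolute
#'   generations increasing from root to leaves.
#' @export
assemble_cell_lineage <- function(clone_tree, record, sample_df) {
  children_of <- split(clone_tree$nodes[!is.na(clone_tree$parent)],
                       clone_tree$parent[!is.na(clone_tree$parent)])
  final_gen <- clone_tree$final_gen

  resolve_clone <- function(cid) {
    entering <- list()
    cells <- sample_df[sample_df$clone_id == cid, , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      leaf <- .new_lineage_node(time = final_gen, label = cells$cell_id[i])
      entering[[length(entering) + 1L]] <-
        list(node = leaf, entry_gen = final_gen)
    }
    for (child in children_of[[as.character(cid)]]) {
      sub <- resolve_clone(child)
      sub$events <- clone_tree$edge_events[[as.character(child)]]
      entering[[length(entering) + 1L]] <-
        list(node = sub, entry_gen = clone_tree$birth_gen[[as.character(child)]])
    }
    root_c <- resolve_within_clone(entering, clone_size_series(record, cid),
                                   clone_tree$birth_gen[[as.character(cid)]])
    root_c$clone_root <- cid
    root_c
  }

  root <- resolve_clone(clone_tree$root)
  root$events <- clone_tree$edge_events[[as.character(clone_tree$root)]]
  structure(list(root = root, final_gen = final_gen,
                 n_leaves = nrow(sample_df), layout = record$layout),
            class = "cell_lineage_tree")
}

#' @export
print.cell_lineage_tree <- function(x, ...) {
  cat("cell_lineage_tree:", x$n_leaves, "leaves, final generation",
      x$final_gen, "\n")
  invisible(x)
}

#' Per-generation passenger mutation rates
#'
#' Passenger mechanisms default to SNVs and segmental CNAs only; larger-scale
#' passengers (missegregation, WGD) would dominate the profiles and behave
#' like drivers.
#'
#' @param snv,segmental Per-generation, per-cell passenger rates.
#' @param seg_mean_len Mean segmental passenger length in regions.
#' @return A `passenger_rates` list.
#' @export
passenger_rates <- function(snv = 0.02, segmental = 0.002, seg_mean_len = 5) {
  if (snv < 0 || segmental < 0) stop("passenger rates must be >= 0")
  structure(list(rates = c(snv = snv, segmental = segmental),
                 seg_mean_len = seg_mean_len), class = "passenger_rates")
}

#' Add passenger mutations in a top-down traversal
#'
#' For each edge of length `l` generations a `Poisson(nu_total * l)` number
#' of passenger events is drawn, mechanisms by normalized passenger rates and
#' event times uniform along the edge. Events (the edge's inherited driver
#' events plus the new passengers) are applied chronologically to the running
#' genome so that each node's genome equals its parent's genome plus the
#' edge's events; each edge's event list is re-recorded exactly as applied,
#' which makes leaf-genome realization a verbatim replay. Passenger events
#' never alter fitness or the stage-1 record. A driver event whose target
#' strand was removed by an interleaved passenger deletion is skipped.
#'
#' @param tree A `cell_lineage_tree`.
#' @param prates A [passenger_rates()] list.
#' @return The tree with per-edge `events` annotated and genomes stored at
#'   the leaves (`$genome`).
#' @export
add_passenger_mutations <- function(tree, prates = passenger_rates()) {
  nu <- sum(prates$rates)
  layout <- tree$layout

  draw_passenger <- function(g, time) {
    mech <- sample(names(prates$rates), 1L, prob = prates$rates)
    g2 <- .draw_and_apply(g, mech, prates$seg_mean_len, time,
                          origin = "passenger")
    if (is.null(g2)) g else g2
  }

  walk <- function(node, genome) {
    for (i in seq_along(node$children)) {
      child <- node$children[[i]]
      len <- child$time - node$time
      n_pass <- if (nu > 0 && len > 0) stats::rpois(1L, nu * len) else 0L
      p_times <- if (n_pass > 0) sort(stats::runif(n_pass, node$time, child$time)) else numeric(0)
      d_times <- vapply(child$events, function(e)
        if (is.null(e$generation) || is.na(e$generation)) node$time
        else as.numeric(e$generation), numeric(1))
      ## chronological schedule of drivers (given events) and passengers (draws)
      sched <- order(c(d_times, p_times))
      is_driver <- c(rep(TRUE, length(d_times)), rep(FALSE, length(p_times)))[sched]
      which_ev <- c(seq_along(d_times), seq_along(p_times))[sched]
      g <- genome
      n0 <- length(g$log)
      for (k in seq_along(sched)) {
        if (is_driver[k]) {
          g <- apply_event(g, child$events[[which_ev[k]]], tolerant = TRUE)
        } else {
          g <- tryCatch(draw_passenger(g, p_times[which_ev[k]]),
                        oncosim_duplicate_snv = function(e) g)
        }
      }
      child$events <- if (length(g$log) > n0) g$log[(n0 + 1L):length(g$log)] else list()
      if (length(child$children)) {
        child <- walk(child, g)
      } else {
        child$genome <- g
      }
      node$children[[i]] <- child
    }
    node
  }

  ## root genome: the root edge's driver events applied to the diploid founder
  g_root <- init_diploid_genome(layout)
  n0 <- length(g_root$log)
  for (ev in tree$root$events) g_root <- apply_event(g_root, ev, tolerant = TRUE)
  tree$root$events <- if (length(g_root$log) > n0)
    g_root$log[(n0 + 1L):length(g_root$log)] else list()
  root <- walk(tree$root, g_root)
  if (!length(root$children)) root$genome <- g_root
  tree$root <- root
  tree$passengers_added <- TRUE
  tree
}

#' Realize the genome of every sampled cell by replay
#'
#' Replays, for each leaf, the ordered event lists along its root path
#' (driver and passenger events as recorded on the tree's edges) on a fresh
#' diploid founder.
#'
#' @param tree A passenger-annotated `cell_lineage_tree` (see
#'   [add_passenger_mutations()]; a tree without passengers works too and
#'   yields the clone genomes).
#' @return Named list mapping cell id to `tumor_genome`.
#' @export
realize_leaf_genomes <- function(tree) {
  out <- list()
  walk <- function(node, events_above) {
    evs <- c(events_above, node$events)
    if (!length(node$children)) {
      g <- replay_events(tree$layout, evs, tolerant = FALSE)
      out[[node$label]] <<- g
      return(invisible(NULL))
    }
    for (child in node$children) walk(child, evs)
  }
  walk(tree$root, list())
  out
}

#' Collect the leaf labels of a lineage tree
#'
#' @param tree A `cell_lineage_tree`.
#' @return Character vector of cell ids in traversal order.
#' @export
lineage_leaves <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (!length(node$children)) {
      out[[length(out) + 1L]] <<- node$label
      return(invisible(NULL))
    }
    for (child in node$children) walk(child)
  }
  walk(tree$root)
  out
}
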
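## Metastatic migration between anatomical sites. The per-generation, per-cell
## probability of migrating a -> b is p_base / d(a, b) (clamped at 1), with d
## either a static organotropism distance or a genotype-dependent distance
## that shrinks as the cell gains mutations favoured at the target site.

#' Define the anatomical site network
#'
#' @param n_sites Number of anatomical sites.
#' @param distances Optional `n_sites x n_sites` matrix of positive pairwise
#'   distances (diagonal unused, need not be symmetric). When `NULL` and
#'   `n_sites > 1`, off-diagonal distances are drawn `Uniform(1, d_max)` with
#'   the current RNG.
#' @param p_base Baseline per-generation, per-cell migration probability.
#' @param model `"static"` (distances constant across cells and generations)
#'   or `"genotype"` (distance to `b` shrinks with the cell's fitness under
#'   site `b`'s landscape).
#' @param genotype_floor Minimum distance factor in the genotype model.
#' @param d_max Upper bound of randomly generated distances.
#' @return An object of class `site_network`.
#' @export
site_network <- function(n_sites, distances = NULL, p_base = 1e-5,
                         model = c("static", "genotype"),
                         genotype_floor = 0.1, d_max = 10) {
  model <- match.arg(model)
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (p_base < 0 || p_base > 1) stop("p_base must be in [0, 1]")
  if (is.null(distances)) {
    distances <- matrix(NA_real_, n_sites, n_sites)
    if (n_sites > 1) {
      off <- which(row(distances) != col(distances))
      distances[off] <- stats::runif(length(off), 1, d_max)
    }
  } else {
    if (!is.matrix(distances) || nrow(distances) != n_sites ||
        ncol(distances) != n_sites)
      stop("distances must be an n_sites x n_sites matrix")
    off <- which(row(distances) != col(distances))
    if (any(!is.finite(distances[off])) || any(distances[off] <= 0))
      stop("off-diagonal distances must be positive")
  }
  diag(distances) <- NA_real_
  structure(list(n_sites = as.integer(n_sites), distances = distances,
                 p_base = p_base, model = model,
                 genotype_floor = genotype_floor),
            class = "site_network")
}

#' Effective migration distance between two sites
#'
#' Static model: the matrix entry `d(a, b)`, independent of genotype.
#' Genotype model: `d(a, b) * max(genotype_floor, 1 / f_b)` where `f_b` is
#' the cell's fitness under the target site's landscape, so the distance
#' decreases (down to the floor) as the cell acquires mutations advantageous
#' at the target.
#'
#' @param net A [site_network()].
#' @param a,b Source and target site ids (`a != b`).
#' @param fitness_target The cell's fitness under site `b`'s landscape
#'   (ignored by the static model; the diploid founder has fitness 1, for
#'   which both models coincide).
#' @return Positive effective distance (vectorized over `fitness_target`).
#' @export
effective_distance <- function(net, a, b, fitness_target = 1) {
  if (any(a == b)) stop("effective_distance requires a != b")
  d <- net$distances[cbind(a, b)]
  if (net$model == "static") return(rep_len(d, max(length(d), length(fitness_target))))
  d * pmax(net$genotype_floor, 1 / fitness_target)
}

#' Per-generation migration probability at a given effective distance
#'
#' @param net A [site_network()].
#' @param d_eff Positive effective distance (vectorized).
#' @return `min(1, p_base / d_eff)`.
#' @export
migration_probability <- function(net, d_eff) {
  if (any(d_eff <= 0)) stop("effective distance must be positive")
  pmin(1, net$p_base / d_eff)
}

#' Binomially thin a clone's cells into migrants
#'
#' Each of `clone_count` cells migrates independently with probability `p`;
#' the migrant count is `Binomial(clone_count, p)`. Migration moves cells
#' between sites and never creates or destroys them.
#'
#' @param clone_count Number of cells of the clone at the source site.
#' @param p Per-cell migration probability.
#' @return Integer migrant count.
#' @export
sample_migrants <- function(clone_count, p) {
  if (clone_count < 0) stop("clone_count must be >= 0")
  stats::rbinom(length(clone_count), clone_count, p)
}

#' Aggregate realized migrations into a migration graph
#'
#' @param record A `tumor_record` from [run_forward()], or a data frame of
#'   migration events with columns `source`, `target`, `count`, `clone_id`.
#' @return Data frame with one row per directed site pair that realized at
#'   least one migration: `source`, `target`, `n_events`, `n_cells`, and
#'   `clone_ids` (comma-separated).
#' @export
migration_graph <- function(record) {
  ev <- if (is.data.frame(record)) record else record$migration_events
  if (!nrow(ev)) {
    return(data.frame(source = integer(0), target = integer(0),
                      n_events = integer(0), n_cells = integer(0),
                      clone_ids = character(0)))
  }
  key <- paste(ev$source, ev$target)
  out <- do.call(rbind, lapply(split(ev, key), function(d) {
    data.frame(source = d$source[1], target = d$target[1],
               n_events = nrow(d), n_cells = sum(d$count),
               clone_ids = paste(sort(unique(d$clone_id)), collapse = ","))
  }))
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
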
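## Stage 1: clone-level agent-based forward simulation. Agents are clones
## (cells sharing an identical ordered driver sequence); per generation each
## clone's cells complete their lifespan, divide or die, mutant daughters
## found singleton clones, and surviving cells may migrate between sites.

#' Per-division, per-daughter driver mutation rates
#'
#' One rate per mechanism; the total driver rate is their sum and the
#' mechanism of a mutant daughter is drawn proportional to the rates.
#' Segmental and missegregation events are gains or losses with equal
#' probability.
#'
#' @param snv,segmental,arm_misseg,chrom_misseg,wgd Per-division,
#'   per-daughter probabilities of each driver mechanism.
#' @return Named numeric vector of rates.
#' @export
driver_rates <- function(snv = 1e-4, segmental = 1e-4, arm_misseg = 5e-5,
                         chrom_misseg = 5e-5, wgd = 1e-5) {
  r <- c(snv = snv, segmental = segmental, arm_misseg = arm_misseg,
         chrom_misseg = chrom_misseg, wgd = wgd)
  if (any(r < 0) || sum(r) > 1) stop("driver rates must be >= 0 and sum to <= 1")
  r
}

#' Configure the forward simulation engine
#'
#' @param layout A [genome_layout()].
#' @param landscapes List of per-site landscapes from [build_landscapes()].
#' @param net A [site_network()]; its site count must match `landscapes`.
#' @param growth A [growth_params()] list, or a list of one per site.
#' @param rates Driver rates from [driver_rates()].
#' @param selection_model `"region"`, `"arm"` or `"hybrid"`.
#' @param seg_mean_len Mean length (regions) of segmental events; lengths are
#'   drawn geometrically with this mean, breakpoints uniformly on the strand.
#' @param viability [viability_limits()] applied to every mutant daughter.
#' @param n_min_detectable Cells every ever-colonized site must hold,
#'   simultaneously, for the simulation to terminate.
#' @param max_generations Hard generation cap (exceeding it is an error
#'   naming the lagging sites).
#' @param max_restarts Restarts after total extinction (each restart derives
#'   a fresh seed `seed + attempt - 1`).
#' @param initial_cells Founder cells at site 1 at generation 0.
#' @return An `engine_config` list.
#' @export
engine_config <- function(layout, landscapes, net = NULL,
                          growth = growth_params(), rates = driver_rates(),
                          selection_model = c("region", "arm", "hybrid"),
                          seg_mean_len = 5,
                          viability = viability_limits(),
                          n_min_detectable = 5e4, max_generations = 5000,
                          max_restarts = 10, initial_cells = 1) {
  selection_model <- match.arg(selection_model)
  n_sites <- length(landscapes)
  if (is.null(net)) net <- site_network(n_sites, p_base = 0)
  if (net$n_sites != n_sites)
    stop("site network has ", net$n_sites, " sites but there are ",
         n_sites, " landscapes")
  if (inherits(growth, "growth_params")) growth <- rep(list(growth), n_sites)
  if (length(growth) != n_sites) stop("need one growth_params per site")
  structure(list(layout = layout, landscapes = landscapes, net = net,
                 growth = growth, rates = rates,
                 mu_total = sum(rates),
                 selection_model = selection_model,
                 seg_mean_len = seg_mean_len, viability = viability,
                 n_min_detectable = n_min_detectable,
                 max_generations = max_generations,
                 max_restarts = max_restarts,
                 initial_cells = as.integer(initial_cells)),
            class = "engine_config")
}

## fitness of a genome under every site's landscape
.fitness_all_sites <- function(g, cfg) {
  vapply(cfg$landscapes, function(ls) clone_fitness(g, ls, cfg$selection_model),
         numeric(1))
}

#' Draw and apply one driver event, creating a candidate daughter genome
#'
#' The mechanism is drawn proportional to the configured rates; event
#' coordinates are drawn uniformly over valid targets (strands weighted by
#' length for SNV and segmental events). The event is applied to a copy of
#' the parent genome and the result is checked against the viability limits.
#'
#' @param parent_genome The parent clone's `tumor_genome`.
#' @param cfg An [engine_config()].
#' @param generation Generation of the founding division.
#' @return A list with the mutated `genome` and the founding `event`, or
#'   `NULL` if the daughter is rejected (no valid target, or a failed
#'   viability checkpoint — the daughter dies).
#' @export
spawn_driver_clone <- function(parent_genome, cfg, generation = NA_real_) {
  mech <- sample(names(cfg$rates), 1L, prob = cfg$rates)
  g <- .draw_and_apply(parent_genome, mech, cfg$seg_mean_len, generation)
  if (is.null(g)) return(NULL)
  if (!check_viability(g, cfg$viability)) return(NULL)
  ev <- g$log[[length(g$log)]]
  list(genome = g, event = ev)
}

## draw coordinates for a mechanism and apply it; NULL when no valid target
.draw_and_apply <- function(g, mech, seg_mean_len, generation,
                            origin = "driver") {
  lens <- .strand_lengths(g)
  if (!length(lens) || sum(lens) == 0) return(NULL)
  switch(mech,
    snv = {
      si <- sample.int(length(lens), 1L, prob = lens)
      st <- g$strands[[si]]
      pos <- sample.int(length(st$regions), 1L)
      region <- st$regions[pos]
      occ <- sum(st$regions[seq_len(pos)] == region)
      for (try in 1:5) {
        offset <- sample.int(g$layout$region_length, 1L) - 1
        if (!any(st$snv_pos == pos & st$snv_offset == offset)) {
          return(apply_snv(g, st$id, region, offset, origin, occ, generation))
        }
      }
      NULL
    },
    segmental = {
      si <- sample.int(length(lens), 1L, prob = lens)
      st <- g$strands[[si]]
      start <- sample.int(length(st$regions), 1L) - 1L
      len <- stats::rgeom(1L, 1 / seg_mean_len) + 1L
      kind <- sample(c("gain", "loss"), 1L)
      apply_segmental_event(g, st$id, start, len, kind, generation)
    },
    arm_misseg = {
      cand_s <- integer(0); cand_a <- integer(0)
      for (i in seq_along(g$strands)) {
        arms <- unique(g$layout$region_arm[g$strands[[i]]$regions])
        cand_s <- c(cand_s, rep.int(i, length(arms)))
        cand_a <- c(cand_a, arms)
      }
      if (!length(cand_s)) return(NULL)
      j <- sample.int(length(cand_s), 1L)
      kind <- sample(c("gain", "loss"), 1L)
      apply_missegregation(g, "arm", g$strands[[cand_s[j]]]$id, kind,
                           cand_a[j], generation)
    },
    chrom_misseg = {
      si <- sample.int(length(lens), 1L)
      kind <- sample(c("gain", "loss"), 1L)
      apply_missegregation(g, "chromosome", g$strands[[si]]$id, kind,
                           generation = generation)
    },
    wgd = apply_wgd(g, generation),
    stop("unknown mechanism: ", mech)
  )
}

#' Run the forward simulation
#'
#' Starts one diploid founder clone with `initial_cells` cells at site 1 and
#' iterates discrete generations of lifespan completion, fitness-dependent
#' division, driver mutation, and migration, until every ever-colonized site
#' simultaneously holds at least `n_min_detectable` cells (or, if
#' `generations` is given, for exactly that many generations). Total
#' extinction triggers a restart with a derived seed, up to `max_restarts`
#' attempts.
#'
#' @param cfg An [engine_config()].
#' @param seed Optional integer seed; restart attempt `i` uses
#'   `seed + i - 1`. When `NULL` the current RNG state is used.
#' @param generations Optional fixed number of generations to simulate
#'   (disables the detection-threshold termination rule; extinction still
#'   restarts).
#' @param verbose Print a progress line every 100 generations.
#' @return An object of class `tumor_record`: the clone registry (all clones
#'   ever created, with genomes and parent pointers), final per-site clone
#'   counts, the per-generation size history, migration events, and the
#'   elapsed generation count.
#' @export
run_forward <- function(cfg, seed = NULL, generations = NULL, verbose = FALSE) {
  for (attempt in seq_len(cfg$max_restarts)) {
    if (!is.null(seed)) set.seed(seed + attempt - 1L)
    res <- .forward_attempt(cfg, generations, verbose)
    if (!is.null(res)) {
      res$seed <- seed
      res$attempt <- attempt
      return(res)
    }
  }
  stop("simulation failed: total extinction in all ", cfg$max_restarts,
       " attempts; raise initial_cells or growth_rate, or allow more restarts")
}

.forward_attempt <- function(cfg, generations = NULL, verbose = FALSE) {
  n_sites <- cfg$net$n_sites
  r_site <- vapply(cfg$growth, `[[`, numeric(1), "growth_rate")
  K_site <- vapply(cfg$growth, `[[`, numeric(1), "carrying_capacity")
  tau_site <- vapply(cfg$growth, `[[`, numeric(1), "turnover")
  mu <- cfg$mu_total
  p_base <- cfg$net$p_base
  dmat <- cfg$net$distances
  genotype_model <- cfg$net$model == "genotype"
  gfloor <- cfg$net$genotype_floor

  alloc <- 1024L
  counts <- matrix(0L, alloc, n_sites)
  fitm <- matrix(NA_real_, alloc, n_sites)
  clones <- vector("list", alloc)

  g0 <- init_diploid_genome(cfg$layout)
  clones[[1L]] <- list(id = 1L, parent = NA_integer_, event = NULL,
                       birth_gen = 0L, birth_site = 1L, genome = g0)
  fitm[1L, ] <- .fitness_all_sites(g0, cfg)
  counts[1L, 1L] <- cfg$initial_cells
  n_clones <- 1L

  grow <- function(upto) {
    while (alloc < upto) alloc <<- alloc * 2L
    counts2 <- matrix(0L, alloc, n_sites); counts2[seq_len(nrow(counts)), ] <- counts
    fitm2 <- matrix(NA_real_, alloc, n_sites); fitm2[seq_len(nrow(fitm)), ] <- fitm
    counts <<- counts2; fitm <<- fitm2
    length(clones) <<- alloc
  }

  snapshot <- function() {
    lapply(seq_len(n_sites), function(s) {
      idx <- which(counts[, s] > 0L)
      list(ids = idx, n = counts[idx, s])
    })
  }

  history <- vector("list", 256L)
  history[[1L]] <- snapshot()
  mig_rows <- list()
  colonized <- c(TRUE, rep(FALSE, n_sites - 1L))
  gen <- 0L

  repeat {
    gen <- gen + 1L

    ## birth-death-mutation, site by site
    for (s in seq_len(n_sites)) {
      idx <- which(counts[, s] > 0L)
      if (!length(idx)) next
      n <- counts[idx, s]
      N <- sum(n)
      f <- fitm[idx, s]
      f_mean <- sum(n * f) / N
      p_div <- division_probability(f, f_mean, N, cfg$growth[[s]])
      m <- stats::rbinom(length(idx), n, tau_site[s])
      b <- stats::rbinom(length(idx), m, p_div)
      k <- if (mu > 0) stats::rbinom(length(idx), 2L * b, mu) else integer(length(idx))
      counts[idx, s] <- n - m + 2L * b - k

      if (any(k > 0L)) {
        parents <- rep(idx, k)
        for (pi in parents) {
          sp <- spawn_driver_clone(clones[[pi]]$genome, cfg, gen)
          if (is.null(sp)) next  # inviable daughter dies
          n_clones <- n_clones + 1L
          if (n_clones > alloc) grow(n_clones)
          clones[[n_clones]] <- list(id = n_clones, parent = pi,
                                     event = sp$event, birth_gen = gen,
                                     birth_site = s, genome = sp$genome)
          fitm[n_clones, ] <- .fitness_all_sites(sp$genome, cfg)
          counts[n_clones, s] <- 1L
        }
      }
    }

    ## migration pass (draw sizes from the post-birth snapshot; at most the
    ## snapshot count can leave a site, thinned sequentially across targets)
    if (n_sites > 1L && p_base > 0) {
      pre <- counts
      for (s in seq_len(n_sites)) {
        idx <- which(pre[, s] > 0L)
        if (!length(idx)) next
        n_rem <- pre[idx, s]
        for (t in seq_len(n_sites)) {
          if (t == s) next
          p_mig <- if (genotype_model) {
            pmin(1, p_base / (dmat[s, t] * pmax(gfloor, 1 / fitm[idx, t])))
          } else {
            min(1, p_base / dmat[s, t])
          }
          mig <- stats::rbinom(length(idx), n_rem, p_mig)
          n_rem <- n_rem - mig
          hit <- which(mig > 0L)
          if (length(hit)) {
            counts[idx[hit], s] <- counts[idx[hit], s] - mig[hit]
            counts[idx[hit], t] <- counts[idx[hit], t] + mig[hit]
            mig_rows[[length(mig_rows) + 1L]] <-
              data.frame(generation = gen, clone_id = idx[hit],
                         source = s, target = t, count = mig[hit])
          }
        }
      }
    }

    if (gen + 1L > length(history)) length(history) <- 2L * length(history)
    history[[gen + 1L]] <- snapshot()

    N_site <- colSums(counts)
    if (sum(N_site) == 0) return(NULL)  # extinction -> restart
    colonized <- colonized | N_site > 0

    if (verbose && gen %% 100L == 0L) {
      message(sprintf("generation=%d N=[%s] clones=%d", gen,
                      paste(N_site, collapse = ","), n_clones))
    }

    if (!is.null(generations)) {
      if (gen >= generations) break
    } else {
      ## with migration enabled every site must fill to the detection
      ## threshold (simultaneously); without it, only colonized sites count
      need <- if (p_base > 0) rep(TRUE, n_sites) else colonized
      if (all(N_site[need] >= cfg$n_min_detectable)) break
      if (gen >= cfg$max_generations) {
        lag <- which(need & N_site < cfg$n_min_detectable)
        stop("max_generations (", cfg$max_generations,
             ") exceeded; lagging sites: ", paste(lag, collapse = ", "))
      }
    }
  }

  mig <- if (length(mig_rows)) do.call(rbind, mig_rows) else
    data.frame(generation = integer(0), clone_id = integer(0),
               source = integer(0), target = integer(0), count = integer(0))
  rownames(mig) <- NULL

  structure(list(layout = cfg$layout, cfg = cfg,
                 clones = clones[seq_len(n_clones)], n_clones = n_clones,
                 counts = counts[seq_len(n_clones), , drop = FALSE],
                 fitness = fitm[seq_len(n_clones), , drop = FALSE],
                 history = history[seq_len(gen + 1L)],
                 migration_events = mig,
                 generations = gen, colonized = colonized),
            class = "tumor_record")
}

#' @export
print.tumor_record <- function(x, ...) {
  cat("tumor_record:", x$generations, "generations,", x$n_clones,
      "clones ever created\n")
  cat("  final cells per site:", paste(colSums(x$counts), collapse = ", "), "\n")
  cat("  migration events:", nrow(x$migration_events), "\n")
  invisible(x)
}

#' Total size of one clone across sites, per generation
#'
#' @param record A `tumor_record`.
#' @param clone_id Clone id.
#' @return Numeric vector of length `generations + 1`; element `t + 1` is the
#'   clone's total cell count at generation `t` (generation 0 is the initial
#'   state).
#' @export
clone_size_series <- function(record, clone_id) {
  vapply(record$history, function(snap) {
    tot <- 0
    for (sitesnap in snap) {
      j <- match(clone_id, sitesnap$ids)
      if (!is.na(j)) tot <- tot + sitesnap$n[j]
    }
    tot
  }, numeric(1))
}

#' Survival fraction of independent founder lineages
#'
#' Runs the engine's neutral birth-death kernel (fixed one-generation
#' lifespan, constant division probability, no capacity, no mutation) for
#' many independent single-cell founder lineages in parallel and returns the
#' fraction still alive. For a supercritical process with division
#' probability `p > 1/2` the long-run survival probability is
#' `(2p - 1) / p`.
#'
#' @param n_lineages Number of independent founder lineages.
#' @param p_div Constant division probability.
#' @param generations Generations to simulate.
#' @return Fraction of lineages with at least one living cell at the end.
#' @export
branching_survival <- function(n_lineages = 1e4, p_div = 0.6,
                               generations = 50) {
  n <- rep(1, n_lineages)
  for (t in seq_len(generations)) {
    alive <- which(n > 0)
    if (!length(alive)) break
    n[alive] <- 2 * stats::rbinom(length(alive), n[alive], p_div)
  }
  mean(n > 0)
}
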
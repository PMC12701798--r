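## End-to-end pipeline: forward simulation -> sampling -> clone tree ->
## coalescent resolution -> passengers -> profiles -> read counts
## (-> sequences when a reference is supplied). One master seed; each stage
## draws its own substream seed so toggling late stages never perturbs
## earlier ones.

#' Run the full simulation pipeline
#'
#' Executes every stage and writes the complete output set to `outdir`:
#' `config.yaml` (effective configuration), `landscapes.tsv`,
#' `distances.tsv`, `clone_registry.tsv`, `events.tsv` (driver founding
#' events), `migration_events.tsv`, `migration_graph.tsv`,
#' `clone_tree.nwk`, `cell_lineage.nwk`, `tree_events.tsv`, `cnp.tsv`
#' (allele-specific `a|b` pairs), `snv.tsv`, `counts.tsv`, `counts.mtx`,
#' `record.json` (run summary) and `log.txt`. With a reference, per-cell
#' FASTA plus a coverage manifest are written under `reads/`.
#'
#' @param cfg An `oncosim_config` (see [load_config()]).
#' @param seed Master integer seed; all stage substreams derive from it.
#' @param outdir Output directory (created if needed).
#' @param reference Optional `DNAStringSet` reference (or path to a FASTA
#'   file) for sequence realization.
#' @param tool_cmd Optional short-read simulator command template (see
#'   [invoke_read_simulator()]).
#' @param verbose Print engine progress.
#' @return The output directory, invisibly; the run record and trees are
#'   also returned in a list attribute-free form via `invisible`.
#' @export
run_pipeline <- function(cfg, seed = 1L, outdir, reference = NULL,
                         tool_cmd = NULL, verbose = FALSE) {
  validate_config(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "log.txt")
  loglines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    loglines <<- c(loglines, line)
    if (verbose) message(line)
  }

  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 6L)

  ## stage 0: landscapes, network, layout
  set.seed(stage_seed[1L])
  layout <- genome_layout(cfg$genome$n_chromosomes,
                          cfg$genome$regions_per_arm,
                          cfg$genome$region_length,
                          cfg$genome$frac_og, cfg$genome$frac_tsg,
                          cfg$genome$frac_essential)
  landscapes <- build_landscapes(layout, cfg$migration$n_sites,
                                 cfg$selection$s_max,
                                 cfg$selection$divergence,
                                 cfg$selection$essential_penalty)
  net <- site_network(cfg$migration$n_sites, p_base = cfg$migration$p_base,
                      model = cfg$migration$model,
                      genotype_floor = cfg$migration$genotype_floor,
                      d_max = cfg$migration$d_max)
  note("stage=setup sites=%d regions=%d", net$n_sites, layout$n_regions)

  ecfg <- engine_config(
    layout, landscapes, net,
    growth = growth_params(cfg$growth$growth_rate,
                           cfg$growth$carrying_capacity,
                           cfg$growth$turnover),
    rates = driver_rates(cfg$rates$snv, cfg$rates$segmental,
                         cfg$rates$arm_misseg, cfg$rates$chrom_misseg,
                         cfg$rates$wgd),
    selection_model = cfg$selection$model,
    seg_mean_len = cfg$rates$seg_mean_len,
    viability = viability_limits(cfg$viability$max_mean_cn,
                                 cfg$viability$max_region_cn,
                                 cfg$viability$max_wgd),
    n_min_detectable = cfg$engine$n_min_detectable,
    max_generations = cfg$engine$max_generations,
    max_restarts = cfg$engine$max_restarts,
    initial_cells = cfg$engine$initial_cells)

  ## stage 1: forward simulation
  record <- run_forward(ecfg, seed = stage_seed[2L], verbose = verbose)
  note("stage=forward generations=%d clones=%d attempts=%d",
       record$generations, record$n_clones, record$attempt)

  ## stage 2: sampling and lineage resolution
  set.seed(stage_seed[3L])
  sample_df <- sample_observed_cells(record, cfg$sampling$n_per_site)
  ctree <- build_clone_tree(sample_df, record)
  tree <- assemble_cell_lineage(ctree, record, sample_df)
  note("stage=lineage observed_clones=%d leaves=%d",
       length(ctree$nodes), tree$n_leaves)

  set.seed(stage_seed[4L])
  tree <- add_passenger_mutations(
    tree, passenger_rates(cfg$passenger$snv, cfg$passenger$segmental,
                          cfg$passenger$seg_mean_len))
  genomes <- realize_leaf_genomes(tree)
  note("stage=passengers leaves_realized=%d", length(genomes))

  ## stage 3: profiles and read counts
  set.seed(stage_seed[5L])
  profiles <- emit_profiles(genomes, layout)
  cm <- coverage_model(cfg$coverage$mean_reads_per_cell,
                       cfg$coverage$total_depth, cfg$coverage$sigma_bias,
                       cfg$coverage$dispersion, cfg$coverage$normal_fraction)
  counts <- simulate_read_counts(profiles$cn_total, cm, cfg$coverage$mode)
  note("stage=datagen cells=%d loci=%d", nrow(profiles$cn_total),
       nrow(profiles$loci))

  ## writers
  save_config(cfg, file.path(outdir, "config.yaml"))
  write_landscapes(landscapes, layout, file.path(outdir, "landscapes.tsv"))
  write_distances(net, file.path(outdir, "distances.tsv"))
  write_clone_registry(record, file.path(outdir, "clone_registry.tsv"))
  write_events(record, file.path(outdir, "events.tsv"))
  utils::write.table(record$migration_events,
                     file.path(outdir, "migration_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(migration_graph(record),
                     file.path(outdir, "migration_graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(ctree, file.path(outdir, "clone_tree.nwk"))
  write_newick(tree, file.path(outdir, "cell_lineage.nwk"))
  utils::write.table(edge_event_table(tree),
                     file.path(outdir, "tree_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_cnp(profiles, file.path(outdir, "cnp.tsv"))
  write_snv(profiles, file.path(outdir, "snv.tsv"))
  utils::write.table(data.frame(cell = rownames(counts), counts,
                                check.names = FALSE),
                     file.path(outdir, "counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE),
                  file.path(outdir, "counts.mtx"))

  ## stage 4: sequences (optional)
  if (!is.null(reference)) {
    if (is.character(reference))
      reference <- Biostrings::readDNAStringSet(reference)
    set.seed(stage_seed[6L])
    invoke_read_simulator(genomes, reference, file.path(outdir, "reads"),
                          coverage = cfg$coverage$mean_reads_per_cell /
                            sum(Biostrings::width(reference)),
                          tool_cmd = tool_cmd)
    note("stage=reads cells=%d", length(genomes))
  }

  summary <- list(seed = seed, stage_seeds = stage_seed,
                  generations = record$generations,
                  attempts = record$attempt,
                  n_clones = record$n_clones,
                  final_cells_per_site = as.numeric(colSums(record$counts)),
                  observed_clones = length(ctree$nodes),
                  n_leaves = tree$n_leaves,
                  n_snv_loci = nrow(profiles$loci),
                  migration_events = nrow(record$migration_events))
  jsonlite::write_json(summary, file.path(outdir, "record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(loglines, logf)
  invisible(outdir)
}

## ---- writers --------------------------------------------------------------

write_landscapes <- function(landscapes, layout, path) {
  df <- data.frame(region = seq_len(layout$n_regions),
                   chrom = layout$region_chrom,
                   arm = c("p", "q")[layout$region_arm],
                   class = layout$gene_class)
  for (i in seq_along(landscapes))
    df[[paste0("delta_site", i)]] <- signif(landscapes[[i]]$delta, 10)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_distances <- function(net, path) {
  d <- net$distances
  rownames(d) <- colnames(d) <- paste0("site", seq_len(net$n_sites))
  utils::write.table(data.frame(source = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_clone_registry <- function(record, path) {
  df <- data.frame(
    clone_id = vapply(record$clones, `[[`, integer(1), "id"),
    parent = vapply(record$clones, function(x)
      if (is.na(x$parent)) NA_integer_ else x$parent, integer(1)),
    birth_gen = vapply(record$clones, `[[`, integer(1), "birth_gen"),
    birth_site = vapply(record$clones, `[[`, integer(1), "birth_site"),
    founding_event = vapply(record$clones, function(x)
      if (is.null(x$event)) "founder" else x$event$kind, character(1)),
    n_drivers = vapply(record$clones, function(x)
      length(x$genome$log), integer(1)))
  for (s in seq_len(ncol(record$counts)))
    df[[paste0("final_n_site", s)]] <- record$counts[, s]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_events <- function(record, path) {
  rows <- lapply(record$clones, function(cl) {
    ev <- cl$event
    if (is.null(ev)) return(NULL)
    data.frame(generation = cl$birth_gen, clone_id = cl$id,
               site = cl$birth_site, kind = ev$kind,
               strand_id = if (is.null(ev$strand_id)) NA_integer_ else ev$strand_id,
               region = if (is.null(ev$region)) NA_integer_ else ev$region,
               offset = if (is.null(ev$offset)) NA_real_ else ev$offset,
               start = if (is.null(ev$start)) NA_integer_ else ev$start,
               length = if (is.null(ev$length)) NA_integer_ else ev$length,
               arm = if (is.null(ev$arm)) NA_integer_ else ev$arm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(generation = integer(0), clone_id = integer(0),
                      site = integer(0), kind = character(0),
                      strand_id = integer(0), region = integer(0),
                      offset = numeric(0), start = integer(0),
                      length = integer(0), arm = integer(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_cnp <- function(profiles, path) {
  a <- profiles$cn_maternal
  b <- profiles$cn_paternal
  pairs <- matrix(paste0(a, "|", b), nrow(a), ncol(a))
  df <- data.frame(cell = rownames(a), pairs, check.names = FALSE)
  names(df)[-1L] <- paste0("region_", seq_len(ncol(a)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_snv <- function(profiles, path) {
  if (!nrow(profiles$loci)) {
    utils::write.table(data.frame(cell = rownames(profiles$snv)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df <- data.frame(cell = rownames(profiles$snv), profiles$snv,
                   check.names = FALSE)
  names(df)[-1L] <- paste0("chr", profiles$loci$chrom, ":",
                           format(profiles$loci$pos, scientific = FALSE,
                                  trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
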
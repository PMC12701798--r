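## Run configuration: a nested list with documented defaults for every
## parameter; YAML in, YAML out, losslessly.

#' Default run configuration
#'
#' Returns the full nested configuration with every parameter at its
#' default. Sections: `genome` (layout), `selection` (model and landscape
#' generation), `growth` (logistic parameters), `rates` (driver mechanisms),
#' `passenger` (stage-2 rates), `migration` (site network), `engine`
#' (termination and restarts), `sampling` (cells per site), `coverage`
#' (read-count model), `viability` (mutation checkpoints).
#'
#' @return A named nested list of class `oncosim_config`.
#' @export
default_config <- function() {
  structure(list(
    genome = list(n_chromosomes = 10L, regions_per_arm = 10L,
                  region_length = 1e6, frac_og = 0.10, frac_tsg = 0.10,
                  frac_essential = 0.05),
    selection = list(model = "region", s_max = 0.1, divergence = 0.2,
                     essential_penalty = 0.95),
    growth = list(growth_rate = 0.4, carrying_capacity = 1e5, turnover = 1),
    rates = list(snv = 1e-4, segmental = 1e-4, arm_misseg = 5e-5,
                 chrom_misseg = 5e-5, wgd = 1e-5, seg_mean_len = 5),
    passenger = list(snv = 0.02, segmental = 0.002, seg_mean_len = 5),
    migration = list(n_sites = 1L, p_base = 1e-5, model = "static",
                     genotype_floor = 0.1, d_max = 10),
    engine = list(n_min_detectable = 5e4, max_generations = 5000,
                  max_restarts = 10, initial_cells = 1L),
    sampling = list(n_per_site = 100L),
    coverage = list(mode = "single_cell", mean_reads_per_cell = 1e5,
                    total_depth = 1e7, sigma_bias = 0.1, dispersion = Inf,
                    normal_fraction = 0),
    viability = list(max_mean_cn = 8, max_region_cn = 10, max_wgd = 2)
  ), class = "oncosim_config")
}

#' Load a run configuration
#'
#' Reads a YAML file (if given), overlays it on the defaults, and validates.
#' Unknown keys are an error listing them; invalid values are errors naming
#' the field and constraint.
#'
#' @param path Optional path to a YAML configuration; `NULL` returns the
#'   validated defaults.
#' @return A validated `oncosim_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- .merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

.merge_config <- function(cfg, user, prefix = "") {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(cfg))
      stop("unknown configuration key(s): ", full)
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      cfg[[key]] <- .merge_config(cfg[[key]], user[[key]],
                                  prefix = paste0(full, "."))
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  cfg
}

#' Validate a run configuration
#'
#' @param cfg An `oncosim_config` list.
#' @return The configuration, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, constraint) {
    if (!ok) stop("invalid configuration: `", field, "` must ", constraint)
  }
  chk(cfg$genome$n_chromosomes >= 1, "genome.n_chromosomes", "be >= 1")
  chk(cfg$genome$regions_per_arm >= 1, "genome.regions_per_arm", "be >= 1")
  chk(cfg$genome$region_length >= 1, "genome.region_length", "be >= 1")
  fr <- c(cfg$genome$frac_og, cfg$genome$frac_tsg, cfg$genome$frac_essential)
  chk(all(fr >= 0) && sum(fr) <= 1, "genome.frac_*",
      "be non-negative and sum to at most 1")
  chk(cfg$selection$model %in% c("region", "arm", "hybrid"),
      "selection.model", "be region, arm or hybrid")
  chk(cfg$selection$divergence >= 0 && cfg$selection$divergence < 2 / 3,
      "selection.divergence", "be in [0, 2/3)")
  chk(cfg$growth$growth_rate > 0, "growth.growth_rate", "be positive")
  chk(cfg$growth$turnover > 0 && cfg$growth$turnover <= 1,
      "growth.turnover", "be in (0, 1]")
  rates <- unlist(cfg$rates[c("snv", "segmental", "arm_misseg",
                              "chrom_misseg", "wgd")])
  chk(all(rates >= 0) && all(rates <= 1), "rates.*", "be probabilities")
  chk(cfg$migration$n_sites >= 1, "migration.n_sites", "be >= 1")
  chk(cfg$migration$p_base >= 0 && cfg$migration$p_base <= 1,
      "migration.p_base", "be in [0, 1]")
  chk(cfg$migration$model %in% c("static", "genotype"), "migration.model",
      "be static or genotype")
  chk(all(cfg$sampling$n_per_site <= cfg$engine$n_min_detectable),
      "sampling.n_per_site",
      "not exceed engine.n_min_detectable (cells cannot be oversampled)")
  chk(cfg$engine$n_min_detectable <= cfg$growth$carrying_capacity,
      "engine.n_min_detectable", "not exceed growth.carrying_capacity")
  chk(cfg$coverage$mode %in% c("single_cell", "bulk"), "coverage.mode",
      "be single_cell or bulk")
  chk(cfg$coverage$normal_fraction >= 0 && cfg$coverage$normal_fraction <= 1,
      "coverage.normal_fraction", "be in [0, 1]")
  invisible(cfg)
}

#' Save a configuration to YAML
#'
#' `load_config(save_config(cfg, path))` round-trips losslessly.
#'
#' @param cfg An `oncosim_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
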
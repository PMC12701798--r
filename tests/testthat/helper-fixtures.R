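# Shared fixtures: small layouts and random-event generators built in code.

# deterministic tiny layout: 2 chromosomes x (2+2) regions, explicit classes
tiny_layout <- function(region_length = 1000) {
  genome_layout(n_chromosomes = 2, regions_per_arm = 2,
                region_length = region_length,
                gene_class = c("OG", "neutral", "TSG", "neutral",
                               "essential", "neutral", "neutral", "neutral"))
}

# mid-size layout with random classes (uses current RNG)
small_layout <- function() genome_layout(n_chromosomes = 3, regions_per_arm = 4)

# neutral landscape (all delta = 1) over a layout
neutral_landscape <- function(layout, site = 1L) {
  new_landscape(layout, site = site, delta = rep(1, layout$n_regions))
}

# apply `len` random driver-style events (all five mechanisms, uniform),
# skipping draws with no valid target; returns the genome (event log inside)
random_genome <- function(layout, len = 15) {
  g <- init_diploid_genome(layout)
  mechs <- c("snv", "segmental", "arm_misseg", "chrom_misseg", "wgd")
  for (i in seq_len(len)) {
    g2 <- tryCatch(
      oncosim:::.draw_and_apply(g, sample(mechs, 1), 3, i),
      oncosim_duplicate_snv = function(e) NULL)
    if (!is.null(g2) && length(g2$strands)) g <- g2
  }
  g
}

# profile + SNV-set equality between genomes
expect_same_genome_state <- function(g1, g2) {
  expect_identical(copy_number_profile(g1), copy_number_profile(g2))
  s1 <- genome_snvs(g1); s2 <- genome_snvs(g2)
  o1 <- order(s1$strand_id, s1$region, s1$offset)
  o2 <- order(s2$strand_id, s2$region, s2$offset)
  expect_equal(s1[o1, ], s2[o2, ], ignore_attr = TRUE)
}

# small single-site engine config for fast runs
quick_engine <- function(layout, K = 2000, n_min = 1000, n_sites = 1,
                         p_base = 0, r = 0.4, rates = driver_rates(),
                         initial_cells = 10, model = "region",
                         divergence = 0.2, net_model = "static") {
  landscapes <- build_landscapes(layout, n_sites, divergence = divergence)
  net <- site_network(n_sites, p_base = p_base, model = net_model)
  engine_config(layout, landscapes, net,
                growth = growth_params(r, K, 1), rates = rates,
                selection_model = model,
                n_min_detectable = n_min, initial_cells = initial_cells)
}
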
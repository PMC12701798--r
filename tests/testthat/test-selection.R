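test_that("all three selection models give fitness 1 on the diploid founder", {
  lay <- tiny_layout()
  g <- init_diploid_genome(lay)
  for (i in 1:5) {
    ls <- build_landscapes(lay, 1, s_max = 0.3)[[1]]
    expect_equal(region_fitness(g, ls), 1)
    expect_equal(arm_fitness(g, ls), 1)
    expect_equal(hybrid_fitness(g, ls), 1)
  }
})

test_that("region fitness matches the multiplicative formula on hand cases", {
  lay <- tiny_layout()  # region 1 OG, region 3 TSG
  delta <- rep(1, 8); delta[1] <- 1.2; delta[3] <- 0.9
  ls <- new_landscape(lay, delta = delta)
  cn <- rep(2, 8)
  # OG at copy 3: f = 1.2
  cn3 <- cn; cn3[1] <- 3
  expect_equal(region_fitness(cn3, ls), 1.2)
  # TSG at copy 1: f = 0.9^-1
  cn1 <- cn; cn1[3] <- 1
  expect_equal(region_fitness(cn1, ls), 1 / 0.9)
  # combined, exponents add
  cnb <- cn; cnb[1] <- 4; cnb[3] <- 0
  expect_equal(region_fitness(cnb, ls), 1.2^2 * 0.9^-2)
  # a stored zero coefficient acts as the neutral sentinel
  dz <- delta; dz[5] <- 0
  lz <- new_landscape(lay, delta = dz)
  expect_equal(region_fitness(cn3, lz), 1.2)
})

test_that("OG amplification raises and TSG amplification lowers fitness", {
  lay <- tiny_layout()
  delta <- rep(1, 8); delta[1] <- 1.15; delta[3] <- 0.85
  ls <- new_landscape(lay, delta = delta)
  cn <- rep(2, 8)
  for (extra in 1:3) {
    up <- cn; up[1] <- 2 + extra
    dn <- cn; dn[1] <- 2 + extra - 1
    expect_gt(region_fitness(up, ls), region_fitness(dn, ls))
    tup <- cn; tup[3] <- 2 + extra
    tdn <- cn; tdn[3] <- 2 + extra - 1
    expect_lt(region_fitness(tup, ls), region_fitness(tdn, ls))
  }
  # deletions have the opposite effects
  expect_lt(region_fitness(replace(cn, 1, 1), ls), 1)
  expect_gt(region_fitness(replace(cn, 3, 1), ls), 1)
})

test_that("arm fitness uses arm means and agrees with the region model on whole-arm events", {
  lay <- tiny_layout()
  # every region on chr1 p arm shares delta = 1.1; whole-arm gain
  delta <- rep(1, 8); delta[1:2] <- 1.1
  ls <- new_landscape(lay, delta = delta)
  g <- apply_missegregation(init_diploid_genome(lay), "arm", 1, "gain",
                            arm = 1)
  expect_equal(arm_fitness(g, ls), region_fitness(g, ls))
  expect_equal(arm_fitness(g, ls), 1.1^2)  # two regions gained
  # an arm whose aggregate coefficient is delta_A gives f = delta_A at cbar = 3
  lsA <- new_landscape(lay, delta = c(sqrt(1.1), sqrt(1.1), rep(1, 6)))
  expect_equal(arm_fitness(g, lsA), 1.1)
  # sub-arm events enter through the arm mean copy number
  g2 <- apply_segmental_event(init_diploid_genome(lay), 1, 0, 1, "gain")
  expect_equal(arm_fitness(g2, lsA), 1.1^(1 / 2))
})

test_that("hybrid SNV multipliers follow the per-class rules", {
  lay <- tiny_layout()  # 1 OG, 3 TSG, 5 essential, rest neutral
  delta <- rep(1, 8); delta[1] <- 1.2; delta[3] <- 0.8
  ls <- new_landscape(lay, delta = delta, essential_penalty = 0.95)
  g <- init_diploid_genome(lay)
  expect_equal(hybrid_fitness(g, ls), region_fitness(g, ls))
  # driver SNV in the TSG: multiplier 1/0.8 = 1.25
  expect_equal(hybrid_fitness(apply_snv(g, 1, 3, 10, "driver"), ls), 1.25)
  # driver SNV in the OG: multiplier 1.2
  expect_equal(hybrid_fitness(apply_snv(g, 1, 1, 10, "driver"), ls), 1.2)
  # driver SNV in an essential neutral region: multiplier 0.95
  expect_equal(hybrid_fitness(apply_snv(g, 3, 5, 10, "driver"), ls), 0.95)
  # plain neutral region: no effect; passengers never count
  expect_equal(hybrid_fitness(apply_snv(g, 3, 7, 10, "driver"), ls), 1)
  expect_equal(hybrid_fitness(apply_snv(g, 1, 3, 10, "passenger"), ls), 1)
  # multiple SNVs in one region count once
  g2 <- apply_snv(apply_snv(g, 1, 3, 10, "driver"), 1, 3, 20, "driver")
  expect_equal(hybrid_fitness(g2, ls), 1.25)
})

test_that("with all delta = 1 every genome has fitness exactly 1", {
  lay <- small_layout()
  # essential_penalty = 1 switches off the hybrid model's only
  # coefficient-independent effect (SNVs in essential regions)
  ls <- new_landscape(lay, delta = rep(1, lay$n_regions),
                      essential_penalty = 1)
  for (i in 1:10) {
    g <- random_genome(lay, 15)
    expect_equal(region_fitness(g, ls), 1)
    expect_equal(arm_fitness(g, ls), 1)
    expect_equal(hybrid_fitness(g, ls), 1)
  }
})

test_that("landscape generation respects divergence", {
  lay <- genome_layout(5, 10)  # 100 regions
  # divergence 0: identical coefficients at every site
  ls0 <- build_landscapes(lay, 3, divergence = 0)
  expect_identical(ls0[[1]]$delta, ls0[[2]]$delta)
  expect_identical(ls0[[2]]$delta, ls0[[3]]$delta)
  # Monte-Carlo check of the divergence calibration: over many draws the
  # mean |delta_1 - delta_2| over non-neutral regions approaches
  # divergence * mean |delta_base - 1| (by construction of the generator)
  div <- 0.2
  diffs <- effect <- numeric(0)
  for (i in 1:40) {
    ls <- build_landscapes(lay, 2, s_max = 0.2, divergence = div)
    nz <- which(ls[[1]]$delta != 1 | ls[[2]]$delta != 1)
    diffs <- c(diffs, abs(ls[[1]]$delta[nz] - ls[[2]]$delta[nz]))
    effect <- c(effect, abs((ls[[1]]$delta[nz] + ls[[2]]$delta[nz]) / 2 - 1))
  }
  expect_equal(mean(diffs) / mean(effect), div, tolerance = 0.1)
  # direction is preserved at every site
  ls <- build_landscapes(lay, 4, s_max = 0.2, divergence = 0.5)
  og <- which(lay$gene_class == "OG"); tsg <- which(lay$gene_class == "TSG")
  for (l in ls) {
    expect_true(all(l$delta[og] > 1))
    expect_true(all(l$delta[tsg] < 1))
  }
})

test_that("division probability implements scaled logistic selection", {
  gp <- growth_params(0.4, 1e4, 1)
  # stationary point: f = f_mean, N = K
  expect_equal(division_probability(1, 1, 1e4, gp), 0.5)
  # N << K: (1 + r) / 2
  expect_equal(division_probability(1, 1, 1, gp), 0.7, tolerance = 1e-4)
  # no capacity: exactly (1 + r) / 2
  expect_equal(division_probability(1, 1, 100, growth_params(0.4, Inf)), 0.7)
  # proportional selection and clamping
  expect_equal(division_probability(2, 1, 1, growth_params(0.2, Inf)), 1)
  expect_gt(division_probability(1.1, 1, 5000, gp),
            division_probability(1.0, 1, 5000, gp))
  expect_equal(division_probability(1, 1, 3.5e4, gp), 0)  # overshoot clamps
  expect_error(division_probability(-1, 1, 10, gp), "fitness")
})

test_that("fixed-p branching survival approaches (2p-1)/p", {
  set.seed(301)
  p <- 0.6
  frac <- branching_survival(n_lineages = 3000, p_div = p, generations = 50)
  se <- sqrt((1 / 3) * (2 / 3) / 3000)
  expect_lt(abs(frac - (2 * p - 1) / p), 3 * se + 0.01)
})
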
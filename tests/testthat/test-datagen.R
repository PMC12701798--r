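test_that("profile emission round-trips genomes exactly", {
  set.seed(61)
  lay <- tiny_layout()
  g0 <- init_diploid_genome(lay)
  # all-diploid cells: CNP all (1,1), empty SNV matrix
  prof <- emit_profiles(list(c1 = g0, c2 = g0), lay)
  expect_true(all(prof$cn_maternal == 1L) && all(prof$cn_paternal == 1L))
  expect_identical(ncol(prof$snv), 0L)
  # one cell with a pre-WGD SNV: CNP all (2,2), SNV multiplicity 2
  g1 <- apply_wgd(apply_snv(g0, 1, 2, 50, "driver"))
  prof1 <- emit_profiles(list(c1 = g1), lay)
  expect_true(all(prof1$cn_maternal == 2L) && all(prof1$cn_paternal == 2L))
  expect_identical(as.integer(prof1$snv[1, 1]), 2L)
  expect_identical(prof1$loci$region, 2L)
  expect_identical(prof1$loci$pos, lay$region_length + 51)
  # random genomes: profiles agree with copy_number_profile per cell and
  # SNV column sums equal a direct recount over the genomes
  lay2 <- small_layout()
  gens <- lapply(1:6, function(i) random_genome(lay2, 15))
  names(gens) <- paste0("cell_", 1:6)
  pr <- emit_profiles(gens, lay2)
  for (i in 1:6) {
    p <- copy_number_profile(gens[[i]])
    expect_identical(unname(pr$cn_maternal[i, ]), unname(p["maternal", ]))
    expect_identical(unname(pr$cn_paternal[i, ]), unname(p["paternal", ]))
  }
  if (nrow(pr$loci)) {
    all_snv <- do.call(rbind, lapply(gens, genome_snvs))
    recount <- vapply(seq_len(nrow(pr$loci)), function(j)
      sum(all_snv$region == pr$loci$region[j] &
            all_snv$offset == pr$loci$offset[j]), integer(1))
    expect_identical(as.integer(colSums(pr$snv)), recount)
  }
})

test_that("read counts follow the copy-number-proportional coverage model", {
  set.seed(71)
  # uniform CN, no bias, Poisson: every rate equals R / n_regions
  cn <- matrix(2L, 50, 20)
  cm <- coverage_model(mean_reads_per_cell = 2e4, sigma_bias = 0,
                       dispersion = Inf)
  cnt <- simulate_read_counts(cn, cm, "single_cell")
  lam <- 2e4 / 20
  expect_lt(max(abs(colMeans(cnt) - lam)), 4 * sqrt(lam / 50))
  # row sums concentrate on R_i
  expect_lt(max(abs(rowSums(cnt) - 2e4)), 4 * sqrt(2e4))
  # expected counts are linear in copy number: regression slope = R / sum(c)
  cnv <- matrix(rep(c(1L, 2L, 3L, 4L, 6L), 4), 200, 20, byrow = TRUE)
  cntv <- simulate_read_counts(cnv, cm, "single_cell")
  fit <- stats::lm(colMeans(cntv) ~ cnv[1, ])
  slope <- unname(stats::coef(fit)[2])
  expect_lt(abs(slope - 2e4 / sum(cnv[1, ])) / (2e4 / sum(cnv[1, ])), 0.05)
  # negative binomial dispersion inflates the variance
  cmnb <- coverage_model(mean_reads_per_cell = 2e4, sigma_bias = 0,
                         dispersion = 2)
  cntnb <- simulate_read_counts(cn, cmnb, "single_cell")
  expect_gt(stats::var(as.numeric(cntnb)), 2 * stats::var(as.numeric(cnt)))
  # degenerate all-zero profile errors
  expect_error(simulate_read_counts(matrix(0L, 2, 5), cm, "single_cell"),
               "degenerate")
})

test_that("bulk mode mixes a diploid normal fraction", {
  set.seed(81)
  cn <- matrix(rep(c(4L, 2L, 1L), each = 10), 30, 30, byrow = TRUE)
  cm0 <- coverage_model(total_depth = 3e5, sigma_bias = 0,
                        normal_fraction = 0)
  b0 <- simulate_read_counts(cn, cm0, "bulk")
  expect_identical(nrow(b0), 1L)
  # expected counts proportional to the mean profile
  lam <- 3e5 * colMeans(cn) / sum(colMeans(cn))
  expect_lt(max(abs(b0[1, ] - lam) / sqrt(lam)), 5)
  # normal_fraction = 1: indistinguishable from a pure diploid profile
  cm1 <- coverage_model(total_depth = 3e5, sigma_bias = 0,
                        normal_fraction = 1)
  b1 <- simulate_read_counts(cn, cm1, "bulk")
  dip <- simulate_read_counts(matrix(2L, 1, 30), cm0, "bulk")
  expect_gt(suppressWarnings(
    stats::ks.test(as.numeric(b1), as.numeric(dip))$p.value), 0.01)
  # variant-allele read counts stay within depth
  lay <- tiny_layout()
  g <- apply_snv(init_diploid_genome(lay), 1, 2, 50, "driver")
  pr <- emit_profiles(list(c1 = g, c2 = g), lay)
  bc <- simulate_read_counts(pr$cn_total, cm0, "bulk")
  vr <- bulk_variant_reads(pr, bc, cm0)
  expect_identical(nrow(vr), 1L)
  expect_lte(vr$variant_reads, vr$depth)
})

test_that("sequence realization concatenates region references and applies transitions", {
  set.seed(91)
  lay <- genome_layout(2, 2, region_length = 40,
                       gene_class = rep("neutral", 8))
  ref <- synthetic_reference(lay)
  g <- init_diploid_genome(lay)
  seqs <- realize_sequences(g, ref, prefix = "c0")
  # diploid, no SNVs: every strand equals its reference chromosome
  expect_identical(as.character(seqs[["c0_chr1_strand1"]]),
                   as.character(ref[[1]]))
  expect_identical(as.character(seqs[["c0_chr2_strand4"]]),
                   as.character(ref[[2]]))
  # strand length identity: regions on strand x region_length
  expect_true(all(Biostrings::width(seqs) == 4 * 40))
  # one SNV differs from the reference at exactly one position (a transition)
  g1 <- apply_snv(g, 1, 2, 5, "driver")
  s1 <- as.character(realize_sequences(g1, ref)[[1]])
  r1 <- as.character(ref[[1]])
  diff <- which(strsplit(s1, "")[[1]] != strsplit(r1, "")[[1]])
  expect_identical(diff, 40L + 6L)
  pair <- c(substr(r1, diff, diff), substr(s1, diff, diff))
  expect_true(paste(pair, collapse = "") %in% c("AG", "GA", "CT", "TC"))
  # post-WGD cell emits twice the strand count
  expect_length(realize_sequences(apply_wgd(g), ref), 8L)
  # a too-short reference is a configuration error
  short <- Biostrings::DNAStringSet(c(substr(as.character(ref[[1]]), 1, 100),
                                      as.character(ref[[2]])))
  expect_error(realize_sequences(g, short), "shorter")
})

test_that("the read-simulator interface degrades to manifest-only mode", {
  set.seed(101)
  lay <- genome_layout(2, 1, region_length = 30,
                       gene_class = rep("neutral", 4))
  ref <- synthetic_reference(lay)
  g <- init_diploid_genome(lay)
  out <- withr::local_tempdir()
  expect_warning(
    man <- invoke_read_simulator(list(cellA = g, cellB = g), ref, out,
                                 coverage = 0.5),
    "manifest")
  expect_true(file.exists(file.path(out, "cellA.fasta")))
  expect_true(file.exists(file.path(out, "coverage_manifest.tsv")))
  # per-cell manifest coverage sums to the configured cell coverage
  for (cell in c("cellA", "cellB"))
    expect_equal(sum(man$coverage[man$cell == cell]), 0.5)
  # with a (mock) tool command, one output per cell is produced
  tool <- 'sh -c "touch {out}.fastq"'
  man2 <- invoke_read_simulator(list(cellA = g), ref, out, coverage = 0.5,
                                tool_cmd = tool)
  expect_true(file.exists(file.path(out, "cellA.fastq")))
  expect_error(
    invoke_read_simulator(list(cellA = g), ref, out, coverage = 0.5,
                          tool_cmd = "false"),
    "read simulator failed")
})
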
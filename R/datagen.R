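## Output data generation: mutation profiles, single-cell / bulk read counts.

#' Emit copy-number and SNV profile matrices for a set of cells
#'
#' @param genomes Named list mapping cell (or clone) id to `tumor_genome`.
#' @param layout The shared [genome_layout()].
#' @return A list with `cn_maternal`, `cn_paternal`, `cn_total` (cells x
#'   regions integer matrices), `snv` (cells x loci matrix of mutated-copy
#'   multiplicities; 0 = absent) and `loci` (data frame `region`, `offset`,
#'   `chrom`, `pos` with 1-based absolute position under the contiguous
#'   region-to-reference mapping).
#' @export
emit_profiles <- function(genomes, layout) {
  if (!length(genomes)) stop("emit_profiles needs at least one genome")
  cells <- names(genomes)
  R <- layout$n_regions
  cn_a <- matrix(0L, length(cells), R, dimnames = list(cells, NULL))
  cn_b <- cn_a
  snv_tabs <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    g <- genomes[[i]]
    prof <- copy_number_profile(g)
    cn_a[i, ] <- prof["maternal", ]
    cn_b[i, ] <- prof["paternal", ]
    snv_tabs[[i]] <- genome_snvs(g)
  }
  all_snv <- do.call(rbind, snv_tabs)
  if (nrow(all_snv)) {
    loci <- unique(all_snv[, c("region", "offset")])
    loci <- loci[order(loci$region, loci$offset), , drop = FALSE]
    key <- paste(loci$region, loci$offset)
    snv <- matrix(0L, length(cells), nrow(loci),
                  dimnames = list(cells, NULL))
    for (i in seq_along(cells)) {
      tb <- snv_tabs[[i]]
      if (!nrow(tb)) next
      j <- match(paste(tb$region, tb$offset), key)
      for (k in seq_along(j)) snv[i, j[k]] <- snv[i, j[k]] + 1L
    }
    loci$chrom <- layout$region_chrom[loci$region]
    loci$pos <- .region_start(layout, loci$region) + loci$offset
  } else {
    loci <- data.frame(region = integer(0), offset = numeric(0),
                       chrom = integer(0), pos = numeric(0))
    snv <- matrix(0L, length(cells), 0L, dimnames = list(cells, NULL))
  }
  rownames(loci) <- NULL
  list(cn_maternal = cn_a, cn_paternal = cn_b, cn_total = cn_a + cn_b,
       snv = snv, loci = loci)
}

## 1-based start of a region within its chromosome's reference sequence,
## under the contiguous mapping from the chromosome start
.region_start <- function(layout, region) {
  idx_within <- integer(length(region))
  for (i in seq_along(region)) {
    r <- region[i]
    k <- layout$region_chrom[r]
    idx_within[i] <- r - match(k, layout$region_chrom) + 1L
  }
  (idx_within - 1L) * layout$region_length + 1
}

#' Configure the read-count coverage model
#'
#' Counts follow a negative binomial around a rate proportional to the
#' region's copy number times a shared lognormal per-region bin bias;
#' `dispersion = Inf` degrades to Poisson.
#'
#' @param mean_reads_per_cell Expected total reads per cell (single-cell
#'   mode).
#' @param total_depth Expected total reads of the pseudobulk sample (bulk
#'   mode).
#' @param sigma_bias Standard deviation of the lognormal per-region bias
#'   (`0` = no bias); the bias vector is drawn once and shared across cells.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param normal_fraction Fraction of diploid normal cells mixed into the
#'   bulk profile, in `[0, 1)`... `[0, 1]` is accepted so a pure-normal
#'   control can be generated.
#' @return A `coverage_model` list.
#' @export
coverage_model <- function(mean_reads_per_cell = 1e5, total_depth = 1e7,
                           sigma_bias = 0.1, dispersion = Inf,
                           normal_fraction = 0) {
  if (mean_reads_per_cell <= 0 || total_depth <= 0)
    stop("read depths must be positive")
  if (sigma_bias < 0) stop("sigma_bias must be >= 0")
  if (dispersion <= 0) stop("dispersion must be positive (Inf = Poisson)")
  if (normal_fraction < 0 || normal_fraction > 1)
    stop("normal_fraction must be in [0, 1]")
  structure(list(mean_reads_per_cell = mean_reads_per_cell,
                 total_depth = total_depth, sigma_bias = sigma_bias,
                 dispersion = dispersion, normal_fraction = normal_fraction),
            class = "coverage_model")
}

#' Simulate per-region read counts from copy-number profiles
#'
#' Single-cell mode: for cell `i` and region `j`,
#' `lambda_ij = R_i * c_ij * bias_j / sum_k(c_ik * bias_k)` with
#' `R_i = mean_reads_per_cell`, and `count ~ NB(mean lambda, dispersion)`.
#' Bulk mode: the population profile
#' `cbar_j = (1 - normal_fraction) * mean_i(c_ij) + normal_fraction * 2`
#' is converted to a single row of counts at `total_depth` by the same
#' formula.
#'
#' @param cn_total Cells x regions matrix of total copy numbers.
#' @param cm A [coverage_model()].
#' @param mode `"single_cell"` or `"bulk"`.
#' @return Integer count matrix (cells x regions, or 1 x regions for bulk)
#'   with the per-region `bias` vector attached as an attribute.
#' @export
simulate_read_counts <- function(cn_total, cm, mode = c("single_cell", "bulk")) {
  mode <- match.arg(mode)
  if (!is.matrix(cn_total)) cn_total <- matrix(cn_total, nrow = 1)
  R <- ncol(cn_total)
  bias <- if (cm$sigma_bias > 0) stats::rlnorm(R, 0, cm$sigma_bias) else rep(1, R)

  draw <- function(lambda) {
    if (is.finite(cm$dispersion))
      stats::rnbinom(length(lambda), size = cm$dispersion, mu = lambda)
    else stats::rpois(length(lambda), lambda)
  }

  if (mode == "single_cell") {
    w <- sweep(cn_total, 2, bias, `*`)
    tot <- rowSums(w)
    if (any(tot == 0)) stop("degenerate input: a cell has an all-zero profile")
    lambda <- cm$mean_reads_per_cell * w / tot
    counts <- matrix(draw(lambda), nrow(cn_total), R,
                     dimnames = dimnames(cn_total))
  } else {
    cbar <- (1 - cm$normal_fraction) * colMeans(cn_total) +
      cm$normal_fraction * 2
    w <- cbar * bias
    if (sum(w) == 0) stop("degenerate input: all-zero bulk profile")
    lambda <- cm$total_depth * w / sum(w)
    counts <- matrix(draw(lambda), 1L, R, dimnames = list("bulk", NULL))
  }
  attr(counts, "bias") <- bias
  counts
}

#' Variant-allele read counts for bulk SNV loci
#'
#' For each SNV locus the local depth is drawn from the bulk coverage of the
#' locus's region and variant reads are `Binomial(depth, multiplicity / CN)`
#' where multiplicity and CN are averaged over the sampled cells (with the
#' diploid normal fraction contributing copy number 2 and no variant
#' copies).
#'
#' @param profiles Output of [emit_profiles()].
#' @param bulk_counts 1 x regions bulk count matrix from
#'   [simulate_read_counts()].
#' @param cm The [coverage_model()] used for the bulk counts.
#' @return Data frame `region`, `offset`, `chrom`, `pos`, `depth`,
#'   `variant_reads`.
#' @export
bulk_variant_reads <- function(profiles, bulk_counts, cm) {
  loci <- profiles$loci
  if (!nrow(loci)) {
    return(cbind(loci, data.frame(depth = integer(0),
                                  variant_reads = integer(0))))
  }
  nf <- cm$normal_fraction
  cn_mean <- (1 - nf) * colMeans(profiles$cn_total) + nf * 2
  mult_mean <- (1 - nf) * colMeans(profiles$snv)
  depth_region <- as.numeric(bulk_counts[1L, loci$region])
  n_reg <- as.numeric(table(factor(loci$region,
                                   levels = unique(loci$region))))[
    match(loci$region, unique(loci$region))]
  depth <- stats::rpois(nrow(loci), depth_region / pmax(1, n_reg))
  ## snv matrix columns are aligned with loci rows
  vaf <- pmin(1, mult_mean / pmax(cn_mean[loci$region], 1e-9))
  variant <- stats::rbinom(nrow(loci), depth, vaf)
  cbind(loci, data.frame(depth = depth, variant_reads = variant))
}
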
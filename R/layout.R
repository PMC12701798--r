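#' Define a region-resolved genome layout
#'
#' The simulator uses a simplified genome representation: each chromosome is
#' split into a p and a q arm, each arm into fixed-length regions. Regions are
#' the unit of the copy-number profile and carry a gene-class label: oncogene
#' (`"OG"`), tumor suppressor (`"TSG"`), `"essential"`, or `"neutral"`.
#' Region ids are stable integers `1..n_regions`, numbered chromosome by
#' chromosome, p arm before q arm.
#'
#' Gene classes are assigned by sampling regions without replacement according
#' to the class fractions (using the current RNG state), unless an explicit
#' `gene_class` vector is supplied.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param regions_per_arm Either a single count used for every arm, or an
#'   `n_chromosomes x 2` matrix of per-arm region counts (columns p, q).
#' @param region_length Bases per region (uniform across the genome).
#' @param frac_og,frac_tsg,frac_essential Fractions of regions assigned to
#'   the OG, TSG and essential classes; the remainder is neutral.
#' @param gene_class Optional explicit character vector of classes, one per
#'   region, overriding the random assignment.
#' @return An object of class `genome_layout`.
#' @examples
#' set.seed(1)
#' lay <- genome_layout(n_chromosomes = 2, regions_per_arm = 5)
#' lay$n_regions  # 20
#' @export
genome_layout <- function(n_chromosomes = 10,
                          regions_per_arm = 10,
                          region_length = 1e6,
                          frac_og = 0.10,
                          frac_tsg = 0.10,
                          frac_essential = 0.05,
                          gene_class = NULL) {
  if (n_chromosomes < 1) stop("layout must have at least one chromosome")
  if (region_length < 1) stop("region_length must be a positive number of bases")
  if (is.matrix(regions_per_arm)) {
    if (nrow(regions_per_arm) != n_chromosomes || ncol(regions_per_arm) != 2)
      stop("regions_per_arm matrix must be n_chromosomes x 2")
    rpa <- matrix(as.integer(regions_per_arm), n_chromosomes, 2)
  } else if (length(regions_per_arm) == 1L) {
    rpa <- matrix(as.integer(regions_per_arm), n_chromosomes, 2)
  } else {
    stop("regions_per_arm must be a scalar or an n_chromosomes x 2 matrix")
  }
  if (any(rpa < 1L)) stop("every chromosome arm needs at least one region")

  region_chrom <- integer(0)
  region_arm <- integer(0)
  for (k in seq_len(n_chromosomes)) {
    for (a in 1:2) {
      region_chrom <- c(region_chrom, rep.int(k, rpa[k, a]))
      region_arm <- c(region_arm, rep.int(a, rpa[k, a]))
    }
  }
  n_regions <- length(region_chrom)
  arm_id <- (region_chrom - 1L) * 2L + region_arm

  if (is.null(gene_class)) {
    fr <- c(frac_og, frac_tsg, frac_essential)
    if (any(fr < 0) || sum(fr) > 1)
      stop("gene-class fractions must be non-negative and sum to at most 1")
    n_og <- round(frac_og * n_regions)
    n_tsg <- round(frac_tsg * n_regions)
    n_ess <- round(frac_essential * n_regions)
    gene_class <- rep("neutral", n_regions)
    pick <- sample.int(n_regions, n_og + n_tsg + n_ess)
    gene_class[pick[seq_len(n_og)]] <- "OG"
    if (n_tsg > 0) gene_class[pick[n_og + seq_len(n_tsg)]] <- "TSG"
    if (n_ess > 0) gene_class[pick[n_og + n_tsg + seq_len(n_ess)]] <- "essential"
  } else {
    if (length(gene_class) != n_regions)
      stop("gene_class must have one entry per region")
    if (!all(gene_class %in% c("OG", "TSG", "essential", "neutral")))
      stop("gene_class entries must be OG, TSG, essential or neutral")
  }

  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    regions_per_arm = rpa,
    region_length = as.numeric(region_length),
    n_regions = n_regions,
    n_arms = 2L * as.integer(n_chromosomes),
    region_chrom = region_chrom,
    region_arm = region_arm,
    arm_id = arm_id,
    arm_sizes = tabulate(arm_id, 2L * n_chromosomes),
    gene_class = gene_class,
    essential_regions = which(gene_class == "essential")
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", x$n_chromosomes, "chromosomes,",
      x$n_regions, "regions of", format(x$region_length, big.mark = ","),
      "bp\n")
  cat("  gene classes:",
      paste(names(table(x$gene_class)), table(x$gene_class),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
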
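## Multiplicative, site-specific fitness landscapes.
## delta > 1: oncogene region (extra copies raise fitness);
## delta < 1: tumor suppressor (extra copies lower fitness, losses raise it);
## delta = 1: neutral. A stored 0 is treated as the no-effect sentinel (1).

#' Build site-specific selection landscapes
#'
#' One landscape per anatomical site, all over the same region set and gene
#' classes. Base coefficients are drawn once: OG regions
#' `delta ~ Uniform(1, 1 + s_max)`, TSG regions `delta ~ Uniform(1 - s_max, 1)`,
#' neutral and essential regions `delta = 1`. Per site, each non-neutral
#' effect is rescaled as `delta_site - 1 = (delta - 1) * (1 + 1.5 * divergence * z)`
#' with `z ~ Uniform(-1, 1)`, so the expected absolute difference of
#' coefficients between two sites equals `divergence * |delta - 1|`, i.e.
#' sites differ in their selection coefficients by about `divergence`
#' relative to the effect size, while every site preserves the OG/TSG
#' direction (requires `divergence < 2/3`).
#'
#' Chromosome-arm coefficients are derived per site as the product of the
#' arm's per-region coefficients, so the arm-level model agrees exactly with
#' the region-level model on whole-arm events when an arm's regions share one
#' coefficient, and the arm coefficient reflects the balance of OGs and TSGs
#' on the arm.
#'
#' @param layout A [genome_layout()].
#' @param n_sites Number of anatomical sites.
#' @param s_max Maximum selection-coefficient deviation from 1.
#' @param divergence Site-divergence parameter in `[0, 2/3)`; 0 gives
#'   identical landscapes at every site.
#' @param essential_penalty Multiplier `epsilon` in `(0, 1]` applied by the
#'   hybrid model when a driver SNV hits an essential-class region.
#' @return List of `n_sites` objects of class `selection_landscape`.
#' @export
build_landscapes <- function(layout, n_sites, s_max = 0.1, divergence = 0.2,
                             essential_penalty = 0.95) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (divergence < 0 || divergence >= 2 / 3)
    stop("divergence must be in [0, 2/3) to preserve OG/TSG direction")
  if (essential_penalty <= 0 || essential_penalty > 1)
    stop("essential_penalty must be in (0, 1]")
  R <- layout$n_regions
  base <- rep(1, R)
  og <- which(layout$gene_class == "OG")
  tsg <- which(layout$gene_class == "TSG")
  base[og] <- stats::runif(length(og), 1, 1 + s_max)
  base[tsg] <- stats::runif(length(tsg), 1 - s_max, 1)
  nz <- c(og, tsg)

  lapply(seq_len(n_sites), function(s) {
    delta <- base
    if (divergence > 0 && length(nz)) {
      z <- stats::runif(length(nz), -1, 1)
      delta[nz] <- 1 + (base[nz] - 1) * (1 + 1.5 * divergence * z)
    }
    new_landscape(layout, site = s, delta = delta,
                  essential_penalty = essential_penalty)
  })
}

#' Construct a selection landscape from explicit coefficients
#'
#' @param layout A [genome_layout()].
#' @param site Site id the landscape belongs to.
#' @param delta Numeric vector of per-region selection coefficients (0 is
#'   accepted as a no-effect sentinel and mapped to 1).
#' @param essential_penalty Hybrid-model SNV penalty for essential regions.
#' @return An object of class `selection_landscape`.
#' @export
new_landscape <- function(layout, site = 1L, delta = rep(1, layout$n_regions),
                          essential_penalty = 0.95) {
  if (length(delta) != layout$n_regions)
    stop("delta must have one coefficient per region")
  delta[delta == 0] <- 1  # stored-zero sentinel means "no effect"
  if (any(delta <= 0)) stop("selection coefficients must be positive")
  log_delta <- log(delta)
  # arm coefficient = product of region coefficients on the arm
  log_arm <- as.numeric(rowsum(log_delta, layout$arm_id))
  structure(list(site = as.integer(site), delta = delta,
                 log_delta = log_delta,
                 arm_delta = exp(log_arm), log_arm_delta = log_arm,
                 essential_penalty = essential_penalty,
                 gene_class = layout$gene_class,
                 arm_id = layout$arm_id,
                 arm_sizes = layout$arm_sizes),
            class = "selection_landscape")
}

#' Region-model fitness
#'
#' `f = prod_r delta_r ^ (c_r - 2)` where `c_r` is the total copy number of
#' region `r`. The diploid profile has fitness exactly 1.
#'
#' @param cn Total copy-number vector (or a `tumor_genome`, or an
#'   allele-specific profile matrix).
#' @param landscape A `selection_landscape`.
#' @return Positive fitness value.
#' @export
region_fitness <- function(cn, landscape) {
  cn <- .as_total_cn(cn)
  exp(sum((cn - 2) * landscape$log_delta))
}

#' Chromosome-arm-model fitness
#'
#' `f = prod_A delta_A ^ (cbar_A - 2)` where `cbar_A` is the mean total copy
#' number over the arm's regions (a real-valued exponent) and `delta_A` is
#' the product of the arm's per-region coefficients.
#'
#' @inheritParams region_fitness
#' @return Positive fitness value.
#' @export
arm_fitness <- function(cn, landscape) {
  cn <- .as_total_cn(cn)
  cbar <- as.numeric(rowsum(cn, landscape$arm_id)) / landscape$arm_sizes
  exp(sum((cbar - 2) * landscape$log_arm_delta))
}

#' Hybrid-model fitness
#'
#' Region-model fitness times one multiplier per region holding at least one
#' driver SNV: `delta_r` if `delta_r > 1` (oncogene activation), `1/delta_r`
#' if `delta_r < 1` (tumor-suppressor inactivation), the essential penalty
#' `epsilon` if the region is essential-class, and 1 otherwise. Multiple SNVs
#' in one region count once.
#'
#' @inheritParams region_fitness
#' @param snv_regions Integer vector of regions carrying at least one driver
#'   SNV (see [driver_snv_regions()]); extracted automatically when `cn` is a
#'   `tumor_genome`.
#' @return Positive fitness value.
#' @export
hybrid_fitness <- function(cn, landscape, snv_regions = NULL) {
  if (inherits(cn, "tumor_genome") && is.null(snv_regions))
    snv_regions <- driver_snv_regions(cn)
  cn <- .as_total_cn(cn)
  f <- exp(sum((cn - 2) * landscape$log_delta))
  if (length(snv_regions)) {
    ld <- landscape$log_delta[snv_regions]
    m <- ifelse(ld > 0, exp(ld),
         ifelse(ld < 0, exp(-ld),
         ifelse(landscape$gene_class[snv_regions] == "essential",
                landscape$essential_penalty, 1)))
    f <- f * prod(m)
  }
  f
}

.as_total_cn <- function(cn) {
  if (inherits(cn, "tumor_genome")) return(total_copy_number(cn))
  if (is.matrix(cn)) return(colSums(cn))
  cn
}

#' Fitness under a chosen selection model
#'
#' @param g A `tumor_genome`.
#' @param landscape A `selection_landscape`.
#' @param model `"region"`, `"arm"` or `"hybrid"`.
#' @return Positive fitness value.
#' @export
clone_fitness <- function(g, landscape, model = c("region", "arm", "hybrid")) {
  model <- match.arg(model)
  switch(model,
         region = region_fitness(g, landscape),
         arm = arm_fitness(g, landscape),
         hybrid = hybrid_fitness(g, landscape))
}

#' Per-site logistic growth parameters
#'
#' @param growth_rate Intrinsic per-generation growth rate `r > 0`.
#' @param carrying_capacity Logistic ceiling `K` in cells (may be `Inf` for
#'   unconstrained growth).
#' @param turnover Turnover rate `tau` in `(0, 1]`: the per-generation
#'   probability that a cell completes its lifespan. `tau = 1` is a fixed
#'   one-generation lifespan; `tau < 1` is the memoryless discrete analogue
#'   of exponentially distributed lifespans with mean `1/tau` generations.
#' @return A `growth_params` list.
#' @export
growth_params <- function(growth_rate = 0.4, carrying_capacity = 1e5,
                          turnover = 1) {
  if (growth_rate <= 0) stop("growth_rate must be positive")
  if (carrying_capacity < 1) stop("carrying_capacity must be >= 1")
  if (turnover <= 0 || turnover > 1) stop("turnover must be in (0, 1]")
  structure(list(growth_rate = growth_rate,
                 carrying_capacity = carrying_capacity,
                 turnover = turnover), class = "growth_params")
}

#' Division probability of a cell completing its lifespan
#'
#' `p = clamp((f / f_mean) * (1 + r * (1 - N / K)) / 2, 0, 1)`. The cell dies
#' with probability `1 - p`. For a neutral population (`f = f_mean`) this
#' yields the exact logistic recursion `E[N'] = N * (1 + r * (1 - N / K))`;
#' at the carrying capacity it is the stationary value 1/2.
#'
#' @param f Fitness of the cell at its site.
#' @param f_mean Population mean fitness at the site.
#' @param N Current site population size.
#' @param gp A [growth_params()] list.
#' @return Probability in `[0, 1]`.
#' @export
division_probability <- function(f, f_mean, N, gp) {
  if (any(f <= 0) || f_mean <= 0)
    stop("internal error: nonpositive fitness reached the division step")
  r <- gp$growth_rate
  K <- gp$carrying_capacity
  grow <- if (is.finite(K)) 1 + r * (1 - N / K) else 1 + r
  pmin(1, pmax(0, (f / f_mean) * grow / 2))
}
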
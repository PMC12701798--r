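## Genome representation: a multiset of chromosome strands, each an ordered
## vector of region ids, plus SNVs attached to (strand, position-slot).
## Storing SNVs against position slots (not bare region ids) gives physical
## copying semantics: tandem duplication co-duplicates the SNVs inside the
## duplicated slice and deletion drops them.

.new_strand <- function(id, chrom, allele, regions,
                        snv_pos = integer(0), snv_offset = numeric(0),
                        snv_origin = character(0)) {
  list(id = as.integer(id), chrom = as.integer(chrom), allele = allele,
       regions = as.integer(regions), snv_pos = as.integer(snv_pos),
       snv_offset = as.numeric(snv_offset), snv_origin = snv_origin)
}

#' Initialize a diploid founder genome
#'
#' Creates two strands (maternal, paternal) per chromosome, each carrying the
#' full ordered region list of that chromosome, with no SNVs and no
#' whole-genome duplications.
#'
#' @param layout A [genome_layout()].
#' @return An object of class `tumor_genome`.
#' @export
init_diploid_genome <- function(layout) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  strands <- vector("list", 2L * layout$n_chromosomes)
  nm <- character(length(strands))
  id <- 0L
  for (k in seq_len(layout$n_chromosomes)) {
    regs <- which(layout$region_chrom == k)
    for (allele in c("maternal", "paternal")) {
      id <- id + 1L
      strands[[id]] <- .new_strand(id, k, allele, regs)
      nm[id] <- as.character(id)
    }
  }
  names(strands) <- nm
  structure(list(strands = strands, wgd_count = 0L, next_strand = id + 1L,
                 log = list(), layout = layout),
            class = "tumor_genome")
}

#' @export
print.tumor_genome <- function(x, ...) {
  cat("tumor_genome:", length(x$strands), "strands,",
      sum(genome_snv_count(x)), "SNV copies,",
      x$wgd_count, "WGD(s),", length(x$log), "logged events\n")
  invisible(x)
}

.strand_lengths <- function(g) {
  vapply(g$strands, function(s) length(s$regions), integer(1))
}

genome_snv_count <- function(g) {
  vapply(g$strands, function(s) length(s$snv_pos), integer(1))
}

.log_event <- function(g, ev) {
  g$log[[length(g$log) + 1L]] <- ev
  g
}

#' Apply a segmental amplification or deletion
#'
#' Operates on a contiguous slice of regions on one strand. Gains are tandem:
#' the slice is duplicated in place, immediately after the original. Losses
#' remove the slice; a fully emptied strand is removed from the genome. SNVs
#' inside a duplicated slice are co-duplicated; SNVs inside a deleted slice
#' are dropped. The slice is half-open in 0-based coordinates:
#' `[start, start + length)`, truncated at the strand end.
#'
#' @param g A `tumor_genome`.
#' @param strand_id Id of the strand to modify.
#' @param start 0-based index of the first region of the slice.
#' @param length Number of regions in the slice (>= 1).
#' @param kind `"gain"` or `"loss"`.
#' @param generation Generation at which the event occurs (stored in the
#'   event log; may be fractional for passenger events).
#' @return The modified genome.
#' @export
apply_segmental_event <- function(g, strand_id, start, length, kind,
                                  generation = NA_real_) {
  kind <- match.arg(kind, c("gain", "loss"))
  key <- as.character(strand_id)
  st <- g$strands[[key]]
  if (is.null(st)) stop("internal consistency error: unknown strand ", strand_id)
  L <- base::length(st$regions)
  if (start < 0 || start >= L) stop("segmental start out of range")
  if (length < 1) stop("segmental length must be >= 1")
  s <- as.integer(start) + 1L
  e <- min(L, as.integer(start) + as.integer(length))
  seglen <- e - s + 1L

  if (kind == "gain") {
    st$regions <- append(st$regions, st$regions[s:e], after = e)
    if (base::length(st$snv_pos)) {
      in_slice <- st$snv_pos >= s & st$snv_pos <= e
      after <- st$snv_pos > e
      dup_pos <- st$snv_pos[in_slice] + seglen
      dup_off <- st$snv_offset[in_slice]
      dup_org <- st$snv_origin[in_slice]
      st$snv_pos[after] <- st$snv_pos[after] + seglen
      st$snv_pos <- c(st$snv_pos, dup_pos)
      st$snv_offset <- c(st$snv_offset, dup_off)
      st$snv_origin <- c(st$snv_origin, dup_org)
    }
    g$strands[[key]] <- st
  } else {
    removed <- logical(L)
    removed[s:e] <- TRUE
    if (all(removed)) {
      g$strands[[key]] <- NULL
    } else {
      if (base::length(st$snv_pos)) {
        newindex <- cumsum(!removed)
        keep <- !removed[st$snv_pos]
        st$snv_pos <- newindex[st$snv_pos[keep]]
        st$snv_offset <- st$snv_offset[keep]
        st$snv_origin <- st$snv_origin[keep]
      }
      st$regions <- st$regions[!removed]
      g$strands[[key]] <- st
    }
  }
  .log_event(g, list(kind = paste0("segmental_", kind),
                     generation = generation,
                     strand_id = as.integer(strand_id),
                     start = as.integer(start),
                     length = as.integer(length)))
}

#' Apply a chromosome-arm or whole-chromosome missegregation
#'
#' A gain creates a new strand (with a fresh strand id) copying the target
#' strand (chromosome scope) or the target arm's regions on that strand (arm
#' scope); SNVs are copied onto the new strand. A loss removes the target
#' strand, or the arm's regions from it.
#'
#' @param g A `tumor_genome`.
#' @param scope `"arm"` or `"chromosome"`.
#' @param strand_id Target strand id.
#' @param arm For arm scope, `1` (p) or `2` (q).
#' @param kind `"gain"` or `"loss"`.
#' @param generation Generation of the event (for the log).
#' @return The modified genome.
#' @export
apply_missegregation <- function(g, scope, strand_id, kind, arm = NULL,
                                 generation = NA_real_) {
  scope <- match.arg(scope, c("arm", "chromosome"))
  kind <- match.arg(kind, c("gain", "loss"))
  key <- as.character(strand_id)
  st <- g$strands[[key]]
  if (is.null(st)) stop("internal consistency error: unknown strand ", strand_id)

  if (scope == "chromosome") {
    if (kind == "gain") {
      nid <- g$next_strand
      ns <- st
      ns$id <- nid
      g$strands[[as.character(nid)]] <- ns
      g$next_strand <- nid + 1L
    } else {
      g$strands[[key]] <- NULL
    }
    ev <- list(kind = paste0("chrom_misseg_", kind), generation = generation,
               strand_id = as.integer(strand_id))
  } else {
    if (is.null(arm) || !(arm %in% 1:2)) stop("arm scope requires arm = 1 or 2")
    idx <- which(g$layout$region_arm[st$regions] == arm)
    if (!base::length(idx))
      stop("internal consistency error: strand ", strand_id,
           " carries no regions on arm ", arm)
    if (kind == "gain") {
      nid <- g$next_strand
      sel <- if (base::length(st$snv_pos)) st$snv_pos %in% idx else logical(0)
      ns <- .new_strand(nid, st$chrom, st$allele, st$regions[idx],
                        snv_pos = match(st$snv_pos[sel], idx),
                        snv_offset = st$snv_offset[sel],
                        snv_origin = st$snv_origin[sel])
      g$strands[[as.character(nid)]] <- ns
      g$next_strand <- nid + 1L
    } else {
      L <- base::length(st$regions)
      removed <- logical(L)
      removed[idx] <- TRUE
      if (all(removed)) {
        g$strands[[key]] <- NULL
      } else {
        if (base::length(st$snv_pos)) {
          newindex <- cumsum(!removed)
          keep <- !removed[st$snv_pos]
          st$snv_pos <- newindex[st$snv_pos[keep]]
          st$snv_offset <- st$snv_offset[keep]
          st$snv_origin <- st$snv_origin[keep]
        }
        st$regions <- st$regions[!removed]
        g$strands[[key]] <- st
      }
    }
    ev <- list(kind = paste0("arm_misseg_", kind), generation = generation,
               strand_id = as.integer(strand_id), arm = as.integer(arm))
  }
  .log_event(g, ev)
}

#' Apply a whole-genome duplication
#'
#' Every strand is duplicated with a fresh strand id (SNVs copied) and the
#' genome's WGD counter is incremented; every region's total copy number
#' exactly doubles.
#'
#' @param g A `tumor_genome`.
#' @param generation Generation of the event (for the log).
#' @return The modified genome.
#' @export
apply_wgd <- function(g, generation = NA_real_) {
  if (!length(g$strands)) stop("cannot duplicate an empty genome")
  nid <- g$next_strand
  new <- vector("list", length(g$strands))
  nm <- character(length(new))
  for (i in seq_along(g$strands)) {
    ns <- g$strands[[i]]
    ns$id <- nid
    new[[i]] <- ns
    nm[i] <- as.character(nid)
    nid <- nid + 1L
  }
  names(new) <- nm
  g$strands <- c(g$strands, new)
  g$next_strand <- nid
  g$wgd_count <- g$wgd_count + 1L
  .log_event(g, list(kind = "wgd", generation = generation))
}

#' Add an SNV to a genome
#'
#' Places a single-nucleotide variant on one occurrence of `region` on the
#' given strand. Adding an SNV never changes the copy-number profile. A
#' duplicate site (same strand occurrence and offset) raises a condition of
#' class `oncosim_duplicate_snv`, signalling the caller to re-draw the
#' position.
#'
#' @param g A `tumor_genome`.
#' @param strand_id Strand carrying the region.
#' @param region Region id.
#' @param offset 0-based base position within the region,
#'   `0 <= offset < region_length`.
#' @param origin `"driver"` or `"passenger"`.
#' @param occurrence Which occurrence of `region` on the strand carries the
#'   SNV (1-based; occurrences beyond 1 exist only after tandem duplication).
#' @param generation Generation of the event (for the log).
#' @return The modified genome.
#' @export
apply_snv <- function(g, strand_id, region, offset, origin = "driver",
                      occurrence = 1L, generation = NA_real_) {
  origin <- match.arg(origin, c("driver", "passenger"))
  key <- as.character(strand_id)
  st <- g$strands[[key]]
  if (is.null(st)) stop("internal consistency error: unknown strand ", strand_id)
  if (offset < 0 || offset >= g$layout$region_length)
    stop("SNV offset outside the region")
  pos <- which(st$regions == region)[occurrence]
  if (is.na(pos))
    stop("strand ", strand_id, " does not carry occurrence ", occurrence,
         " of region ", region)
  if (any(st$snv_pos == pos & st$snv_offset == offset))
    stop(structure(list(message = "duplicate SNV site; re-draw the position",
                        call = sys.call()),
                   class = c("oncosim_duplicate_snv", "error", "condition")))
  st$snv_pos <- c(st$snv_pos, pos)
  st$snv_offset <- c(st$snv_offset, as.numeric(offset))
  st$snv_origin <- c(st$snv_origin, origin)
  g$strands[[key]] <- st
  .log_event(g, list(kind = "snv", generation = generation,
                     strand_id = as.integer(strand_id),
                     region = as.integer(region), offset = as.numeric(offset),
                     origin = origin, occurrence = as.integer(occurrence)))
}

#' Allele-specific copy-number profile
#'
#' @param g A `tumor_genome`.
#' @return A `2 x n_regions` integer matrix with rows `maternal` and
#'   `paternal`; the total copy number of a region is the column sum.
#' @export
copy_number_profile <- function(g) {
  R <- g$layout$n_regions
  out <- matrix(0L, 2L, R, dimnames = list(c("maternal", "paternal"), NULL))
  for (st in g$strands) {
    row <- if (st$allele == "maternal") 1L else 2L
    out[row, ] <- out[row, ] + tabulate(st$regions, R)
  }
  out
}

#' Total copy number per region
#'
#' @param g A `tumor_genome` or an allele-specific profile matrix as returned
#'   by [copy_number_profile()].
#' @return Integer vector of per-region total copy numbers.
#' @export
total_copy_number <- function(g) {
  if (inherits(g, "tumor_genome")) g <- copy_number_profile(g)
  colSums(g)
}

#' Regions carrying at least one driver SNV
#'
#' Used by the hybrid selection model.
#' @param g A `tumor_genome`.
#' @return Sorted integer vector of region ids.
#' @export
driver_snv_regions <- function(g) {
  regs <- integer(0)
  for (st in g$strands) {
    if (length(st$snv_pos)) {
      drv <- st$snv_origin == "driver"
      if (any(drv)) regs <- c(regs, st$regions[st$snv_pos[drv]])
    }
  }
  sort(unique(regs))
}

#' All SNVs of a genome as a table
#'
#' @param g A `tumor_genome`.
#' @return Data frame with columns `strand_id`, `region`, `offset`, `origin`;
#'   one row per SNV copy (a co-duplicated SNV appears once per carrying
#'   occurrence).
#' @export
genome_snvs <- function(g) {
  rows <- lapply(g$strands, function(st) {
    if (!length(st$snv_pos)) return(NULL)
    data.frame(strand_id = st$id, region = st$regions[st$snv_pos],
               offset = st$snv_offset, origin = st$snv_origin)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(strand_id = integer(0), region = integer(0),
                      offset = numeric(0), origin = character(0))
  rownames(out) <- NULL
  out
}

#' Viability limits for the mutation checkpoints
#'
#' Cells are checked upon acquiring a new driver mutation and die immediately
#' if any condition fails: a homozygously deleted essential region, a mean
#' total copy number above `max_mean_cn`, any single region above
#' `max_region_cn`, or more than `max_wgd` whole-genome duplications.
#'
#' @param max_mean_cn Maximum mean total copy number over all regions.
#' @param max_region_cn Maximum total copy number of any single region.
#' @param max_wgd Maximum number of whole-genome duplications.
#' @return A named list of limits.
#' @export
viability_limits <- function(max_mean_cn = 8, max_region_cn = 10, max_wgd = 2) {
  list(max_mean_cn = max_mean_cn, max_region_cn = max_region_cn,
       max_wgd = max_wgd)
}

#' Check genome viability
#'
#' @param g A `tumor_genome`.
#' @param limits A [viability_limits()] list.
#' @return `TRUE` if the genome passes every checkpoint, otherwise `FALSE`.
#' @export
check_viability <- function(g, limits = viability_limits()) {
  if (!length(g$strands)) return(FALSE)
  if (g$wgd_count > limits$max_wgd) return(FALSE)
  tc <- total_copy_number(g)
  ess <- g$layout$essential_regions
  if (length(ess) && any(tc[ess] == 0L)) return(FALSE)
  if (mean(tc) > limits$max_mean_cn) return(FALSE)
  if (any(tc > limits$max_region_cn)) return(FALSE)
  TRUE
}

#' Replay a mutation-event log on a fresh diploid founder
#'
#' Events are replayed in order exactly as logged; because strand ids are
#' assigned deterministically, replaying a genome's own log reproduces its
#' copy-number profile and SNV set.
#'
#' @param layout A [genome_layout()].
#' @param events A list of event records as found in `genome$log`.
#' @param tolerant If `TRUE`, events whose target strand no longer exists are
#'   silently skipped (used when passenger events are interleaved with driver
#'   events recorded in their absence); if `FALSE` such events are errors.
#' @return A `tumor_genome`.
#' @export
replay_events <- function(layout, events, tolerant = FALSE) {
  g <- init_diploid_genome(layout)
  for (ev in events) {
    g <- apply_event(g, ev, tolerant = tolerant)
  }
  g
}

#' Apply one logged event record to a genome
#'
#' @param g A `tumor_genome`.
#' @param ev A single event record (list with a `kind` field).
#' @param tolerant See [replay_events()].
#' @return The modified genome.
#' @export
apply_event <- function(g, ev, tolerant = FALSE) {
  key <- if (!is.null(ev$strand_id)) as.character(ev$strand_id) else NULL
  if (tolerant && !is.null(key) && is.null(g$strands[[key]])) return(g)
  switch(ev$kind,
    snv = {
      st <- g$strands[[key]]
      occ <- ev$occurrence
      pos_cand <- which(st$regions == ev$region)
      if (!length(pos_cand)) {
        if (tolerant) return(g) else stop("replay failure: region absent")
      }
      if (is.na(pos_cand[occ])) occ <- 1L
      pos <- pos_cand[occ]
      if (any(st$snv_pos == pos & st$snv_offset == ev$offset)) {
        if (tolerant) return(g) else stop("replay failure: duplicate SNV")
      }
      apply_snv(g, ev$strand_id, ev$region, ev$offset, ev$origin, occ,
                ev$generation)
    },
    segmental_gain = ,
    segmental_loss = {
      st <- g$strands[[key]]
      start <- ev$start
      if (start >= length(st$regions)) {
        if (tolerant) start <- length(st$regions) - 1L
        else stop("replay failure: segmental start out of range")
      }
      apply_segmental_event(g, ev$strand_id, start, ev$length,
                            sub("segmental_", "", ev$kind), ev$generation)
    },
    arm_misseg_gain = ,
    arm_misseg_loss = {
      st <- g$strands[[key]]
      if (!any(g$layout$region_arm[st$regions] == ev$arm)) {
        if (tolerant) return(g) else stop("replay failure: arm absent")
      }
      apply_missegregation(g, "arm", ev$strand_id,
                           sub("arm_misseg_", "", ev$kind), ev$arm,
                           ev$generation)
    },
    chrom_misseg_gain = ,
    chrom_misseg_loss = {
      apply_missegregation(g, "chromosome", ev$strand_id,
                           sub("chrom_misseg_", "", ev$kind),
                           generation = ev$generation)
    },
    wgd = {
      if (!length(g$strands)) {
        if (tolerant) return(g) else stop("replay failure: empty genome")
      }
      apply_wgd(g, ev$generation)
    },
    stop("unknown event kind: ", ev$kind)
  )
}

#' Retrieve the mutation-event log of a genome
#'
#' @param g A `tumor_genome`.
#' @return List of event records, in order of application.
#' @export
genome_events <- function(g) g$log
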
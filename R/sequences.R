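## Per-cell mutated reference sequences. Each region maps to a fixed,
## contiguous interval of its chromosome's reference sequence starting at
## the chromosome start; the unused reference tail is ignored. A strand's
## sequence is the concatenation of the reference substrings of its region
## list, with each SNV applied as a deterministic transition substitution.

.transition <- c(A = "G", G = "A", C = "T", T = "C",
                 a = "g", g = "a", c = "t", t = "c")

#' Construct the mutated sequences of one genome
#'
#' @param g A `tumor_genome`.
#' @param reference A [Biostrings::DNAStringSet] with one sequence per
#'   chromosome, each at least `regions_per_chromosome * region_length`
#'   bases long.
#' @param prefix Name prefix for the emitted records; each strand becomes
#'   `<prefix>_chr<k>_strand<m>`.
#' @return A `DNAStringSet` with one record per strand; a strand's length is
#'   always `number of regions * region_length`.
#' @export
realize_sequences <- function(g, reference, prefix = "cell") {
  layout <- g$layout
  if (length(reference) < layout$n_chromosomes)
    stop("reference must supply one sequence per chromosome")
  ref_chr <- lapply(seq_len(layout$n_chromosomes), function(k) {
    need <- sum(layout$region_chrom == k) * layout$region_length
    if (Biostrings::width(reference)[k] < need)
      stop("reference chromosome ", k, " is shorter than the layout extent (",
           need, " bp)")
    as.character(reference[[k]])
  })
  L <- layout$region_length
  ## cache region substrings per chromosome
  region_seq <- function(r) {
    k <- layout$region_chrom[r]
    start <- .region_start(layout, r)
    substr(ref_chr[[k]], start, start + L - 1)
  }

  seqs <- character(length(g$strands))
  nms <- character(length(g$strands))
  for (i in seq_along(g$strands)) {
    st <- g$strands[[i]]
    s <- paste0(vapply(st$regions, region_seq, character(1)), collapse = "")
    if (length(st$snv_pos)) {
      at <- (st$snv_pos - 1) * L + st$snv_offset + 1
      for (j in seq_along(at)) {
        base <- substr(s, at[j], at[j])
        sub <- .transition[base]
        if (!is.na(sub)) substr(s, at[j], at[j]) <- sub
      }
    }
    seqs[i] <- s
    nms[i] <- paste0(prefix, "_chr", st$chrom, "_strand", st$id)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  out
}

#' Generate a random reference genome matching a layout
#'
#' Convenience generator for tests and self-contained runs (labelled
#' synthetic: a real reference FASTA can be passed anywhere this output is
#' used).
#'
#' @param layout A [genome_layout()].
#' @return A `DNAStringSet` with one random sequence per chromosome, exactly
#'   covering the layout extent.
#' @export
synthetic_reference <- function(layout) {
  seqs <- vapply(seq_len(layout$n_chromosomes), function(k) {
    need <- sum(layout$region_chrom == k) * layout$region_length
    paste0(sample(c("A", "C", "G", "T"), need, replace = TRUE), collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("chr", seq_len(layout$n_chromosomes))
  out
}

#' Write per-cell FASTA files and invoke a short-read simulator
#'
#' For every cell, writes the mutated strand sequences as FASTA together
#' with a coverage manifest (the cell's total coverage apportioned over
#' strands by strand length). When a tool command template is configured the
#' tool is shelled out per cell; otherwise the function degrades, with a
#' warning, to manifest-only mode (FASTA + manifest, no reads). Read
#' simulation itself (error models, quality strings) is delegated entirely
#' to the external tool.
#'
#' @param genomes Named list of cell id to `tumor_genome`.
#' @param reference Reference `DNAStringSet` (see [realize_sequences()]).
#' @param outdir Output directory (created if needed).
#' @param coverage Total per-cell coverage (e.g. 0.1 for shallow
#'   single-cell whole-genome sequencing).
#' @param tool_cmd Optional command template with placeholders `{fasta}`,
#'   `{coverage}` and `{out}`; run through the shell once per cell.
#' @return Data frame manifest with columns `cell`, `strand`, `length`,
#'   `coverage` (also written to `coverage_manifest.tsv`).
#' @export
invoke_read_simulator <- function(genomes, reference, outdir,
                                  coverage = 0.1, tool_cmd = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tool_cmd))
    warning("no read-simulator command configured; writing per-cell FASTA ",
            "and coverage manifest only")
  rows <- list()
  for (cell in names(genomes)) {
    seqs <- realize_sequences(genomes[[cell]], reference, prefix = cell)
    fasta <- file.path(outdir, paste0(cell, ".fasta"))
    Biostrings::writeXStringSet(seqs, fasta)
    w <- Biostrings::width(seqs)
    cov <- coverage * w / sum(w)
    rows[[cell]] <- data.frame(cell = cell, strand = names(seqs),
                               length = w, coverage = cov)
    if (!is.null(tool_cmd)) {
      cmd <- gsub("{fasta}", fasta, tool_cmd, fixed = TRUE)
      cmd <- gsub("{coverage}", format(coverage, scientific = FALSE), cmd,
                  fixed = TRUE)
      cmd <- gsub("{out}", file.path(outdir, cell), cmd, fixed = TRUE)
      status <- system(cmd)
      if (status != 0)
        stop("read simulator failed for ", cell, " (exit ", status,
             "): ", cmd)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(outdir, "coverage_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
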
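## Loss-of-heterozygosity run test.
##
## A hemizygous deletion destroys heterozygous calls, so a large deletion
## segregating with the disease shows up as a long run in which every
## affected individual is homozygous (or missing).  Such a deletion can
## also split one linked region into two in the sharing scan, so detected
## runs are annotated onto overlapping or adjacent candidate regions.

#' LOH run-test parameters
#'
#' @param min_kb minimum run span in kb; runs must exceed it strictly
#'   (default 500, i.e. "> 500 kb").
#' @param min_snps minimum SNPs in a run (default 25).
#' @param max_het_run heterozygous calls (summed over affected individuals)
#'   tolerated per run before it is split at the offending site
#'   (default 0).
#' @return list of class `LOHParams`.
#' @export
loh_params <- function(min_kb = 500, min_snps = 25, max_het_run = 0) {
  stopifnot(min_kb > 0, min_snps >= 1, max_het_run >= 0)
  structure(list(min_kb = min_kb, min_snps = min_snps,
                 max_het_run = max_het_run), class = "LOHParams")
}

#' Detect candidate-deletion LOH runs
#'
#' Finds maximal runs of consecutive SNPs at which every affected
#' individual is homozygous or missing, allowing up to `max_het_run`
#' heterozygous calls per run (beyond that the run is split at the
#' offending site, each part judged against the thresholds separately).
#' Runs are reported when their span strictly exceeds `min_kb` and they
#' hold at least `min_snps` SNPs.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map the matching [marker_map()].
#' @param affected_ids ids (rownames) of the affected individuals.
#' @param params a [loh_params()].
#' @return data frame: `chrom`, `start_bp`, `end_bp`, `n_snps`, `n_het`.
#' @export
detect_loh <- function(genotypes, map, affected_ids, params = loh_params()) {
  stopifnot(length(affected_ids) >= 1)
  G <- genotypes[affected_ids, , drop = FALSE]
  het_calls <- colSums(G == 1L, na.rm = TRUE)
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    h <- het_calls[sel]; pos <- map$bp[sel]
    # greedy left-to-right walk, splitting at the het call that would
    # exceed the budget (the offending site joins neither part)
    n <- length(sel); i <- 1L
    while (i <= n) {
      if (h[i] > params$max_het_run) { i <- i + 1L; next }
      used <- h[i]; j <- i
      while (j < n && used + h[j + 1L] <= params$max_het_run) {
        used <- used + h[j + 1L]; j <- j + 1L
      }
      span <- pos[j] - pos[i] + 1
      if (span > params$min_kb * 1000 && (j - i + 1L) >= params$min_snps)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start_bp = pos[i], end_bp = pos[j],
          n_snps = j - i + 1L, n_het = used)
      i <- j + 1L
      if (i <= n && h[i] > 0L) i <- i + 1L
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(), n_het = integer()))
  do.call(rbind, out)
}

#' Annotate candidate regions with nearby LOH runs
#'
#' Regions overlapping, or within `gap_kb` of, a detected LOH run receive a
#' note that a deletion may have split one linked region in two.
#'
#' @param regions candidate-region data frame ([score_segments()]).
#' @param loh_runs output of [detect_loh()].
#' @param gap_kb adjacency margin in kb (default 100).
#' @return `regions` with an added `loh_note` character column.
#' @export
annotate_loh <- function(regions, loh_runs, gap_kb = 100) {
  regions$loh_note <- ""
  if (nrow(regions) == 0L || is.null(loh_runs) || nrow(loh_runs) == 0L)
    return(regions)
  gap <- gap_kb * 1000
  for (i in seq_len(nrow(regions))) {
    hit <- loh_runs$chrom == regions$chrom[i] &
      loh_runs$start_bp <= regions$end_bp[i] + gap &
      loh_runs$end_bp >= regions$start_bp[i] - gap
    if (any(hit))
      regions$loh_note[i] <- "possible deletion - two linked regions may be one"
  }
  regions
}
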
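## Sliding-window haplotype-sharing scan.
##
## Per SNP, over the assured aHaps: a SNP is *evaluable* when at least two
## aHaps have a resolved allele there, and *consistent* when all resolved
## alleles agree.  Windows are placed in physical (bp) space; a window is
## homozygous when it holds at least `min_snps` evaluable SNPs and its
## inconsistent fraction is strictly below the tolerance.  Consecutive
## homozygous windows (they overlap or abut whenever step <= window) merge
## into one segment whose bounds snap to the outermost consistent SNPs:
## the merged span is extended outward, at most one window length past each
## edge, until the first inconsistent evaluable SNP.

#' Scan parameters
#'
#' @param window_kb window length in kilobases (default 500).
#' @param step_kb step size in kilobases (default 50; must not exceed the
#'   window so consecutive windows overlap or abut).
#' @param tolerance maximum tolerated inconsistent-SNP fraction per window;
#'   the comparison is strict (`< tolerance`), taking "less than 5%"
#'   literally (default 0.05).
#' @param min_snps minimum evaluable SNPs for a window to carry evidence
#'   (default 20); sparser windows are uninformative and break merging.
#' @return list of class `ScanParams`.
#' @export
scan_params <- function(window_kb = 500, step_kb = 50, tolerance = 0.05,
                        min_snps = 20) {
  stopifnot(step_kb > 0, step_kb <= window_kb, tolerance >= 0, tolerance < 1,
            min_snps >= 1)
  structure(list(window_kb = window_kb, step_kb = step_kb,
                 tolerance = tolerance, min_snps = min_snps),
            class = "ScanParams")
}

# per-SNP consistency among assured aHaps
.site_consistency <- function(A) {
  resolved <- colSums(!is.na(A))
  mx <- do.call(pmax, c(lapply(seq_len(nrow(A)), function(i) A[i, ]), na.rm = TRUE))
  mn <- do.call(pmin, c(lapply(seq_len(nrow(A)), function(i) A[i, ]), na.rm = TRUE))
  evaluable <- resolved >= 2L
  list(evaluable = evaluable,
       consistent = evaluable & (mx == mn),
       consensus = ifelse(evaluable & (mx == mn), mx, NA_integer_))
}

#' Inconsistent-SNP fraction of one window
#'
#' SNPs with fewer than two resolved aHap alleles are excluded from both
#' numerator and denominator; a window with no evaluable SNP returns `NA`
#' (an uninformative window, treated as non-homozygous).
#'
#' @param ahaps integer matrix of assured aHap alleles (rows = aHaps), as
#'   from [ahap_matrix()].
#' @param idx column indices of the window (default: all columns).
#' @return fraction in `[0, 1]`, or `NA` for an uninformative window.
#' @export
window_inconsistency <- function(ahaps, idx = seq_len(ncol(ahaps))) {
  cs <- .site_consistency(ahaps[, idx, drop = FALSE])
  n_eval <- sum(cs$evaluable)
  if (n_eval == 0L) return(NA_real_)
  sum(cs$evaluable & !cs$consistent) / n_eval
}

.merge_run_segment <- function(run_lo_bp, run_hi_bp, pos, cons, eval, window_bp) {
  # indices inside the merged window span
  inside <- which(pos >= run_lo_bp & pos <= run_hi_bp)
  b1 <- inside[which(cons[inside])[1]]
  b2 <- inside[rev(which(cons[inside]))[1]]
  if (is.na(b1)) return(NULL)
  # extend outward, capped at one window length beyond the span edge,
  # stopping at the first inconsistent evaluable SNP
  i <- min(inside) - 1L
  while (i >= 1L && pos[i] >= run_lo_bp - window_bp) {
    if (eval[i] && !cons[i]) break
    if (cons[i]) b1 <- i
    i <- i - 1L
  }
  i <- max(inside) + 1L
  while (i <= length(pos) && pos[i] <= run_hi_bp + window_bp) {
    if (eval[i] && !cons[i]) break
    if (cons[i]) b2 <- i
    i <- i + 1L
  }
  c(b1, b2)
}

#' Scan one chromosome for segments shared by all assured aHaps
#'
#' @param ahapset an `AHapSet` from [select_ahaps()].
#' @param map the [marker_map()] aligned with the aHap allele vectors.
#' @param params a [scan_params()].
#' @param chrom chromosome label to scan.
#' @param allow_single_ahap with a single assured aHap every window is
#'   trivially homozygous; unless this is `TRUE` such a scan warns
#'   (`W_UNPOWERED`) and returns no segments.
#' @return data frame of segments: `chrom`, `start_bp`, `end_bp` (1-based
#'   inclusive, outermost consistent SNPs), `n_snps` (supporting consistent
#'   SNPs), `inconsistent_fraction`, and global map row indices
#'   `i_start`, `i_end`.
#' @export
scan_chromosome <- function(ahapset, map, params = scan_params(), chrom,
                            allow_single_ahap = FALSE) {
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      inconsistent_fraction = numeric(),
                      i_start = integer(), i_end = integer())
  A <- ahap_matrix(ahapset)
  if (nrow(A) < 2L) {
    if (!allow_single_ahap) {
      warning("W_UNPOWERED: a single assured aHap is trivially homozygous everywhere; no segments reported (set allow_single_ahap = TRUE to override)")
      return(empty)
    }
    A <- rbind(A, A)  # duplicate so every resolved site is evaluable
  }
  sel <- which(map$chrom == chrom)
  if (length(sel) == 0L) return(empty)
  pos <- map$bp[sel]
  cs <- .site_consistency(A[, sel, drop = FALSE])
  window_bp <- params$window_kb * 1000
  step_bp <- params$step_kb * 1000

  starts <- seq(min(pos), max(pos), by = step_bp)
  # windows are half-open [w, w + window_bp) in bp
  lo <- findInterval(starts - 0.5, pos) + 1L
  hi <- findInterval(starts + window_bp - 0.5, pos)
  ce <- c(0, cumsum(cs$evaluable)); ci <- c(0, cumsum(cs$evaluable & !cs$consistent))
  nonempty <- hi >= lo
  n_eval <- ifelse(nonempty, ce[hi + 1L] - ce[lo], 0)
  n_inc <- ifelse(nonempty, ci[hi + 1L] - ci[lo], 0)
  # a window with zero inconsistent SNPs is homozygous at any tolerance,
  # including tolerance 0; otherwise the bound is strict ("less than")
  homo <- n_eval >= params$min_snps &
    (n_inc == 0 | (n_inc / pmax(n_eval, 1)) < params$tolerance)

  runs <- rle(homo)
  ends_at <- cumsum(runs$lengths)
  segs <- list()
  for (r in which(runs$values)) {
    w2 <- ends_at[r]; w1 <- w2 - runs$lengths[r] + 1L
    b <- .merge_run_segment(starts[w1], starts[w2] + window_bp - 1, pos,
                            cs$consistent, cs$evaluable, window_bp)
    if (is.null(b)) next
    rng <- b[1]:b[2]
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = chrom, start_bp = pos[b[1]], end_bp = pos[b[2]],
      n_snps = sum(cs$consistent[rng]),
      inconsistent_fraction = {
        ne <- sum(cs$evaluable[rng])
        if (ne == 0L) 0 else sum(cs$evaluable[rng] & !cs$consistent[rng]) / ne
      },
      i_start = sel[b[1]], i_end = sel[b[2]])
  }
  if (length(segs) == 0L) return(empty)
  segs <- do.call(rbind, segs)
  # segments whose snapped bounds overlap or abut (no separating SNP
  # between them) describe one homozygosity area: an uninformative window
  # broke the window-level merge, but there is no inconsistent evaluable
  # SNP between the pieces, so they are re-joined; truly distinct blocks
  # stay apart because bound extension stops at inconsistent SNPs
  segs <- segs[order(segs$start_bp), , drop = FALSE]
  i <- 1L
  while (i < nrow(segs)) {
    if (segs$i_start[i + 1L] <= segs$i_end[i] + 1L) {
      b1 <- min(segs$i_start[i], segs$i_start[i + 1L])
      b2 <- max(segs$i_end[i], segs$i_end[i + 1L])
      loc <- match(b1, sel):match(b2, sel)
      segs$i_start[i] <- b1; segs$i_end[i] <- b2
      segs$start_bp[i] <- pos[match(b1, sel)]
      segs$end_bp[i] <- pos[match(b2, sel)]
      segs$n_snps[i] <- sum(cs$consistent[loc])
      ne <- sum(cs$evaluable[loc])
      segs$inconsistent_fraction[i] <-
        if (ne == 0L) 0 else sum(cs$evaluable[loc] & !cs$consistent[loc]) / ne
      segs <- segs[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(segs) <- NULL
  segs
}

#' Scan every chromosome
#'
#' @inheritParams scan_chromosome
#' @return row-bound segments of [scan_chromosome()] over
#'   `unique(map$chrom)`.  When at least two assured aHaps exist but no
#'   segment is found anywhere, a `W_TWO_FOUNDERS` warning is raised: more
#'   than one disease founder (locus heterogeneity) yields several disease
#'   haplotypes and no genome-wide consensus.
#' @export
scan_genome <- function(ahapset, map, params = scan_params(),
                        allow_single_ahap = FALSE) {
  segs <- do.call(rbind, lapply(unique(map$chrom), function(ch)
    scan_chromosome(ahapset, map, params, ch, allow_single_ahap)))
  if (nrow(segs) == 0L && length(ahapset$assured) >= 2L)
    warning("W_TWO_FOUNDERS: no region is shared by all assured aHaps; the family may carry more than one disease founder (locus heterogeneity), which this method does not support")
  segs
}

#' Refine a segment with paired aHaps
#'
#' Within the segment, the consensus allele at a SNP is the unanimous
#' assured-aHap allele (SNPs without unanimity are skipped).  A SNP is
#' pair-supported iff for every pair at least one member matches the
#' consensus.  Windows (same geometry as the scan) whose pair-supported
#' fraction drops below `1 - tolerance` cut the segment, which may shrink
#' or split.  Per pair, the member matching the consensus is reported:
#' `carrier = "transmitted"` means the child received the disease
#' haplotype.
#'
#' @param segment one row of [scan_chromosome()] output.
#' @param ahapset an `AHapSet` (its `paired` sets are used; if none, the
#'   segment is returned unchanged).
#' @param map,params as in [scan_chromosome()].
#' @return `list(segments = data.frame, pair_calls = data.frame)`;
#'   `pair_calls` has one row per pair (`pair_id`, `child`, `carrier`,
#'   `match_transmitted`, `match_untransmitted`).
#' @export
refine_with_paired <- function(segment, ahapset, map, params = scan_params()) {
  seg_df <- as.data.frame(segment)[, c("chrom", "start_bp", "end_bp", "n_snps",
                                       "inconsistent_fraction", "i_start", "i_end")]
  if (length(ahapset$paired) == 0L)
    return(list(segments = seg_df, pair_calls = data.frame()))

  rng <- segment$i_start:segment$i_end
  A <- ahap_matrix(ahapset)[, rng, drop = FALSE]
  cs <- .site_consistency(A)
  cons <- cs$consensus
  pos <- map$bp[rng]

  match_frac <- function(v) {
    ok <- !is.na(cons) & !is.na(v)
    if (!any(ok)) return(NA_real_)
    mean(v[ok] == cons[ok])
  }
  pair_calls <- do.call(rbind, lapply(ahapset$paired, function(p) {
    ft <- match_frac(p$transmitted$alleles[rng])
    fu <- match_frac(p$untransmitted$alleles[rng])
    thr <- 1 - params$tolerance
    carrier <- if (is.na(ft) || is.na(fu)) "unresolved"
    else if (ft >= thr && fu < thr) "transmitted"
    else if (fu >= thr && ft < thr) "untransmitted"
    else "unresolved"
    data.frame(pair_id = p$pair_id, child = p$child,
               child_affection = p$child_affection, carrier = carrier,
               match_transmitted = ft, match_untransmitted = fu)
  }))

  # per-SNP pair support at consensus-defined SNPs
  has_cons <- !is.na(cons)
  supported <- rep(TRUE, length(rng))
  for (p in ahapset$paired) {
    tv <- p$transmitted$alleles[rng]; uv <- p$untransmitted$alleles[rng]
    bad <- has_cons & !is.na(tv) & tv != cons & !is.na(uv) & uv != cons
    supported <- supported & !bad
  }

  window_bp <- params$window_kb * 1000; step_bp <- params$step_kb * 1000
  starts <- seq(min(pos), max(pos), by = step_bp)
  keep_win <- vapply(starts, function(w) {
    inw <- has_cons & pos >= w & pos < w + window_bp
    if (!any(inw)) return(TRUE)  # no evidence against
    mean(supported[inw]) >= 1 - params$tolerance
  }, logical(1))

  runs <- rle(keep_win); ends_at <- cumsum(runs$lengths)
  segs <- list()
  for (r in which(runs$values)) {
    w2 <- ends_at[r]; w1 <- w2 - runs$lengths[r] + 1L
    lo_bp <- starts[w1]; hi_bp <- starts[w2] + window_bp - 1
    inside <- which(pos >= lo_bp & pos <= hi_bp & has_cons & supported)
    if (length(inside) == 0L) next
    b1 <- min(inside); b2 <- max(inside)
    sub <- b1:b2
    segs[[length(segs) + 1L]] <- data.frame(
      chrom = segment$chrom, start_bp = pos[b1], end_bp = pos[b2],
      n_snps = sum(cs$consistent[sub]),
      inconsistent_fraction = segment$inconsistent_fraction,
      i_start = rng[b1], i_end = rng[b2])
  }
  segs <- if (length(segs)) do.call(rbind, segs) else seg_df[0, ]
  list(segments = segs, pair_calls = pair_calls)
}
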
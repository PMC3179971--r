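## Two-point parametric LOD scores for haplotype markers.
##
## A shared-haplotype segment behaves as a single fully informative marker
## under a fully penetrant model: with k informative meioses of which r are
## recombinant,
##
##     LOD(theta) = log10( theta^r (1 - theta)^(k - r) / 0.5^k ),
##
## with the convention 0^0 = 1 (so r = 0, theta = 0 gives k * log10(2);
## with zero recombinants across 10 informative meioses the genome-wide
## ceiling is 3.0103).  r > 0 at theta = 0 is impossible under linkage and
## returns -Inf.

#' Two-point LOD score
#'
#' @param k number of informative meioses (>= 1).
#' @param r number of recombinant meioses (0 <= r <= k).
#' @param theta recombination fraction(s) in `[0, 0.5]` (vectorized).
#' @return LOD score(s), base-10; `-Inf` when `r > 0` and `theta = 0`.
#' @export
lod <- function(k, r, theta) {
  stopifnot(k >= 1, r >= 0, r <= k)
  if (any(theta < 0 | theta > 0.5))
    .hl_error("theta must lie in [0, 0.5]", "haplolink_domain")
  lt <- ifelse(theta == 0, ifelse(r == 0, 0, -Inf), r * log10(theta))
  l1 <- ifelse(theta == 1, ifelse(k - r == 0, 0, -Inf), (k - r) * log10(1 - theta))
  lt + l1 + k * log10(2)
}

#' Maximum-likelihood two-point LOD
#'
#' The likelihood is maximized at `theta_hat = r / k`, clipped to
#' `[0, 0.5]`.
#'
#' @inheritParams lod
#' @return `list(theta_hat, lod)`.
#' @export
max_lod <- function(k, r) {
  theta_hat <- min(max(r / k, 0), 0.5)
  list(theta_hat = theta_hat, lod = lod(k, r, theta_hat))
}

#' Count informative meioses supporting a segment
#'
#' Every assured aHap with at least one resolved allele inside the segment
#' is one informative meiosis (its segregation matches the
#' affection-predicted pattern by construction inside a homozygous
#' segment, so it contributes to `k` with no recombinant).  Resolved
#' paired aHaps (one member matching the assured consensus, the other
#' not) contribute one further meiosis each when `include_pairs = TRUE`.
#' A resolved carrier that is phenotypically unaffected under incomplete
#' penetrance is explained by penetrance, not recombination, and is not
#' counted in `r`; only under a complete-penetrance model would such a
#' contradiction count as a recombinant.
#'
#' @param ahapset an `AHapSet`.
#' @param segment one row of [scan_chromosome()] output.
#' @param map,params as in [scan_chromosome()].
#' @param include_pairs count resolved paired aHaps in `k` (default TRUE).
#' @return `list(k, r, pair_calls)`.
#' @export
count_informative_meioses <- function(ahapset, segment, map,
                                      params = scan_params(),
                                      include_pairs = TRUE) {
  rng <- segment$i_start:segment$i_end
  k <- sum(vapply(ahapset$assured,
                  function(a) any(!is.na(a$alleles[rng])), logical(1)))
  r <- 0L
  pair_calls <- data.frame()
  if (include_pairs && length(ahapset$paired) > 0L) {
    pair_calls <- refine_with_paired(segment, ahapset, map, params)$pair_calls
    resolved <- pair_calls$carrier %in% c("transmitted", "untransmitted")
    k <- k + sum(resolved)
    contradiction <- resolved & pair_calls$carrier == "transmitted" &
      pair_calls$child_affection == "unaffected" & ahapset$penetrance == "complete"
    r <- r + sum(contradiction)
  }
  list(k = k, r = r, pair_calls = pair_calls)
}

#' Score segments into candidate regions
#'
#' Attaches `(k, r, theta_hat, lod)` to every segment and sorts by LOD
#' (descending), then chromosome, then start; regions attaining the
#' maximum LOD are flagged.
#'
#' @param segments data frame from [scan_genome()] (possibly refined).
#' @inheritParams count_informative_meioses
#' @return data frame of candidate regions: segment columns plus
#'   `k_meioses`, `r_recomb`, `theta_hat`, `lod`, `is_max`.  Segments with
#'   no resolvable meiosis get `NA` LOD and are flagged unscored.
#' @export
score_segments <- function(segments, ahapset, map, params = scan_params(),
                           include_pairs = TRUE) {
  if (is.null(segments) || nrow(segments) == 0L)
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      inconsistent_fraction = numeric(),
                      i_start = integer(), i_end = integer(),
                      k_meioses = integer(), r_recomb = integer(),
                      theta_hat = numeric(), lod = numeric(),
                      is_max = logical()))
  scored <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    kr <- count_informative_meioses(ahapset, seg, map, params, include_pairs)
    if (kr$k == 0L) {
      seg$k_meioses <- 0L; seg$r_recomb <- 0L
      seg$theta_hat <- NA_real_; seg$lod <- NA_real_
    } else {
      ml <- max_lod(kr$k, kr$r)
      seg$k_meioses <- kr$k; seg$r_recomb <- kr$r
      seg$theta_hat <- ml$theta_hat; seg$lod <- ml$lod
    }
    seg
  })
  out <- do.call(rbind, scored)
  out <- out[order(-ifelse(is.na(out$lod), -Inf, out$lod),
                   out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  top <- suppressWarnings(max(out$lod, na.rm = TRUE))
  out$is_max <- !is.na(out$lod) & is.finite(top) & abs(out$lod - top) < 1e-9
  out
}
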
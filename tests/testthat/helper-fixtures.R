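# Shared test helpers: tiny in-code fixtures and independent oracles.

# three-person family (affected father) with explicit genotype codes;
# codes: NA missing, 0 = 1/1, 1 = 1/2, 2 = 2/2
make_trio_fixture <- function(gF, gM, gC, snp_ids = NULL) {
  n <- length(gF)
  if (is.null(snp_ids)) snp_ids <- sprintf("rs%d", seq_len(n))
  ped <- pedigree(fam = "F1", id = c("dad", "mum", "kid"),
                  father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
                  sex = c("male", "female", "male"),
                  affection = c("affected", "unaffected", "affected"))
  codes <- rbind(dad = gF, mum = gM, kid = gC)
  colnames(codes) <- snp_ids
  list(ped = ped, genotypes = genotype_matrix(codes))
}

# independent single-site phasing oracle: enumerate parental transmissions
phase_site_oracle <- function(gF, gM, gC) {
  if (any(is.na(c(gF, gM, gC)))) return("missing")
  trans <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)
  sols <- expand.grid(aF = trans(gF), aM = trans(gM))
  sols <- sols[sols$aF + sols$aM == gC, , drop = FALSE]
  if (nrow(sols) == 0L) "mendel_error"
  else if (nrow(sols) == 1L) "phased"
  else "uninformative"
}

# exhaustive maximal-consistent-run oracle for the sharing scan at
# tolerance 0: split at every inconsistent evaluable SNP, snap each piece
# to its outermost consistent SNPs
oracle_consistent_runs <- function(A, pos, min_snps = 1L) {
  resolved <- colSums(!is.na(A))
  mx <- suppressWarnings(apply(A, 2, max, na.rm = TRUE))
  mn <- suppressWarnings(apply(A, 2, min, na.rm = TRUE))
  evaluable <- resolved >= 2L
  consistent <- evaluable & (mx == mn)
  breaks <- which(evaluable & !consistent)
  bounds <- c(0L, breaks, ncol(A) + 1L)
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    rng <- seq(bounds[b] + 1L, bounds[b + 1L] - 1L)
    rng <- rng[rng >= 1L & rng <= ncol(A)]
    cc <- rng[consistent[rng]]
    if (length(cc) >= min_snps)
      out[[length(out) + 1L]] <- data.frame(
        start_bp = pos[min(cc)], end_bp = pos[max(cc)], n_snps = length(cc))
  }
  if (length(out) == 0L)
    return(data.frame(start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  do.call(rbind, out)
}

# random aHap matrix on one chromosome, optionally with a planted
# identical block between SNP indices b1..b2
random_ahap_chromosome <- function(n_ahap, n_snp, block = NULL,
                                   na_rate = 0.05, len_bp = 20e6) {
  pos <- sort(sample.int(len_bp, n_snp))
  A <- matrix(sample(1:2, n_ahap * n_snp, replace = TRUE), n_ahap, n_snp)
  if (!is.null(block)) {
    shared <- sample(1:2, diff(block) + 1L, replace = TRUE)
    for (i in seq_len(n_ahap)) A[i, block[1]:block[2]] <- shared
  }
  A[matrix(runif(length(A)) < na_rate, nrow(A))] <- NA_integer_
  map <- marker_map("1", sprintf("s%d", seq_len(n_snp)), pos)
  list(A = A, map = map, pos = pos)
}

# wrap an allele matrix as a minimal AHapSet so scan functions accept it
ahapset_from_matrix <- function(A) {
  assured <- lapply(seq_len(nrow(A)), function(i)
    structure(list(alleles = A[i, ], child = sprintf("c%d", i), parent = "p",
                   which = "transmitted", status = "assured",
                   pair_id = NA, child_affection = "affected"),
              class = "AHap"))
  structure(list(assured = assured, paired = list(), model = "dominant",
                 penetrance = "complete"), class = "AHapSet")
}

# cached six-region validation fixture (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())
get_validation_fixture <- function(seed = 11L, n_snps = 2000L) {
  key <- sprintf("fix_%d_%d", seed, n_snps)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_validation_fixture(n_snps, seed = seed)
  .fixture_cache[[key]]
}
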
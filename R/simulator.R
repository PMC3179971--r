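## Seeded gene-dropping pedigree simulator.
##
## Founders receive independent haplotypes (per-SNP allele-2 frequency
## drawn uniformly from the minor-allele-frequency range); every child
## gamete copies one parental chromatid with crossovers from either a
## Haldane model (Poisson count, uniform positions, no interference) or a
## fixed per-meiosis crossover list.  One founder carries the disease
## haplotype; descent of that haplotype is forced to match the declared
## carrier pattern by choosing the gamete's starting phase (the crossover
## process itself is untouched).  All truth -- chromatid mosaics,
## crossovers, carrier status, and the realized shared disease-haplotype
## interval per locus -- is retained.
##
## Intervals in the truth bookkeeping are half-open [start, end) in bp, so
## a crossover placed at the exact midpoint of a disease interval halves
## its realized length exactly.

#' Simulation configuration
#'
#' @param pedigree_spec data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), `sex` (`male`/`female`), `carrier` (logical:
#'   carries the disease haplotype; `NA` lets the gamete fall where it
#'   may).  Exactly one founder must be a carrier (the disease founder);
#'   parents must precede children or be reorderable.
#' @param chromosomes data frame `chrom`, `length_bp`, `n_snps`.
#' @param disease_loci data frame `chrom`, `mutation_bp`, and optionally
#'   `designed_start`, `designed_end` (half-open bp interval the disease
#'   haplotype is meant to span; used only for truth reporting).
#' @param model `"dominant"` (affected with >= 1 copy) or `"recessive"`
#'   (2 copies).
#' @param maf_range allele-2 founder frequency interval (default
#'   `c(0.1, 0.5)`).
#' @param recomb `list(model = "haldane", rate_per_100mb = 1)` or
#'   `list(model = "fixed", transmissions = <data frame>)` with columns
#'   `child`, `parent`, `chrom`, `phase` (1 = start on the parent's
#'   paternal chromatid, 2 = maternal) and `crossovers` (list column of bp
#'   vectors).
#' @param penetrance probability a carrier is affected (default 1).
#' @param error_rate,missing_rate per-call genotyping-error / missingness
#'   probabilities (default 0).
#' @param deletion optional `list(chrom, start_bp, end_bp, carrier_ids)`:
#'   calls of those individuals inside the interval are forced hemizygous
#'   (reported homozygous for the remaining chromatid's allele).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(pedigree_spec, chromosomes, disease_loci,
                       model = c("dominant", "recessive"),
                       maf_range = c(0.1, 0.5),
                       recomb = list(model = "haldane", rate_per_100mb = 1),
                       penetrance = 1, error_rate = 0, missing_rate = 0,
                       deletion = NULL, seed = 1L) {
  model <- match.arg(model)
  stopifnot(penetrance > 0, penetrance <= 1,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  for (i in seq_len(nrow(disease_loci))) {
    ch <- match(disease_loci$chrom[i], chromosomes$chrom)
    if (is.na(ch) || disease_loci$mutation_bp[i] < 1 ||
        disease_loci$mutation_bp[i] > chromosomes$length_bp[ch])
      .hl_error("disease locus outside its chromosome", "haplolink_config")
  }
  structure(list(pedigree_spec = pedigree_spec, chromosomes = chromosomes,
                 disease_loci = disease_loci, model = model,
                 maf_range = maf_range, recomb = recomb,
                 penetrance = penetrance, error_rate = error_rate,
                 missing_rate = missing_rate, deletion = deletion,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.splice_mosaic <- function(mos, a, b) {
  keep <- mos$end > a & mos$start < b
  out <- mos[keep, , drop = FALSE]
  out$start <- pmax(out$start, a); out$end <- pmin(out$end, b)
  out
}

.merge_mosaic <- function(mos) {
  if (nrow(mos) <= 1L) return(mos)
  keep <- c(TRUE, mos$src[-1] != mos$src[-nrow(mos)])
  grp <- cumsum(keep)
  data.frame(start = tapply(mos$start, grp, min),
             end = tapply(mos$end, grp, max),
             src = mos$src[keep])
}

.source_at <- function(mos, pos) mos$src[findInterval(pos, mos$start)]

.make_gamete <- function(p1, p2, xpos, phase) {
  pts <- c(1, sort(xpos))
  ends <- c(pts[-1], max(p1$end))
  pieces <- lapply(seq_along(pts), function(q) {
    chromatid <- if ((q - 1L + phase - 1L) %% 2L == 0L) p1 else p2
    .splice_mosaic(chromatid, pts[q], ends[q])
  })
  .merge_mosaic(do.call(rbind, pieces))
}

.chromatid_at_m <- function(xpos, phase, m) {
  # which parental chromatid (1/2) the gamete copies at position m
  k <- sum(xpos <= m)
  if ((k + phase - 1L) %% 2L == 0L) 1L else 2L
}

.topo_order <- function(spec) {
  ord <- integer(0); placed <- character(0)
  remaining <- seq_len(nrow(spec))
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      f <- spec$father[i]; m <- spec$mother[i]
      (is.na(f) || f %in% placed) && (is.na(m) || m %in% placed)
    }, logical(1))]
    if (length(ready) == 0L)
      .hl_error("pedigree_spec contains a cycle or unknown parent", "haplolink_config")
    ord <- c(ord, ready); placed <- c(placed, spec$id[ready])
    remaining <- setdiff(remaining, ready)
  }
  ord
}

#' Gene-drop a pedigree
#'
#' @param config a [sim_config()].
#' @return `list(pedigree, genotypes, map, truth, config)` where `truth`
#'   holds per-individual chromatid mosaics, the crossover list, per-locus
#'   carrier copy counts, and the realized shared disease-haplotype
#'   interval per locus (`realized`: `chrom`, `mutation_bp`,
#'   `designed_start/end`, `realized_start/end`, `realized_length_mb`).
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  spec <- config$pedigree_spec
  spec$father[spec$father %in% c("0", "")] <- NA
  spec$mother[spec$mother %in% c("0", "")] <- NA
  ord <- .topo_order(spec)
  chroms <- config$chromosomes
  n_chrom <- nrow(chroms)

  # marker map: sorted uniform positions per chromosome
  map_list <- lapply(seq_len(n_chrom), function(c) {
    pos <- sort(sample.int(chroms$length_bp[c] - 1L, chroms$n_snps[c])) + 0
    data.frame(chrom = chroms$chrom[c],
               snp = sprintf("c%s_%05d", chroms$chrom[c], seq_along(pos)),
               cm = pos / 1e6, bp = pos)
  })
  map <- do.call(rbind, map_list)
  map <- marker_map(map$chrom, map$snp, map$bp, map$cm)
  m_total <- nrow(map)
  col_of_chrom <- lapply(chroms$chrom, function(ch) which(map$chrom == ch))

  # founder haplotypes
  founders <- spec$id[is.na(spec$father) & is.na(spec$mother)]
  dis_founder <- spec$id[spec$id %in% founders & spec$carrier %in% TRUE]
  if (config$model == "dominant" && length(dis_founder) != 1L)
    .hl_error("exactly one founder must carry the disease haplotype", "haplolink_config")
  hap_labels <- as.vector(t(outer(founders, 1:2, paste, sep = ".")))
  H <- matrix(NA_integer_, length(hap_labels), m_total,
              dimnames = list(hap_labels, map$snp))
  freq <- stats::runif(m_total, config$maf_range[1], config$maf_range[2])
  for (i in seq_len(nrow(H)))
    H[i, ] <- 1L + stats::rbinom(m_total, 1L, freq)
  disease_hap <- paste0(dis_founder[1], ".1")

  fixed <- identical(config$recomb$model, "fixed")
  tx <- if (fixed) config$recomb$transmissions else NULL
  rate <- if (!fixed) config$recomb$rate_per_100mb else NULL
  locus_of_chrom <- match(chroms$chrom, config$disease_loci$chrom)

  haps <- list()       # haps[[id]][[chrom index]] = list(pat=, mat=)
  xover_log <- list()
  for (i in ord) {
    id <- spec$id[i]
    if (id %in% founders) {
      haps[[id]] <- lapply(seq_len(n_chrom), function(c) {
        full <- function(h) data.frame(start = 1, end = chroms$length_bp[c] + 1,
                                       src = paste0(id, ".", h))
        list(pat = full(1), mat = full(2))
      })
      next
    }
    haps[[id]] <- vector("list", n_chrom)
    for (c in seq_len(n_chrom)) {
      L <- chroms$length_bp[c]
      li <- locus_of_chrom[c]
      m <- if (!is.na(li)) config$disease_loci$mutation_bp[li] else NA
      gam <- list()
      for (side in c("father", "mother")) {
        parent <- spec[[side]][i]
        p1 <- haps[[parent]][[c]]$pat; p2 <- haps[[parent]][[c]]$mat
        if (fixed) {
          row <- which(tx$child == id & tx$parent == parent &
                         tx$chrom == chroms$chrom[c])
          xpos <- if (length(row) && length(tx$crossovers[[row]]))
            tx$crossovers[[row]] else numeric(0)
          phase <- if (length(row)) tx$phase[row] else 1L
        } else {
          n_x <- stats::rpois(1L, rate * L / 1e8)
          xpos <- if (n_x > 0L) sort(stats::runif(n_x, 1, L)) else numeric(0)
          phase <- sample(1:2, 1L)
          # force descent of the disease haplotype per the carrier column
          want <- spec$carrier[i]
          if (!is.na(li) && !is.na(want)) {
            carries <- vapply(1:2, function(ph) {
              chromatid <- if (.chromatid_at_m(xpos, ph, m) == 1L) p1 else p2
              .source_at(chromatid, m) == disease_hap
            }, logical(1))
            parent_is_carrier <- any(carries)
            if (want && parent_is_carrier && !carries[phase])
              phase <- which(carries)[1]
            if (!want && carries[phase]) {
              if (all(carries))
                .hl_error(sprintf("parent %s carries the disease haplotype on both chromatids; child %s cannot be a non-carrier", parent, id),
                          "haplolink_config")
              phase <- which(!carries)[1]
            }
          }
        }
        gam[[side]] <- .make_gamete(p1, p2, xpos, phase)
        if (length(xpos))
          xover_log[[length(xover_log) + 1L]] <- data.frame(
            child = id, parent = parent, chrom = chroms$chrom[c], pos = xpos)
      }
      haps[[id]][[c]] <- list(pat = gam$father, mat = gam$mother)
    }
  }

  # carrier copies and affection
  ids <- spec$id
  copies <- do.call(rbind, lapply(seq_len(nrow(config$disease_loci)), function(l) {
    c_idx <- match(config$disease_loci$chrom[l], chroms$chrom)
    m <- config$disease_loci$mutation_bp[l]
    data.frame(id = ids, chrom = config$disease_loci$chrom[l], copies = vapply(ids, function(id) {
      sum(.source_at(haps[[id]][[c_idx]]$pat, m) == disease_hap,
          .source_at(haps[[id]][[c_idx]]$mat, m) == disease_hap)
    }, numeric(1)))
  }))
  need <- if (config$model == "dominant") 1L else 2L
  max_copies <- tapply(copies$copies, copies$id, max)[ids]
  is_carrier <- max_copies >= need
  affected <- is_carrier & (stats::runif(length(ids)) < config$penetrance)
  if (fixed) {
    declared <- spec$carrier
    if (any(!is.na(declared) & (declared != (max_copies >= 1L))))
      .hl_error("fixed transmissions contradict the declared carrier pattern", "haplolink_config")
  }

  ped <- pedigree(fam = "FAM1", id = ids, father = spec$father,
                  mother = spec$mother, sex = spec$sex,
                  affection = ifelse(affected, "affected", "unaffected"))

  # genotypes from the mosaics
  Apat <- Amat <- matrix(NA_integer_, length(ids), m_total,
                         dimnames = list(ids, map$snp))
  for (id in ids) for (c in seq_len(n_chrom)) {
    cols <- col_of_chrom[[c]]
    pos <- map$bp[cols]
    for (side in c("pat", "mat")) {
      mos <- haps[[id]][[c]][[side]]
      src <- mos$src[findInterval(pos, mos$start)]
      al <- H[cbind(match(src, hap_labels), cols)]
      if (side == "pat") Apat[id, cols] <- al else Amat[id, cols] <- al
    }
  }
  # genotyping errors flip one allele per event
  if (config$error_rate > 0) {
    for (A in c("Apat", "Amat")) {
      M <- get(A)
      hit <- stats::runif(length(M)) < config$error_rate / 2
      M[hit] <- 3L - M[hit]
      assign(A, M)
    }
  }
  codes <- (Apat == 2L) + (Amat == 2L)
  if (config$missing_rate > 0)
    codes[stats::runif(length(codes)) < config$missing_rate] <- NA_integer_
  if (!is.null(config$deletion)) {
    del <- config$deletion
    cols <- which(map$chrom == del$chrom & map$bp >= del$start_bp &
                    map$bp <= del$end_bp)
    for (id in del$carrier_ids)
      codes[id, cols] <- 2L * (Apat[id, cols] == 2L)
  }
  genotypes <- genotype_matrix(codes)

  # realized shared disease-haplotype interval per locus
  realized <- do.call(rbind, lapply(seq_len(nrow(config$disease_loci)), function(l) {
    loc <- config$disease_loci[l, ]
    c_idx <- match(loc$chrom, chroms$chrom)
    m <- loc$mutation_bp
    carr <- ids[copies$copies[copies$chrom == loc$chrom] >= 1L]
    lo <- 1; hi <- chroms$length_bp[c_idx] + 1
    for (id in carr) {
      for (side in c("pat", "mat")) {
        mos <- .merge_mosaic(haps[[id]][[c_idx]][[side]])
        seg <- which(mos$start <= m & mos$end > m)
        if (length(seg) && mos$src[seg] == disease_hap) {
          lo <- max(lo, mos$start[seg]); hi <- min(hi, mos$end[seg])
        }
      }
    }
    ds <- if ("designed_start" %in% names(loc)) loc$designed_start else NA
    de <- if ("designed_end" %in% names(loc)) loc$designed_end else NA
    if (!is.na(ds)) { lo <- max(lo, ds); hi <- min(hi, de) }
    data.frame(chrom = loc$chrom, mutation_bp = m,
               designed_start = ds, designed_end = de,
               realized_start = lo, realized_end = hi,
               realized_length_mb = (hi - lo) / 1e6)
  }))

  truth <- list(haplotypes = haps, founder_haps = H, disease_hap = disease_hap,
                crossovers = if (length(xover_log)) do.call(rbind, xover_log)
                             else data.frame(),
                carriers = copies, realized = realized)
  list(pedigree = ped, genotypes = genotypes, map = map, truth = truth,
       config = config)
}

#' Six-region validation fixture
#'
#' A three-generation autosomal-dominant, fully penetrant pedigree with
#' exactly ten assured meioses, typed on six synthetic chromosomes
#' (labels 1, 5, 9, 13, 17, 21; 24 Mb each).  Each chromosome carries one
#' disease interval, initialized at 1, 3, 4, 5, 8 and 10 Mb; on the 8 and
#' 10 Mb intervals one crossover is placed exactly mid-interval in the
#' meiosis to an affected grandchild, so the realized shared
#' disease-haplotype lengths are 1, 3, 4, 5, 4 and 5 Mb.  All crossovers
#' are fixed; only founder haplotypes and marker positions are random
#' (seeded).
#'
#' @param snps_per_chromosome markers per chromosome (>= 500, default 2000).
#' @param seed RNG seed.
#' @return as [simulate_pedigree()].
#' @export
build_validation_fixture <- function(snps_per_chromosome = 2000, seed = 1L) {
  stopifnot(snps_per_chromosome >= 500)
  labels <- c("1", "5", "9", "13", "17", "21")
  len <- 24e6
  chroms <- data.frame(chrom = labels, length_bp = len,
                       n_snps = snps_per_chromosome)
  s <- 7e6
  Lmb <- c(1, 3, 4, 5, 8, 10) * 1e6
  loci <- data.frame(chrom = labels, mutation_bp = s + Lmb / 4,
                     designed_start = s, designed_end = s + Lmb)

  spec <- data.frame(
    id = c("1", "2", "10", "11", "16", "5", "6", "7", "8", "9",
           "12", "13", "14", "15", "17"),
    father = c(NA, NA, NA, NA, NA, "1", "1", "1", "1", "1",
               "5", "5", "7", "7", "16"),
    mother = c(NA, NA, NA, NA, NA, "2", "2", "2", "2", "2",
               "10", "10", "11", "11", "8"),
    sex = c("male", "female", "female", "female", "male",
            "male", "female", "male", "female", "male",
            "male", "female", "male", "female", "female"),
    carrier = c(FALSE, TRUE, FALSE, FALSE, FALSE,
                TRUE, FALSE, TRUE, TRUE, FALSE,
                TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )

  # fixed transmissions; phase 1 = parent's paternal chromatid (for a
  # founder parent, its ".1" haplotype -- the disease haplotype for
  # founder 2), phase 2 = maternal
  tx_rows <- list()
  add_tx <- function(child, parent, chrom, phase, xpos = numeric(0)) {
    tx_rows[[length(tx_rows) + 1L]] <<- list(child = child, parent = parent,
                                             chrom = chrom, phase = phase,
                                             crossovers = xpos)
  }
  for (c in seq_along(labels)) {
    ch <- labels[c]; e <- s + Lmb[c]; mid <- s + Lmb[c] / 2
    add_tx("5", "2", ch, 2L, s)          # B left of s, disease hap from s on
    add_tx("6", "2", ch, 2L)             # untransmitted complement = disease hap
    add_tx("7", "2", ch, 1L, e)          # disease hap up to e
    add_tx("8", "2", ch, 1L)             # full disease hap
    add_tx("9", "2", ch, 2L)
    add_tx("5", "1", ch, 1L); add_tx("6", "1", ch, 2L); add_tx("7", "1", ch, 1L)
    add_tx("8", "1", ch, 2L); add_tx("9", "1", ch, 1L)
    add_tx("12", "5", ch, 2L); add_tx("13", "5", ch, 1L)
    add_tx("12", "10", ch, 1L); add_tx("13", "10", ch, 2L)
    add_tx("14", "7", ch, 2L); add_tx("15", "7", ch, 1L)
    add_tx("14", "11", ch, 1L); add_tx("15", "11", ch, 2L)
    if (ch %in% c("17", "21")) add_tx("17", "8", ch, 2L, mid)  # mid-interval crossover
    else add_tx("17", "8", ch, 2L)
    add_tx("17", "16", ch, 1L)
  }
  tx <- data.frame(child = vapply(tx_rows, `[[`, "", "child"),
                   parent = vapply(tx_rows, `[[`, "", "parent"),
                   chrom = vapply(tx_rows, `[[`, "", "chrom"),
                   phase = vapply(tx_rows, `[[`, 0L, "phase"))
  tx$crossovers <- lapply(tx_rows, `[[`, "crossovers")

  cfg <- sim_config(spec, chroms, loci, model = "dominant",
                    recomb = list(model = "fixed", transmissions = tx),
                    penetrance = 1, seed = seed)
  simulate_pedigree(cfg)
}

#' Simulate a cohort of structurally varied pedigrees
#'
#' Each pedigree carries exactly one causal mutation on a rotating
#' chromosome; sibship sizes and depth vary with the pedigree index, and
#' per-pedigree seeds derive deterministically from the master seed.
#'
#' @param n_pedigrees number of pedigrees (default 30).
#' @param base_config optional overrides: `n_chrom`, `chrom_length_bp`,
#'   `n_snps`, `rate_per_100mb`, `error_rate`, `missing_rate`,
#'   `penetrance`.
#' @param seed master seed.
#' @return list of [simulate_pedigree()] results.
#' @export
simulate_cohort <- function(n_pedigrees = 30, base_config = NULL, seed = 1L) {
  stopifnot(n_pedigrees >= 1)
  bc <- utils::modifyList(list(n_chrom = 6L, chrom_length_bp = 24e6,
                               n_snps = 2000L, rate_per_100mb = 1,
                               error_rate = 0, missing_rate = 0,
                               penetrance = 1),
                          if (is.null(base_config)) list() else base_config)
  labels <- as.character(seq_len(bc$n_chrom))
  lapply(seq_len(n_pedigrees), function(i) {
    ped_seed <- (as.integer(seed) * 1009L + i * 7919L) %% 2147483647L
    set.seed(ped_seed)
    k2 <- 3L + (i %% 3L)           # gen-II sibship size 3..5
    k3 <- 2L + (i %% 2L)           # gen-III sibship sizes 2..3
    g2_ids <- sprintf("II%d", seq_len(k2))
    g2_carrier <- rep(c(TRUE, FALSE), length.out = k2)
    g2_sex <- rep(c("male", "female"), length.out = k2)
    carrier_kids <- which(g2_carrier)[1:2]
    rows <- list(
      data.frame(id = "I1", father = NA, mother = NA, sex = "male", carrier = FALSE),
      data.frame(id = "I2", father = NA, mother = NA, sex = "female", carrier = TRUE),
      data.frame(id = g2_ids, father = "I1", mother = "I2", sex = g2_sex,
                 carrier = g2_carrier))
    for (b in seq_along(carrier_kids)) {
      p <- g2_ids[carrier_kids[b]]
      p_sex <- g2_sex[carrier_kids[b]]
      sp <- sprintf("S%d", b)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sp, father = NA, mother = NA,
        sex = ifelse(p_sex == "male", "female", "male"), carrier = FALSE)
      kid_ids <- sprintf("III%d_%d", b, seq_len(k3))
      rows[[length(rows) + 1L]] <- data.frame(
        id = kid_ids,
        father = ifelse(p_sex == "male", p, sp),
        mother = ifelse(p_sex == "male", sp, p),
        sex = rep(c("female", "male"), length.out = k3),
        carrier = rep(c(TRUE, FALSE), length.out = k3))
    }
    spec <- do.call(rbind, rows)
    chroms <- data.frame(chrom = labels, length_bp = bc$chrom_length_bp,
                         n_snps = bc$n_snps)
    dis_chrom <- labels[(i - 1L) %% bc$n_chrom + 1L]
    mut <- floor(stats::runif(1, 0.3, 0.7) * bc$chrom_length_bp)
    loci <- data.frame(chrom = dis_chrom, mutation_bp = mut,
                       designed_start = NA_real_, designed_end = NA_real_)
    cfg <- sim_config(spec, chroms, loci, model = "dominant",
                      recomb = list(model = "haldane",
                                    rate_per_100mb = bc$rate_per_100mb),
                      penetrance = bc$penetrance, error_rate = bc$error_rate,
                      missing_rate = bc$missing_rate, seed = ped_seed)
    simulate_pedigree(cfg)
  })
}

#' Draw Haldane crossover positions (no interference)
#' @param length_bp chromosome length; `rate_per_100mb` expected crossovers
#'   per 100 Mb per meiosis.
#' @param rate_per_100mb see above.
#' @return sorted numeric vector of crossover positions (possibly empty).
#' @keywords internal
draw_crossovers <- function(length_bp, rate_per_100mb = 1) {
  n <- stats::rpois(1L, rate_per_100mb * length_bp / 1e8)
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, 1, length_bp))
}

#' Read a simulation config from YAML
#'
#' Maps a YAML file with keys mirroring [sim_config()] arguments
#' (pedigree as a list of individual records, chromosomes and disease loci
#' as lists of records) onto a `SimConfig`.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x) do.call(rbind, lapply(x, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  spec <- as_df(y$pedigree)
  spec$father <- as.character(spec$father); spec$mother <- as.character(spec$mother)
  spec$father[spec$father %in% c("0", "NA")] <- NA
  spec$mother[spec$mother %in% c("0", "NA")] <- NA
  sim_config(
    pedigree_spec = spec,
    chromosomes = as_df(y$chromosomes),
    disease_loci = as_df(y$disease_loci),
    model = if (is.null(y$model)) "dominant" else y$model,
    maf_range = if (is.null(y$maf_range)) c(0.1, 0.5) else unlist(y$maf_range),
    recomb = if (is.null(y$recomb)) list(model = "haldane", rate_per_100mb = 1)
             else y$recomb,
    penetrance = if (is.null(y$penetrance)) 1 else y$penetrance,
    error_rate = if (is.null(y$error_rate)) 0 else y$error_rate,
    missing_rate = if (is.null(y$missing_rate)) 0 else y$missing_rate,
    seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Write a simulated fixture as PED/MAP plus a truth JSON
#'
#' @param fixture output of [simulate_pedigree()].
#' @param dir output directory (created if needed); writes
#'   `family.ped`, `family.map`, `truth.json`.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedfile(fixture$pedigree, fixture$genotypes, file.path(dir, "family.ped"))
  write_mapfile(fixture$map, file.path(dir, "family.map"))
  jsonlite::write_json(list(disease_hap = fixture$truth$disease_hap,
                            carriers = fixture$truth$carriers,
                            realized = fixture$truth$realized),
                       file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
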
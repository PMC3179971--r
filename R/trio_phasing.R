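## Trio decomposition and Mendelian phasing.
##
## Every site is phased independently: with father/mother/child genotype
## codes (0 = 1/1, 1 = 1/2, 2 = 2/2, NA missing) the set of (paternal,
## maternal) transmitted-allele solutions is enumerated; a unique solution
## phases the site, none is a Mendelian error, and the only ambiguous case
## (all three members heterozygous) is uninformative.  Lookup tables over
## the 4^3 genotype combinations make the per-trio pass a single indexing
## operation.

.SITE_STATES <- c("phased", "uninformative", "mendel_error", "missing")

.gidx <- function(g) ifelse(is.na(g), 1L, g + 2L)  # NA,0,1,2 -> 1..4

.build_phase_tables <- function() {
  ft <- fu <- mt <- mu <- array(NA_integer_, c(4, 4, 4))
  st <- array("missing", c(4, 4, 4))
  transmissible <- function(g) switch(g + 1L, 0L, c(0L, 1L), 1L)  # allele-2 dose
  other_allele <- function(g, trans) {           # untransmitted allele (1/2)
    if (g == 1L) 3L - (trans + 1L) else trans + 1L
  }
  for (gF in 0:2) for (gM in 0:2) for (gC in 0:2) {
    sols <- expand.grid(aF = transmissible(gF), aM = transmissible(gM))
    sols <- sols[sols$aF + sols$aM == gC, , drop = FALSE]
    i <- .gidx(gF); j <- .gidx(gM); k <- .gidx(gC)
    if (nrow(sols) == 0L) {
      st[i, j, k] <- "mendel_error"
    } else if (nrow(sols) == 1L) {
      st[i, j, k] <- "phased"
      ft[i, j, k] <- sols$aF + 1L
      mt[i, j, k] <- sols$aM + 1L
      fu[i, j, k] <- other_allele(gF, sols$aF)
      mu[i, j, k] <- other_allele(gM, sols$aM)
    } else {
      st[i, j, k] <- "uninformative"   # only F=M=C=1/2
    }
  }
  list(ft = ft, fu = fu, mt = mt, mu = mu, st = st)
}

.build_duo_tables <- function() {
  # single genotyped parent: phase only where transmission is forced
  # (parent homozygous, or child homozygous); otherwise missing
  pt <- pu <- array(NA_integer_, c(4, 4))
  st <- array("missing", c(4, 4))
  for (gP in 0:2) for (gC in 0:2) {
    i <- .gidx(gP); k <- .gidx(gC)
    if (gC == 0L && gP == 2L) { st[i, k] <- "mendel_error"; next }
    if (gC == 2L && gP == 0L) { st[i, k] <- "mendel_error"; next }
    trans <- if (gC == 0L) 0L else if (gC == 2L) 1L else
      if (gP == 0L) 0L else if (gP == 2L) 1L else NA_integer_
    if (!is.na(trans)) {
      st[i, k] <- "phased"
      pt[i, k] <- trans + 1L
      pu[i, k] <- if (gP == 1L) 3L - (trans + 1L) else trans + 1L
    }
  }
  list(pt = pt, pu = pu, st = st)
}

.phase_tables <- .build_phase_tables()
.duo_tables <- .build_duo_tables()

#' Decompose a pedigree into nuclear trios
#'
#' One trio per child whose two parents are both recorded; children with
#' exactly one recorded parent are returned separately as duos (they are
#' still phasable where transmission is forced).  Order follows the
#' pedigree row order, so the decomposition is deterministic.
#'
#' @param ped a [pedigree()].
#' @return `list(trios = data.frame(father, mother, child),
#'   duos = data.frame(parent, role, child))` where `role` is
#'   `"father"`/`"mother"`.
#' @export
decompose_trios <- function(ped) {
  has_f <- !is.na(ped$father); has_m <- !is.na(ped$mother)
  trios <- data.frame(father = ped$father[has_f & has_m],
                      mother = ped$mother[has_f & has_m],
                      child = ped$id[has_f & has_m], stringsAsFactors = FALSE)
  solo <- xor(has_f, has_m)
  duos <- data.frame(
    parent = ifelse(has_f[solo], ped$father[solo], ped$mother[solo]),
    role = ifelse(has_f[solo], "father", "mother"),
    child = ped$id[solo], stringsAsFactors = FALSE)
  list(trios = trios, duos = duos)
}

#' Phase one site of a father-mother-child trio
#'
#' @param gF,gM,gC genotype codes (`NA`, 0, 1, 2 = missing, 1/1, 1/2, 2/2).
#' @return list with `state` (one of `phased`, `uninformative`,
#'   `mendel_error`, `missing`) and transmitted/untransmitted alleles
#'   (1/2 or `NA`) for each parent.
#' @export
phase_site <- function(gF, gM, gC) {
  i <- .gidx(gF); j <- .gidx(gM); k <- .gidx(gC)
  list(state = .phase_tables$st[i, j, k],
       f_trans = .phase_tables$ft[i, j, k],
       f_untrans = .phase_tables$fu[i, j, k],
       m_trans = .phase_tables$mt[i, j, k],
       m_untrans = .phase_tables$mu[i, j, k])
}

#' Phase a whole trio across all SNPs
#'
#' Applies the single-site Mendelian rules of [phase_site()] at every SNP;
#' no site is dropped here (error removal is a separate pass,
#' [remove_mendelian_errors()]).
#'
#' @param father,mother,child individual ids (rownames of `genotypes`).
#' @param genotypes a [genotype_matrix()].
#' @return object of class `PhasedTrio`: ids, per-SNP `state`, and allele
#'   vectors `f_trans`, `f_untrans`, `m_trans`, `m_untrans` (1/2/`NA`).
#' @export
phase_trio <- function(father, mother, child, genotypes) {
  idx <- cbind(.gidx(genotypes[father, ]), .gidx(genotypes[mother, ]),
               .gidx(genotypes[child, ]))
  structure(list(
    father = father, mother = mother, child = child, type = "trio",
    state = .phase_tables$st[idx],
    f_trans = .phase_tables$ft[idx], f_untrans = .phase_tables$fu[idx],
    m_trans = .phase_tables$mt[idx], m_untrans = .phase_tables$mu[idx]
  ), class = "PhasedTrio")
}

#' Phase a single-parent duo
#'
#' @param parent,child ids; `role` is the parent's role
#'   (`"father"`/`"mother"`); the absent parent's vectors stay `NA`.
#' @param role,genotypes see above.
#' @return a `PhasedTrio` with `type = "duo"`.
#' @export
phase_duo <- function(parent, child, role, genotypes) {
  idx <- cbind(.gidx(genotypes[parent, ]), .gidx(genotypes[child, ]))
  trans <- .duo_tables$pt[idx]; untrans <- .duo_tables$pu[idx]
  empty <- rep(NA_integer_, ncol(genotypes))
  out <- list(father = NA_character_, mother = NA_character_, child = child,
              type = "duo", state = .duo_tables$st[idx],
              f_trans = empty, f_untrans = empty,
              m_trans = empty, m_untrans = empty)
  if (role == "father") {
    out$father <- parent; out$f_trans <- trans; out$f_untrans <- untrans
  } else {
    out$mother <- parent; out$m_trans <- trans; out$m_untrans <- untrans
  }
  structure(out, class = "PhasedTrio")
}

#' Phase every nuclear unit of a pedigree
#'
#' @param ped a [pedigree()]; `genotypes` the matching [genotype_matrix()].
#' @param genotypes see above.
#' @return list of `PhasedTrio` (trios first, then duos, pedigree order).
#' @export
phase_all <- function(ped, genotypes) {
  units <- decompose_trios(ped)
  phased <- lapply(seq_len(nrow(units$trios)), function(i)
    phase_trio(units$trios$father[i], units$trios$mother[i],
               units$trios$child[i], genotypes))
  c(phased, lapply(seq_len(nrow(units$duos)), function(i)
    phase_duo(units$duos$parent[i], units$duos$child[i],
              units$duos$role[i], genotypes)))
}

#' Remove SNPs showing Mendelian errors
#'
#' A SNP inconsistent with Mendelian transmission in any nuclear unit is
#' removed genome-wide (for all individuals), keeping every trio on one
#' marker grid; the removed ids are returned for the run log.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phased list of `PhasedTrio` from [phase_all()] (or a [pedigree()],
#'   in which case phasing is done internally).
#' @return `list(genotypes, removed)` with the cleaned matrix and the
#'   character vector of removed SNP ids.
#' @export
remove_mendelian_errors <- function(genotypes, phased) {
  if (inherits(phased, "Pedigree")) phased <- phase_all(phased, genotypes)
  bad <- Reduce(`|`, lapply(phased, function(pt) pt$state == "mendel_error"),
                rep(FALSE, ncol(genotypes)))
  removed <- colnames(genotypes)[bad]
  if (all(bad)) warning("all SNPs removed as Mendelian errors")
  keep <- genotypes[, !bad, drop = FALSE]
  out <- genotype_matrix(keep, attr(genotypes, "allele_labels")[, !bad, drop = FALSE])
  list(genotypes = out, removed = removed)
}

# subset the per-SNP vectors of phased objects to the surviving columns
.subset_phased <- function(phased, keep) {
  lapply(phased, function(pt) {
    for (f in c("state", "f_trans", "f_untrans", "m_trans", "m_untrans"))
      pt[[f]] <- pt[[f]][keep]
    pt
  })
}
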
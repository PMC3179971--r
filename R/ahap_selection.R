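## Selection of affected haploids (aHaps).
##
## Dominant model, per nuclear unit with an affected genotyped parent:
##   * child affected                  -> that parent's transmitted haploid
##                                        is an assured aHap;
##   * child unaffected, complete
##     penetrance                      -> the parent's untransmitted haploid
##                                        is an assured aHap;
##   * child status unknown, or child
##     unaffected under incomplete
##     penetrance                      -> the parent's transmitted and
##                                        untransmitted haploids enter as a
##                                        paired set: at least one of the
##                                        two is the disease haploid.
## Mother-affected cases mirror the father-affected rules; when both
## parents are affected each contributes independently.  Recessive model:
## both deduced haploids of every affected child (its paternal- and
## maternal-transmitted haploids) are assured aHaps.

.new_ahap <- function(alleles, child, parent, which, status, pair_id = NA_character_,
                      child_affection = NA_character_) {
  structure(list(alleles = alleles, child = child, parent = parent,
                 which = which, status = status, pair_id = pair_id,
                 child_affection = child_affection), class = "AHap")
}

.haploid_of <- function(pt, side, which) {
  v <- pt[[paste0(substr(side, 1, 1), "_", if (which == "transmitted") "trans" else "untrans")]]
  v[pt$state != "phased"] <- NA_integer_
  v
}

#' Select the affected haploids (aHaps) of a family
#'
#' Applies the inheritance-model rules above to every phased nuclear unit
#' and collects the assured aHaps plus, for status-unknown (or, under
#' incomplete penetrance, unaffected) children of an affected parent, the
#' paired transmitted/untransmitted candidates.
#'
#' @param phased list of `PhasedTrio` from [phase_all()].
#' @param ped the [pedigree()] supplying affection statuses.
#' @param model `"dominant"` or `"recessive"`.
#' @param penetrance `"complete"` or `"incomplete"`.
#' @return object of class `AHapSet`: `assured` (list of `AHap`), `paired`
#'   (list of two-member `AHap` lists sharing a `pair_id`), `model`,
#'   `penetrance`.
#' @export
select_ahaps <- function(phased, ped, model = c("dominant", "recessive"),
                         penetrance = c("complete", "incomplete")) {
  model <- match.arg(model); penetrance <- match.arg(penetrance)
  aff_of <- function(id) ped$affection[match(id, ped$id)]
  assured <- list(); paired <- list()

  if (model == "dominant") {
    if (penetrance == "complete") {
      # model-violation guard: an affected child of two genotyped unaffected
      # parents is impossible under dominant/complete
      for (pt in phased) {
        pa <- c(pt$father, pt$mother); pa <- pa[!is.na(pa)]
        if (pt$type == "trio" && aff_of(pt$child) == "affected" &&
            all(aff_of(pa) == "unaffected"))
          .hl_error(sprintf(
            "affected child %s with two unaffected parents is incompatible with a dominant model under complete penetrance; use penetrance = \"incomplete\"",
            pt$child), "haplolink_model_violation")
      }
    }
    for (pt in phased) {
      for (side in c("father", "mother")) {
        parent <- pt[[side]]
        if (is.na(parent) || aff_of(parent) != "affected") next
        ca <- aff_of(pt$child)
        if (ca == "affected") {
          assured <- c(assured, list(.new_ahap(.haploid_of(pt, side, "transmitted"),
                                               pt$child, parent, "transmitted",
                                               "assured", child_affection = ca)))
        } else if (ca == "unaffected" && penetrance == "complete") {
          assured <- c(assured, list(.new_ahap(.haploid_of(pt, side, "untransmitted"),
                                               pt$child, parent, "untransmitted",
                                               "assured", child_affection = ca)))
        } else {
          pid <- sprintf("pair_%s_%s", parent, pt$child)
          paired <- c(paired, list(list(
            transmitted = .new_ahap(.haploid_of(pt, side, "transmitted"),
                                    pt$child, parent, "transmitted", "paired", pid, ca),
            untransmitted = .new_ahap(.haploid_of(pt, side, "untransmitted"),
                                      pt$child, parent, "untransmitted", "paired", pid, ca),
            pair_id = pid, child = pt$child, child_affection = ca)))
        }
      }
    }
  } else {
    # recessive: both haploids received by each affected child are assured;
    # unaffected siblings are non-informative for aHap construction
    for (pt in phased) {
      if (aff_of(pt$child) != "affected") next
      for (side in c("father", "mother")) {
        if (is.na(pt[[side]])) next
        assured <- c(assured, list(.new_ahap(.haploid_of(pt, side, "transmitted"),
                                             pt$child, pt[[side]], "transmitted",
                                             "assured", child_affection = "affected")))
      }
    }
  }

  if (length(assured) == 0L)
    .hl_error("no assured aHap can be formed from the pedigree (E_NO_AHAP): need an affected parent with a status-known child (dominant) or an affected child (recessive)",
              "haplolink_no_ahap")
  structure(list(assured = assured, paired = paired,
                 model = model, penetrance = penetrance),
            class = "AHapSet")
}

#' Assured aHap alleles as a matrix
#'
#' @param ahapset an `AHapSet`.
#' @return integer matrix, one row per assured aHap (alleles 1/2, `NA`
#'   unresolved), columns = surviving SNPs.
#' @export
ahap_matrix <- function(ahapset) {
  do.call(rbind, lapply(ahapset$assured, `[[`, "alleles"))
}

#' @export
print.AHapSet <- function(x, ...) {
  cat(sprintf("AHapSet: %d assured aHap(s), %d paired set(s); model %s, penetrance %s\n",
              length(x$assured), length(x$paired), x$model, x$penetrance))
  invisible(x)
}
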
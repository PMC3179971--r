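# pedigree: affected father x unaffected mother with three children of
# differing status; genotypes chosen so every site phases
make_family <- function(child_affection = c("affected", "unaffected", "unknown"),
                        father_affection = "affected") {
  ids <- c("dad", "mum", "k1", "k2", "k3")
  ped <- pedigree("F1", ids,
                  father = c(NA, NA, "dad", "dad", "dad"),
                  mother = c(NA, NA, "mum", "mum", "mum"),
                  sex = c("male", "female", "male", "male", "male"),
                  affection = c(father_affection, "unaffected", child_affection))
  # dad 1/2 everywhere, mum 1/1: child het <=> dad transmitted allele 2
  codes <- rbind(dad = rep(1L, 4), mum = rep(0L, 4),
                 k1 = c(1L, 1L, 0L, 0L),
                 k2 = c(0L, 0L, 1L, 1L),
                 k3 = c(1L, 0L, 1L, 0L))
  colnames(codes) <- sprintf("s%d", 1:4)
  list(ped = ped, genotypes = genotype_matrix(codes))
}

test_that("dominant-model aHap selection follows the affection-driven rules", {
  fam <- make_family()
  phased <- phase_all(fam$ped, fam$genotypes)
  ah <- select_ahaps(phased, fam$ped, "dominant", "complete")
  expect_s3_class(ah, "AHapSet")
  # affected child k1 -> father's transmitted haploid assured
  a1 <- ah$assured[[1]]
  expect_equal(a1$child, "k1"); expect_equal(a1$which, "transmitted")
  expect_equal(unname(a1$alleles), c(2L, 2L, 1L, 1L))
  # healthy child k2 under complete penetrance -> untransmitted assured
  a2 <- ah$assured[[2]]
  expect_equal(a2$child, "k2"); expect_equal(a2$which, "untransmitted")
  expect_equal(unname(a2$alleles), c(2L, 2L, 1L, 1L))
  # unknown-status child k3 -> paired transmitted/untransmitted set
  expect_length(ah$paired, 1L)
  expect_equal(ah$paired[[1]]$child, "k3")
  expect_equal(unname(ah$paired[[1]]$transmitted$alleles), c(2L, 1L, 2L, 1L))
  expect_equal(unname(ah$paired[[1]]$untransmitted$alleles), c(1L, 2L, 1L, 2L))
  expect_equal(ah$paired[[1]]$transmitted$pair_id,
               ah$paired[[1]]$untransmitted$pair_id)

  # incomplete penetrance: the healthy child also becomes a paired set
  ah2 <- select_ahaps(phased, fam$ped, "dominant", "incomplete")
  expect_length(ah2$assured, 1L)
  expect_length(ah2$paired, 2L)

  # count property: assured = trios with affected parent and status-known child
  expect_length(ah$assured, 2L)
})

test_that("recessive model takes both haploids of every affected child", {
  fam <- make_family(child_affection = c("affected", "unaffected", "unaffected"),
                     father_affection = "unaffected")
  phased <- phase_all(fam$ped, fam$genotypes)
  ah <- select_ahaps(phased, fam$ped, "recessive", "complete")
  expect_length(ah$assured, 2L)   # k1's paternal- and maternal-transmitted
  expect_setequal(vapply(ah$assured, function(a) a$parent, ""), c("dad", "mum"))
  expect_true(all(vapply(ah$assured, function(a) a$which, "") == "transmitted"))
  expect_length(ah$paired, 0L)    # unaffected sibs are non-informative
})

test_that("degenerate affection patterns raise the documented errors", {
  fam <- make_family(child_affection = rep("unaffected", 3),
                     father_affection = "unaffected")
  phased <- phase_all(fam$ped, fam$genotypes)
  expect_error(select_ahaps(phased, fam$ped, "dominant", "complete"),
               class = "haplolink_no_ahap")
  # affected child of two unaffected parents contradicts dominant/complete
  fam2 <- make_family(child_affection = c("affected", "unaffected", "unaffected"),
                      father_affection = "unaffected")
  phased2 <- phase_all(fam2$ped, fam2$genotypes)
  expect_error(select_ahaps(phased2, fam2$ped, "dominant", "complete"),
               class = "haplolink_model_violation")
  # ... and under incomplete penetrance it is admissible but still yields
  # no aHap, since every selection rule starts from an affected parent
  expect_error(select_ahaps(phased2, fam2$ped, "dominant", "incomplete"),
               class = "haplolink_no_ahap")
})

test_that("assured aHaps reproduce the simulated parental haploids", {
  fix <- get_validation_fixture()
  phased <- phase_all(fix$pedigree, fix$genotypes)
  ah <- select_ahaps(phased, fix$pedigree, "dominant", "complete")
  expect_length(ah$assured, 10L)   # ten assured meioses by design
  H <- fix$truth$founder_haps
  # truth for a transmitted aHap: allele sequence of the child's chromatid
  # received from that parent
  true_gamete <- function(child, side) {
    al <- integer(nrow(fix$map))
    for (ci in seq_along(unique(fix$map$chrom))) {
      ch <- unique(fix$map$chrom)[ci]
      cols <- which(fix$map$chrom == ch)
      mos <- fix$truth$haplotypes[[child]][[ci]][[side]]
      src <- mos$src[findInterval(fix$map$bp[cols], mos$start)]
      al[cols] <- H[cbind(match(src, rownames(H)), cols)]
    }
    al
  }
  for (a in ah$assured) {
    mother_side <- a$parent %in% fix$pedigree$mother
    truth <- true_gamete(a$child, if (mother_side) "mat" else "pat")
    if (a$which == "untransmitted") {
      # untransmitted allele = parent allele-2 dose minus transmitted dose
      par_dose <- unclass(fix$genotypes)[a$parent, ]
      truth <- par_dose - (truth - 1L) + 1L
    }
    ok <- !is.na(a$alleles)
    expect_true(all(a$alleles[ok] == truth[ok]),
                label = sprintf("aHap %s/%s matches simulated truth",
                                a$parent, a$child))
  }
})
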
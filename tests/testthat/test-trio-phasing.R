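test_that("single-site phasing matches the enumeration oracle over all genotype combinations", {
  # spec-level anchor cases
  s <- phase_site(0L, 2L, 1L)    # 1/1 x 2/2 -> 1/2: fully forced
  expect_equal(s$state, "phased")
  expect_equal(c(s$f_trans, s$f_untrans, s$m_trans, s$m_untrans), c(1, 1, 2, 2))
  expect_equal(phase_site(1L, 1L, 1L)$state, "uninformative")  # all-het
  expect_equal(phase_site(0L, 0L, 1L)$state, "mendel_error")   # allele 2 from nobody
  s <- phase_site(1L, 0L, 0L)    # het father forced to transmit allele 1
  expect_equal(s$state, "phased")
  expect_equal(c(s$f_trans, s$f_untrans, s$m_trans), c(1, 2, 1))
  expect_equal(phase_site(NA, 1L, 1L)$state, "missing")

  geno_alleles <- list(c(1L, 1L), c(1L, 2L), c(2L, 2L))
  for (gF in 0:2) for (gM in 0:2) for (gC in 0:2) {
    s <- phase_site(gF, gM, gC)
    expect_equal(s$state, phase_site_oracle(gF, gM, gC),
                 label = sprintf("state at (%d,%d,%d)", gF, gM, gC))
    # father/mother symmetry
    sw <- phase_site(gM, gF, gC)
    expect_equal(sw$state, s$state)
    expect_equal(c(sw$m_trans, sw$m_untrans), c(s$f_trans, s$f_untrans))
    if (s$state == "phased") {
      # transmitted+untransmitted reconstruct each parent; the two
      # transmitted alleles reconstruct the child
      expect_equal(sort(c(s$f_trans, s$f_untrans)), geno_alleles[[gF + 1L]])
      expect_equal(sort(c(s$m_trans, s$m_untrans)), geno_alleles[[gM + 1L]])
      expect_equal(sort(c(s$f_trans, s$m_trans)), geno_alleles[[gC + 1L]])
    }
    # uninformative exactly when all three are heterozygous
    expect_equal(s$state == "uninformative", gF == 1L && gM == 1L && gC == 1L)
  }
})

test_that("whole-trio phasing equals independent site-wise phasing", {
  # the documented 5-SNP state vector
  fix <- make_trio_fixture(gF = c(0L, 1L, 1L, 0L, 1L),
                           gM = c(2L, 0L, 1L, 0L, NA),
                           gC = c(1L, 0L, 1L, 1L, 1L))
  pt <- phase_trio("dad", "mum", "kid", fix$genotypes)
  expect_equal(pt$state,
               c("phased", "phased", "uninformative", "mendel_error", "missing"))

  set.seed(91)
  n <- 1000L
  g <- function() sample(c(NA, 0L, 1L, 2L), n, replace = TRUE,
                         prob = c(0.05, 0.3, 0.4, 0.25))
  fix <- make_trio_fixture(g(), g(), g())
  pt <- phase_trio("dad", "mum", "kid", fix$genotypes)
  for (j in seq_len(n)) {
    s <- phase_site(fix$genotypes["dad", j], fix$genotypes["mum", j],
                    fix$genotypes["kid", j])
    expect_identical(pt$state[j], s$state)
    expect_identical(pt$f_trans[j], s$f_trans)
    expect_identical(pt$m_untrans[j], s$m_untrans)
  }
})

test_that("single-parent duos phase only forced transmissions", {
  phase_duo_codes <- function(gP, gC, role = "father") {
    ped <- pedigree("F1", c("p", "k"), c(NA, if (role == "father") "p" else NA),
                    c(NA, if (role == "mother") "p" else NA),
                    c(if (role == "father") "male" else "female", "male"),
                    c("affected", "affected"))
    codes <- rbind(p = gP, k = gC); colnames(codes) <- sprintf("s%d", seq_along(gP))
    phase_duo("p", "k", role, genotype_matrix(codes))
  }
  pt <- phase_duo_codes(gP = c(0L, 1L, 2L, 1L, NA), gC = c(1L, 0L, 0L, 1L, 1L))
  # parent hom -> forced; child hom -> forced; both het -> missing
  expect_equal(pt$state, c("phased", "phased", "mendel_error", "missing", "missing"))
  expect_equal(pt$f_trans[1:2], c(1L, 1L))
  expect_equal(pt$f_untrans[1:2], c(1L, 2L))
  pt <- phase_duo_codes(gP = 0L, gC = 2L)
  expect_equal(pt$state, "mendel_error")
  # the absent parent's haploids stay unresolved
  pt <- phase_duo_codes(gP = 0L, gC = 0L, role = "mother")
  expect_true(all(is.na(pt$f_trans)))
  expect_equal(pt$m_trans, 1L)
})

test_that("Mendelian-error SNPs are removed genome-wide and logged", {
  ped <- pedigree("F1",
                  id = c("f1", "m1", "c1", "f2", "m2", "c2"),
                  father = c(NA, NA, "f1", NA, NA, "f2"),
                  mother = c(NA, NA, "m1", NA, NA, "m2"),
                  sex = c("male", "female", "male", "male", "female", "female"),
                  affection = rep("affected", 6))
  codes <- rbind(
    f1 = c(0L, 0L, 1L), m1 = c(0L, 2L, 1L), c1 = c(0L, 1L, 1L),
    f2 = c(0L, 0L, 0L), m2 = c(0L, 0L, 0L), c2 = c(2L, 0L, 0L))  # snp1 bad in trio 2 only
  colnames(codes) <- c("s1", "s2", "s3")
  G <- genotype_matrix(codes)
  out <- remove_mendelian_errors(G, phase_all(ped, G))
  expect_equal(out$removed, "s1")
  expect_equal(colnames(out$genotypes), c("s2", "s3"))  # removed for everyone
  expect_equal(nrow(out$genotypes), 6L)

  clean <- remove_mendelian_errors(G[, 2:3], phase_all(ped, G[, 2:3]))
  expect_equal(length(clean$removed), 0L)
  expect_identical(unclass(clean$genotypes)[, ], unclass(G)[, 2:3])

  all_bad <- genotype_matrix(rbind(f1 = 0L, m1 = 0L, c1 = 2L, f2 = 0L,
                                   m2 = 0L, c2 = 2L))
  colnames(all_bad) <- "s1"
  expect_warning(out <- remove_mendelian_errors(all_bad, phase_all(ped, all_bad)),
                 "all SNPs")
  expect_equal(ncol(out$genotypes), 0L)
})

test_that("trio decomposition yields one trio per fully-parented child plus duos", {
  ped <- pedigree("F1",
                  id = c("f", "m", "a", "b", "c", "d"),
                  father = c(NA, NA, "f", "f", "f", NA),
                  mother = c(NA, NA, "m", "m", "m", "m"),
                  sex = c("male", "female", "male", "female", "male", "male"),
                  affection = rep("unknown", 6))
  units <- decompose_trios(ped)
  expect_equal(units$trios$child, c("a", "b", "c"))  # couple with 3 children
  expect_equal(units$duos$child, "d")                # father absent -> duo
  expect_equal(units$duos$role, "mother")
})
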
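## Genotype codes used throughout: NA = missing call, 0 = 1/1, 1 = 1/2,
## 2 = 2/2 (i.e. the count of allele "2").  Alleles are coded 1/2; letter
## alleles in PED input are recoded per SNP by first occurrence and the
## original labels kept so output can restore them.

.affection_levels <- c("unaffected", "affected", "unknown")
.sex_levels <- c("male", "female", "unknown")

.hl_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "haplolink_error")))
}

#' Construct a pedigree table
#'
#' A `Pedigree` is a data frame with one row per individual: `fam`, `id`,
#' `father`, `mother` (`NA` when absent), `sex` (`male`/`female`/`unknown`)
#' and `affection` (`unaffected`/`affected`/`unknown`).  The constructor
#' validates single-family structure, unique ids, parental references of
#' compatible sex, and acyclicity.
#'
#' @param fam,id,father,mother,sex,affection vectors of equal length.
#' @return a data frame of class `Pedigree`.
#' @export
pedigree <- function(fam, id, father, mother, sex, affection) {
  ped <- data.frame(
    fam = as.character(fam), id = as.character(id),
    father = as.character(father), mother = as.character(mother),
    sex = as.character(sex), affection = as.character(affection),
    stringsAsFactors = FALSE
  )
  ped$father[ped$father %in% c("0", "", NA)] <- NA_character_
  ped$mother[ped$mother %in% c("0", "", NA)] <- NA_character_
  validate_pedigree(ped)
  class(ped) <- c("Pedigree", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (length(unique(ped$fam)) > 1L)
    .hl_error(sprintf(
      "multiple families in input (%s): the method assumes a single disease founder; split the file per family",
      paste(unique(ped$fam), collapse = ", ")), "haplolink_multifamily")
  if (anyDuplicated(ped$id))
    .hl_error(sprintf("duplicate individual id(s): %s",
                      paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")),
              "haplolink_format")
  if (!all(ped$sex %in% .sex_levels))
    .hl_error("sex must be male/female/unknown", "haplolink_format")
  if (!all(ped$affection %in% .affection_levels))
    .hl_error("affection must be unaffected/affected/unknown", "haplolink_format")
  for (col in c("father", "mother")) {
    ref <- ped[[col]]
    bad <- !is.na(ref) & !(ref %in% ped$id)
    if (any(bad))
      .hl_error(sprintf("%s id(s) not present as individuals: %s", col,
                        paste(ref[bad], collapse = ", ")), "haplolink_format")
    want <- if (col == "father") "male" else "female"
    psex <- ped$sex[match(ref[!is.na(ref)], ped$id)]
    if (any(psex != want & psex != "unknown"))
      .hl_error(sprintf("a recorded %s has incompatible sex", col), "haplolink_format")
  }
  # acyclicity: repeatedly strip individuals with no remaining parent;
  # a non-empty residue means someone is their own ancestor
  remaining <- ped$id
  while (length(remaining) > 0L) {
    i <- match(remaining, ped$id)
    has_parent <- (ped$father[i] %in% remaining) | (ped$mother[i] %in% remaining)
    if (all(has_parent))
      .hl_error("pedigree contains a cycle (an individual is its own ancestor)",
                "haplolink_format")
    remaining <- remaining[has_parent]
  }
  invisible(ped)
}

#' Construct a genotype matrix
#'
#' Integer matrix, individuals in rows (rownames = ids) and SNPs in columns
#' (colnames = SNP ids); entries are `NA` (missing), 0 (`1/1`), 1 (`1/2`),
#' 2 (`2/2`).  The per-SNP mapping from internal allele codes 1/2 back to
#' the input allele labels is kept in the `allele_labels` attribute
#' (2 x nsnp character matrix).
#'
#' @param codes integer matrix of genotype codes.
#' @param allele_labels optional 2 x ncol character matrix of original
#'   allele labels (defaults to "1"/"2").
#' @return matrix of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(codes, allele_labels = NULL) {
  storage.mode(codes) <- "integer"
  if (any(!(codes %in% c(NA, 0L, 1L, 2L))))
    .hl_error("genotype codes must be NA/0/1/2", "haplolink_format")
  if (is.null(allele_labels))
    allele_labels <- matrix(rep(c("1", "2"), ncol(codes)), nrow = 2,
                            dimnames = list(NULL, colnames(codes)))
  attr(codes, "allele_labels") <- allele_labels
  class(codes) <- c("GenotypeMatrix", class(codes))
  codes
}

#' Construct a marker map
#'
#' @param chrom,snp,bp,cm per-SNP chromosome label, id, 1-based physical
#'   position, and optional genetic position (centimorgan, `NA` if absent).
#' @return data frame of class `MarkerMap` with columns
#'   `chrom`, `snp`, `cm`, `bp`.
#' @export
marker_map <- function(chrom, snp, bp, cm = NA_real_) {
  map <- data.frame(chrom = as.character(chrom), snp = as.character(snp),
                    cm = as.numeric(cm), bp = as.numeric(bp),
                    stringsAsFactors = FALSE)
  validate_marker_map(map)
  class(map) <- c("MarkerMap", "data.frame")
  map
}

validate_marker_map <- function(map) {
  if (any(is.na(map$bp)) || any(map$bp < 1))
    .hl_error("bp positions must be numeric and >= 1", "haplolink_format")
  for (ch in unique(map$chrom)) {
    bp <- map$bp[map$chrom == ch]
    if (any(diff(bp) <= 0)) {
      i <- which(diff(bp) <= 0)[1] + 1L
      .hl_error(sprintf("bp not strictly increasing on chromosome %s at SNP %s",
                        ch, map$snp[map$chrom == ch][i]), "haplolink_format")
    }
  }
  invisible(map)
}

#' Read a linkage PED file
#'
#' Whitespace-delimited, 6 leading columns (family, individual, father,
#' mother, sex, affection) then two allele columns per SNP.  Affection codes
#' 1 = unaffected, 2 = affected, 0 or -9 = unknown; parent id "0" = absent.
#' Allele codes may be 1/2 or letters (at most two distinct non-missing
#' codes per SNP); letters are recoded to 1/2 by first occurrence and the
#' original labels retained for round-tripping.
#'
#' @param path path to the .ped file.
#' @param map optional [marker_map()]; when given, the number of allele
#'   column pairs must match its length and its SNP ids are used.
#' @return `list(pedigree = Pedigree, genotypes = GenotypeMatrix)`.
#' @export
read_pedfile <- function(path, map = NULL) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 8L || (ncol(tab) - 6L) %% 2L != 0L)
    .hl_error(sprintf("PED file %s: need 6 leading columns plus 2 allele columns per SNP (found %d columns)",
                      path, ncol(tab)), "haplolink_format")
  n_snp <- (ncol(tab) - 6L) %/% 2L
  if (!is.null(map) && n_snp != nrow(map))
    .hl_error(sprintf("PED file has %d SNPs but map has %d", n_snp, nrow(map)),
              "haplolink_format")
  aff <- c("1" = "unaffected", "2" = "affected", "0" = "unknown", "-9" = "unknown")[tab[[6]]]
  if (any(is.na(aff)))
    .hl_error(sprintf("unrecognized affection code in row %d",
                      which(is.na(aff))[1]), "haplolink_format")
  sex <- c("1" = "male", "2" = "female")[tab[[5]]]
  sex[is.na(sex)] <- "unknown"
  ped <- pedigree(tab[[1]], tab[[2]], tab[[3]], tab[[4]], sex, aff)

  snp_ids <- if (!is.null(map)) map$snp else sprintf("snp%d", seq_len(n_snp))
  a1 <- as.matrix(tab[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE])
  a2 <- as.matrix(tab[, 6L + 2L * seq_len(n_snp), drop = FALSE])
  codes <- matrix(NA_integer_, nrow(tab), n_snp,
                  dimnames = list(ped$id, snp_ids))
  labels <- matrix(NA_character_, 2, n_snp, dimnames = list(NULL, snp_ids))
  ok_codes <- c("0", "1", "2", "A", "C", "G", "T")
  for (j in seq_len(n_snp)) {
    # first-seen order across rows: row1 allele1, row1 allele2, row2 allele1, ...
    seen <- as.vector(rbind(a1[, j], a2[, j]))
    if (any(!(seen %in% ok_codes)))
      .hl_error(sprintf("SNP %s: allele code '%s' not in {0,1,2,A,C,G,T}",
                        snp_ids[j], setdiff(seen, ok_codes)[1]), "haplolink_format")
    obs <- unique(seen[seen != "0"])
    if (length(obs) > 2L)
      .hl_error(sprintf("SNP %s: more than two alleles observed (%s)",
                        snp_ids[j], paste(obs, collapse = ",")), "haplolink_format")
    lab <- if (all(obs %in% c("1", "2"))) c("1", "2") else c(obs, "N")[1:2]
    labels[, j] <- lab
    c1 <- (a1[, j] == lab[2]) ; c2 <- (a2[, j] == lab[2])
    miss <- a1[, j] == "0" | a2[, j] == "0"
    codes[, j] <- ifelse(miss, NA_integer_, as.integer(c1) + as.integer(c2))
  }
  list(pedigree = ped, genotypes = genotype_matrix(codes, labels))
}

#' Write a linkage PED file
#'
#' Inverse of [read_pedfile()]: restores the original allele labels stored
#' on the genotype matrix.
#'
#' @param ped a [pedigree()]; `genotypes` a [genotype_matrix()] with rows
#'   matching `ped$id`; `path` output file.
#' @param genotypes,path see above.
#' @export
write_pedfile <- function(ped, genotypes, path) {
  lab <- attr(genotypes, "allele_labels")
  n_snp <- ncol(genotypes)
  out <- matrix("0", nrow(genotypes), 2L * n_snp)
  for (j in seq_len(n_snp)) {
    g <- genotypes[, j]
    out[, 2L * j - 1L] <- ifelse(is.na(g), "0", ifelse(g == 2L, lab[2, j], lab[1, j]))
    out[, 2L * j]      <- ifelse(is.na(g), "0", ifelse(g >= 1L, lab[2, j], lab[1, j]))
  }
  sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  aff <- c(unaffected = "1", affected = "2", unknown = "0")[ped$affection]
  lead <- cbind(ped$fam, ped$id,
                ifelse(is.na(ped$father), "0", ped$father),
                ifelse(is.na(ped$mother), "0", ped$mother), sex, aff)
  utils::write.table(cbind(lead, out), path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a linkage MAP file
#'
#' Accepts the 4-column (`chrom id cM bp`) and 3-column (`chrom id bp`)
#' dialects.  Positions are checked to be strictly increasing within each
#' chromosome; violations are an error (the map is never silently re-sorted).
#'
#' @param path path to the .map file.
#' @return a [marker_map()].
#' @export
read_mapfile <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (!ncol(tab) %in% c(3L, 4L))
    .hl_error(sprintf("MAP file %s: expected 3 or 4 columns, found %d",
                      path, ncol(tab)), "haplolink_format")
  bp_col <- ncol(tab)
  bp <- suppressWarnings(as.numeric(tab[[bp_col]]))
  if (any(is.na(bp)))
    .hl_error(sprintf("MAP file: non-numeric bp for SNP %s",
                      tab[[2]][which(is.na(bp))[1]]), "haplolink_format")
  cm <- if (ncol(tab) == 4L) suppressWarnings(as.numeric(tab[[3]])) else NA_real_
  marker_map(tab[[1]], tab[[2]], bp, cm)
}

#' Write a MAP file (4-column dialect; cM written as 0 when absent)
#' @param map a [marker_map()]; `path` output file.
#' @param path output file.
#' @export
write_mapfile <- function(map, path) {
  cm <- ifelse(is.na(map$cm), 0, map$cm)
  utils::write.table(
    data.frame(map$chrom, map$snp, cm, format(map$bp, scientific = FALSE, trim = TRUE)),
    path, quote = FALSE, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.region_columns <- c("chrom", "start_bp", "end_bp", "n_snps", "k_meioses",
                     "r_recomb", "theta_hat", "lod")

.region_table <- function(regions) {
  # single formatting pipeline shared by the TSV writer and the HTML report
  data.frame(
    chrom = as.character(regions$chrom),
    start_bp = format(regions$start_bp, scientific = FALSE, trim = TRUE),
    end_bp = format(regions$end_bp, scientific = FALSE, trim = TRUE),
    n_snps = regions$n_snps,
    k_meioses = regions$k_meioses,
    r_recomb = regions$r_recomb,
    theta_hat = formatC(regions$theta_hat, digits = 4, format = "f"),
    lod = formatC(regions$lod, digits = 3, format = "f"),
    stringsAsFactors = FALSE
  )
}

#' Write candidate regions
#'
#' Internal coordinates are 1-based inclusive.  The BED dialect converts to
#' 0-based half-open (`start_bp - 1`, `end_bp`); TSV and JSON keep 1-based
#' inclusive coordinates and carry `lod`, `n_snps`, `k_meioses`, `r_recomb`
#' and `theta_hat`.  An empty region set writes a header-only (or empty
#' BED / empty JSON array) file.
#'
#' @param regions data frame of candidate regions (see [score_segments()]).
#' @param path output file.
#' @param dialect one of `"tsv"`, `"bed"`, `"json"`.
#' @export
write_regions <- function(regions, path, dialect = c("tsv", "bed", "json")) {
  dialect <- match.arg(dialect)
  if (is.null(regions) || nrow(regions) == 0L)
    regions <- data.frame(chrom = character(), start_bp = numeric(),
                          end_bp = numeric(), n_snps = integer(),
                          k_meioses = integer(), r_recomb = integer(),
                          theta_hat = numeric(), lod = numeric())
  if (dialect == "bed") {
    bed <- data.frame(
      chrom = paste0(ifelse(grepl("^chr", regions$chrom), "", "chr"), regions$chrom),
      start = format(regions$start_bp - 1, scientific = FALSE, trim = TRUE),
      end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
      name = sprintf("region_%d", seq_len(nrow(regions))),
      score = formatC(regions$lod, digits = 3, format = "f"))
    utils::write.table(bed, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else if (dialect == "tsv") {
    utils::write.table(.region_table(regions), path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = TRUE)
  } else {
    jsonlite::write_json(regions[, intersect(.region_columns, names(regions))],
                         path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
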
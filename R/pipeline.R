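## End-to-end analysis: phasing -> Mendelian-error removal -> aHap
## selection -> sharing scan -> paired refinement -> LOD scoring
## (-> optional LOH annotation).

#' Run the whole haplotype-sharing linkage analysis
#'
#' @param ped a [pedigree()].
#' @param genotypes the matching [genotype_matrix()].
#' @param map the matching [marker_map()].
#' @param model inheritance model, `"dominant"` or `"recessive"`.
#' @param penetrance `"complete"` or `"incomplete"`.
#' @param params a [scan_params()].
#' @param include_pairs count resolved paired aHaps in the LOD
#'   (default TRUE).
#' @param allow_single_ahap see [scan_chromosome()].
#' @param loh run the loss-of-heterozygosity deletion test and annotate
#'   regions (default FALSE).
#' @param loh_parameters a [loh_params()].
#' @return list of class `haplolink_result`: `regions` (scored candidate
#'   regions), `segments` (pre-scoring), `ahaps`, `pair_calls`,
#'   `removed_snps`, `loh_runs`, `map` (surviving markers), `log`
#'   (character vector of run messages).
#' @export
run_linkage <- function(ped, genotypes, map,
                        model = c("dominant", "recessive"),
                        penetrance = c("complete", "incomplete"),
                        params = scan_params(), include_pairs = TRUE,
                        allow_single_ahap = FALSE, loh = FALSE,
                        loh_parameters = loh_params()) {
  model <- match.arg(model); penetrance <- match.arg(penetrance)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  raw_genotypes <- genotypes; raw_map <- map
  phased <- phase_all(ped, genotypes)
  note("nuclear units phased: %d", length(phased))
  cleaned <- remove_mendelian_errors(genotypes, phased)
  note("SNPs removed for Mendelian errors: %d", length(cleaned$removed))
  keep <- !(colnames(genotypes) %in% cleaned$removed)
  genotypes <- cleaned$genotypes
  map <- map[keep, , drop = FALSE]
  phased <- .subset_phased(phased, keep)

  ahaps <- select_ahaps(phased, ped, model, penetrance)
  note("assured aHaps: %d; paired sets: %d",
       length(ahaps$assured), length(ahaps$paired))

  segments <- scan_genome(ahaps, map, params, allow_single_ahap)
  note("homozygous segments before refinement: %d", nrow(segments))

  pair_calls <- data.frame()
  if (length(ahaps$paired) > 0L && nrow(segments) > 0L) {
    refined <- lapply(seq_len(nrow(segments)), function(i)
      refine_with_paired(segments[i, ], ahaps, map, params))
    segments <- do.call(rbind, lapply(refined, `[[`, "segments"))
    pair_calls <- unique(do.call(rbind, lapply(refined, `[[`, "pair_calls")))
    note("segments after paired-aHap refinement: %d", nrow(segments))
  }

  regions <- score_segments(segments, ahaps, map, params, include_pairs)

  loh_runs <- NULL
  if (loh) {
    # the LOH test reads the raw genotypes: a hemizygous deletion produces
    # Mendelian errors, so its SNPs would be absent from the cleaned matrix
    affected <- ped$id[ped$affection == "affected"]
    loh_runs <- detect_loh(raw_genotypes, raw_map, affected, loh_parameters)
    regions <- annotate_loh(regions, loh_runs)
    note("LOH runs detected: %d", nrow(loh_runs))
  }

  structure(list(regions = regions, segments = segments, ahaps = ahaps,
                 pair_calls = pair_calls, removed_snps = cleaned$removed,
                 loh_runs = loh_runs, map = map, log = log),
            class = "haplolink_result")
}

#' @export
print.haplolink_result <- function(x, ...) {
  cat("Haplotype-sharing linkage analysis\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  if (nrow(x$regions) == 0L) {
    cat("  no candidate regions\n")
  } else {
    cat(sprintf("  %d candidate region(s); top LOD %.3f\n",
                nrow(x$regions), max(x$regions$lod, na.rm = TRUE)))
  }
  invisible(x)
}

#' File-level pipeline wrapper
#'
#' Reads PED/MAP, runs [run_linkage()], and writes `regions.tsv`,
#' `regions.bed`, `regions.json`, `report.html`, `lod_genome.png` and
#' `run_log.txt` into `out_dir`.
#'
#' @param ped_path,map_path input files.
#' @param out_dir output directory (created if needed).
#' @param genes_path optional BED/GFF3 gene annotation for the report.
#' @param ... passed to [run_linkage()].
#' @return the `haplolink_result`, invisibly.
#' @export
run_linkage_files <- function(ped_path, map_path, out_dir, genes_path = NULL,
                              ...) {
  map <- read_mapfile(map_path)
  inp <- read_pedfile(ped_path, map)
  res <- run_linkage(inp$pedigree, inp$genotypes, map, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_regions(res$regions, file.path(out_dir, "regions.tsv"), "tsv")
  write_regions(res$regions, file.path(out_dir, "regions.bed"), "bed")
  write_regions(res$regions, file.path(out_dir, "regions.json"), "json")
  gene_lists <- if (!is.null(genes_path) && nrow(res$regions) > 0L)
    intersect_genes(res$regions, genes_path) else NULL
  meta <- list(ped = basename(ped_path), map = basename(map_path),
               snps_removed = length(res$removed_snps),
               assured_ahaps = length(res$ahaps$assured),
               paired_sets = length(res$ahaps$paired))
  render_html(res$regions, gene_lists, meta, file.path(out_dir, "report.html"))
  render_genome_figure(res$regions, res$map, file.path(out_dir, "lod_genome.png"))
  writeLines(c(res$log, if (length(res$removed_snps))
    paste("removed:", paste(res$removed_snps, collapse = " "))),
    file.path(out_dir, "run_log.txt"))
  invisible(res)
}
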
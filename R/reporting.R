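## Hypertext report, genome-wide LOD figure, and candidate-gene
## intersection.  Gene links are URL templates only (no network access).

.GENE_URL <- "https://www.ncbi.nlm.nih.gov/gene/?term=%s"
.OMIM_URL <- "https://omim.org/search?search=%s"

#' Intersect candidate regions with a gene annotation
#'
#' The annotation may be BED (0-based half-open) or GFF3 (1-based
#' inclusive); the convention is set automatically by the file extension
#' via the importer.  A gene is reported for a region iff their intervals
#' overlap by at least 1 bp.  Each reported gene carries gene-database and
#' OMIM hyperlink templates parameterized by its symbol.
#'
#' @param regions candidate-region data frame ([score_segments()]).
#' @param annotation_path path to a .bed/.gff/.gff3 gene file.
#' @return list (one element per region row) of data frames
#'   `gene`, `chrom`, `start_bp`, `end_bp`, `gene_url`, `omim_url`.
#' @export
intersect_genes <- function(regions, annotation_path) {
  genes <- tryCatch(rtracklayer::import(annotation_path),
                    error = function(e) .hl_error(
                      sprintf("malformed annotation file %s: %s",
                              annotation_path, conditionMessage(e)),
                      "haplolink_format"))
  mc <- S4Vectors::mcols(genes)
  name <- if ("Name" %in% names(mc)) mc$Name
    else if ("name" %in% names(mc)) mc$name
    else if ("gene_name" %in% names(mc)) mc$gene_name
    else if ("ID" %in% names(mc)) mc$ID
    else sprintf("feature_%d", seq_along(genes))
  gchrom <- sub("^chr", "", as.character(GenomicRanges::seqnames(genes)))
  lapply(seq_len(nrow(regions)), function(i) {
    hit <- which(gchrom == sub("^chr", "", regions$chrom[i]) &
                   GenomicRanges::start(genes) <= regions$end_bp[i] &
                   GenomicRanges::end(genes) >= regions$start_bp[i])
    data.frame(gene = as.character(name[hit]),
               chrom = gchrom[hit],
               start_bp = GenomicRanges::start(genes)[hit],
               end_bp = GenomicRanges::end(genes)[hit],
               gene_url = sprintf(.GENE_URL, name[hit]),
               omim_url = sprintf(.OMIM_URL, name[hit]),
               stringsAsFactors = FALSE)
  })
}

.html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render the hypertext report
#'
#' A single self-contained HTML file: run-parameter table, candidate-region
#' table (coordinates, supporting SNPs, k, r, theta-hat, LOD, maximum-LOD
#' flag, LOH note), and per-region candidate-gene lists with database
#' links.  Output is deterministic for identical inputs (no timestamps).
#'
#' @param regions candidate-region data frame.
#' @param gene_lists optional output of [intersect_genes()].
#' @param run_metadata named list rendered into the parameter table.
#' @param path output HTML path.
#' @export
render_html <- function(regions, gene_lists = NULL, run_metadata = list(),
                        path) {
  h <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
         "<title>Haplotype-sharing linkage report</title>",
         "<style>body{font-family:sans-serif}table{border-collapse:collapse}",
         "td,th{border:1px solid #999;padding:4px 8px}th{background:#eee}</style>",
         "</head><body>",
         "<h1>Haplotype-sharing linkage report</h1>")
  if (length(run_metadata)) {
    h <- c(h, "<h2>Parameters</h2>", "<table>")
    for (k in names(run_metadata))
      h <- c(h, sprintf("<tr><th>%s</th><td>%s</td></tr>", .html_escape(k),
                        .html_escape(paste(run_metadata[[k]], collapse = ", "))))
    h <- c(h, "</table>")
  }
  h <- c(h, "<h2>Candidate regions</h2>")
  if (is.null(regions) || nrow(regions) == 0L) {
    h <- c(h, "<p><strong>No candidate regions were found.</strong></p>")
  } else {
    tab <- .region_table(regions)
    tab$max_lod <- ifelse(regions$is_max, "&#9650;", "")
    tab$loh_note <- if ("loh_note" %in% names(regions))
      .html_escape(regions$loh_note) else ""
    h <- c(h, "<table>", paste0("<tr>", paste0("<th>", names(tab), "</th>",
                                               collapse = ""), "</tr>"))
    for (i in seq_len(nrow(tab)))
      h <- c(h, paste0("<tr>", paste0("<td>", unlist(tab[i, ]), "</td>",
                                      collapse = ""), "</tr>"))
    h <- c(h, "</table>")
    if (!is.null(gene_lists)) {
      h <- c(h, "<h2>Candidate genes</h2>")
      for (i in seq_len(nrow(regions))) {
        h <- c(h, sprintf("<h3>Region %d (chr%s:%s-%s)</h3>", i,
                          regions$chrom[i],
                          format(regions$start_bp[i], scientific = FALSE),
                          format(regions$end_bp[i], scientific = FALSE)))
        gl <- gene_lists[[i]]
        if (is.null(gl) || nrow(gl) == 0L) {
          h <- c(h, "<p>No annotated genes overlap this region.</p>")
        } else {
          h <- c(h, "<ul>", sprintf(
            "<li>%s (<a href='%s'>gene</a>, <a href='%s'>OMIM</a>)</li>",
            .html_escape(gl$gene), gl$gene_url, gl$omim_url), "</ul>")
        }
      }
    }
  }
  h <- c(h, "</body></html>")
  writeLines(h, path)
  invisible(path)
}

#' Render the genome-wide LOD figure
#'
#' Chromosome / physical position / LOD are drawn as stacked per-chromosome
#' tracks: each chromosome is one horizontal lane spanning its physical
#' extent, every candidate region is a stem at its midpoint with height
#' proportional to its LOD, and maximum-LOD regions are marked with filled
#' arrowheads (others with open circles).
#'
#' @param regions candidate-region data frame.
#' @param map the [marker_map()] (supplies chromosome extents).
#' @param path output PNG path.
#' @export
render_genome_figure <- function(regions, map, path) {
  chroms <- unique(map$chrom)
  ext <- vapply(chroms, function(ch) max(map$bp[map$chrom == ch]), numeric(1))
  max_lod <- if (nrow(regions) && any(is.finite(regions$lod)))
    max(regions$lod, na.rm = TRUE) else 1
  lane_h <- max_lod * 1.3
  grDevices::png(path, width = 900, height = 120 * length(chroms) + 120,
                 res = 96)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 6, 2, 1))
  graphics::plot(NA, xlim = c(0, max(ext)), ylim = c(0, lane_h * length(chroms)),
                 xlab = "physical position (bp)", ylab = "", yaxt = "n",
                 main = "Candidate linkage regions")
  graphics::axis(2, at = (seq_along(chroms) - 0.5) * lane_h,
                 labels = paste0("chr", chroms), las = 1)
  for (ci in seq_along(chroms)) {
    y0 <- (ci - 1) * lane_h
    graphics::segments(0, y0, ext[ci], y0, col = "grey60")
    rr <- regions[regions$chrom == chroms[ci] & !is.na(regions$lod), ,
                  drop = FALSE]
    for (j in seq_len(nrow(rr))) {
      mid <- (rr$start_bp[j] + rr$end_bp[j]) / 2
      graphics::segments(mid, y0, mid, y0 + rr$lod[j], lwd = 2,
                         col = if (rr$is_max[j]) "firebrick" else "grey30")
      if (rr$is_max[j])
        graphics::points(mid, y0 + rr$lod[j], pch = 17, col = "firebrick")
      else graphics::points(mid, y0 + rr$lod[j], pch = 1)
    }
  }
  invisible(path)
}
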
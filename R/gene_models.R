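#' Load gene models from an annotation file
#'
#' Reads gene annotations in refFlat, BED12 or GTF format into a gene table
#' with one row per transcript. All coordinates are normalized to 0-based
#' half-open intervals. The transcription start site (TSS) is the `start`
#' coordinate on the + strand and the `end` coordinate on the - strand; the
#' transcription end site (TES) is the opposite terminus.
#'
#' @param path Path to the annotation file.
#' @param format One of `"refFlat"`, `"BED12"`, `"GTF"`.
#' @return A `data.frame` with columns `symbol`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `tes`, `length`.
#' @details refFlat columns are geneName, name, chrom, strand, txStart,
#'   txEnd, ... (txStart/txEnd already 0-based half-open). BED12 uses the
#'   `name` field as both symbol and transcript id. GTF is read through
#'   [rtracklayer::import()]; `transcript` features are used, with
#'   `gene_name` (falling back to `gene_id`) as the symbol, and 1-based
#'   closed coordinates converted to 0-based half-open.
#'   Records with a strand other than `+`/`-` are dropped with a warning.
#' @export
load_gene_models <- function(path, format = c("refFlat", "BED12", "GTF")) {
  format <- match.arg(format)
  genes <- switch(format,
    refFlat = read_refflat(path),
    BED12   = read_bed12(path),
    GTF     = read_gtf_transcripts(path)
  )
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    warning(sum(bad), " record(s) with unknown strand symbol rejected")
    genes <- genes[!bad, , drop = FALSE]
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes$length <- genes$end - genes$start
  stopifnot(all(genes$start < genes$end))
  rownames(genes) <- NULL
  genes[, c("symbol", "transcript_id", "chrom", "strand",
            "start", "end", "tss", "tes", "length")]
}

read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 6)) {
    stop("refFlat parse error at line ", which(n < 6)[1],
         ": expected >= 6 tab-separated fields")
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(f(5)))
  end <- suppressWarnings(as.integer(f(6)))
  if (anyNA(start) || anyNA(end)) {
    stop("refFlat parse error at line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric txStart/txEnd")
  }
  data.frame(symbol = f(1), transcript_id = f(2), chrom = f(3),
             strand = f(4), start = start, end = end,
             stringsAsFactors = FALSE)
}

read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 6)) {
    stop("BED parse error at line ", which(n < 6)[1],
         ": expected >= 6 tab-separated fields")
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  start <- suppressWarnings(as.integer(f(2)))
  end <- suppressWarnings(as.integer(f(3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED parse error at line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric chromStart/chromEnd")
  }
  data.frame(symbol = f(4), transcript_id = f(4), chrom = f(1),
             strand = f(6), start = start, end = end,
             stringsAsFactors = FALSE)
}

read_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0) stop("GTF contains no 'transcript' features")
  sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  sym <- ifelse(is.na(sym) | sym == "", gr$gene_id, sym)
  txid <- if (!is.null(gr$transcript_id)) gr$transcript_id else sym
  data.frame(symbol = sym, transcript_id = txid,
             chrom = as.character(GenomeInfoDb::seqnames(gr)),
             strand = as.character(BiocGenerics::strand(gr)),
             # GTF is 1-based closed; convert to 0-based half-open
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Deduplicate gene models to one record per symbol
#'
#' For gene symbols with multiple transcript records the record with the
#' longest genomic span (`end - start`) is retained. Length ties are broken
#' by the lexicographically smallest transcript id so reruns are
#' deterministic.
#'
#' @param genes Gene table from [load_gene_models()].
#' @return The gene table restricted to one row per symbol.
#' @export
dedup_by_symbol <- function(genes) {
  ord <- order(genes$symbol, -genes$length, genes$transcript_id)
  genes <- genes[ord, , drop = FALSE]
  genes <- genes[!duplicated(genes$symbol), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Derive promoter and gene-body regions
#'
#' The promoter spans `flank` bp on either side of the TSS (4 kb total at
#' the default); the gene body runs from `flank` bp downstream of the TSS to
#' the TES. Genes whose genomic length is at most `flank` have no gene body
#' (`body_empty` is set) and are excluded from gene-body summaries
#' downstream. Promoters are clipped at position 0 when the TSS lies within
#' `flank` bp of the contig start.
#'
#' @param genes Deduplicated gene table.
#' @param flank Promoter half-width in bp (default 2000).
#' @return A `data.frame` with one row per gene: `symbol`, `chrom`,
#'   `strand`, `tss`, `tes`, `length`, `promoter_start`, `promoter_end`,
#'   `body_start`, `body_end` (NA when empty), `body_empty`. All intervals
#'   0-based half-open.
#' @export
derive_regions <- function(genes, flank = 2000L) {
  stopifnot(flank > 0)
  flank <- as.integer(flank)
  plus <- genes$strand == "+"
  promoter_start <- pmax(0L, genes$tss - flank)
  promoter_end <- genes$tss + flank
  body_empty <- genes$length <= flank
  body_start <- ifelse(plus, genes$tss + flank, genes$start)
  body_end <- ifelse(plus, genes$end, genes$tss - flank)
  body_start[body_empty] <- NA_integer_
  body_end[body_empty] <- NA_integer_
  data.frame(symbol = genes$symbol, chrom = genes$chrom,
             strand = genes$strand, tss = genes$tss, tes = genes$tes,
             length = genes$length,
             promoter_start = promoter_start, promoter_end = promoter_end,
             body_start = body_start, body_end = body_end,
             body_empty = body_empty,
             stringsAsFactors = FALSE)
}

# put two GRanges on the union of their seqlevels so overlap ops are quiet
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a, b)
}

# GRanges view of one region type; 0-based half-open -> 1-based closed
regions_gr <- function(regions, which = c("promoter", "gene_body")) {
  which <- match.arg(which)
  if (which == "promoter") {
    keep <- rep(TRUE, nrow(regions))
    s <- regions$promoter_start; e <- regions$promoter_end
  } else {
    keep <- !regions$body_empty
    s <- regions$body_start; e <- regions$body_end
  }
  gr <- GenomicRanges::GRanges(
    regions$chrom[keep],
    IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
  )
  names(gr) <- regions$symbol[keep]
  gr
}

#' Flag promoters overlapping CpG islands
#'
#' @param regions Region table from [derive_regions()].
#' @param cgis `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), e.g. read from a 3-column BED.
#' @return Named logical vector (by symbol): TRUE iff the promoter overlaps
#'   at least one CpG island by >= 1 bp.
#' @export
promoter_cgi_flag <- function(regions, cgis) {
  flags <- stats::setNames(rep(FALSE, nrow(regions)), regions$symbol)
  if (is.null(cgis) || nrow(cgis) == 0) return(flags)
  prom <- regions_gr(regions, "promoter")
  cgi_gr <- GenomicRanges::GRanges(
    cgis$chrom, IRanges::IRanges(start = cgis$start + 1L, end = cgis$end))
  h <- harmonize_seqlevels(prom, cgi_gr)
  hit <- IRanges::overlapsAny(h[[1]], h[[2]])
  flags[names(prom)] <- hit
  flags
}

#' Read a 3-column BED file of intervals
#'
#' @param path BED path (chrom, start, end; 0-based half-open).
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  data.frame(chrom = as.character(x[[1]]), start = as.integer(x[[2]]),
             end = as.integer(x[[3]]), stringsAsFactors = FALSE)
}

#' Write regions as BED
#'
#' Writes promoter and gene-body intervals of each gene as BED6 lines with
#' the name field `<symbol>|promoter` / `<symbol>|gene_body`.
#'
#' @param regions Region table from [derive_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  prom <- data.frame(regions$chrom, regions$promoter_start,
                     regions$promoter_end,
                     paste0(regions$symbol, "|promoter"), 0L,
                     regions$strand)
  body <- regions[!regions$body_empty, , drop = FALSE]
  gb <- data.frame(body$chrom, body$body_start, body$body_end,
                   paste0(body$symbol, "|gene_body"), 0L, body$strand)
  names(gb) <- names(prom)
  utils::write.table(rbind(prom, gb), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}
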
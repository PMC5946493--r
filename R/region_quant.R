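#' Construct a fragment set
#'
#' A fragment set bundles aligned fragment intervals with the library size
#' used for per-million normalization. `library_size` defaults to the
#' number of fragments but can be larger when fragments elsewhere in the
#' genome were filtered out upstream.
#'
#' @param fragments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param library_size Total mapped fragments in the library.
#' @param read_mode `"paired"` or `"single_extended"`.
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, library_size = nrow(fragments),
                         read_mode = c("paired", "single_extended")) {
  read_mode <- match.arg(read_mode)
  stopifnot(all(c("chrom", "start", "end") %in% names(fragments)),
            all(fragments$start < fragments$end),
            library_size >= nrow(fragments))
  structure(list(fragments = fragments[, c("chrom", "start", "end")],
                 library_size = library_size, read_mode = read_mode),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", nrow(x$fragments), "fragments,",
      "library size", x$library_size, ", mode", x$read_mode, "\n")
  invisible(x)
}

#' Load aligned fragments from BAM or BED
#'
#' In `paired` mode each properly paired template contributes one fragment
#' spanning the template (leftmost mate start to mate start + insert size).
#' In `single_extended` mode each single-end read is extended from its 5'
#' alignment start to a fixed `extend_to` bp fragment in the read's strand
#' direction, mimicking pretend paired-end fragments of 250 bp. Unmapped,
#' secondary, supplementary and duplicate-flagged records are skipped, as
#' are reads below `min_mapq`; skipped counts are reported in the
#' `filtered` attribute.
#'
#' BED input (3 or 6 columns) is taken as already-assembled fragments in
#' `paired` mode, or as 5' read starts to extend when
#' `read_mode = "single_extended"` (column 6 strand required).
#'
#' @param path BAM or BED path.
#' @param read_mode `"paired"` or `"single_extended"`.
#' @param format `"bam"` or `"bed"`; guessed from the extension by default.
#' @param extend_to Pretend fragment length for single-end reads
#'   (default 250 bp).
#' @param min_mapq Minimum mapping quality (BAM only; default 0).
#' @return A [fragment_set()].
#' @export
load_fragments <- function(path, read_mode = c("paired", "single_extended"),
                           format = NULL, extend_to = 250L, min_mapq = 0L) {
  read_mode <- match.arg(read_mode)
  if (is.null(format)) {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  }
  if (format == "bam") {
    load_fragments_bam(path, read_mode, extend_to, min_mapq)
  } else {
    load_fragments_bed(path, read_mode, extend_to)
  }
}

load_fragments_bed <- function(path, read_mode, extend_to) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  chrom <- as.character(x[[1]])
  start <- as.integer(x[[2]])
  end <- as.integer(x[[3]])
  if (read_mode == "single_extended") {
    if (ncol(x) < 6) stop("single_extended BED input requires a strand column")
    strand <- as.character(x[[6]])
    frag <- extend_read(start, end, strand, extend_to)
    fragment_set(data.frame(chrom = chrom, start = frag$start,
                            end = frag$end, stringsAsFactors = FALSE),
                 read_mode = "single_extended")
  } else {
    fragment_set(data.frame(chrom = chrom, start = start, end = end,
                            stringsAsFactors = FALSE), read_mode = "paired")
  }
}

# 5' anchored fixed-length extension; clipped at contig start
extend_read <- function(start, end, strand, extend_to) {
  fs <- ifelse(strand == "+", start, pmax(0L, end - extend_to))
  fe <- ifelse(strand == "+", start + extend_to, end)
  list(start = as.integer(fs), end = as.integer(fe))
}

load_fragments_bam <- function(path, read_mode, extend_to, min_mapq) {
  flag0 <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  total <- Rsamtools::countBam(path)$records
  if (read_mode == "paired") {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isProperPair = TRUE)
    p <- Rsamtools::ScanBamParam(flag = flag,
                                 what = c("rname", "pos", "isize", "mapq"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    # the leftmost mate of each template carries the positive insert size,
    # so keeping isize > 0 emits one fragment per properly paired template
    keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize > 0 &
      (is.na(b$mapq) | b$mapq >= min_mapq)
    frags <- data.frame(chrom = as.character(b$rname[keep]),
                        start = b$pos[keep] - 1L,
                        end = b$pos[keep] - 1L + b$isize[keep],
                        stringsAsFactors = FALSE)
    fs <- fragment_set(frags, library_size = nrow(frags),
                       read_mode = "paired")
  } else {
    p <- Rsamtools::ScanBamParam(flag = flag0,
                                 what = c("rname", "pos", "qwidth",
                                          "strand", "mapq"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq >= min_mapq)
    start0 <- b$pos[keep] - 1L
    end0 <- start0 + b$qwidth[keep]
    frag <- extend_read(start0, end0, as.character(b$strand[keep]), extend_to)
    frags <- data.frame(chrom = as.character(b$rname[keep]),
                        start = frag$start, end = frag$end,
                        stringsAsFactors = FALSE)
    fs <- fragment_set(frags, library_size = nrow(frags),
                       read_mode = "single_extended")
  }
  attr(fs, "filtered") <- total - nrow(fs$fragments)
  fs
}

fragments_gr <- function(frags) {
  GenomicRanges::GRanges(
    frags$fragments$chrom,
    IRanges::IRanges(start = frags$fragments$start + 1L,
                     end = frags$fragments$end))
}

#' Region FPKM / signal-per-length quantification
#'
#' Counts fragments overlapping each promoter and gene-body region (a
#' fragment overlapping a region by >= 1 bp counts once for that region)
#' and converts counts to fragments per kilobase of region per million
#' mapped fragments. The same quantity is called "signal per length" when
#' the fragment set is a ChIP library; there is a single implementation.
#'
#' @param frags A [fragment_set()].
#' @param regions Region table from [derive_regions()].
#' @return Long `data.frame`: `symbol`, `region`, `region_length`, `count`,
#'   `fpkm`. Empty-flagged gene bodies are reported with `NA` count/fpkm.
#' @export
region_fpkm <- function(frags, regions) {
  stopifnot(frags$library_size > 0)
  fgr <- fragments_gr(frags)
  lib_m <- frags$library_size / 1e6
  out <- list()
  for (reg in c("promoter", "gene_body")) {
    gr <- regions_gr(regions, reg)
    h <- harmonize_seqlevels(gr, fgr)
    cnt <- GenomicRanges::countOverlaps(h[[1]], h[[2]])
    len <- BiocGenerics::width(gr)
    out[[reg]] <- data.frame(
      symbol = names(gr), region = reg, region_length = len,
      count = as.numeric(cnt),
      fpkm = cnt / (len / 1000) / lib_m,
      stringsAsFactors = FALSE)
  }
  empty <- regions[regions$body_empty, , drop = FALSE]
  if (nrow(empty)) {
    out$missing <- data.frame(symbol = empty$symbol, region = "gene_body",
                              region_length = NA_real_, count = NA_real_,
                              fpkm = NA_real_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble per-sample quantifications into a genes-by-samples matrix
#'
#' @param quants Named list (by sample) of [region_fpkm()] outputs.
#' @param region `"gene_body"` or `"promoter"`.
#' @param value Column to spread (default `"fpkm"`).
#' @return Numeric matrix, rows = gene symbols, columns = samples.
#' @export
quant_matrix <- function(quants, region = "gene_body", value = "fpkm") {
  stopifnot(length(quants) >= 1, !is.null(names(quants)))
  sub <- lapply(quants, function(q) q[q$region == region, , drop = FALSE])
  syms <- sort(unique(unlist(lapply(sub, `[[`, "symbol"))))
  m <- sapply(sub, function(q) q[[value]][match(syms, q$symbol)])
  m <- matrix(m, nrow = length(syms),
              dimnames = list(syms, names(quants)))
  m
}

#' Scale per-cluster mean signal across samples
#'
#' Computes the mean signal of each cluster's member genes in every sample,
#' then standardizes each cluster's profile across samples to mean 0 and
#' unit (sample) standard deviation, the way `scale()` standardizes
#' columns. Zero-variance profiles are returned as all-zero rows with a
#' warning so that flat clusters stay visible.
#'
#' @param mat Genes-by-samples matrix (e.g. from [quant_matrix()]).
#' @param clusters `data.frame` with columns `symbol` and `km_label` (or
#'   `group`), as produced by [kmeans_expression()] or truth labels.
#' @param label_col Column of `clusters` holding the grouping.
#' @return Clusters-by-samples matrix of scaled means.
#' @export
scale_cluster_means <- function(mat, clusters, label_col = "km_label") {
  stopifnot(ncol(mat) >= 2)
  idx <- match(clusters$symbol, rownames(mat))
  ok <- !is.na(idx)
  lab <- as.character(clusters[[label_col]][ok])
  sub <- mat[idx[ok], , drop = FALSE]
  means <- apply(sub, 2, function(col)
    tapply(col, lab, mean, na.rm = TRUE))
  means <- matrix(means, nrow = length(unique(lab)),
                  dimnames = list(sort(unique(lab)), colnames(mat)))
  scale_rows(means)
}

# row-wise center/scale to unit sample SD; constant rows -> 0 with warning
scale_rows <- function(m) {
  ctr <- m - rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning(sum(zero), " zero-variance row(s) scaled to all-zero")
    sds[zero] <- 1
  }
  out <- ctr / sds
  out[zero, ] <- 0
  out
}

#' Write a genes-by-samples quantification matrix as TSV
#'
#' @param mat Matrix from [quant_matrix()].
#' @param path Output path.
#' @export
write_quant_tsv <- function(mat, path) {
  df <- data.frame(symbol = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
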
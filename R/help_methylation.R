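#' Read a per-sample HELP-tagging site table
#'
#' Each sample's HELP-tagging output is a TSV with one row per HpaII site:
#' `chrom`, `pos` (0-based bp), `angle` (0-100, increasing with
#' hypomethylation), `confidence` (non-negative; lower is better; may be
#' missing).
#'
#' @param path TSV path with a header row.
#' @return `data.frame` with columns `chrom`, `pos`, `angle`, `confidence`.
#' @export
read_help_sites <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "angle", "confidence") %in% names(x)))
  x[, c("chrom", "pos", "angle", "confidence")]
}

#' Merge per-sample HELP tables into the analysed-site universe
#'
#' A HpaII site is retained iff, in every one of the samples, its angle is
#' present and its confidence is strictly below `conf_cutoff`. A missing
#' confidence counts as failing. The retained sites form the "analysed
#' HpaII" universe used for all between-sample comparisons.
#'
#' @param tables Named list of per-sample site tables
#'   (see [read_help_sites()]).
#' @param conf_cutoff Confidence cutoff; retention requires
#'   `confidence < conf_cutoff` (strict). Default 3.
#' @return `data.frame` with columns `chrom`, `pos` and one
#'   `angle.<sample>` column per sample, one row per retained site.
#' @export
merge_analysed_sites <- function(tables, conf_cutoff = 3) {
  stopifnot(length(tables) >= 1)
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  keys <- lapply(tables, function(t) paste(t$chrom, t$pos, sep = ":"))
  pass <- mapply(function(t, k) {
    ok <- !is.na(t$angle) & !is.na(t$confidence) & t$confidence < conf_cutoff
    k[ok]
  }, tables, keys, SIMPLIFY = FALSE)
  kept <- Reduce(intersect, pass)
  ref <- tables[[1]]
  ref_key <- keys[[1]]
  idx <- match(kept, ref_key)
  out <- data.frame(chrom = ref$chrom[idx], pos = ref$pos[idx],
                    stringsAsFactors = FALSE)
  for (s in names(tables)) {
    m <- match(kept, keys[[s]])
    out[[paste0("angle.", s)]] <- tables[[s]]$angle[m]
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("no sites retained after merging")
  out
}

#' Summarize methylation angles per gene region
#'
#' For each gene, region (promoter / gene body) and sample, takes the median
#' angle of the analysed HpaII sites falling inside the region, and reports
#' `100 - median angle` as the approximate percent DNA methylation. Site
#' membership uses the half-open region interval, so a site exactly on the
#' promoter/gene-body boundary belongs to the gene body. Regions with fewer
#' than `min_sites` sites are reported as missing; empty-flagged gene bodies
#' are not reported at all.
#'
#' @param sites Merged site table from [merge_analysed_sites()].
#' @param regions Region table from [derive_regions()].
#' @param min_sites Minimum sites per region for a defined summary
#'   (default 1).
#' @return Long `data.frame`: `symbol`, `region`, `sample`, `n_sites`,
#'   `median_angle`, `approx_methylation`.
#' @export
region_median_angle <- function(sites, regions, min_sites = 1L) {
  samples <- sub("^angle\\.", "", grep("^angle\\.", names(sites), value = TRUE))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L))
  out <- list()
  for (reg in c("promoter", "gene_body")) {
    gr <- regions_gr(regions, reg)
    h <- harmonize_seqlevels(gr, site_gr)
    hits <- GenomicRanges::findOverlaps(h[[1]], h[[2]])
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (s in samples) {
      ang <- sites[[paste0("angle.", s)]][sh]
      med <- tapply(ang, factor(qh, levels = seq_along(gr)), stats::median)
      n <- tabulate(qh, nbins = length(gr))
      med[n < min_sites] <- NA_real_
      out[[paste(reg, s)]] <- data.frame(
        symbol = names(gr), region = reg, sample = s, n_sites = n,
        median_angle = as.numeric(med),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$approx_methylation <- 100 - res$median_angle
  rownames(res) <- NULL
  res
}

#' Calibrate a HELP angle to a percent-methylation estimate
#'
#' Applies the bisulfite-validation regression `-1.0113 * angle + 108.33`
#' mapping HELP angles to percent methylation. The raw regression value is
#' returned alongside a copy clamped to the \[0, 100\] percentage range. This
#' estimate complements, and never replaces, the `100 - angle`
#' approximation reported by [region_median_angle()].
#'
#' @param angle Numeric vector of angles in \[0, 100\].
#' @param slope,intercept Regression coefficients.
#' @return `data.frame` with columns `angle`, `raw`, `clamped`.
#' @export
angle_calibration <- function(angle, slope = -1.0113, intercept = 108.33) {
  raw <- slope * angle + intercept
  data.frame(angle = angle, raw = raw,
             clamped = pmin(100, pmax(0, raw)))
}

#' Write a region methylation summary as TSV
#'
#' @param summary Output of [region_median_angle()].
#' @param path Output path.
#' @export
write_methylation_tsv <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
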
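#' Call gene-body accumulated genes from length-normalized signal
#'
#' A gene is "accumulated" for a factor when its gene-body signal per
#' length (FPKM-style, see [region_fpkm()]) strictly exceeds `threshold`.
#' The Pol II-high call uses the same rule at its own threshold
#' (conventionally 1.5 instead of 1). Genes with an empty gene body carry
#' no signal value and are excluded.
#'
#' @param quant [region_fpkm()] output for one factor/sample.
#' @param factor_id Factor name recorded in the output (e.g. "PolII").
#' @param sample Sample name recorded in the output.
#' @param threshold Accumulation threshold on signal/length (default 1.0).
#' @return `data.frame`: `symbol`, `factor_id`, `sample`,
#'   `signal_per_length`, `accumulated`.
#' @export
call_accumulated <- function(quant, factor_id = "factor", sample = "sample",
                             threshold = 1.0) {
  gb <- quant[quant$region == "gene_body" & !is.na(quant$fpkm), ,
              drop = FALSE]
  data.frame(symbol = gb$symbol, factor_id = factor_id, sample = sample,
             signal_per_length = gb$fpkm,
             accumulated = gb$fpkm > threshold,
             stringsAsFactors = FALSE)
}

#' Per-group count and fold enrichment of accumulated genes
#'
#' Fold enrichment of a group is the group's accumulated proportion over
#' the universe-wide accumulated proportion. Genes in `calls` without a
#' group label are ignored; the universe is the intersection of the call
#' table and the group table.
#'
#' @param calls [call_accumulated()] output.
#' @param groups `data.frame` with `symbol` and a grouping column.
#' @param label_col Grouping column name (default `"name"`).
#' @return `data.frame`: `group`, `n_genes`, `count`, `fold`.
#' @export
fold_enrichment <- function(calls, groups, label_col = "name") {
  m <- merge(calls, groups[, c("symbol", label_col)], by = "symbol")
  total_n <- nrow(m)
  total_acc <- sum(m$accumulated)
  if (total_acc == 0) warning("no accumulated genes; folds undefined")
  grp <- as.character(m[[label_col]])
  n_genes <- as.integer(table(grp))
  gnames <- names(table(grp))
  count <- as.integer(tapply(m$accumulated, grp, sum))
  fold <- if (total_acc == 0) rep(NA_real_, length(gnames)) else
    (count / n_genes) / (total_acc / total_n)
  data.frame(group = gnames, n_genes = n_genes, count = count, fold = fold,
             stringsAsFactors = FALSE)
}

#' Co-localization of two accumulation call sets
#'
#' @param calls_a,calls_b [call_accumulated()] outputs over the same gene
#'   universe.
#' @return List: `table` (2x2 counts: both, a_only, b_only, neither),
#'   `jaccard`, `n`.
#' @export
colocalization <- function(calls_a, calls_b) {
  common <- intersect(calls_a$symbol, calls_b$symbol)
  a <- calls_a$accumulated[match(common, calls_a$symbol)]
  b <- calls_b$accumulated[match(common, calls_b$symbol)]
  tab <- c(both = sum(a & b), a_only = sum(a & !b),
           b_only = sum(!a & b), neither = sum(!a & !b))
  denom <- tab["both"] + tab["a_only"] + tab["b_only"]
  jac <- if (denom == 0) NA_real_ else unname(tab["both"] / denom)
  list(table = tab, jaccard = jac, n = length(common))
}

#' Gene-body methylation of accumulated vs non-accumulated genes
#'
#' Summarizes the distribution of gene-body approximate methylation
#' (100 - median angle) separately for accumulated and non-accumulated
#' genes: median, quartiles and a kernel density grid.
#'
#' @param calls [call_accumulated()] output.
#' @param meth [region_median_angle()] output.
#' @param sample Methylation sample to summarize.
#' @return `data.frame` with one row per stratum (`accumulated`,
#'   `not_accumulated`): `n`, `q25`, `median`, `q75`; the density grids are
#'   attached as the `densities` attribute (list of `density` objects, or
#'   NULL for strata with < 2 genes).
#' @export
methylation_of_accumulated <- function(calls, meth, sample) {
  gb <- meth[meth$region == "gene_body" & meth$sample == sample &
               !is.na(meth$approx_methylation), , drop = FALSE]
  m <- merge(calls[, c("symbol", "accumulated")],
             gb[, c("symbol", "approx_methylation")], by = "symbol")
  strata <- list(accumulated = m$approx_methylation[m$accumulated],
                 not_accumulated = m$approx_methylation[!m$accumulated])
  strata <- strata[vapply(strata, length, integer(1)) > 0]
  if (length(strata) == 0) {
    out <- data.frame(stratum = character(0), n = integer(0),
                      q25 = numeric(0), median = numeric(0),
                      q75 = numeric(0))
    attr(out, "densities") <- list()
    return(out)
  }
  out <- data.frame(
    stratum = names(strata),
    n = vapply(strata, length, integer(1)),
    q25 = vapply(strata, function(v) unname(stats::quantile(v, 0.25)),
                 numeric(1)),
    median = vapply(strata, stats::median, numeric(1)),
    q75 = vapply(strata, function(v) unname(stats::quantile(v, 0.75)),
                 numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "densities") <- lapply(strata, function(v)
    if (length(v) >= 2 && stats::sd(v) > 0) stats::density(v) else NULL)
  out
}
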
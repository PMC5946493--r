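#' Pairwise Kolmogorov-Smirnov tests on gene lengths between clusters
#'
#' Runs a two-sample two-sided KS test on log10 gene length for every
#' unordered pair of groups. The D statistic is invariant under the
#' monotone log transform; p-values use the exact two-sample distribution
#' for small groups (both sizes <= `exact_max`) and the asymptotic
#' approximation otherwise. Groups with fewer than 2 genes are skipped with
#' a warning.
#'
#' @param genes Gene table with `symbol` and `length`.
#' @param groups `data.frame` with `symbol` and a grouping column.
#' @param label_col Grouping column (default `"name"`).
#' @param exact_max Largest group size for exact p-values (default 10).
#' @return `data.frame`: `group_a`, `group_b`, `n_a`, `n_b`, `D`,
#'   `p_value`.
#' @export
length_ks_matrix <- function(genes, groups, label_col = "name",
                             exact_max = 10L) {
  m <- merge(genes[, c("symbol", "length")],
             groups[, c("symbol", label_col)], by = "symbol")
  lab <- as.character(m[[label_col]])
  lens <- split(log10(m$length), lab)
  small <- names(lens)[vapply(lens, length, integer(1)) < 2]
  if (length(small)) {
    warning("group(s) with < 2 genes skipped: ",
            paste(small, collapse = ", "))
    lens <- lens[!names(lens) %in% small]
  }
  gn <- names(lens)
  if (length(gn) < 2) return(data.frame())
  pairs <- utils::combn(gn, 2)
  out <- lapply(seq_len(ncol(pairs)), function(ci) {
    p <- pairs[, ci]
    x <- lens[[p[1]]]; y <- lens[[p[2]]]
    exact <- length(x) <= exact_max && length(y) <= exact_max
    kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
    data.frame(group_a = p[1], group_b = p[2],
               n_a = length(x), n_b = length(y),
               D = unname(kt$statistic), p_value = kt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-by-gene correlations between modalities
#'
#' Computes pairwise correlation coefficients between per-gene values of
#' different modalities (expression, gene-body methylation, 5hmC FPKM,
#' ChIP signal per length, ...) over the intersected gene universe, with
#' pairwise deletion of missing values. Cells with fewer than `min_genes`
#' shared genes are reported as NA.
#'
#' @param tables Named list of named numeric vectors (values by gene
#'   symbol), one per modality.
#' @param method `"spearman"` (default, robust to the heavy-tailed FPKM
#'   scale) or `"pearson"`.
#' @param min_genes Minimum shared genes per pair (default 10).
#' @return Symmetric correlation matrix with unit diagonal; the pairwise
#'   gene counts are attached as attribute `n`.
#' @export
modality_correlations <- function(tables, method = c("spearman", "pearson"),
                                  min_genes = 10L) {
  method <- match.arg(method)
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  k <- length(tables)
  mods <- names(tables)
  r <- matrix(NA_real_, k, k, dimnames = list(mods, mods))
  nmat <- matrix(0L, k, k, dimnames = list(mods, mods))
  diag(r) <- 1
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      common <- intersect(names(tables[[i]]), names(tables[[j]]))
      x <- tables[[i]][common]; y <- tables[[j]][common]
      ok <- !is.na(x) & !is.na(y)
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) >= min_genes) {
        r[i, j] <- r[j, i] <- stats::cor(x[ok], y[ok], method = method)
      }
    }
  }
  diag(nmat) <- vapply(tables, function(v) sum(!is.na(v)), integer(1))
  attr(r, "n") <- nmat
  attr(r, "method") <- method
  r
}

#' Mark densities within Pol II-high genes, per expression group
#'
#' Restricts the gene universe to Pol II-high genes (gene-body Pol II
#' signal per length above its threshold, see [call_accumulated()]) and
#' summarizes the distribution of each mark's gene-body level within each
#' expression cluster: gene count, median, quartiles and a kernel density
#' grid per (mark, group).
#'
#' @param polii_calls [call_accumulated()] output for Pol II at the
#'   Pol II-high threshold.
#' @param marks Named list of named numeric vectors (gene-body level by
#'   symbol), one per mark (e.g. H3K36me3, H3K79me2).
#' @param groups `data.frame` with `symbol` and a grouping column.
#' @param label_col Grouping column (default `"name"`).
#' @return `data.frame`: `mark`, `group`, `n`, `q25`, `median`, `q75`,
#'   `mode` (density-peak location, NA for degenerate strata); densities
#'   attached as attribute `densities` (named `mark|group`).
#' @export
density_in_polii_high <- function(polii_calls, marks, groups,
                                  label_col = "name") {
  high <- polii_calls$symbol[polii_calls$accumulated]
  if (length(high) == 0) {
    out <- data.frame(mark = character(0), group = character(0),
                      n = integer(0), q25 = numeric(0), median = numeric(0),
                      q75 = numeric(0), mode = numeric(0))
    attr(out, "densities") <- list()
    return(out)
  }
  grp <- groups[groups$symbol %in% high, c("symbol", label_col)]
  rows <- list()
  dens <- list()
  for (mk in names(marks)) {
    v <- marks[[mk]]
    for (g in sort(unique(as.character(grp[[label_col]])))) {
      syms <- grp$symbol[grp[[label_col]] == g]
      x <- v[names(v) %in% syms]
      x <- x[!is.na(x)]
      if (length(x) == 0) next
      d <- if (length(x) >= 2 && stats::sd(x) > 0) stats::density(x) else NULL
      dens[[paste(mk, g, sep = "|")]] <- d
      rows[[paste(mk, g)]] <- data.frame(
        mark = mk, group = g, n = length(x),
        q25 = unname(stats::quantile(x, 0.25)),
        median = stats::median(x),
        q75 = unname(stats::quantile(x, 0.75)),
        mode = if (is.null(d)) unique(x)[1] else d$x[which.max(d$y)],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "densities") <- dens
  out
}
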
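#' Gene-body-centred metaplot
#'
#' Builds average coverage profiles over a fixed gene anatomy: a 5' flank
#' binned at fixed width, the gene body rescaled to `body_bins` equal bins,
#' and a 3' flank. Per gene, base-wise fragment coverage is averaged within
#' each bin; minus-strand genes are orientation-flipped so profiles always
#' read 5' to 3' left to right. Per-group profiles are across-gene
#' means (or medians), normalized to reads per million mapped fragments
#' (RPM). Genes shorter than `body_bins` bp are excluded with a message.
#'
#' @param frags A [fragment_set()].
#' @param genes Deduplicated gene table from [load_gene_models()].
#' @param groups Optional `data.frame` with `symbol` and a grouping column;
#'   when NULL all genes form one group `"all"`.
#' @param label_col Grouping column in `groups` (default `"name"`).
#' @param flank Flank width in bp (default 2000).
#' @param body_bins Bins across the gene body (default 100).
#' @param flank_bins Bins per flank (default 20).
#' @param summary `"mean"` or `"median"` across genes.
#' @return `data.frame`: `group`, `segment` (`flank5`/`body`/`flank3`),
#'   `bin` (1-based within segment), `position` (global bin index),
#'   `mean_rpm`, `n_genes`.
#' @export
gene_metaplot <- function(frags, genes, groups = NULL, label_col = "name",
                          flank = 2000L, body_bins = 100L, flank_bins = 20L,
                          summary = c("mean", "median")) {
  summary <- match.arg(summary)
  ok <- genes$length > body_bins
  if (any(!ok)) {
    message(sum(!ok), " gene(s) shorter than ", body_bins, " bp excluded")
  }
  genes <- genes[ok, , drop = FALSE]
  if (is.null(groups)) {
    groups <- data.frame(symbol = genes$symbol, name = "all",
                         stringsAsFactors = FALSE)
    label_col <- "name"
  }
  cov <- GenomicRanges::coverage(fragments_gr(frags))
  nb <- 2L * flank_bins + body_bins
  prof <- matrix(NA_real_, nrow = nrow(genes), ncol = nb,
                 dimnames = list(genes$symbol, NULL))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cv <- if (g$chrom %in% names(cov)) cov[[g$chrom]] else
      S4Vectors::Rle(0L, 1L)
    base <- decode_coverage(cv, g$start - flank, g$end + flank)
    off <- flank
    row <- c(bin_means(base, 0, off, flank_bins),
             bin_means(base, off, off + g$length, body_bins),
             bin_means(base, off + g$length, off + g$length + flank,
                       flank_bins))
    if (g$strand == "-") row <- rev(row)
    prof[i, ] <- row
  }
  prof <- prof * 1e6 / frags$library_size
  lab <- groups[[label_col]][match(rownames(prof), groups$symbol)]
  keep <- !is.na(lab)
  prof <- prof[keep, , drop = FALSE]
  lab <- as.character(lab[keep])
  agg <- if (summary == "mean") function(m) colMeans(m) else
    function(m) apply(m, 2, stats::median)
  out <- lapply(sort(unique(lab)), function(l) {
    m <- prof[lab == l, , drop = FALSE]
    data.frame(group = l,
               segment = rep(c("flank5", "body", "flank3"),
                             c(flank_bins, body_bins, flank_bins)),
               bin = c(seq_len(flank_bins), seq_len(body_bins),
                       seq_len(flank_bins)),
               position = seq_len(nb),
               mean_rpm = agg(m), n_genes = nrow(m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# per-base coverage over [from, to) (0-based), zero-padded beyond the contig
decode_coverage <- function(cv, from, to) {
  n <- length(cv)
  s1 <- max(from, 0); e1 <- min(to, n)
  inner <- if (e1 > s1)
    as.numeric(S4Vectors::window(cv, start = s1 + 1, end = e1)) else numeric(0)
  pad_left <- max(0, s1 - from)
  pad_right <- (to - from) - pad_left - length(inner)
  c(numeric(pad_left), inner, numeric(pad_right))
}

# mean coverage in nbins equal partitions of [from, to) of a base vector
# (0-based offsets into `base`)
bin_means <- function(base, from, to, nbins) {
  edges <- from + round(seq(0, to - from, length.out = nbins + 1))
  cs <- c(0, cumsum(base))
  tot <- cs[edges[-1] + 1] - cs[edges[-(nbins + 1)] + 1]
  w <- diff(edges)
  ifelse(w > 0, tot / w, 0)
}

#' Plot metaplot profiles
#'
#' Draws per-group RPM profiles as lines over the flank/body/flank axis.
#'
#' @param profile Output of [gene_metaplot()].
#' @param main Plot title.
#' @export
plot_metaplot <- function(profile, main = "Gene-body-centred metaplot") {
  groups <- sort(unique(profile$group))
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  xmax <- max(profile$position)
  ymax <- max(profile$mean_rpm)
  graphics::plot(NULL, xlim = c(1, xmax), ylim = c(0, ymax * 1.05),
                 xlab = "5' flank | scaled gene body | 3' flank",
                 ylab = "RPM", main = main, xaxt = "n")
  b1 <- max(profile$position[profile$segment == "flank5"])
  b2 <- max(profile$position[profile$segment == "body"])
  graphics::abline(v = c(b1 + 0.5, b2 + 0.5), lty = 3, col = "grey50")
  graphics::axis(1, at = c(1, b1, b2, xmax),
                 labels = c(paste0("-", "flank"), "TSS+2k", "TES", "+flank"))
  for (i in seq_along(groups)) {
    p <- profile[profile$group == groups[i], ]
    graphics::lines(p$position, p$mean_rpm, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(NULL)
}
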
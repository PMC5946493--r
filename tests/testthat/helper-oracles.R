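# independent brute-force reference implementations used to cross-check
# the package's indexed/vectorized code paths

# per-sample region medians by a full scan over all gene-site pairs
brute_region_medians <- function(sites, regions, sample) {
  col <- paste0("angle.", sample)
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (reg in c("promoter", "gene_body")) {
      if (reg == "gene_body" && r$body_empty) next
      lo <- if (reg == "promoter") r$promoter_start else r$body_start
      hi <- if (reg == "promoter") r$promoter_end else r$body_end
      ang <- sites[[col]][sites$chrom == r$chrom &
                            sites$pos >= lo & sites$pos < hi]
      rows[[paste(r$symbol, reg)]] <- data.frame(
        symbol = r$symbol, region = reg,
        median_angle = if (length(ang)) stats::median(ang) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# quadratic any-overlap fragment counting
brute_region_counts <- function(frags, regions) {
  f <- frags$fragments
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (reg in c("promoter", "gene_body")) {
      if (reg == "gene_body" && r$body_empty) next
      lo <- if (reg == "promoter") r$promoter_start else r$body_start
      hi <- if (reg == "promoter") r$promoter_end else r$body_end
      cnt <- sum(f$chrom == r$chrom & f$start < hi & f$end > lo)
      rows[[paste(r$symbol, reg)]] <- data.frame(
        symbol = r$symbol, region = reg, count = cnt,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# fold enrichment recomputed directly from the raw call table
brute_fold <- function(calls, groups, label_col = "group") {
  m <- merge(calls, groups[, c("symbol", label_col)], by = "symbol")
  sapply(sort(unique(m[[label_col]])), function(g) {
    sub <- m[m[[label_col]] == g, ]
    (sum(sub$accumulated) / nrow(sub)) /
      (sum(m$accumulated) / nrow(m))
  })
}

# exhaustive two-sample KS: D and exact p by enumerating label assignments
brute_ks <- function(x, y) {
  d_of <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(vapply(v, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
  }
  D <- d_of(x, y)
  pool <- c(x, y)
  idx <- utils::combn(length(pool), length(x))
  ds <- apply(idx, 2, function(ii) d_of(pool[ii], pool[-ii]))
  list(D = D, p_value = mean(ds >= D - 1e-12))
}
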
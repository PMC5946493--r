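# shared fixtures: a small deterministic synthetic dataset for fast tests
small_config <- function(seed = 7, ...) {
  synthetic_config(seed = seed, genes_per_specific = 8L,
                   genes_per_const = 12L, background_frags = 300L, ...)
}

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(small_config())
    cache
  }
})

# the default-scale study design (600 genes), generated once per run
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_dataset(synthetic_config(seed = 1))
    cache
  }
})

make_gene <- function(symbol = "g1", chrom = "chr1", strand = "+",
                      start = 10000L, end = 50000L,
                      transcript_id = paste0("tx_", symbol)) {
  g <- data.frame(symbol = symbol, transcript_id = transcript_id,
                  chrom = chrom, strand = strand,
                  start = as.integer(start), end = as.integer(end),
                  stringsAsFactors = FALSE)
  g$tss <- ifelse(g$strand == "+", g$start, g$end)
  g$tes <- ifelse(g$strand == "+", g$end, g$start)
  g$length <- g$end - g$start
  g
}

# named gene-body value vector from a region_fpkm table
gb_vector <- function(quant) {
  gb <- quant[quant$region == "gene_body", ]
  stats::setNames(gb$fpkm, gb$symbol)
}
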
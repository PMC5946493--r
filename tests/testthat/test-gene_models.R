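test_that("annotation readers map coordinates, strand and symbols", {
  rf <- tempfile(fileext = ".refflat")
  writeLines(c("GeneA\tNM_001\tchr1\t+\t10000\t50000\t10000\t50000\t1\t10000\t50000"),
             rf)
  g <- load_gene_models(rf, "refFlat")
  expect_equal(g$tss, 10000)
  expect_equal(g$tes, 50000)
  expect_equal(g$length, 40000)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr2\t10000\t50000\tGeneB\t0\t-", bed)
  g <- load_gene_models(bed, "BED12")
  expect_equal(g$tss, 50000)
  expect_equal(g$tes, 10000)

  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t10001\t50000\t.\t+\t.\t",
           "gene_id \"G1\"; gene_name \"GeneC\"; transcript_id \"tx1\";"),
    paste0("chr1\tsrc\ttranscript\t10001\t60000\t.\t+\t.\t",
           "gene_id \"G1\"; gene_name \"GeneC\"; transcript_id \"tx2\";")), gtf)
  g <- load_gene_models(gtf, "GTF")
  expect_equal(nrow(g), 2)
  expect_equal(unique(g$symbol), "GeneC")
  expect_equal(g$start, c(10000, 10000))  # 1-based GTF converted

  writeLines("chr1\tonly-two-fields", rf)
  expect_error(load_gene_models(rf, "refFlat"), "line 1")

  writeLines("chr2\t10000\t50000\tGeneB\t0\t.", bed)
  expect_warning(g <- load_gene_models(bed, "BED12"), "strand")
  expect_equal(nrow(g), 0)
})

test_that("dedup keeps the longest record per symbol, deterministic ties", {
  genes <- rbind(make_gene("A", start = 0, end = 40000, transcript_id = "t2"),
                 make_gene("A", start = 100000, end = 160000,
                           transcript_id = "t1"),
                 make_gene("B", start = 0, end = 5000, transcript_id = "t3"))
  d <- dedup_by_symbol(genes)
  expect_equal(nrow(d), 2)
  expect_equal(d$length[d$symbol == "A"], 60000)
  expect_equal(d$symbol[order(d$symbol)], c("A", "B"))
  # single-record symbol unchanged
  expect_equal(d[d$symbol == "B", c("start", "end")],
               genes[3, c("start", "end")], ignore_attr = TRUE)
  # equal lengths: smallest transcript_id wins
  tie <- rbind(make_gene("C", start = 0, end = 1000, transcript_id = "tB"),
               make_gene("C", start = 5000, end = 6000, transcript_id = "tA"))
  expect_equal(dedup_by_symbol(tie)$transcript_id, "tA")
  # idempotent, one symbol each
  expect_identical(dedup_by_symbol(d), d)
})

test_that("promoter and gene-body derivation, clipping and degenerate genes", {
  g <- make_gene("p", strand = "+", start = 10000, end = 50000)
  r <- derive_regions(g)
  expect_equal(c(r$promoter_start, r$promoter_end), c(8000, 12000))
  expect_equal(c(r$body_start, r$body_end), c(12000, 50000))

  gm <- make_gene("m", strand = "-", start = 10000, end = 50000)
  rm_ <- derive_regions(gm)
  expect_equal(c(rm_$promoter_start, rm_$promoter_end), c(48000, 52000))
  expect_equal(c(rm_$body_start, rm_$body_end), c(10000, 48000))

  short <- derive_regions(make_gene("s", start = 10000, end = 11500))
  expect_true(short$body_empty)
  expect_true(is.na(short$body_start))

  clipped <- derive_regions(make_gene("c", start = 500, end = 9000))
  expect_equal(clipped$promoter_start, 0)
  expect_equal(clipped$promoter_end, 2500)
})

test_that("regions tile the locus without gap or overlap and are strand-symmetric", {
  set.seed(42)
  for (i in 1:20) {
    start <- sample(5000:50000, 1)
    len <- sample(2500:80000, 1)
    strand <- sample(c("+", "-"), 1)
    g <- make_gene("x", strand = strand, start = start, end = start + len)
    r <- derive_regions(g)
    # tiling: promoter and body are adjacent and disjoint
    if (strand == "+") {
      expect_equal(r$body_start, r$promoter_end)
      expect_equal(sort(c(r$promoter_start, r$promoter_end,
                          r$body_start, r$body_end)),
                   c(g$tss - 2000, g$tss + 2000, g$tss + 2000, g$tes))
    } else {
      expect_equal(r$body_end, r$promoter_start)
    }
    # strand symmetry: reflect all coordinates, flip strand
    L <- 200000
    g2 <- make_gene("x", strand = if (strand == "+") "-" else "+",
                    start = L - g$end, end = L - g$start)
    r2 <- derive_regions(g2)
    expect_equal(c(L - r2$promoter_end, L - r2$promoter_start),
                 c(r$promoter_start, r$promoter_end))
    expect_equal(c(L - r2$body_end, L - r2$body_start),
                 c(r$body_start, r$body_end))
  }
})

test_that("promoter CGI overlap uses half-open intervals", {
  r <- derive_regions(make_gene("g1", start = 10000, end = 50000))
  expect_true(promoter_cgi_flag(r, data.frame(chrom = "chr1",
                                              start = 11990, end = 12500)))
  expect_false(promoter_cgi_flag(r, data.frame(chrom = "chr1",
                                               start = 12000, end = 12500)))
  expect_false(promoter_cgi_flag(r, data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0))))
})
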
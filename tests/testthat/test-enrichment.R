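make_quant <- function(symbols, fpkm, region = "gene_body") {
  data.frame(symbol = symbols, region = region, region_length = 10000,
             count = fpkm * 10, fpkm = fpkm, stringsAsFactors = FALSE)
}

test_that("accumulation calls use a strict threshold and skip empty bodies", {
  q <- rbind(make_quant(c("a", "b", "c"), c(1.2, 1.0, 0.4)),
             data.frame(symbol = "d", region = "gene_body",
                        region_length = NA, count = NA, fpkm = NA),
             make_quant("a", 9, region = "promoter"))
  calls <- call_accumulated(q, "PolII", "CM")
  expect_equal(calls$symbol, c("a", "b", "c"))
  expect_equal(calls$accumulated, c(TRUE, FALSE, FALSE))  # 1.0 is not > 1
  high <- call_accumulated(q, "PolII", "CM", threshold = 1.5)
  expect_equal(sum(high$accumulated), 0)
  # raising the threshold is monotone in every group
  thr <- seq(0, 2, by = 0.25)
  counts <- vapply(thr, function(t)
    sum(call_accumulated(q, "PolII", "CM", threshold = t)$accumulated),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fold enrichment matches the formula and the brute-force recount", {
  # group of 100 genes with 20 accumulated; universe 1000 with 50
  syms <- paste0("g", 1:1000)
  grp <- data.frame(symbol = syms,
                    group = rep(c("A", "rest"), c(100, 900)))
  acc <- c(rep(TRUE, 20), rep(FALSE, 80),       # 20/100 in A
           rep(TRUE, 30), rep(FALSE, 870))      # 30/900 elsewhere
  calls <- data.frame(symbol = syms, factor_id = "PolII", sample = "CM",
                      signal_per_length = ifelse(acc, 2, 0.1),
                      accumulated = acc)
  fe <- fold_enrichment(calls, grp, label_col = "group")
  expect_equal(fe$fold[fe$group == "A"], (20 / 100) / (50 / 1000))
  expect_equal(fe$count[fe$group == "A"], 20L)

  # group with the universe proportion -> fold 1
  grp2 <- data.frame(symbol = syms, group = rep(c("x", "y"), 500))
  calls2 <- calls
  calls2$accumulated <- rep(c(TRUE, TRUE, FALSE, FALSE), 250)
  fe2 <- fold_enrichment(calls2, grp2, label_col = "group")
  expect_equal(fe2$fold, c(1, 1))

  # 200-gene fixture vs exhaustive recomputation; group-size-weighted mean 1
  set.seed(11)
  grp3 <- data.frame(symbol = paste0("g", 1:200),
                     group = sample(letters[1:4], 200, replace = TRUE))
  calls3 <- data.frame(symbol = paste0("g", 1:200), factor_id = "p300",
                       sample = "CM",
                       signal_per_length = stats::rlnorm(200),
                       accumulated = stats::runif(200) < 0.3)
  fe3 <- fold_enrichment(calls3, grp3, label_col = "group")
  want <- brute_fold(calls3, grp3)
  expect_equal(fe3$fold, unname(want[fe3$group]), tolerance = 1e-12)
  expect_equal(sum(fe3$fold * fe3$n_genes) / sum(fe3$n_genes), 1)

  expect_warning(
    fe0 <- fold_enrichment(transform(calls3, accumulated = FALSE), grp3,
                           label_col = "group"),
    "no accumulated")
  expect_true(all(is.na(fe0$fold)))
})

test_that("co-localization table, Jaccard and the shuffled baseline", {
  a <- data.frame(symbol = paste0("g", 1:10),
                  accumulated = rep(c(TRUE, FALSE), 5))
  expect_equal(colocalization(a, a)$jaccard, 1)
  b <- a
  b$accumulated <- !a$accumulated
  expect_equal(colocalization(a, b)$jaccard, 0)
  co <- colocalization(a, b)
  expect_equal(sum(co$table), 10)

  # planted Pol II / p300 co-occurrence beats a label-shuffled control
  ds <- small_dataset()
  polii <- call_accumulated(region_fpkm(ds$fragments$chip$PolII, ds$regions),
                            "PolII", "CM_W8")
  p300 <- call_accumulated(region_fpkm(ds$fragments$chip$p300, ds$regions),
                           "p300", "CM_W8")
  observed <- colocalization(polii, p300)$jaccard
  set.seed(3)
  shuffled <- replicate(20, {
    perm <- p300
    perm$accumulated <- sample(perm$accumulated)
    colocalization(polii, perm)$jaccard
  })
  expect_gt(observed, max(shuffled))
})

test_that("methylation of accumulated genes summarizes planted hypomethylation", {
  # accumulated genes planted hypomethylated (low percent methylation)
  syms <- paste0("g", 1:40)
  acc <- rep(c(TRUE, FALSE), each = 20)
  calls <- data.frame(symbol = syms, factor_id = "PolII", sample = "CM",
                      signal_per_length = ifelse(acc, 3, 0.2),
                      accumulated = acc)
  meth <- data.frame(symbol = syms, region = "gene_body", sample = "CM",
                     n_sites = 5, median_angle = ifelse(acc, 80, 25),
                     approx_methylation = ifelse(acc, 20, 75) +
                       rep(seq(-2, 2, length.out = 20), 2))
  s <- methylation_of_accumulated(calls, meth, sample = "CM")
  expect_lt(s$median[s$stratum == "accumulated"],
            s$median[s$stratum == "not_accumulated"])
  # quartiles match direct quantile computation
  vals <- meth$approx_methylation[acc]
  expect_equal(s$q25[s$stratum == "accumulated"],
               unname(stats::quantile(vals, 0.25)))
  expect_equal(s$q75[s$stratum == "accumulated"],
               unname(stats::quantile(vals, 0.75)))
  # empty accumulated set -> no accumulated stratum
  s0 <- methylation_of_accumulated(transform(calls, accumulated = FALSE),
                                   meth, sample = "CM")
  expect_false("accumulated" %in% s0$stratum)
})
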
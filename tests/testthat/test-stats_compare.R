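test_that("length KS tests: boundary cases and exact-enumeration agreement", {
  # identical length multisets in two groups -> D = 0, p = 1
  genes <- rbind(make_gene(paste0("a", 1:3)), make_gene(paste0("b", 1:3)))
  genes$length <- rep(c(10000, 20000, 30000), 2)
  groups <- data.frame(symbol = genes$symbol, name = rep(c("A", "B"), each = 3))
  r <- length_ks_matrix(genes, groups)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)

  # disjoint supports -> D = 1
  genes$length <- c(1000, 2000, 3000, 40000, 50000, 60000)
  r <- length_ks_matrix(genes, groups)
  expect_equal(r$D, 1)

  # D and exact p agree with exhaustive enumeration for n, m <= 6
  set.seed(21)
  for (rep_i in 1:5) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    lens <- round(stats::rlnorm(n + m, log(20000), 0.6))
    g2 <- rbind(make_gene(paste0("x", 1:n)), make_gene(paste0("y", 1:m)))
    g2$length <- lens
    grp2 <- data.frame(symbol = g2$symbol,
                       name = rep(c("X", "Y"), c(n, m)))
    got <- length_ks_matrix(g2, grp2)
    want <- brute_ks(log10(lens[1:n]), log10(lens[-(1:n)]))
    expect_equal(got$D, want$D, tolerance = 1e-9)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  }

  # D invariant under the monotone log transform (raw vs log10 lengths)
  g3 <- g2
  grp3 <- grp2
  got_log <- length_ks_matrix(g3, grp3)
  d_raw <- suppressWarnings(stats::ks.test(
    g3$length[grp3$name == "X"], g3$length[grp3$name == "Y"]))$statistic
  expect_equal(got_log$D, unname(d_raw))

  # undersized group skipped with warning
  g4 <- rbind(make_gene("solo"), make_gene(paste0("z", 1:3)))
  g4$length <- c(1000, 2000, 3000, 4000)
  grp4 <- data.frame(symbol = g4$symbol, name = c("S", "Z", "Z", "Z"))
  expect_warning(r4 <- length_ks_matrix(g4, grp4), "skipped")
  expect_equal(nrow(r4), 0)
})

test_that("modality correlations: symmetry, boundaries, pairwise deletion", {
  x <- stats::setNames(1:20, paste0("g", 1:20))
  r <- modality_correlations(list(a = x, b = x,
                                  c = stats::setNames(20:1, names(x))))
  expect_equal(unname(r["a", "b"]), 1)
  expect_equal(unname(r["a", "c"]), -1)  # reversed ranks, spearman
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), c(1, 1, 1))

  # fewer than min_genes shared genes -> NA cell
  y <- stats::setNames(1:5, paste0("g", 1:5))
  r2 <- modality_correlations(list(a = x, b = y))
  expect_true(is.na(r2["a", "b"]))

  # planted structure: H3K36me3 is the tightest expression-coupled mark
  # (a group-proportion-sensitive property, so checked at the default scale)
  ds <- default_dataset()
  marks <- lapply(ds$fragments$chip, function(f)
    gb_vector(region_fpkm(f, ds$regions)))
  hmc <- gb_vector(region_fpkm(ds$fragments$hmc$CM_W8, ds$regions))
  tabs <- c(list(expression = ds$expr[, "CM_W8"]),
            marks[c("PolII", "p300", "H3K36me3", "H3K79me2")],
            list(hmc = hmc))
  cm <- modality_correlations(tabs)
  marks_only <- setdiff(colnames(cm), "expression")
  expect_equal(marks_only[which.max(cm["expression", marks_only])],
               "H3K36me3")
})

test_that("mark densities in Pol II-high genes stratify by cluster", {
  syms <- paste0("g", 1:60)
  grp <- data.frame(symbol = syms,
                    name = rep(c("1st CM", "1st Const", "low"), each = 20))
  polii <- data.frame(symbol = syms, factor_id = "PolII", sample = "CM",
                      signal_per_length = c(rep(3, 20), rep(2, 20),
                                            rep(0.2, 20)),
                      accumulated = c(rep(TRUE, 40), rep(FALSE, 20)))
  # H3K36me3 suppressed in the CM-specific Pol II-high stratum
  h3k36 <- stats::setNames(c(stats::rnorm(20, 0.8, 0.1),
                             stats::rnorm(20, 2.5, 0.1),
                             stats::rnorm(20, 1.5, 0.1)), syms)
  d <- density_in_polii_high(polii, list(H3K36me3 = h3k36), grp)
  expect_lt(d$mode[d$group == "1st CM"], d$mode[d$group == "1st Const"])
  # stratum gene counts cover the Pol II-high set
  expect_equal(sum(d$n), 40)
  # degenerate stratum: one shared value
  one <- stats::setNames(rep(1.5, 60), syms)
  d1 <- density_in_polii_high(polii, list(m = one), grp)
  expect_equal(unique(d1$median), 1.5)
  # empty Pol II-high set -> empty output
  none <- transform(polii, accumulated = FALSE)
  expect_equal(nrow(density_in_polii_high(none, list(m = one), grp)), 0)
})
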
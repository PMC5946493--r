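test_that("relative profiles standardize rows and drop flat genes", {
  m <- rbind(g1 = c(4, 6, 8), g2 = c(7, 7, 7))
  colnames(m) <- paste0("s", 1:3)
  expect_warning(std <- relative_profiles(m), "zero-variance")
  expect_equal(rownames(std), "g1")
  expect_equal(unname(std["g1", ]), c(-1, 0, 1))
  # argmax preserved under standardization
  expect_equal(which.max(std["g1", ]), which.max(m["g1", ]))
})

test_that("k-means is deterministic given a seed and recovers planted groups", {
  ds <- small_dataset()
  std <- relative_profiles(ds$expr)
  km1 <- kmeans_expression(std, seed = 5)
  km2 <- kmeans_expression(std, seed = 5)
  expect_identical(km1$assignment, km2$assignment)

  truth <- ds$truth$group[match(km1$assignment$symbol, ds$truth$symbol)]
  expect_gt(mclust::adjustedRandIndex(km1$assignment$km_label, truth), 0.9)

  km_one <- kmeans_expression(std, k = 1)
  expect_equal(unique(km_one$assignment$km_label), 1L)
  expect_error(kmeans_expression(std, k = nrow(std) + 1), "exceeds")

  # every gene in exactly one cluster; sizes sum to n
  expect_equal(sum(table(km1$assignment$km_label)), nrow(std))
})

test_that("cluster categorization applies the specificity-margin rule", {
  # constructed three-type design: one specific, one shared, one flat cluster
  sample_info <- data.frame(sample = paste0("s", 1:6),
                            cell_type = rep(c("CM", "Liver", "ESC"), each = 2))
  expr <- rbind(
    a1 = c(9, 9, 6, 6, 6, 6), a2 = c(9.1, 8.9, 6, 6.1, 5.9, 6),
    b1 = c(9, 9, 9, 9, 6, 6), b2 = c(9.1, 9, 8.9, 9, 6, 6.1),
    c1 = c(8, 8.05, 7.95, 8, 8.02, 7.98), c2 = c(8, 8.1, 7.9, 8, 8.1, 7.9))
  colnames(expr) <- sample_info$sample
  km <- structure(list(
    assignment = data.frame(symbol = rownames(expr),
                            km_label = rep(1:3, each = 2)),
    centers = relative_profiles(expr)[c(1, 3, 5), ],
    k = 3L, seed = 1L), class = "km_clusters")
  rownames(km$centers) <- 1:3
  cats <- categorize_clusters(km, expr, sample_info, specificity_margin = 0.75)
  cl <- cats$clusters
  expect_equal(cl$category, c("cell_type_specific", "multi_type_specific",
                              "constitutive"))
  expect_equal(cl$cell_type[1:2], c("CM", "CM+Liver"))
  expect_equal(cl$name[3], "1st Const")

  # label permutation invariance: renumber clusters, same per-gene category
  km2 <- km
  relabel <- c(3L, 1L, 2L)
  km2$assignment$km_label <- relabel[km$assignment$km_label]
  km2$centers <- km$centers[order(relabel), ]
  rownames(km2$centers) <- 1:3
  cats2 <- categorize_clusters(km2, expr, sample_info)
  a1 <- cats$assignment[order(cats$assignment$symbol), ]
  a2 <- cats2$assignment[order(cats2$assignment$symbol), ]
  expect_equal(a1$category, a2$category)
  expect_equal(a1$name, a2$name)

  # raising the margin never increases the cell-type-specific cluster count
  n_spec <- vapply(c(0.25, 0.75, 1.5, 3), function(m)
    sum(categorize_clusters(km, expr, sample_info,
                            specificity_margin = m)$clusters$category ==
          "cell_type_specific"), numeric(1))
  expect_true(all(diff(n_spec) <= 0))
})

test_that("planted category design and constitutive fraction are recovered", {
  ds <- small_dataset()
  std <- relative_profiles(ds$expr)
  km <- kmeans_expression(std)
  cats <- categorize_clusters(km, ds$expr, ds$expr_samples)
  tab <- table(cats$clusters$category)
  expect_equal(unname(tab["cell_type_specific"]), 5L)  # 2 CM + 2 ESC + 1 Liver
  expect_equal(unname(tab["multi_type_specific"]), 1L)
  expect_equal(unname(tab["constitutive"]), 6L)
  planted <- sum(ds$truth$is_constitutive) / nrow(ds$truth)
  expect_equal(constitutive_fraction(cats), planted)

  # arithmetic: 6 of 12 equal-size clusters constitutive -> 0.5
  fake <- structure(list(assignment = data.frame(
    symbol = paste0("g", 1:120),
    category = rep(c("constitutive", "cell_type_specific"), each = 60))),
    class = "cluster_categories")
  expect_equal(constitutive_fraction(fake), 0.5)
  fake$assignment$category <- "constitutive"
  expect_equal(constitutive_fraction(fake), 1.0)
})
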
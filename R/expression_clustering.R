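#' Read an expression matrix from TSV
#'
#' Expects a genes-by-samples table: first column gene symbols, header row
#' holding sample identifiers, values RMA-summarized log-scale expression.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene-symbol rownames.
#' @export
read_expression_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(x)
}

#' Standardize expression rows to relative profiles
#'
#' Centers each gene's profile and scales it to unit (sample) standard
#' deviation so that clustering groups genes by profile shape rather than
#' absolute level. Zero-variance rows carry no shape information and are
#' dropped with a warning.
#'
#' @param expr Genes-by-samples matrix.
#' @return Standardized matrix, possibly with fewer rows.
#' @export
relative_profiles <- function(expr) {
  stopifnot(ncol(expr) >= 2)
  sds <- apply(expr, 1, stats::sd)
  flat <- sds == 0 | is.na(sds)
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) dropped from clustering")
    expr <- expr[!flat, , drop = FALSE]
  }
  t(scale(t(expr)))
}

#' K-means clustering of expression profiles
#'
#' Partitions standardized expression profiles into `k` groups
#' (`Exp_Km12` at the default `k = 12`), taking the best of `n_restarts`
#' random starts by total within-cluster sum of squares. Results are
#' deterministic for a given `seed`.
#'
#' @param expr_std Standardized matrix from [relative_profiles()].
#' @param k Number of clusters (default 12).
#' @param seed RNG seed (default 1).
#' @param n_restarts Random restarts (default 50).
#' @return List of class `km_clusters`: `assignment` (`data.frame` with
#'   `symbol`, `km_label`), `centers` (k-by-samples matrix),
#'   `tot_withinss`, `k`, `seed`.
#' @export
kmeans_expression <- function(expr_std, k = 12L, seed = 1L,
                              n_restarts = 50L) {
  if (k > nrow(expr_std)) stop("k exceeds the number of genes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(expr_std, centers = k, nstart = n_restarts,
                      iter.max = 100L)
  structure(list(
    assignment = data.frame(symbol = rownames(expr_std),
                            km_label = as.integer(km$cluster),
                            stringsAsFactors = FALSE),
    centers = km$centers, tot_withinss = km$tot.withinss,
    k = as.integer(k), seed = as.integer(seed)), class = "km_clusters")
}

#' @export
print.km_clusters <- function(x, ...) {
  cat("km_clusters: k =", x$k, ", n =", nrow(x$assignment),
      ", tot within-SS =", format(x$tot_withinss, digits = 4), "\n")
  print(table(x$assignment$km_label))
  invisible(x)
}

#' Categorize K-means clusters as cell-type-specific or constitutive
#'
#' For each cluster, cell-type means of the standardized centroid are
#' compared: the specific type-set is the set of cell types whose centroid
#' mean exceeds that of every type outside the set by at least
#' `specificity_margin` standardized units. One specific type gives a
#' cell-type-specific cluster (e.g. "CM"); several give a multi-type
#' cluster (e.g. "CM+Liver"); none (or all) gives a constitutive cluster.
#' Within the single-type and constitutive categories, clusters are ranked
#' by descending mean expression in the unstandardized matrix ("1st CM",
#' "2nd CM", "1st Const", ...).
#'
#' @param km A `km_clusters` object.
#' @param expr Unstandardized genes-by-samples matrix.
#' @param sample_info `data.frame` with columns `sample`, `cell_type`
#'   matching `colnames(expr)`.
#' @param specificity_margin Margin in standardized units (default 0.75).
#' @return A `cluster_categories` list: `clusters` (`data.frame` per
#'   cluster: `km_label`, `category`, `cell_type`, `rank`, `name`,
#'   `n_genes`, `mean_expression`), `assignment` (per gene with those
#'   columns joined), `margin`.
#' @export
categorize_clusters <- function(km, expr, sample_info,
                                specificity_margin = 0.75) {
  stopifnot(all(colnames(expr) %in% sample_info$sample))
  types <- sample_info$cell_type[match(colnames(expr), sample_info$sample)]
  utypes <- unique(types)
  labs <- sort(unique(km$assignment$km_label))
  cent <- km$centers[as.character(labs), , drop = FALSE]
  type_means <- sapply(utypes, function(ty)
    rowMeans(cent[, types == ty, drop = FALSE]))
  type_means <- matrix(type_means, nrow = length(labs),
                       dimnames = list(labs, utypes))
  spec_set <- apply(type_means, 1, function(v) {
    ord <- order(v, decreasing = TRUE)
    # smallest prefix of the type ranking separated from the rest by the margin
    for (sz in seq_len(length(v) - 1)) {
      if (min(v[ord[seq_len(sz)]]) - max(v[ord[-seq_len(sz)]]) >=
          specificity_margin) {
        return(paste(sort(names(v)[ord[seq_len(sz)]]), collapse = "+"))
      }
    }
    ""
  })
  mean_expr <- vapply(labs, function(l) {
    g <- km$assignment$symbol[km$assignment$km_label == l]
    mean(expr[rownames(expr) %in% g, , drop = FALSE])
  }, numeric(1))
  n_genes <- vapply(labs, function(l)
    sum(km$assignment$km_label == l), integer(1))
  category <- ifelse(spec_set == "", "constitutive",
                     ifelse(grepl("\\+", spec_set), "multi_type_specific",
                            "cell_type_specific"))
  cl <- data.frame(km_label = labs, category = category,
                   cell_type = ifelse(spec_set == "", NA, spec_set),
                   mean_expression = mean_expr, n_genes = n_genes,
                   stringsAsFactors = FALSE)
  cl$rank <- NA_integer_
  for (grp in unique(cl$cell_type[cl$category == "cell_type_specific"])) {
    i <- which(cl$category == "cell_type_specific" & cl$cell_type == grp)
    cl$rank[i] <- rank(-cl$mean_expression[i], ties.method = "first")
  }
  i <- which(cl$category == "constitutive")
  cl$rank[i] <- rank(-cl$mean_expression[i], ties.method = "first")
  cl$name <- ifelse(
    cl$category == "constitutive", paste0(ordinal(cl$rank), " Const"),
    ifelse(cl$category == "multi_type_specific", cl$cell_type,
           ifelse(tapply_count(cl) > 1,
                  paste0(ordinal(cl$rank), " ", cl$cell_type),
                  cl$cell_type)))
  assignment <- merge(km$assignment, cl[, c("km_label", "category",
                                            "cell_type", "rank", "name")],
                      by = "km_label", sort = FALSE)
  structure(list(clusters = cl[, c("km_label", "category", "cell_type",
                                   "rank", "name", "n_genes",
                                   "mean_expression")],
                 assignment = assignment, margin = specificity_margin),
            class = "cluster_categories")
}

ordinal <- function(n) {
  suf <- rep("th", length(n))
  suf[n %% 10 == 1 & n %% 100 != 11] <- "st"
  suf[n %% 10 == 2 & n %% 100 != 12] <- "nd"
  suf[n %% 10 == 3 & n %% 100 != 13] <- "rd"
  paste0(n, suf)
}

# how many clusters share each row's specific cell type
tapply_count <- function(cl) {
  cnt <- table(cl$cell_type[cl$category == "cell_type_specific"])
  out <- rep(1L, nrow(cl))
  idx <- cl$category == "cell_type_specific"
  out[idx] <- as.integer(cnt[cl$cell_type[idx]])
  out
}

#' @export
print.cluster_categories <- function(x, ...) {
  cat("cluster_categories (margin", x$margin, "):\n")
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Fraction of genes in constitutive clusters
#'
#' @param categories A `cluster_categories` object.
#' @return Proportion in \[0, 1\].
#' @export
constitutive_fraction <- function(categories) {
  a <- categories$assignment
  mean(a$category == "constitutive")
}

#' Write cluster assignments as TSV
#'
#' @param categories A `cluster_categories` object.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(categories, path) {
  utils::write.table(categories$assignment, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}
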
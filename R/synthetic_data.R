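#' Configuration for the synthetic multi-omics generator
#'
#' Builds the planted study design used by [generate_dataset()]: 12 gene
#' groups (two CM-specific, two ESC-specific, one liver-specific, one
#' CM+Liver shared, six constitutive expression ranks), group-specific
#' log-normal gene-length distributions with the CM-specific groups
#' longest, per-sample expression means, a HELP angle model per region and
#' developmental stage in which adult-CM gene bodies of the 1st CM group
#' are the most demethylated, a 5hmC intensity trajectory peaking at the
#' neonatal stage in CM-specific gene bodies, and per-factor ChIP
#' intensities concentrating Pol II/p300 accumulation in the 1st CM group.
#'
#' With the defaults the six constitutive groups hold 6 x 68 = 408 of 600
#' genes, a planted constitutive fraction of exactly 0.68.
#'
#' @param seed RNG seed.
#' @param genes_per_specific Genes in each of the six non-constitutive
#'   groups (default 32).
#' @param genes_per_const Genes in each of the six constitutive groups
#'   (default 68).
#' @param expr_noise_sd Expression noise SD on the RMA log scale
#'   (default 0.3).
#' @param angle_noise_sd HELP angle noise SD (default 8).
#' @param site_spacing Mean bp between HpaII sites (default 1500).
#' @param gene_gap Intergenic gap in bp (default 10000).
#' @param n_contigs Synthetic contigs (default 4).
#' @param contig_length Optional fixed contig length in bp; genes that do
#'   not fit raise an error. NULL (default) sizes contigs to the placement.
#' @param frag_len Fragment length in bp (default 250).
#' @param library_size Total mapped fragments of each simulated library;
#'   the toy contigs carry the slice of it that the planted FPKM targets
#'   imply (default 1e6).
#' @param background_frags Background fragments per library (default 2000).
#' @param conf_fail_rate Mean of the exponential confidence score; about
#'   5 percent of scores exceed the cutoff 3 (default 1).
#' @param angle_missing_rate Per-sample missing-angle probability
#'   (default 0.02).
#' @return A list of class `synthetic_config` including the group design
#'   tables (`groups`, `expr_means`, `body_angle`, `promoter_angle`,
#'   `hmc_fpkm`, `chip`), sample layouts (`expr_samples`, `help_samples`,
#'   `hmc_stages`) and the scalar knobs above.
#' @export
synthetic_config <- function(seed = 1L,
                             genes_per_specific = 32L,
                             genes_per_const = 68L,
                             expr_noise_sd = 0.3,
                             angle_noise_sd = 8,
                             site_spacing = 1500L,
                             gene_gap = 10000L,
                             n_contigs = 4L,
                             contig_length = NULL,
                             frag_len = 250L,
                             library_size = 1e6,
                             background_frags = 2000L,
                             conf_fail_rate = 1,
                             angle_missing_rate = 0.02) {
  groups <- c("CM_1", "CM_2", "ESC_1", "ESC_2", "Liver", "CM_Liver",
              paste0("Const_", 1:6))
  const <- grepl("^Const", groups)
  g <- data.frame(
    group = groups,
    n_genes = ifelse(const, genes_per_const, genes_per_specific),
    is_constitutive = const,
    # gene-length model: CM-specific groups longest; among constitutive
    # groups higher expression rank -> shorter genes
    length_meanlog = log(c(60000, 80000, 25000, 22000, 30000, 30000,
                           12000, 16000, 20000, 24000, 28000, 32000)),
    length_sdlog = 0.4,
    stringsAsFactors = FALSE)

  expr_samples <- data.frame(
    sample = c("ESC_r1", "ESC_r2", "CM_P1", "CM_W8", "Liver_r1", "Liver_r2"),
    cell_type = c("ESC", "ESC", "CM", "CM", "Liver", "Liver"),
    stage = c("adult", "adult", "neonatal", "adult", "adult", "adult"),
    stringsAsFactors = FALSE)
  # planted expression means (RMA log scale); the six constitutive groups
  # get small within-cell-type contrasts so all 12 centroids stay mutually
  # separated after row standardization while their cell-type means stay
  # within the specificity margin (a synthetic-only device)
  expr_means <- rbind(
    CM_1    = c(6.0, 6.0, 8.5, 12.0, 6.0, 6.0),
    CM_2    = c(5.5, 5.5, 9.5, 7.0, 5.5, 5.5),
    ESC_1   = c(11.0, 11.0, 6.0, 6.0, 6.0, 6.0),
    ESC_2   = c(10.3, 6.7, 6.0, 6.0, 6.0, 6.0),
    Liver   = c(6.0, 6.0, 6.0, 6.0, 11.0, 11.0),
    CM_Liver = c(6.0, 6.0, 10.0, 10.0, 10.0, 10.0),
    Const_1 = 11.5 + 1.8 * c(1, -1, 0, 0, 0, 0),
    Const_2 = 10.5 + 1.8 * c(0, 0, 1, -1, 0, 0),
    Const_3 = 9.5 + 1.8 * c(0, 0, 0, 0, 1, -1),
    Const_4 = 8.5 - 1.8 * c(1, -1, 0, 0, 0, 0),
    Const_5 = 7.5 - 1.8 * c(0, 0, 1, -1, 0, 0),
    Const_6 = 6.5 - 1.8 * c(0, 0, 0, 0, 1, -1))
  colnames(expr_means) <- expr_samples$sample

  help_samples <- data.frame(
    sample = c("ESC", "CM_E9", "CM_P1", "CM_W8", "CF_W8",
               "Liver_P1", "Liver_W8", "MEF"),
    stringsAsFactors = FALSE)
  # gene-body HELP angle means (angle rises with hypomethylation): the
  # genome is hypermethylated at baseline (angle ~25); CM-specific gene
  # bodies progressively demethylate towards adult CM, 1st CM deepest
  body_angle <- rbind(
    CM_1    = c(30, 35, 55, 85, 25, 25, 25, 25),
    CM_2    = c(30, 32, 50, 70, 25, 25, 25, 25),
    ESC_1   = c(55, 25, 25, 25, 25, 25, 25, 25),
    ESC_2   = c(50, 25, 25, 25, 25, 25, 25, 25),
    Liver   = c(25, 25, 25, 25, 25, 50, 75, 25),
    CM_Liver = c(25, 25, 45, 60, 25, 45, 60, 25),
    Const_1 = 30, Const_2 = 30, Const_3 = 30,
    Const_4 = 22, Const_5 = 22, Const_6 = 22)
  body_angle <- matrix(body_angle, nrow = 12, ncol = 8,
                       dimnames = list(groups, help_samples$sample))
  promoter_angle <- matrix(85, nrow = 12, ncol = 8,
                           dimnames = list(groups, help_samples$sample))
  promoter_angle[c("Const_4", "Const_5", "Const_6"), ] <- 70

  hmc_stages <- c("CM_E14", "CM_P1", "CM_W8")
  # gene-body 5hmC FPKM targets over developmental stages: a transient
  # neonatal peak planted in the CM-specific groups only
  hmc_fpkm <- rbind(
    CM_1 = c(0.5, 3.0, 1.0), CM_2 = c(0.5, 2.5, 1.0),
    ESC_1 = 0.4, ESC_2 = 0.4, Liver = 0.4,
    CM_Liver = c(0.3, 0.5, 0.6),
    Const_1 = 0.4, Const_2 = 0.4, Const_3 = 0.4,
    Const_4 = 0.4, Const_5 = 0.4, Const_6 = 0.4)
  hmc_fpkm <- matrix(hmc_fpkm, nrow = 12, ncol = 3,
                     dimnames = list(groups, hmc_stages))

  # adult-heart ChIP/GRO gene-body intensity model; `base` is a per-group
  # FPKM target, `act_coef` couples intensity to the gene's realized
  # adult-CM expression, `cm1_factor` rescales the 1st CM group, `sdlog`
  # is per-gene log-normal scatter
  chip <- list(
    PolII = list(base = c(CM_1 = 3.0, CM_2 = 0.8, ESC_1 = 0.25,
                          ESC_2 = 0.25, Liver = 0.25, CM_Liver = 0.7,
                          Const_1 = 0.45, Const_2 = 0.45, Const_3 = 0.4,
                          Const_4 = 0.35, Const_5 = 0.3, Const_6 = 0.3),
                 act_coef = 0, cm1_factor = 1, sdlog = 0.6),
    p300 = list(base = c(CM_1 = 2.5, CM_2 = 1.5, ESC_1 = 0.3,
                         ESC_2 = 0.3, Liver = 0.3, CM_Liver = 0.6,
                         Const_1 = 0.45, Const_2 = 0.4, Const_3 = 0.4,
                         Const_4 = 0.3, Const_5 = 0.3, Const_6 = 0.3),
                act_coef = 0, cm1_factor = 1, sdlog = 0.6),
    H3K36me3 = list(base = 0.25, act_coef = 0.45, cm1_factor = 0.35,
                    sdlog = 0.25),
    H3K79me2 = list(base = 0.25, act_coef = 0.2, cm1_factor = 1,
                    sdlog = 0.45),
    GRO = list(base = 0.2, act_coef = 0.45, cm1_factor = 1.5, sdlog = 0.6))

  structure(list(seed = as.integer(seed), groups = g,
                 expr_samples = expr_samples, expr_means = expr_means,
                 expr_noise_sd = expr_noise_sd,
                 help_samples = help_samples, body_angle = body_angle,
                 promoter_angle = promoter_angle,
                 angle_noise_sd = angle_noise_sd,
                 intergenic_angle = 25,
                 hmc_stages = hmc_stages, hmc_fpkm = hmc_fpkm,
                 promoter_hmc_fpkm = 0.2, chip = chip,
                 site_spacing = as.integer(site_spacing),
                 gene_gap = as.integer(gene_gap),
                 n_contigs = as.integer(n_contigs),
                 contig_length = contig_length,
                 frag_len = as.integer(frag_len),
                 library_size = library_size,
                 background_frags = as.integer(background_frags),
                 conf_fail_rate = conf_fail_rate,
                 angle_missing_rate = angle_missing_rate),
            class = "synthetic_config")
}

#' Load a synthetic-generator configuration from YAML
#'
#' Reads scalar overrides (any argument of [synthetic_config()]) from a
#' YAML file and builds the config.
#'
#' @param path YAML path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  ov <- yaml::read_yaml(path)
  allowed <- names(formals(synthetic_config))
  bad <- setdiff(names(ov), allowed)
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(synthetic_config, ov)
}

#' Generate a synthetic multi-tissue, multi-stage dataset
#'
#' Deterministically (given `cfg$seed`) generates gene models placed
#' without overlap on synthetic contigs, an 8-sample HELP angle table,
#' expression profiles with 12 planted groups, stage-resolved 5hmC
#' fragment sets and adult-heart ChIP/GRO fragment sets, together with the
#' truth labels of every planted quantity.
#'
#' Fragments are drawn per region as Poisson counts with rates
#' proportional to the planted FPKM targets and placed uniformly inside
#' the region (3'-shifted for H3K36me3/GRO in the 1st CM group), on top of
#' a uniform genomic background.
#'
#' @param cfg A [synthetic_config()].
#' @return List: `config`, `genes`, `regions`, `truth`, `expr`,
#'   `expr_samples`, `help` (named list of per-sample site tables),
#'   `fragments` (`hmc` by stage, `chip` by factor), `contigs`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"),
            all(cfg$groups$n_genes >= 2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  ## gene models
  grp <- rep(cfg$groups$group, cfg$groups$n_genes)
  n <- length(grp)
  lens <- round(stats::rlnorm(n,
    meanlog = rep(cfg$groups$length_meanlog, cfg$groups$n_genes),
    sdlog = rep(cfg$groups$length_sdlog, cfg$groups$n_genes)))
  lens <- pmax(lens, 2500)
  symbol <- sprintf("gene_%04d", seq_len(n))
  ord <- sample.int(n)  # interleave groups along the contigs
  chrom_i <- rep(seq_len(cfg$n_contigs), length.out = n)
  start <- integer(n); chrom <- character(n)
  pos <- rep(5000L, cfg$n_contigs)
  for (k in seq_len(n)) {
    i <- ord[k]
    ci <- chrom_i[k]
    chrom[i] <- paste0("chr", ci)
    start[i] <- pos[ci]
    pos[ci] <- pos[ci] + as.integer(lens[i]) + cfg$gene_gap
  }
  contig_len <- pos + 5000L
  if (!is.null(cfg$contig_length)) {
    if (any(contig_len > cfg$contig_length)) {
      stop("infeasible placement: total gene span exceeds contig length")
    }
    contig_len <- rep(as.integer(cfg$contig_length), cfg$n_contigs)
  }
  contigs <- data.frame(chrom = paste0("chr", seq_len(cfg$n_contigs)),
                        length = contig_len, stringsAsFactors = FALSE)
  strand <- rep(c("+", "-"), length.out = n)
  genes <- data.frame(symbol = symbol, transcript_id = paste0("tx_", symbol),
                      chrom = chrom, strand = strand,
                      start = start, end = start + as.integer(lens),
                      stringsAsFactors = FALSE)
  genes$tss <- ifelse(strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(strand == "+", genes$end, genes$start)
  genes$length <- genes$end - genes$start
  regions <- derive_regions(genes)

  truth <- data.frame(symbol = symbol, group = grp,
                      is_constitutive = grepl("^Const", grp),
                      length = genes$length, chrom = chrom,
                      strand = strand, stringsAsFactors = FALSE)

  ## expression
  mu <- cfg$expr_means[grp, , drop = FALSE]
  expr <- mu + matrix(stats::rnorm(length(mu), 0, cfg$expr_noise_sd),
                      nrow = n)
  rownames(expr) <- symbol
  colnames(expr) <- cfg$expr_samples$sample

  ## HELP site tables
  help <- generate_help_tables(cfg, genes, regions, truth, contigs)

  ## fragment sets
  act <- pmax(expr[, "CM_W8"] - 6, 0)
  hmc <- list()
  for (st in cfg$hmc_stages) {
    rate <- cfg$hmc_fpkm[grp, st]
    hmc[[st]] <- simulate_fragments(cfg, genes, regions,
                                    body_fpkm = rate,
                                    promoter_fpkm = rep(cfg$promoter_hmc_fpkm, n),
                                    shift3 = rep(FALSE, n), contigs = contigs)
  }
  chip <- list()
  for (fac in names(cfg$chip)) {
    p <- cfg$chip[[fac]]
    base <- if (length(p$base) == 1) rep(p$base, n) else p$base[grp]
    rate <- (base + p$act_coef * act) *
      ifelse(grp == "CM_1", p$cm1_factor, 1) *
      stats::rlnorm(n, -p$sdlog^2 / 2, p$sdlog)
    shift3 <- grp == "CM_1" & fac %in% c("H3K36me3", "GRO")
    chip[[fac]] <- simulate_fragments(cfg, genes, regions,
                                      body_fpkm = rate,
                                      promoter_fpkm = pmin(rate, 0.5),
                                      shift3 = shift3, contigs = contigs)
  }

  list(config = cfg, genes = genes, regions = regions, truth = truth,
       expr = expr, expr_samples = cfg$expr_samples, help = help,
       fragments = list(hmc = hmc, chip = chip), contigs = contigs)
}

generate_help_tables <- function(cfg, genes, regions, truth, contigs) {
  sites <- list()
  for (ci in seq_len(nrow(contigs))) {
    n_sites <- floor(contigs$length[ci] / cfg$site_spacing)
    pos <- sort(sample.int(contigs$length[ci], n_sites))
    sites[[ci]] <- data.frame(chrom = contigs$chrom[ci], pos = pos,
                              stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  ns <- nrow(sites)
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, width = 1L))
  region_of <- rep(NA_character_, ns)
  group_of <- rep(NA_character_, ns)
  for (reg in c("promoter", "gene_body")) {
    gr <- regions_gr(regions, reg)
    hits <- GenomicRanges::findOverlaps(site_gr, gr)
    qi <- S4Vectors::queryHits(hits)
    region_of[qi] <- reg
    group_of[qi] <- truth$group[match(names(gr)[S4Vectors::subjectHits(hits)],
                                      truth$symbol)]
  }
  out <- list()
  for (s in cfg$help_samples$sample) {
    mean_angle <- rep(cfg$intergenic_angle, ns)
    in_body <- !is.na(region_of) & region_of == "gene_body"
    in_prom <- !is.na(region_of) & region_of == "promoter"
    mean_angle[in_body] <- cfg$body_angle[group_of[in_body], s]
    mean_angle[in_prom] <- cfg$promoter_angle[group_of[in_prom], s]
    angle <- pmin(100, pmax(0, mean_angle +
                              stats::rnorm(ns, 0, cfg$angle_noise_sd)))
    angle[stats::runif(ns) < cfg$angle_missing_rate] <- NA_real_
    conf <- stats::rexp(ns, rate = 1 / cfg$conf_fail_rate)
    out[[s]] <- data.frame(chrom = sites$chrom, pos = sites$pos,
                           angle = angle, confidence = conf,
                           stringsAsFactors = FALSE)
  }
  out
}

# Poisson fragment counts per region at the target FPKM, uniform (or
# 3'-shifted Beta(2, 1.2)) placement inside the region, plus uniform
# background; library size is the realized total
simulate_fragments <- function(cfg, genes, regions, body_fpkm,
                               promoter_fpkm, shift3, contigs) {
  lib_target <- cfg$library_size
  frag <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    r <- regions[i, ]
    if (!r$body_empty) {
      len_kb <- (r$body_end - r$body_start) / 1000
      cnt <- stats::rpois(1, body_fpkm[i] * len_kb * (lib_target / 1e6))
      if (cnt > 0) {
        f <- if (shift3[i]) stats::rbeta(cnt, 2, 1.2) else stats::runif(cnt)
        # f is the fractional position along the 5'->3' gene body
        if (g$strand == "-") f <- 1 - f
        span <- (r$body_end - r$body_start) - cfg$frag_len
        s <- r$body_start + floor(f * max(1, span))
        frag[[length(frag) + 1]] <- data.frame(
          chrom = g$chrom, start = as.integer(s),
          end = as.integer(s + cfg$frag_len), stringsAsFactors = FALSE)
      }
    }
    pl <- (r$promoter_end - r$promoter_start) / 1000
    pc <- stats::rpois(1, promoter_fpkm[i] * pl * (lib_target / 1e6))
    if (pc > 0) {
      span <- (r$promoter_end - r$promoter_start) - cfg$frag_len
      s <- r$promoter_start + floor(stats::runif(pc) * max(1, span))
      frag[[length(frag) + 1]] <- data.frame(
        chrom = g$chrom, start = as.integer(s),
        end = as.integer(s + cfg$frag_len), stringsAsFactors = FALSE)
    }
  }
  nb <- cfg$background_frags
  ci <- sample.int(nrow(contigs), nb, replace = TRUE,
                   prob = contigs$length / sum(contigs$length))
  s <- floor(stats::runif(nb) * (contigs$length[ci] - cfg$frag_len))
  frag[[length(frag) + 1]] <- data.frame(
    chrom = contigs$chrom[ci], start = as.integer(s),
    end = as.integer(s + cfg$frag_len), stringsAsFactors = FALSE)
  all <- do.call(rbind, frag)
  # the toy contigs stand in for a small slice of a genome-wide library;
  # the library size is the full library so planted FPKM targets are
  # realized on their own scale
  fragment_set(all, library_size = lib_target, read_mode = "single_extended")
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the annotation as refFlat, per-sample HELP site tables, the
#' expression matrix, fragment BEDs per modality and the truth labels into
#' a directory.
#'
#' @param ds Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(annotation = file.path(dir, "genes.refflat"))
  write_refflat(ds$genes, paths["annotation"])
  for (s in names(ds$help)) {
    p <- file.path(dir, paste0("help_", s, ".tsv"))
    utils::write.table(ds$help[[s]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[paste0("help_", s)] <- p
  }
  p <- file.path(dir, "expression.tsv")
  utils::write.table(
    data.frame(symbol = rownames(ds$expr), ds$expr, check.names = FALSE),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["expression"] <- p
  for (mod in names(ds$fragments)) {
    for (s in names(ds$fragments[[mod]])) {
      p <- file.path(dir, paste0(mod, "_", s, ".bed"))
      utils::write.table(ds$fragments[[mod]][[s]]$fragments, p, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      paths[paste0(mod, "_", s)] <- p
    }
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(ds$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- p
  invisible(paths)
}

#' Write gene models as refFlat
#'
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_refflat <- function(genes, path) {
  df <- data.frame(genes$symbol, genes$transcript_id, genes$chrom,
                   genes$strand, genes$start, genes$end,
                   genes$start, genes$end, 1L, genes$start, genes$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Tiny hand-checkable worked fixture with oracle expectations
#'
#' Builds a fixed six-gene dataset (no randomness) together with expected
#' values computed by deliberately naive reference routines: region median
#' angles by a full scan over all gene-site pairs, fragment counts by
#' all-pairs overlap, and the two-group Kolmogorov-Smirnov D with its
#' exact p-value by exhaustive enumeration of all label assignments.
#'
#' @return List: `genes`, `regions`, `sites` (merged-format table with one
#'   `angle.s1` column), `frags`, `expected` (`medians`, `fpkm`, `ks`).
#' @export
emit_worked_fixture <- function() {
  genes <- data.frame(
    symbol = paste0("g", 1:6),
    transcript_id = paste0("t", 1:6),
    chrom = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB"),
    strand = c("+", "-", "+", "-", "+", "+"),
    start = c(10000L, 40000L, 70000L, 10000L, 30000L, 50000L),
    end = c(20000L, 52000L, 86000L, 18000L, 41500L, 51500L),
    stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  genes$length <- genes$end - genes$start
  regions <- derive_regions(genes)

  pos <- c(seq(8000, 20000, by = 700), seq(38000, 54000, by = 900),
           seq(68000, 88000, by = 800))
  posB <- c(seq(8000, 20000, by = 650), seq(28000, 43000, by = 750),
            seq(48000, 53500, by = 500))
  sites <- data.frame(
    chrom = c(rep("chrA", length(pos)), rep("chrB", length(posB))),
    pos = as.integer(c(pos, posB)), stringsAsFactors = FALSE)
  sites$angle.s1 <- round(100 * abs(sin(seq_len(nrow(sites)))), 1)

  fr <- expand.grid(off = seq(0, 95000, by = 1700), chrom = c("chrA", "chrB"),
                    stringsAsFactors = FALSE)
  frags <- fragment_set(
    data.frame(chrom = fr$chrom, start = as.integer(fr$off + 500),
               end = as.integer(fr$off + 750), stringsAsFactors = FALSE),
    library_size = 120000, read_mode = "single_extended")

  expected <- list(
    medians = oracle_region_medians(sites, regions),
    fpkm = oracle_region_fpkm(frags, regions),
    ks = oracle_ks_exact(log10(genes$length[1:3]), log10(genes$length[4:6])))
  list(genes = genes, regions = regions, sites = sites, frags = frags,
       expected = expected)
}

# naive per-gene scan over every site (no interval index)
oracle_region_medians <- function(sites, regions) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (reg in c("promoter", "gene_body")) {
      if (reg == "gene_body" && r$body_empty) next
      lo <- if (reg == "promoter") r$promoter_start else r$body_start
      hi <- if (reg == "promoter") r$promoter_end else r$body_end
      sel <- sites$chrom == r$chrom & sites$pos >= lo & sites$pos < hi
      ang <- sites$angle.s1[sel]
      ang <- ang[!is.na(ang)]
      out[[paste(r$symbol, reg)]] <- data.frame(
        symbol = r$symbol, region = reg, n_sites = length(ang),
        median_angle = if (length(ang)) stats::median(ang) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# quadratic all-pairs overlap counting
oracle_region_fpkm <- function(frags, regions) {
  f <- frags$fragments
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    for (reg in c("promoter", "gene_body")) {
      if (reg == "gene_body" && r$body_empty) next
      lo <- if (reg == "promoter") r$promoter_start else r$body_start
      hi <- if (reg == "promoter") r$promoter_end else r$body_end
      cnt <- 0
      for (j in seq_len(nrow(f))) {
        if (f$chrom[j] == r$chrom && f$start[j] < hi && f$end[j] > lo) {
          cnt <- cnt + 1
        }
      }
      out[[paste(r$symbol, reg)]] <- data.frame(
        symbol = r$symbol, region = reg, count = cnt,
        fpkm = cnt / ((hi - lo) / 1000) / (frags$library_size / 1e6),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# exhaustive two-sample KS: D from the pooled ECDF difference, exact p as
# the fraction of all C(n+m, n) label assignments with D at least as large
oracle_ks_exact <- function(x, y) {
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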
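#' Percent 5hmC from the three-aliquot BGT protection assay
#'
#' The glucosylation assay splits a sample into three aliquots: A) T4 BGT
#' then MspI digestion, B) T4 BGT alone, C) MspI alone. Glucosylated 5hmC
#' at the CCGG site blocks MspI, so the protected fraction
#' `100 * (A - C) / (B - C)` estimates percent 5hmC at the locus. The raw
#' value is preserved: estimates outside \[0, 100\] are flagged as assay
#' anomalies rather than clipped, and `B == C` (no protection range)
#' yields NA with a warning.
#'
#' @param A,B,C Non-negative qPCR relative-abundance vectors for the three
#'   aliquots (recycled to a common length).
#' @return `data.frame`: `A`, `B`, `C`, `percent_5hmc`, `anomaly`.
#' @export
percent_5hmc <- function(A, B, C) {
  stopifnot(all(A >= 0, na.rm = TRUE), all(B >= 0, na.rm = TRUE),
            all(C >= 0, na.rm = TRUE))
  n <- max(length(A), length(B), length(C))
  A <- rep_len(A, n); B <- rep_len(B, n); C <- rep_len(C, n)
  pct <- ifelse(B == C, NA_real_, 100 * (A - C) / (B - C))
  if (any(B == C)) warning("B == C: uninformative assay, percent undefined")
  data.frame(A = A, B = B, C = C, percent_5hmc = pct,
             anomaly = !is.na(pct) & (pct < 0 | pct > 100))
}

#' hMeDIP qPCR relative enrichment
#'
#' Computes delta-delta-Ct enrichment of a target locus in the
#' immunoprecipitated (IP) fraction over input, normalized to a reference
#' locus (conventionally Gapdh):
#' `eff^-(Ct_target_IP - Ct_target_input) / eff^-(Ct_ref_IP - Ct_ref_input)`.
#' With `mode = "ip_only"` the input terms are omitted and the IP fraction
#' is normalized to the reference alone. Replicate mean and SD of the
#' per-replicate enrichments are reported; at least three replicates mark
#' the measurement compliant.
#'
#' @param ct `data.frame` with columns `locus`, `replicate`,
#'   `ct_target_ip`, `ct_target_input`, `ct_ref_ip`, `ct_ref_input`
#'   (input columns may be absent in `"ip_only"` mode). All Ct > 0.
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @param mode `"input_normalized"` (default) or `"ip_only"`.
#' @return `data.frame` per locus: `n_replicates`, `mean_enrichment`,
#'   `sd_enrichment`, `compliant`.
#' @export
hmedip_enrichment <- function(ct, efficiency = 2,
                              mode = c("input_normalized", "ip_only")) {
  mode <- match.arg(mode)
  need <- c("locus", "replicate", "ct_target_ip", "ct_ref_ip")
  if (mode == "input_normalized") {
    need <- c(need, "ct_target_input", "ct_ref_input")
  }
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols)) {
    stop("missing Ct column(s): ", paste(missing_cols, collapse = ", "))
  }
  ctn <- ct[, intersect(names(ct), c(need))]
  if (anyNA(ctn) || any(ctn[, grep("^ct_", names(ctn))] <= 0)) {
    stop("Ct values must be present and > 0")
  }
  d_target <- if (mode == "input_normalized")
    ct$ct_target_ip - ct$ct_target_input else ct$ct_target_ip
  d_ref <- if (mode == "input_normalized")
    ct$ct_ref_ip - ct$ct_ref_input else ct$ct_ref_ip
  enr <- efficiency^(-(d_target)) / efficiency^(-(d_ref))
  locus <- as.character(ct$locus)
  out <- data.frame(
    locus = sort(unique(locus)),
    n_replicates = as.integer(table(locus)),
    mean_enrichment = as.numeric(tapply(enr, locus, mean)),
    sd_enrichment = as.numeric(tapply(enr, locus, stats::sd)),
    stringsAsFactors = FALSE)
  out$compliant <- out$n_replicates >= 3
  out
}
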
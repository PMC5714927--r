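# Single-locus validation math: methylation-sensitive restriction enzyme
# qPCR (MSRE-qPCR). Genomic DNA is digested with HpaII (or mock-digested) and
# the region around the cut site amplified; surviving template reflects
# methylation at the locus.

#' Relative methylation from MSRE-qPCR quantification cycles
#'
#' Implements FC = E^dCp with dCp = Cp_digested - Cp_mock, where E is the
#' mean amplification efficiency of the region (1 < E <= 2). Higher FC means
#' more cleavage survived to delay amplification, i.e. LESS methylation at
#' the locus; the methylated-fraction view E^(-dCp) is reported alongside
#' because the subtraction order convention varies between labs.
#'
#' @param E Mean amplification efficiency in (1, 2].
#' @param cp_digested,cp_mock Quantification cycles of the HpaII-digested and
#'   mock-digested templates (positive).
#' @param region Optional region identifier.
#' @return Data frame: `region`, `E`, `cp_digested`, `cp_mock`, `delta_cp`,
#'   `fc` (= E^dCp), `methylated_view` (= E^(-dCp)).
#' @examples
#' relative_methylation(2, 25, 22)$fc  # 8
#' @export
relative_methylation <- function(E, cp_digested, cp_mock, region = NA_character_) {
  if (any(E <= 1)) stop("amplification efficiency must exceed 1 (non-amplifying)")
  if (any(E > 2)) stop("amplification efficiency cannot exceed 2")
  if (any(cp_digested <= 0) || any(cp_mock <= 0)) {
    stop("Cp values must be positive")
  }
  delta_cp <- cp_digested - cp_mock
  fc <- E^delta_cp
  data.frame(region = region, E = E, cp_digested = cp_digested,
             cp_mock = cp_mock, delta_cp = delta_cp, fc = fc,
             methylated_view = E^(-delta_cp), stringsAsFactors = FALSE)
}

#' Compare per-replicate qPCR fold changes between two groups
#'
#' Two-sided two-sample Student's t-test (equal variance) on the replicate FC
#' values; significant at p <= alpha. When both groups have zero variance and
#' equal means, p = 1 by convention.
#'
#' @param fc_a,fc_b Numeric vectors of replicate FC values (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param region Optional region identifier.
#' @return One-row data frame: `region`, `mean_a`, `mean_b`, `t`, `p`,
#'   `significant`.
#' @export
compare_groups <- function(fc_a, fc_b, alpha = 0.05, region = NA_character_) {
  if (length(fc_a) < 2L || length(fc_b) < 2L) {
    stop("need at least two replicates per group")
  }
  if (stats::var(fc_a) == 0 && stats::var(fc_b) == 0) {
    if (mean(fc_a) == mean(fc_b)) {
      return(data.frame(region = region, mean_a = mean(fc_a),
                        mean_b = mean(fc_b), t = 0, p = 1,
                        significant = FALSE, stringsAsFactors = FALSE))
    }
    stop("both groups have zero variance with different means: ",
         "t statistic undefined")
  }
  fit <- t.test(fc_a, fc_b, var.equal = TRUE)
  data.frame(region = region, mean_a = mean(fc_a), mean_b = mean(fc_b),
             t = unname(fit$statistic), p = fit$p.value,
             significant = fit$p.value <= alpha, stringsAsFactors = FALSE)
}

#' Analyze a full MSRE-qPCR Cp table
#'
#' Computes per-replicate relative methylation with [relative_methylation()]
#' and, for each region with two conditions, the replicate-level group
#' comparison with [compare_groups()].
#'
#' @param cp_table Data frame as read by [read_qpcr_table()]: columns
#'   `region`, `condition`, `replicate`, `cp_digested`, `cp_mock`,
#'   `efficiency`.
#' @param alpha Significance level for the group test.
#' @return List with `per_replicate` and `comparisons` data frames.
#' @export
analyze_qpcr <- function(cp_table, alpha = 0.05) {
  per_rep <- do.call(rbind, lapply(seq_len(nrow(cp_table)), function(i) {
    row <- cp_table[i, ]
    res <- relative_methylation(row$efficiency, row$cp_digested, row$cp_mock,
                                region = row$region)
    res$condition <- row$condition
    res$replicate <- row$replicate
    res
  }))
  comparisons <- NULL
  for (reg in unique(per_rep$region)) {
    sub <- per_rep[per_rep$region == reg, ]
    conds <- unique(sub$condition)
    if (length(conds) == 2L) {
      cmp <- compare_groups(sub$fc[sub$condition == conds[1L]],
                            sub$fc[sub$condition == conds[2L]],
                            alpha = alpha, region = reg)
      cmp$condition_a <- conds[1L]
      cmp$condition_b <- conds[2L]
      comparisons <- rbind(comparisons, cmp)
    }
  }
  list(per_replicate = per_rep, comparisons = comparisons)
}
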
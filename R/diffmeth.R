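# Differential methylation calling. Lower tag abundance at a CCGG site means
# higher methylation (HpaII is blocked by methylation), so an abundance
# decrease is a new-methylation event and an increase a demethylation.

#' Exact conditional binomial rate-ratio test
#'
#' Tests whether two count rates differ, conditioning on the total: given
#' n = x1 + x2, under the null x1 ~ Binomial(n, N1 / (N1 + N2)). The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one (with a 1 + 1e-7 relative tolerance for
#' floating-point ties, as in the classical exact binomial test).
#'
#' @param x1,x2 Observed counts (non-negative integers).
#' @param N1,N2 Library sizes (positive).
#' @return Two-sided p-value in (0, 1]; p = 1 when x1 + x2 = 0.
#' @examples
#' rate_ratio_test(10, 1e6, 10, 1e6)  # 1: observed outcome is the mode
#' @export
rate_ratio_test <- function(x1, N1, x2, N2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 == round(x1), x2 == round(x2),
            N1 > 0, N2 > 0)
  n <- x1 + x2
  if (n == 0) return(1)
  pr <- N1 / (N1 + N2)
  d_obs <- stats::dbinom(x1, n, pr)
  d_all <- stats::dbinom(0:n, n, pr)
  p <- sum(d_all[d_all <= d_obs * (1 + 1e-7)])
  min(1, max(p, .Machine$double.xmin))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1 and order-preserving.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

# Pseudocount in RPM units: half a read at the median library depth.
default_pseudocount <- function(lib_sizes) {
  1e6 * 0.5 / median(lib_sizes)
}

dms_record <- function(site_id, mean_rpm_a, mean_rpm_b, log2_fc, p, q,
                       significant, qualitative) {
  direction <- rep(NA_character_, length(site_id))
  dec <- significant & mean_rpm_b < mean_rpm_a
  inc <- significant & mean_rpm_b > mean_rpm_a
  direction[dec] <- "new_methylation"
  direction[inc] <- "demethylation"
  data.frame(site_id = site_id, mean_rpm_a = mean_rpm_a,
             mean_rpm_b = mean_rpm_b, log2_fc = log2_fc, p = p, q = q,
             significant = significant, direction = direction,
             qualitative = qualitative, stringsAsFactors = FALSE)
}

# Align two count tables on the union of their sites (zeros for absences).
align_tables <- function(tab_a, tab_b) {
  sites <- sort(union(rownames(tab_a$raw), rownames(tab_b$raw)))
  expand <- function(tab) {
    raw <- matrix(0L, nrow = length(sites), ncol = ncol(tab$raw),
                  dimnames = list(sites, colnames(tab$raw)))
    raw[rownames(tab$raw), ] <- tab$raw
    lib <- tab$lib_sizes
    if (is.null(lib)) lib <- colSums(tab$raw)
    list(raw = raw, lib = lib)
  }
  list(a = expand(tab_a), b = expand(tab_b), sites = sites)
}

#' Replicated differential methylation calling
#'
#' Within-group replicate counts are pooled (summed, with pooled library
#' sizes) and each site is tested with the exact conditional rate-ratio test;
#' q-values come from Benjamini-Hochberg and a site is significant at
#' q <= alpha. The fold change is reported as
#' log2((meanRPM_B + c) / (meanRPM_A + c)) with pseudocount c (in RPM units,
#' default half a read at the median library depth). Sites with zero counts
#' in both groups are excluded.
#'
#' @param tab_a,tab_b `site_count_table`s for conditions A (e.g. control) and
#'   B (e.g. stress), each with >= 2 replicate columns.
#' @param alpha Significance level on q (default 0.05).
#' @param pseudocount Pseudocount in RPM units (NULL = default rule).
#' @return Data frame of DMS records (see [call_dms_unreplicated()] for the
#'   columns); `direction` is `new_methylation` when abundance decreased from
#'   A to B, `demethylation` when it increased.
#' @export
call_dms_replicated <- function(tab_a, tab_b, alpha = 0.05, pseudocount = NULL) {
  stopifnot(inherits(tab_a, "site_count_table"), inherits(tab_b, "site_count_table"))
  if (ncol(tab_a$raw) < 2L || ncol(tab_b$raw) < 2L) {
    stop("replicated calling needs >= 2 replicates per group; ",
         "use call_dms_unreplicated() for single samples")
  }
  al <- align_tables(tab_a, tab_b)
  xa <- rowSums(al$a$raw)
  xb <- rowSums(al$b$raw)
  keep <- xa + xb > 0
  sites <- al$sites[keep]
  xa <- xa[keep]; xb <- xb[keep]
  Na <- sum(al$a$lib)
  Nb <- sum(al$b$lib)
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(c(al$a$lib, al$b$lib))
  rpm_a <- rowMeans(sweep(al$a$raw[keep, , drop = FALSE], 2L, al$a$lib,
                          function(x, n) x * 1e6 / n))
  rpm_b <- rowMeans(sweep(al$b$raw[keep, , drop = FALSE], 2L, al$b$lib,
                          function(x, n) x * 1e6 / n))
  p <- vapply(seq_along(sites), function(i)
    rate_ratio_test(xa[i], Na, xb[i], Nb), numeric(1))
  q <- bh_adjust(p)
  sig <- q <= alpha
  log2_fc <- log2((rpm_b + pseudocount) / (rpm_a + pseudocount))
  qualitative <- (xa == 0) != (xb == 0)
  dms_record(sites, rpm_a, rpm_b, log2_fc, p, q, sig, qualitative)
}

#' Unreplicated differential methylation calling (fold-change rule)
#'
#' For single samples per condition (e.g. pooled material), a site is called
#' differentially methylated when the pseudocounted RPM fold change between
#' the conditions is at least `fc_threshold` (protocol default 5) in either
#' direction. Sites detected in one condition and absent in the other are
#' additionally flagged qualitative (presence/absence events, as scored in
#' conventional gel-based MSAP).
#'
#' @param tab_a,tab_b Single-sample `site_count_table`s (condition A and B).
#' @param fc_threshold Minimum fold change (default 5).
#' @param pseudocount Pseudocount in RPM units (NULL = default rule).
#' @return Data frame: `site_id`, `mean_rpm_a`, `mean_rpm_b`, `log2_fc`
#'   (B over A), `p`/`q` (NA: no test), `significant`, `direction`,
#'   `qualitative`.
#' @export
call_dms_unreplicated <- function(tab_a, tab_b, fc_threshold = 5,
                                  pseudocount = NULL) {
  stopifnot(inherits(tab_a, "site_count_table"), inherits(tab_b, "site_count_table"))
  if (ncol(tab_a$raw) != 1L || ncol(tab_b$raw) != 1L) {
    stop("unreplicated calling expects exactly one sample per condition")
  }
  al <- align_tables(tab_a, tab_b)
  xa <- al$a$raw[, 1L]
  xb <- al$b$raw[, 1L]
  keep <- xa + xb > 0
  sites <- al$sites[keep]
  xa <- xa[keep]; xb <- xb[keep]
  if (is.null(pseudocount)) pseudocount <- default_pseudocount(c(al$a$lib, al$b$lib))
  rpm_a <- xa * 1e6 / al$a$lib
  rpm_b <- xb * 1e6 / al$b$lib
  fc <- pmax(rpm_a + pseudocount, rpm_b + pseudocount) /
    pmin(rpm_a + pseudocount, rpm_b + pseudocount)
  sig <- fc >= fc_threshold
  log2_fc <- log2((rpm_b + pseudocount) / (rpm_a + pseudocount))
  qualitative <- sig & ((xa == 0) != (xb == 0))
  rec <- dms_record(sites, rpm_a, rpm_b, log2_fc, rep(NA_real_, length(sites)),
                    rep(NA_real_, length(sites)), sig, qualitative)
  rec$fc <- fc
  rec
}

#' Direction of a significant methylation change
#'
#' Read abundance at a CCGG site is inversely related to its methylation:
#' a significant abundance decrease from condition A to B is a new
#' methylation, an increase a demethylation. Non-significant records get NA.
#'
#' @param records DMS data frame from a `call_dms_*` function.
#' @return Character vector of directions (`new_methylation`,
#'   `demethylation`, or NA).
#' @export
classify_direction <- function(records) {
  out <- rep(NA_character_, nrow(records))
  dec <- records$significant & records$mean_rpm_b < records$mean_rpm_a
  inc <- records$significant & records$mean_rpm_b > records$mean_rpm_a
  out[dec] <- "new_methylation"
  out[inc] <- "demethylation"
  out
}

#' Reversibility of stress-induced methylation changes
#'
#' For each site called differentially methylated between control and stress,
#' the change is reversible when the recovery condition is NOT distinguishable
#' from the control under the same caller and thresholds (abundance reverted
#' to its initial level), and irreversible otherwise. Sites absent from the
#' recovery table are treated as zero counts.
#'
#' @param tab_control,tab_stress,tab_recovery `site_count_table`s for the
#'   three conditions.
#' @param caller `"unreplicated"` or `"replicated"`.
#' @param ... Threshold arguments passed to the caller
#'   (`fc_threshold`/`alpha`, `pseudocount`).
#' @return Data frame: `site_id`, `stress_event` (direction of the
#'   control-vs-stress change), `recovery_class` (`reversible` or
#'   `irreversible`).
#' @export
classify_reversibility <- function(tab_control, tab_stress, tab_recovery,
                                   caller = c("unreplicated", "replicated"),
                                   ...) {
  caller <- match.arg(caller)
  call_fun <- if (caller == "unreplicated") call_dms_unreplicated else call_dms_replicated
  stress_dms <- call_fun(tab_control, tab_stress, ...)
  stress_dms <- stress_dms[stress_dms$significant, , drop = FALSE]
  if (nrow(stress_dms) == 0L) {
    return(data.frame(site_id = character(0), stress_event = character(0),
                      recovery_class = character(0)))
  }
  recovery_cmp <- call_fun(tab_control, tab_recovery, ...)
  still_changed <- recovery_cmp$site_id[recovery_cmp$significant]
  data.frame(
    site_id = stress_dms$site_id,
    stress_event = stress_dms$direction,
    recovery_class = ifelse(stress_dms$site_id %in% still_changed,
                            "irreversible", "reversible"),
    stringsAsFactors = FALSE
  )
}
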
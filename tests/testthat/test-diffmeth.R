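# Exhaustive-enumeration oracle for the conditional rate test, independent of
# the implementation: binomial coefficients on the log scale.
oracle_rate_p <- function(x1, N1, x2, N2) {
  n <- x1 + x2
  if (n == 0) return(1)
  pr <- N1 / (N1 + N2)
  logd <- function(k) lchoose(n, k) + k * log(pr) + (n - k) * log(1 - pr)
  d_obs <- exp(logd(x1))
  d_all <- exp(vapply(0:n, logd, numeric(1)))
  min(1, sum(d_all[d_all <= d_obs * (1 + 1e-7)]))
}

test_that("the exact conditional test matches enumeration and binom.test", {
  expect_equal(rate_ratio_test(10, 1e6, 10, 1e6), 1)
  expect_equal(rate_ratio_test(0, 1e6, 20, 1e6), 2 * 0.5^20, tolerance = 1e-12)
  expect_equal(rate_ratio_test(0, 1, 0, 1), 1)

  set.seed(19)
  for (i in 1:60) {
    n <- sample(0:50, 1)
    x1 <- if (n > 0) sample(0:n, 1) else 0
    x2 <- n - x1
    N1 <- sample(1e4:1e6, 1)
    N2 <- sample(1e4:1e6, 1)
    p_pkg <- rate_ratio_test(x1, N1, x2, N2)
    expect_equal(p_pkg, oracle_rate_p(x1, N1, x2, N2), tolerance = 1e-12)
    if (n > 0) {
      p_bt <- binom.test(x1, n, N1 / (N1 + N2))$p.value
      expect_equal(p_pkg, p_bt, tolerance = 1e-12)
    }
  }
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")

  step_up_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- p[o] * m / seq_len(m)
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m)
    q[o] <- pmin(1, q_sorted)
    q
  }
  set.seed(29)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), step_up_oracle(p), tolerance = 1e-12)
  }
})

test_that("identical groups yield no significant sites", {
  tabs <- make_count_tables(200, 3, 30, seed = 41)
  res <- call_dms_replicated(tabs$a, tabs$a)
  expect_identical(sum(res$significant), 0L)
})

test_that("group-label swap negates log2 FC and keeps p", {
  tabs <- make_count_tables(150, 3, 30, spike_idx = 1:10, spike_fold = 6,
                            seed = 43)
  ab <- call_dms_replicated(tabs$a, tabs$b)
  ba <- call_dms_replicated(tabs$b, tabs$a)
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p, ba$p)
  flip <- c(new_methylation = "demethylation", demethylation = "new_methylation")
  expect_identical(unname(flip[ab$direction]), ba$direction)
})

test_that("sites with zero counts in both groups are excluded", {
  ids <- c("c1:1", "c1:5", "c1:9")
  mk <- function(x) site_count_table(matrix(as.integer(x), 3, 2,
                                            dimnames = list(ids, c("r1", "r2"))),
                                     lib_sizes = c(r1 = 100, r2 = 100))
  res <- call_dms_replicated(mk(c(5, 0, 3, 5, 0, 3)), mk(c(2, 0, 9, 2, 0, 9)))
  expect_false("c1:5" %in% res$site_id)
})

test_that("the unreplicated rule reproduces the worked fold-change examples", {
  mk <- function(x, s) site_count_table(
    matrix(as.integer(x), length(x), 1,
           dimnames = list(sprintf("c1:%d", seq_along(x) * 4L), s)),
    lib_sizes = setNames(1e6, s))
  ta <- mk(c(100, 100, 0), "ctrl")
  tb <- mk(c(610, 450, 12), "strs")
  res <- call_dms_unreplicated(ta, tb, pseudocount = 1e-4)
  r <- function(site) res[res$site_id == site, ]
  expect_true(r("c1:4")$significant)       # 100 vs 610: FC 6.1 >= 5
  expect_equal(r("c1:4")$fc, 6.1, tolerance = 1e-5)
  expect_false(r("c1:8")$significant)      # 100 vs 450: FC 4.5 < 5
  expect_true(r("c1:12")$significant)      # 0 vs 12: presence/absence
  expect_true(r("c1:12")$qualitative)
  expect_identical(r("c1:12")$direction, "demethylation")
})

test_that("the unreplicated rule is scale invariant", {
  mk <- function(x, s, k) site_count_table(
    matrix(as.integer(x * k), length(x), 1,
           dimnames = list(sprintf("c1:%d", seq_along(x) * 4L), s)))
  x_a <- c(20, 30, 1, 50, 8)
  x_b <- c(20, 6, 14, 49, 44)
  r1 <- call_dms_unreplicated(mk(x_a, "a", 1), mk(x_b, "b", 1), pseudocount = 0.01)
  r5 <- call_dms_unreplicated(mk(x_a, "a", 5), mk(x_b, "b", 5), pseudocount = 0.01)
  expect_identical(r1$significant, r5$significant)
  expect_equal(r1$fc, r5$fc, tolerance = 1e-9)
})

test_that("direction follows the abundance-methylation inversion", {
  rec <- data.frame(significant = c(TRUE, TRUE, FALSE),
                    mean_rpm_a = c(100, 10, 50),
                    mean_rpm_b = c(10, 100, 50))
  expect_identical(classify_direction(rec),
                   c("new_methylation", "demethylation", NA))
})

test_that("reversibility compares recovery against control with the same rule", {
  mk <- function(x, s) site_count_table(
    matrix(as.integer(x), length(x), 1,
           dimnames = list(c("c1:4", "c1:8", "c1:12"), s)),
    lib_sizes = setNames(1e6, s))
  ctrl <- mk(c(100, 100, 100), "ctrl")
  strs <- mk(c(10, 10, 100), "strs")
  recv <- mk(c(95, 12, 100), "recv")
  calls <- classify_reversibility(ctrl, strs, recv, caller = "unreplicated",
                                  pseudocount = 1e-4)
  expect_identical(calls$stress_event, c("new_methylation", "new_methylation"))
  expect_identical(calls$recovery_class[calls$site_id == "c1:4"], "reversible")
  expect_identical(calls$recovery_class[calls$site_id == "c1:8"], "irreversible")
  expect_false("c1:12" %in% calls$site_id)  # flat trajectory: no call

  # a site absent from the recovery table counts as zero there
  recv2 <- site_count_table(
    matrix(c(95L, 12L), 2, 1, dimnames = list(c("c1:4", "c1:8"), "recv")),
    lib_sizes = c(recv = 1e6))
  calls2 <- classify_reversibility(ctrl, strs, recv2, caller = "unreplicated",
                                   pseudocount = 1e-4)
  expect_identical(nrow(calls2), 2L)
})

test_that("replicated calling recovers strong spiked methylation gains", {
  # spikes modeled as methylation gains (8-fold abundance LOSS), the event
  # class the assay was validated on; gains also keep the library-mass shift
  # small so total-count library sizes stay interpretable
  n_sites <- 400
  spike <- 1:20
  tabs <- make_count_tables(n_sites, 3, 30, spike_idx = spike,
                            spike_fold = 1 / 8, seed = 47)
  res <- call_dms_replicated(tabs$a, tabs$b, alpha = 0.05)
  called <- which(res$site_id %in% sprintf("c1:%d", spike * 10L) & res$significant)
  sens <- length(called) / length(spike)
  expect_gte(sens, 0.9)
  false_pos <- sum(res$significant) - length(called)
  expect_lte(false_pos / max(1, sum(res$significant)), 0.1)
  # spiked sites lost reads: called as new methylation
  expect_true(all(res$direction[res$significant &
                                  res$site_id %in% sprintf("c1:%d", spike * 10L)] ==
                    "new_methylation"))
})
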
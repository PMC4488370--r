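test_that("make_windows tiles contigs per the stated rules", {
  asm <- genome_assembly(c("c1", "c2"), c(10000, 1500))
  w <- make_windows(asm, 2000, 1000)
  w1 <- w[w$contig == "c1", ]
  expect_equal(nrow(w1), 9)
  expect_equal(w1$start, seq(0, 8000, by = 1000))
  # step = window -> non-overlapping tiling
  wt <- make_windows(genome_assembly("c", 10000), 2000, 2000)
  expect_equal(wt$start, seq(0, 8000, by = 2000))
  expect_true(all(wt$end - wt$start == 2000))
  # contig shorter than a window -> one truncated window
  w2 <- w[w$contig == "c2", ]
  expect_equal(nrow(w2), 1)
  expect_equal(c(w2$start, w2$end), c(0, 1500))
  expect_error(make_windows(asm, 0, 1), "window_size")
  expect_error(make_windows(asm, 100, 200), "step")
})

test_that("window_test matches the enumeration oracle and the stated examples", {
  N <- 1e6
  r <- window_test(10, 10, N, N)
  expect_equal(r$log2_fc, 0)
  expect_equal(r$p_value, 1)
  r2 <- window_test(10, 40, N, N)
  expect_equal(r2$log2_fc, log2(40.5 / 10.5))
  expect_equal(r2$p_value, oracle_binom_p(40, 50, 0.5), tolerance = 1e-12)
  r3 <- window_test(20, 0, N, N)
  expect_equal(r3$log2_fc, log2(0.5 / 20.5))
  expect_equal(r3$p_value, oracle_binom_p(0, 20, 0.5), tolerance = 1e-12)
  # unequal totals
  r4 <- window_test(30, 12, 2e6, 1e6)
  expect_equal(r4$p_value, oracle_binom_p(12, 42, 1 / 3), tolerance = 1e-12)
  # n = 0 flags no-data
  r0 <- window_test(0, 0, N, N)
  expect_true(r0$no_data)
  expect_equal(c(r0$p_value, r0$log2_fc), c(1, 0))
})

test_that("window_test equals exhaustive enumeration for all n <= 200", {
  q <- 1 / 3
  ks <- integer(0); ns <- integer(0)
  for (n in 1:200) { ks <- c(ks, 0:n); ns <- c(ns, rep(n, n + 1)) }
  got <- window_test(ns - ks, ks, 2e6, 1e6)$p_value
  want <- vapply(seq_along(ks), function(i) oracle_binom_p(ks[i], ns[i], q), 0)
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("apply_thresholds implements the published cutoff semantics", {
  pol <- paper_threshold_policies()
  rs5410_dup <- pol[pol$strain == "RS5410" & pol$sv_type == "duplication", ]
  rs5200_del <- pol[pol$strain == "RS5200" & pol$sv_type == "deletion", ]
  stats <- data.frame(contig = "c", start = 0, end = 1,
                      log2_fc = c(1.2, 1.2, -1.7),
                      p_value = c(1e-20, 1e-10, 1e-6))
  expect_equal(nrow(apply_thresholds(stats[1, ], rs5410_dup)), 1)
  expect_equal(nrow(apply_thresholds(stats[2, ], rs5410_dup)), 0)
  expect_equal(nrow(apply_thresholds(stats[3, ], rs5200_del)), 1)
  expect_error(threshold_policy("s", "deletion", 1.5, 1e-5), "fc_cutoff < 0")
})

test_that("merge_calls unions bookended windows and enforces the size floor", {
  win <- data.frame(contig = "c1", start = c(0, 1000), end = c(2000, 3000),
                    log2_fc = c(1, 1.4), p_value = c(1e-20, 1e-18))
  m <- merge_calls(win, "duplication")
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(0, 3000))
  expect_equal(m$min_p, 1e-20)
  expect_equal(m$mean_log2_fc, 1.2)
  # different types never merge (they are merged per type by call_svs)
  del <- data.frame(contig = "c1", start = 5000, end = 7000,
                    log2_fc = -2, p_value = 1e-8)
  both <- rbind(merge_calls(win, "duplication"), merge_calls(del, "deletion"))
  expect_equal(nrow(both), 2)
  expect_setequal(both$sv_type, c("deletion", "duplication"))
  # sub-threshold span dropped
  short <- data.frame(contig = "c1", start = 0, end = 1800,
                      log2_fc = 1, p_value = 1e-20)
  expect_equal(nrow(merge_calls(short, "duplication")), 0)
  # non-bookended windows stay separate
  apart <- data.frame(contig = "c1", start = c(0, 5000),
                      end = c(2500, 8000), log2_fc = 1, p_value = 1e-20)
  expect_equal(nrow(merge_calls(apart, "duplication")), 2)
  # disjointness invariant
  m2 <- merge_calls(apart, "duplication")
  expect_true(all(m2$start[-1] >= m2$end[-nrow(m2)]))
})

test_that("roc_curve computes rates and handles the stated cases", {
  lab <- data.frame(min_p = c(1e-20, 1e-20, 1e-3, 1e-3),
                    mean_log2_fc = c(2, 2, 2, 2),
                    label = c("true_positive", "true_positive",
                              "false_positive", "false_positive"))
  roc <- roc_curve(lab, p_grid = 1e-5, fc_grid = 1, sv_type = "duplication")
  expect_equal(c(roc$tpr, roc$fpr), c(1, 0))
  roc_all <- roc_curve(lab, p_grid = 1, fc_grid = 0.1,
                       sv_type = "duplication")
  expect_equal(c(roc_all$tpr, roc_all$fpr), c(1, 1))
  expect_error(roc_curve(lab[1:2, ], 1e-5, 1, "duplication"), "both")
})

test_that("random labels give ROC area near 0.5", {
  withr::with_seed(99, {
    n <- 1000
    lab <- data.frame(min_p = 10^-runif(n, 0, 30), mean_log2_fc = 2,
                      label = sample(c("true_positive", "false_positive"),
                                     n, replace = TRUE))
    roc <- roc_curve(lab, p_grid = 10^-(seq(0, 30, by = 1)), fc_grid = 1,
                     sv_type = "duplication")
    roc <- roc[order(roc$fpr, roc$tpr), ]
    auc <- sum(diff(c(0, roc$fpr)) * (roc$tpr + c(0, head(roc$tpr, -1))) / 2)
    expect_lt(abs(auc - 0.5), 0.06)  # ~3 x Monte-Carlo SE for n = 1000
  })
})

test_that("pick_operating_point maximizes TPR under the FPR cap with stated tie-breaks", {
  roc <- data.frame(p_cutoff = c(1e-10, 1e-3, 1e-5, 1e-7),
                    fc_cutoff = 1,
                    tpr = c(0.83, 0.9, 0.8, 0.8),
                    fpr = c(0.02, 0.1, 0.04, 0.04))
  pol <- pick_operating_point(roc, 0.05, "s", "duplication")
  expect_equal(pol$p_cutoff, 1e-10)   # 0.83 is the best under the cap
  pol2 <- pick_operating_point(roc, 1.0, "s", "duplication")
  expect_equal(pol2$p_cutoff, 1e-3)   # global max TPR
  # tie on tpr and fpr -> smaller p_cutoff
  pol3 <- pick_operating_point(roc[3:4, ], 0.05, "s", "duplication")
  expect_equal(pol3$p_cutoff, 1e-7)
  expect_error(pick_operating_point(roc, 0.001, "s", "duplication"),
               "max_fpr")
})

test_that("genome_fraction reports signed union fractions per 100kb window", {
  asm <- genome_assembly("c1", 3e5)
  calls <- sv_calls(c("c1", "c1", "c1"),
                    c(10000, 0, 20000), c(35000, 30000, 50000),
                    c("duplication", "deletion", "deletion"))
  gf <- genome_fraction(calls, asm)
  expect_equal(nrow(gf), 3)
  expect_equal(gf$frac_duplicated[1], 0.25)
  # union of [0,30k) and [20k,50k) is 50kb
  expect_equal(gf$frac_deleted[1], -0.5)
  expect_equal(gf$frac_deleted[2], 0)
  gf0 <- genome_fraction(calls[0, ], asm)
  expect_true(all(gf0$frac_deleted == 0 & gf0$frac_duplicated == 0))
})

test_that("null windows keep the exact test conservative at alpha = 0.01", {
  # 1e5 windows at equal rates; exact-test discreteness may undershoot
  withr::with_seed(12, {
    n <- 1e5
    lam <- 320  # 16X, 2 kb windows, 100 bp reads
    x <- rpois(n, lam); y <- rpois(n, lam)
    p <- window_test(x, y, 1e6, 1e6)$p_value
    alpha <- 0.01
    se <- sqrt(alpha * (1 - alpha) / n)
    expect_lte(mean(p < alpha), alpha + 3 * se)
  })
})
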
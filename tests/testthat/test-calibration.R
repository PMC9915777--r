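test_that("threshold calls use strict inequalities and direction", {
  tab <- toy_calibration_table()
  th <- threshold_pair(ddg_threshold = 1.8)
  # exactly at the threshold is a negative call
  at <- variant_table("G", "p.A1V", "P", ddg_fold = 1.8, cadd = 30)
  expect_false(classify_call(at, th))
  expect_true(classify_call(
    variant_table("G", "p.A1V", "P", ddg_fold = 2.5, cadd = 26),
    threshold_pair(1.8, 25.7)))
  # overstabilizing direction mirrors the threshold
  over <- threshold_pair(ddg_threshold = 1.8,
                         direction = "overstabilizing")
  expect_true(classify_call(
    variant_table("G", "p.A1V", "P", ddg_fold = -2.5), over))
  expect_false(classify_call(
    variant_table("G", "p.A1V", "P", ddg_fold = 2.5), over))
  expect_error(threshold_pair(), "at least one")
  expect_error(classify_call(
    variant_table("G", "p.A1V", "P"), th), "missing")
})

test_that("confusion counts match hand enumeration on the toy set", {
  tab <- toy_calibration_table()
  s <- confusion_at(tab, threshold_pair(1.8))
  expect_equal(c(s$tp, s$fp, s$tn, s$fn), c(2, 1, 3, 2))
  expect_equal(s$ppv, 2 / 3)
  expect_equal(s$specificity, 3 / 4)
  expect_equal(s$sensitivity, 2 / 4)

  # thresholds above every score call nothing; PPV is undefined
  s2 <- confusion_at(tab, threshold_pair(10))
  expect_equal(s2$n_called, 0)
  expect_true(is.na(s2$ppv))

  # no negative-label records at all
  expect_error(confusion_at(tab[tab$classification == "P", ],
                            threshold_pair(1.8)), "specificity")
})

test_that("the reconstructed joint-threshold counts give 99.0% PPV", {
  # 793 true and 8 false positive calls reproduce the printed joint PPV
  expect_equal(round(100 * 793 / (793 + 8), 1), 99.0)
  # as a confusion summary over a table built to those margins
  n_pos <- 1000; n_neg <- 1600
  tab <- variant_table(
    gene = "X", protein_change = sprintf("p.Ala%dVal", 1:(n_pos + n_neg)),
    classification = c(rep("P", n_pos), rep("B", n_neg)),
    ddg_fold = c(rep(2.5, 793), rep(0.5, n_pos - 793),
                 rep(2.5, 8), rep(0.5, n_neg - 8)),
    cadd = 30)
  s <- confusion_at(tab, threshold_pair(1.8, 25.7))
  expect_equal(c(s$tp, s$fp), c(793, 8))
  expect_equal(round(100 * s$ppv, 1), 99.0)
})

test_that("counts are conserved for every threshold pair", {
  tab <- generate_variant_table(generator_config(5000, seed = 3))
  n_pb <- sum(tab$classification %in% c("P", "B") &
                !is.na(tab$ddg_fold) & !is.na(tab$cadd))
  for (th in list(threshold_pair(0.5), threshold_pair(1.8, 25.7),
                  threshold_pair(1.8, direction = "overstabilizing"),
                  threshold_pair(cadd_threshold = 20))) {
    s <- confusion_at(tab, th)
    expect_equal(s$tp + s$fp + s$tn + s$fn,
                 if (is.null(th$ddg_threshold)) {
                   sum(tab$classification %in% c("P", "B") &
                         !is.na(tab$cadd))
                 } else if (is.null(th$cadd_threshold)) {
                   sum(tab$classification %in% c("P", "B") &
                         !is.na(tab$ddg_fold))
                 } else n_pb)
  }
})

test_that("records missing required scores are excluded and counted", {
  tab <- toy_calibration_table()
  tab$cadd[1] <- NA          # a P record missing CADD
  s <- confusion_at(tab, threshold_pair(1.8, 15))
  expect_equal(s$n_excluded_missing, 1)
  expect_equal(s$tp + s$fn, 3)
  # ddG-only threshold still uses it
  s2 <- confusion_at(tab, threshold_pair(1.8))
  expect_equal(s2$n_excluded_missing, 0)
})

test_that("CADD search returns the smallest candidate reaching the target", {
  # constructed so candidate grid {10, 20, 30} gives PPV {0.5, 0.8, 1.0}:
  # all records pass ddG; cadd > 10 keeps 4P+4B... build directly
  tab <- variant_table(
    gene = "G", protein_change = sprintf("p.Ala%dVal", 1:12),
    classification = c(rep("P", 8), rep("B", 4)),
    ddg_fold = 2.5,
    cadd = c(40, 40, 40, 40, 25, 25, 25, 25, 25, 25, 15, 15))
  # candidates {15, 25, 40}: >15 -> 8P/2B (0.8); >25 -> 4P/0B (1.0)
  thr <- find_cadd_threshold(tab, 1.8, 0.9)
  expect_equal(as.numeric(thr), 25)
  expect_equal(attr(thr, "ppv"), 1.0)
  # an easy target is met by the smallest candidate
  thr0 <- find_cadd_threshold(tab, 1.8, 0.05)
  expect_equal(as.numeric(thr0), 15)
  # an unachievable target reports the best attainable PPV
  tab$classification <- rep(c("P", "B"), 6)
  tab$cadd <- rep(20, 12)
  expect_error(find_cadd_threshold(tab, 1.8, 0.99), "unachievable")
})

test_that("CADD search equals the brute-force scan on synthetic data", {
  tab <- generate_variant_table(generator_config(20000, seed = 7))
  target <- 0.99
  thr <- find_cadd_threshold(tab, 1.8, target)

  # brute force over the full candidate grid, independent of the search
  use <- tab[tab$classification %in% c("P", "B") &
               !is.na(tab$ddg_fold) & !is.na(tab$cadd), ]
  pos <- use$classification == "P"
  pass <- use$ddg_fold > 1.8
  cand <- sort(unique(use$cadd))
  ppvs <- vapply(cand, function(c) {
    tp <- sum(pass & use$cadd > c & pos)
    fp <- sum(pass & use$cadd > c & !pos)
    if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  }, numeric(1))
  achieving <- cand[!is.na(ppvs) & ppvs >= target]
  expect_equal(as.numeric(thr), min(achieving))

  # definitional property: the next-smaller candidate misses the target
  smaller <- cand[cand < as.numeric(thr)]
  if (length(smaller) > 0) {
    prev <- ppvs[match(max(smaller), cand)]
    expect_lt(prev, target)
  }
})

test_that("the calibrated threshold is monotone in the target PPV", {
  tab <- generate_variant_table(generator_config(20000, seed = 5))
  thrs <- vapply(c(0.90, 0.95, 0.99), function(t) {
    as.numeric(find_cadd_threshold(tab, 1.8, t))
  }, numeric(1))
  expect_true(all(diff(thrs) >= 0))
})

test_that("ppv_curve rows agree with confusion_at and order", {
  tab <- toy_calibration_table()
  grid <- list(threshold_pair(0.5), threshold_pair(1.8))
  curve <- ppv_curve(tab, grid)
  expect_equal(nrow(curve), 2)
  # hand enumeration: ddG > 0.5 calls P {2.5, 2.0, 1.0} and B {1.9};
  # ddG > 1.8 calls P {2.5, 2.0} and B {1.9}
  expect_equal(curve$ppv, c(3 / 4, 2 / 3))
  expect_equal(curve$n_called, c(4, 3))
  one <- ppv_curve(tab, grid[2])
  s <- confusion_at(tab, grid[[2]])
  expect_equal(one$ppv, s$ppv)
  expect_equal(one$n_called, s$n_called)
})

test_that("the called set shrinks as the ddG threshold rises", {
  tab <- generate_variant_table(generator_config(10000, seed = 9))
  grid <- lapply(seq(0.5, 3, by = 0.5), threshold_pair)
  curve <- ppv_curve(tab, grid)
  expect_true(all(diff(curve$n_called) <= 0))
})

test_that("overstabilizing calibration mirrors the negative tail", {
  set.seed(2)
  n <- 400
  tab <- variant_table(
    gene = "G", protein_change = sprintf("p.Ala%dVal", 1:n),
    classification = rep(c("P", "B"), each = n / 2),
    ddg_fold = c(rnorm(n / 2, -1, 1.2), rnorm(n / 2, 0, 0.5)),
    cadd = 20)
  s <- confusion_at(tab, threshold_pair(1.8,
                                        direction = "overstabilizing"))
  manual_tp <- sum(tab$ddg_fold < -1.8 & tab$classification == "P")
  manual_fp <- sum(tab$ddg_fold < -1.8 & tab$classification == "B")
  expect_equal(c(s$tp, s$fp), c(manual_tp, manual_fp))
})
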
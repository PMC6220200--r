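loop_confusion <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1) fp <- fp + 1L
    else if (gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

test_that("confusion counts match a per-voxel loop oracle", {
  for (s in 1:10) {
    pred <- random_mask(c(8, 8, 8), p = 0.4, seed = s)
    gt <- random_mask(c(8, 8, 8), p = 0.4, seed = s + 100)
    cc <- confusion(pred, gt)
    oc <- loop_confusion(as.numeric(pred$data), as.numeric(gt$data))
    expect_identical(cc$TP, oc$TP); expect_identical(cc$FP, oc$FP)
    expect_identical(cc$FN, oc$FN); expect_identical(cc$TN, oc$TN)
    expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 512)
  }
  same <- random_mask(c(4, 4, 4), seed = 1)
  cc <- confusion(same, same)
  expect_identical(cc$FP + cc$FN, 0L)
  inv <- same; inv$data <- 1 - inv$data
  cc2 <- confusion(same, inv)
  expect_identical(cc2$TP + cc2$TN, 0L)
  expect_error(confusion(same, random_mask(c(5, 4, 4), seed = 2)), "aligned")
})

test_that("overlap metrics follow their defining formulas", {
  cc <- structure(list(TP = 3L, FP = 1L, FN = 2L, TN = 10L),
                  class = "confusion_counts")
  expect_equal(dsc(cc), 6 / 9)
  expect_equal(recall(structure(list(TP = 3L, FP = 0L, FN = 1L, TN = 0L),
                                class = "confusion_counts")), 0.75)
  expect_equal(precision(cc), 3 / 4)
  expect_equal(specificity(cc), 10 / 11)

  perfect <- random_mask(c(6, 6, 6), p = 0.5, seed = 3)
  pc <- confusion(perfect, perfect)
  expect_equal(dsc(pc), 1)
  expect_equal(recall(pc), 1)
  expect_equal(precision(pc), 1)
  expect_equal(specificity(pc), 1)

  a <- array(0, c(4, 4, 1)); a[1, 1, 1] <- 1
  b <- array(0, c(4, 4, 1)); b[4, 4, 1] <- 1
  expect_equal(dsc(confusion(label_mask(a), label_mask(b))), 0)

  expect_warning(d1 <- dsc(confusion(label_mask(array(0, c(2, 2, 2))),
                                     label_mask(array(0, c(2, 2, 2))))),
                 "convention")
  expect_equal(d1, 1)
  expect_warning(precision(confusion(label_mask(array(0, c(2, 2, 2))),
                                     label_mask(array(1, c(2, 2, 2)) * 0 + 1))),
                 "zero denominator")
})

test_that("DSC is the harmonic mean of precision and recall", {
  set.seed(17)
  for (i in 1:20) {
    cc <- structure(as.list(setNames(as.integer(rmultinom(1, 500,
                                                          c(.3, .2, .2, .3))),
                                     c("TP", "FP", "FN", "TN"))),
                    class = "confusion_counts")
    if (cc$TP == 0) next
    p <- precision(cc); r <- recall(cc)
    expect_equal(dsc(cc), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("overlap metrics are invariant under joint voxel permutation", {
  pred <- random_mask(c(6, 6, 6), seed = 4)
  gt <- random_mask(c(6, 6, 6), seed = 5)
  set.seed(6)
  perm <- sample(216)
  pp <- label_mask(array(pred$data[perm], c(6, 6, 6)))
  gp <- label_mask(array(gt$data[perm], c(6, 6, 6)))
  expect_equal(dsc(confusion(pp, gp)), dsc(confusion(pred, gt)))
  expect_equal(precision(confusion(pp, gp)), precision(confusion(pred, gt)))
})

test_that("surface voxels use 6-adjacency with out-of-grid background", {
  one <- array(0, c(5, 5, 5)); one[3, 3, 3] <- 1
  sv <- surface_voxels(label_mask(one))
  expect_identical(nrow(sv$index), 1L)
  expect_equal(as.integer(sv$index[1, ]), c(3L, 3L, 3L))

  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(surface_voxels(label_mask(cube))$index), 26L)

  slab <- array(1, c(4, 4, 2))                  # spans the whole grid
  expect_identical(nrow(surface_voxels(label_mask(slab))$index), 32L)
  expect_error(surface_voxels(label_mask(array(0, c(3, 3, 3)))), "empty")
})

brute_dists <- function(s, g) {
  apply(s, 1, function(v) sqrt(min(colSums((t(g) - v)^2))))
}

test_that("surface distances match the all-pairs brute-force oracle", {
  m1 <- array(0, c(8, 8, 3)); m1[2, 2, 2] <- 1
  m2 <- array(0, c(8, 8, 3)); m2[4, 2, 2] <- 1
  sp <- c(0.5, 0.5, 1.5)
  expect_equal(asd(label_mask(m1, sp), label_mask(m2, sp)), 1.0)
  expect_equal(msd(label_mask(m1, sp), label_mask(m2, sp)), 1.0)

  for (s in 1:8) {
    pred <- random_mask(c(7, 6, 5), p = 0.25, seed = s,
                        spacing = c(0.7, 1.1, 1.9))
    gt <- random_mask(c(7, 6, 5), p = 0.25, seed = s + 50,
                      spacing = c(0.7, 1.1, 1.9))
    if (!any(pred$data == 1) || !any(gt$data == 1)) next
    sv <- surface_voxels(pred)$mm
    gv <- surface_voxels(gt)$mm
    dsg <- brute_dists(sv, gv)
    dgs <- brute_dists(gv, sv)
    expect_equal(asd(pred, gt),
                 (sum(dsg) + sum(dgs)) / (length(dsg) + length(dgs)),
                 tolerance = 1e-9)
    expect_equal(msd(pred, gt), max(max(dsg), max(dgs)), tolerance = 1e-9)
    # symmetry and max >= mean
    expect_equal(asd(gt, pred), asd(pred, gt), tolerance = 1e-12)
    expect_equal(msd(gt, pred), msd(pred, gt), tolerance = 1e-12)
    expect_gte(msd(pred, gt), asd(pred, gt))
  }

  same <- random_mask(c(6, 6, 4), seed = 2)
  expect_equal(asd(same, same), 0)
  expect_equal(msd(same, same), 0)
  expect_warning(asd(same, label_mask(array(0, c(6, 6, 4)))), "empty")
})

test_that("scaling the spacing scales surface distances linearly", {
  pred <- random_mask(c(6, 6, 4), p = 0.3, seed = 7)
  gt <- random_mask(c(6, 6, 4), p = 0.3, seed = 8)
  scale <- function(m, c) label_mask(m$data, m$spacing * c)
  expect_equal(asd(scale(pred, 3), scale(gt, 3)), 3 * asd(pred, gt),
               tolerance = 1e-12)
  expect_equal(msd(scale(pred, 3), scale(gt, 3)), 3 * msd(pred, gt),
               tolerance = 1e-12)
})

test_that("curves attain their closed-form areas and invariants", {
  lab <- array(rbinom(1000, 1, 0.4), c(10, 10, 10))
  cv <- curves(probability_map(lab), label_mask(lab))
  expect_equal(cv$roc$area, 1)
  expect_equal(cv$prc$area, 1)

  set.seed(9)
  n <- 1e5
  labs <- array(rbinom(n, 1, 0.5), c(100, 100, 10))
  rnd <- curves(probability_map(array(runif(n), dim(labs))),
                label_mask(labs))
  expect_lt(abs(rnd$roc$area - 0.5), 0.01)

  # recall non-increasing and FPR non-increasing as the threshold rises
  expect_true(all(diff(rnd$roc$recall) >= 0))       # listed descending t
  expect_true(all(diff(rnd$roc$fpr) >= 0))
  expect_true(rnd$roc$area >= 0 && rnd$roc$area <= 1)

  expect_error(curves(probability_map(array(0.5, c(2, 2, 2))),
                      label_mask(array(1, c(2, 2, 2)))), "single class")
})

test_that("a six-voxel PRC example matches the hand-stepped sum", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  labels <- c(1, 1, 0, 1, 0, 0)
  p <- probability_map(array(scores, c(6, 1, 1)))
  g <- label_mask(array(labels, c(6, 1, 1)))
  ap <- curves(p, g)$prc$area
  # thresholds 0.9..0.4 descending; at each, pred = scores > t:
  # R: 0, 1/3, 2/3, 2/3, 1, 1, 1;  P: -, 1, 1, 2/3, 3/4, 3/5, 1/2
  hand <- (1 / 3) * 1 + (1 / 3) * 1 + 0 + (1 / 3) * (3 / 4) + 0 + 0
  expect_equal(ap, hand, tolerance = 1e-12)
})

test_that("AP and AUC are invariant under strictly monotone transforms", {
  set.seed(10)
  labs <- array(rbinom(500, 1, 0.3), c(500, 1, 1))
  sc <- array(runif(500), c(500, 1, 1))
  a <- curves(probability_map(sc), label_mask(labs))
  b <- curves(probability_map(sc^3), label_mask(labs))
  expect_equal(a$roc$area, b$roc$area, tolerance = 1e-12)
  expect_equal(a$prc$area, b$prc$area, tolerance = 1e-12)
})

test_that("the PRC operating point minimizes distance to (P, R) = (1, 1)", {
  lab <- array(rbinom(400, 1, 0.3), c(400, 1, 1))
  cv <- curves(probability_map(lab), label_mask(lab))
  t <- optimal_threshold(cv$prc)
  expect_equal(cv$prc$precision[cv$prc$recall == 1 &
                                  !is.na(cv$prc$precision)][1], 1)
  cc <- confusion(binarize(probability_map(lab), t), label_mask(lab))
  expect_equal(precision(cc), 1)
  expect_equal(recall(cc), 1)

  # argmin agrees with an exhaustive scan on random curves
  set.seed(11)
  for (i in 1:20) {
    labs <- array(rbinom(300, 1, 0.4), c(300, 1, 1))
    sc <- array(pmin(pmax(runif(300) * 0.5 + labs * runif(300) * 0.5,
                          0), 1), c(300, 1, 1))
    prc <- curves(probability_map(sc), label_mask(labs))$prc
    t <- optimal_threshold(prc)
    ok <- !is.na(prc$precision)
    d2 <- (1 - prc$precision[ok])^2 + (1 - prc$recall[ok])^2
    best <- min(d2)
    chosen <- which(ok)[which(pmax(prc$thresholds[ok], 0) == t)]
    d_chosen <- min((1 - prc$precision[chosen])^2 +
                      (1 - prc$recall[chosen])^2)
    expect_lt(d_chosen - best, 1e-12)
    # tie-break: no candidate at the minimum has a lower threshold
    cand <- pmax(prc$thresholds[ok][d2 <= best + 1e-15], 0)
    expect_equal(t, min(cand))
  }
})

test_that("Wilcoxon signed-rank matches exact and approximate oracles", {
  # n = 6, all-positive differences: exact two-sided p = 2/64
  expect_equal(femurseg:::wilcoxon_signed_rank(11:16, rep(10, 6)), 2 / 64)
  # agreement with stats::wilcox.test in the exact regime
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    ours <- femurseg:::wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # tied/large samples: normal approximation with tie + continuity
  # correction, as implemented by stats::wilcox.test
  x <- rep(c(1, 2, 3, 4), 8); y <- rep(c(2, 1, 1, 6), 8)
  ours <- femurseg:::wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                             exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_warning(p1 <- femurseg:::wilcoxon_signed_rank(1:6, 1:6),
                 "all differences zero")
  expect_equal(p1, 1)
})

test_that("Holm adjustment matches the hand-stepped max formula", {
  praw <- c(0.040, 0.010, 0.030)
  # hand-stepped: adjusted p_(i) = max_{j <= i} (m - j + 1) p_(j), capped at 1
  adj_hand <- numeric(3)
  ord <- order(praw)
  running <- 0
  for (k in seq_along(ord)) {
    running <- max(running, (3 - k + 1) * praw[ord[k]])
    adj_hand[ord[k]] <- min(1, running)
  }
  expect_equal(stats::p.adjust(praw, "holm"), adj_hand)

  set.seed(13)
  scores <- matrix(rnorm(8 * 3, mean = rep(c(0, 0.5, 2), each = 8)), 8, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  res <- wilcoxon_holm(scores)
  expect_identical(dim(res$p_holm), c(3L, 3L))
  expect_true(all(res$p_holm >= res$p_raw, na.rm = TRUE))
  expect_true(all(res$codes[upper.tri(res$codes)] %in%
                    c("ns", "*", "**", "***")))
  # a model compared to itself (identical columns) gives p = 1
  dup <- cbind(scores, a2 = scores[, "a"])
  expect_warning(res2 <- wilcoxon_holm(dup), "all differences zero")
  expect_equal(res2$p_raw["a", "a2"], 1)
  expect_error(wilcoxon_holm(scores[1:4, ]), "at least 6")
  expect_error(wilcoxon_holm(scores[, 1, drop = FALSE]), "at least 2")
})

test_that("subject reports compose the individual metrics", {
  gt <- random_mask(c(10, 10, 6), p = 0.3, seed = 14,
                    spacing = c(0.5, 0.5, 1.5))
  gt$subject_id <- "s1"
  set.seed(15)
  probs <- pmin(pmax(gt$data * 0.8 + runif(600) * 0.3, 0), 1)
  p <- probability_map(probs, gt$spacing, subject_id = "s1")
  pred <- binarize(p, 0.5)
  rep1 <- subject_report(p, pred, gt)
  cc <- confusion(pred, gt)
  expect_equal(rep1$DSC, dsc(cc))
  expect_equal(rep1$precision, precision(cc))
  expect_equal(rep1$recall, recall(cc))
  expect_equal(rep1$ASD, asd(pred, gt))
  expect_equal(rep1$MSD, msd(pred, gt))
  expect_equal(rep1$AP, curves(p, gt)$prc$area)
  expect_identical(rep1$subject_id, "s1")

  perfect <- subject_report(probability_map(gt$data, gt$spacing, "s1"),
                            gt, gt)
  expect_equal(perfect$DSC, 1); expect_equal(perfect$ASD, 0)
  expect_equal(perfect$MSD, 0); expect_equal(perfect$precision, 1)

  reports <- rbind(rep1, perfect)
  agg <- aggregate_reports(reports)
  expect_equal(agg$mean[agg$metric == "DSC"], mean(reports$DSC))
  expect_equal(agg$sd[agg$metric == "DSC"], sd(reports$DSC))
  expect_equal(agg$median[agg$metric == "AP"], median(reports$AP))
  expect_equal(agg$iqr[agg$metric == "AP"], IQR(reports$AP))
})

test_that("mean curves average folds on a common grid", {
  set.seed(16)
  cvs <- lapply(1:3, function(i) {
    labs <- array(rbinom(400, 1, 0.4), c(400, 1, 1))
    sc <- array(pmin(pmax(labs * 0.6 + runif(400) * 0.4, 0), 1),
                c(400, 1, 1))
    curves(probability_map(sc), label_mask(labs))
  })
  mc <- mean_curves(lapply(cvs, `[[`, "prc"))
  expect_length(mc$mean_curve, 101L)
  expect_equal(mc$mean_area, mean(vapply(cvs, function(x) x$prc$area,
                                         numeric(1))))
  mr <- mean_curves(lapply(cvs, `[[`, "roc"))
  expect_true(all(mr$mean_curve >= 0 & mr$mean_curve <= 1))
})
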
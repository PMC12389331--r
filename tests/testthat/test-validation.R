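test_that("fold plans partition positives into near-equal seeded folds", {
  set.seed(1)
  cat <- tiny_catalog(10)
  m1 <- matrix(0, 10, 10, dimnames = list(cat$drug_id, cat$drug_id))
  pairs <- pair_index(cat)
  pos <- pairs[1:20, ]
  m1[cbind(pos$i, pos$j)] <- 1
  m1[cbind(pos$j, pos$i)] <- 1

  plan <- make_folds(m1, cat, k = 10, seed = 4)
  sizes <- vapply(plan$folds, function(f) nrow(f$positives), integer(1))
  expect_equal(sizes, rep(2L, 10))
  all_pos <- do.call(rbind, lapply(plan$folds, `[[`, "positives"))
  expect_equal(nrow(all_pos), 20)
  expect_false(any(duplicated(paste(all_pos$drug_a, all_pos$drug_b))))
  # negatives disjoint from positives
  all_neg <- do.call(rbind, lapply(plan$folds, `[[`, "negatives"))
  expect_true(all(m1[cbind(all_neg$i, all_neg$j)] == 0))

  plan2 <- make_folds(m1, cat, k = 10, seed = 4)
  expect_identical(plan, plan2)                       # determinism
  plan3 <- make_folds(m1, cat, k = 10, seed = 5)
  expect_false(identical(plan, plan3))

  m1small <- m1 * 0
  m1small[1, 2] <- m1small[2, 1] <- 1
  expect_error(make_folds(m1small, cat, k = 10), "fewer known pairs")
})

test_that("auroc matches its closed-form examples", {
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
})

test_that("auroc equals brute-force concordant-pair counting", {
  set.seed(77)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)  # coarse grid to exercise ties
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("auroc is invariant under strictly increasing transforms", {
  set.seed(78)
  scores <- runif(40)
  labels <- c(1, 0, rbinom(38, 1, 0.4))
  base <- auroc(scores, labels)
  expect_equal(auroc(exp(3 * scores), labels), base)
  expect_equal(auroc(rank(scores), labels), base)
})

test_that("the Youden operating point maximizes sensitivity+specificity", {
  op <- youden_operating_point(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)

  op2 <- youden_operating_point(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(op2$youden, 0.5)
  expect_equal(op2$cutoff, 0.85)  # ties broken toward the larger cutoff

  expect_error(youden_operating_point(c(1, 2), c(1, 1)), "both classes")
})

test_that("q3 threshold follows the interpolated-quantile convention", {
  expect_equal(q3_threshold(c(0, 1, 2, 3)), 2.25)
  expect_equal(q3_threshold(rep(0.4, 5)), 0.4)
  expect_equal(q3_threshold(0.7), 0.7)
  expect_error(q3_threshold(numeric(0)), "no known")
})

test_that("strict exceedance of the q3 threshold respects the discrete bound", {
  # with interpolated quantiles the count of values strictly above Q3 is at
  # most (n+3)/4: the 25% bound up to one order statistic of slack; ties
  # only reduce it
  set.seed(12)
  for (rep in 1:50) {
    x <- switch(1 + rep %% 3,
                runif(sample(4:80, 1)),
                round(runif(sample(4:80, 1)), 1),
                rep(0.3, sample(4:20, 1)))
    thr <- q3_threshold(x)
    expect_lte(sum(x > thr), (length(x) + 3) / 4)
  }
  # ties at the quantile keep the strict count well under a quarter
  expect_equal(sum(rep(0.3, 10) > q3_threshold(rep(0.3, 10))), 0)
})

test_that("masked scoring hides fold positives and recovers similarity signal", {
  # 4-drug toy: a is known to interact with b and c; b and c share identical
  # feature profiles, d is unrelated. Masking (a,b) must still score it
  # highly because a's surviving partner c looks exactly like b.
  cat <- tiny_catalog(4)
  m1 <- matrix(0, 4, 4, dimnames = list(cat$drug_id, cat$drug_id))
  m1["a", "b"] <- m1["b", "a"] <- 1
  m1["a", "c"] <- m1["c", "a"] <- 1
  profs <- list(a = "x", b = c("y1", "y2"), c = c("y1", "y2"), d = "z")
  static_m2 <- list()
  for (kind in c("CHEM", "TECT", "ADE", "PATHWAY", "INTERACTOME")) {
    static_m2[[kind]] <- build_m2(profs, cat, kind)
  }
  pairs <- pair_index(cat)
  fold <- list(positives = pairs[pairs$drug_a == "a" & pairs$drug_b == "b",
                                 , drop = FALSE],
               negatives = pairs[pairs$drug_a == "b" & pairs$drug_b == "d",
                                 , drop = FALSE])
  fs <- masked_scores(fold, m1, static_m2, cat)
  expect_equal(nrow(fs), 2)
  expect_gt(fs$score[fs$label == 1], fs$score[fs$label == 0])
  expect_equal(fs$score[fs$label == 1], 1)
})

test_that("every fold's test positives are erased from the matrix it is scored with", {
  u <- small_universe(seed = 9)
  static_m2 <- build_static_m2(u$features, u$catalog, u$ppi)
  plan <- make_folds(u$m1, u$catalog, k = 5, seed = 9)
  for (fold in plan$folds) {
    # masked_scores stops internally if leakage is detected; additionally
    # verify the returned positive pairs really are known pairs of m1
    fs <- masked_scores(fold, u$m1, static_m2, u$catalog)
    pos <- fs[fs$label == 1, ]
    expect_true(all(u$m1[cbind(match(pos$drug_a, u$catalog$drug_id),
                               match(pos$drug_b, u$catalog$drug_id))] == 1))
    expect_equal(nrow(fs), nrow(fold$positives) + nrow(fold$negatives))
  }
})

test_that("cross-validation reports coherent rates and agrees with pROC", {
  skip_if_not_installed("pROC")
  u <- small_universe(seed = 2)
  static_m2 <- build_static_m2(u$features, u$catalog, u$ppi)
  rep <- cross_validate(u$m1, static_m2, u$catalog, k = 5, seed = 2)
  expect_length(rep$fold_auroc, 5)
  expect_true(all(rep$fold_auroc >= 0 & rep$fold_auroc <= 1))
  expect_true(rep$sensitivity >= 0 && rep$sensitivity <= 1)
  expect_true(rep$specificity >= 0 && rep$specificity <= 1)
  # independent cross-check of the pooled AUROC computation
  pooled <- rep$scores
  ours <- auroc(pooled$score, pooled$label)
  ref <- as.numeric(pROC::auc(pROC::roc(pooled$label, pooled$score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})
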
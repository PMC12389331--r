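test_that("effect classification follows the ordered keyword rules", {
  expect_equal(classify_effect("Augmented risk or severity of cardiac arrhythmia."),
               "ADE")
  expect_equal(classify_effect("Slow metabolism of estradiol."), "PK")
  expect_equal(classify_effect("The therapeutic efficacy of triptorelin can be increased."),
               "PD")
  expect_equal(classify_effect(""), "UNCLASSIFIED")
  expect_equal(classify_effect("no informative phrase here"), "UNCLASSIFIED")
  # adverse-event wording wins even when PK/PD vocabulary co-occurs
  expect_equal(classify_effect("risk or severity of reduced efficacy and altered metabolism"),
               "ADE")
  # PK outranks PD
  expect_equal(classify_effect("efficacy changes due to faster metabolism"),
               "PK")
  # vectorized and case-insensitive
  expect_equal(classify_effect(c("SERUM CONCENTRATION increased",
                                 "improved activities")),
               c("PK", "PD"))
})

test_that("discovery rate reproduces the published per-drug examples", {
  expect_equal(discovery_rate(122, 89), 42.18)  # follitropin
  expect_equal(discovery_rate(3, 1), 25.00)     # gonadorelin
  expect_equal(discovery_rate(340, 50), 12.82)  # triptorelin
  expect_equal(discovery_rate(832, 102), 10.92) # oxycodone
  expect_equal(discovery_rate(45, 5), 10.00)    # examestane
  expect_equal(discovery_rate(1110, 116), 9.46) # risperidone
  expect_error(discovery_rate(0, 0), "undefined")
})

test_that("novelty calling applies the strict threshold and flags", {
  cat <- tiny_catalog(3)
  pairs <- pair_index(cat)             # (a,b) (a,c) (b,c)
  m1 <- matrix(0, 3, 3, dimnames = list(cat$drug_id, cat$drug_id))
  m1["a", "b"] <- m1["b", "a"] <- 1
  unified <- c(0.9, 0.5, 0.2)

  preds <- call_novel(unified, pairs, m1, threshold = 0.4)
  expect_equal(sum(preds$known_flag == 1 & preds$above_threshold), 1)
  expect_equal(sum(preds$known_flag == 0), 1)
  expect_equal(preds$drug_b[preds$known_flag == 0], "c")

  # strict inequality: threshold 1 calls nothing novel
  none <- call_novel(unified, pairs, m1, threshold = 1)
  expect_equal(sum(none$known_flag == 0), 0)

  # threshold 0 calls every positively scored non-known pair
  all_calls <- call_novel(unified, pairs, m1, threshold = 0)
  expect_equal(sum(all_calls$known_flag == 0), 2)

  # known pairs inherit the effect class of their description
  inter <- data.frame(drug_a = "a", drug_b = "b",
                      description = "Slow metabolism of estradiol.",
                      stringsAsFactors = FALSE)
  annotated <- call_novel(unified, pairs, m1, 0.4, interactions = inter)
  expect_equal(annotated$effect_class[annotated$known_flag == 1], "PK")
  expect_equal(annotated$effect_class[annotated$known_flag == 0],
               "UNCLASSIFIED")
})

test_that("the discovery table matches a brute-force recount on a toy set", {
  cat <- drug_catalog(c("a", "b", "c", "d"), LETTERS[1:4],
                      groups = list("ovarian", "uterine", "ovarian",
                                    "non_gynecological"),
                      is_wrhd = c(TRUE, TRUE, TRUE, FALSE))
  pairs <- pair_index(cat)
  m1 <- matrix(0, 4, 4, dimnames = list(cat$drug_id, cat$drug_id))
  m1["a", "b"] <- m1["b", "a"] <- 1
  m1["a", "c"] <- m1["c", "a"] <- 1
  key <- paste(pairs$drug_a, pairs$drug_b)
  unified <- numeric(nrow(pairs))
  unified[key == "a b"] <- 0.9   # known, above threshold
  unified[key == "a c"] <- 0.3   # known, below threshold
  unified[key == "a d"] <- 0.8   # novel
  unified[key == "b c"] <- 0.7   # novel
  preds <- call_novel(unified, pairs, m1, threshold = 0.5)
  tab <- discovery_table(preds, m1, cat)

  a_row <- tab[tab$drug_id == "a", ]
  expect_equal(a_row$known_described, 2)
  expect_equal(a_row$known_predicted, 1)
  expect_equal(a_row$new_predicted, 1)
  expect_equal(a_row$rate, 50)
  # b: 1 known (above), 1 novel -> 50; c: 1 known below, 1 novel -> 100
  expect_equal(tab$rate[tab$drug_id == "c"], 100)
  # equal rates are ordered lexicographically after the rate sort
  expect_equal(tab$drug_id, c("c", "a", "b"))
  # d is not a WRHD and never appears
  expect_false("d" %in% tab$drug_id)
  expect_true(all(tab$known_predicted <= tab$known_described))
})

test_that("group summaries attribute bridging pairs to both groups", {
  cat <- drug_catalog(c("a", "b", "c", "d"), LETTERS[1:4],
                      groups = list("ovarian", "uterine", "ovarian",
                                    "non_gynecological"),
                      is_wrhd = c(TRUE, TRUE, TRUE, FALSE))
  pairs <- pair_index(cat)
  m1 <- matrix(0, 4, 4, dimnames = list(cat$drug_id, cat$drug_id))
  key <- paste(pairs$drug_a, pairs$drug_b)
  unified <- numeric(nrow(pairs))
  unified[key == "a b"] <- 0.9   # novel, bridges ovarian and uterine
  preds <- call_novel(unified, pairs, m1, threshold = 0.5)
  g <- group_summary(preds, cat)
  expect_equal(g$novel_count[g$group == "ovarian"], 1)
  expect_equal(g$novel_count[g$group == "uterine"], 1)  # counted in both
  expect_equal(g$novel_count[g$group == "non_gynecological"], 0)
  expect_equal(g$n_drugs[g$group == "ovarian"], 1)
  expect_equal(g$rate_per_drug[g$group == "ovarian"], 1)

  empty <- call_novel(unified * 0, pairs, m1, threshold = 0.5)
  g0 <- group_summary(empty, cat)
  expect_true(all(g0$novel_count == 0))
})

test_that("per-group rate arithmetic matches the published convention", {
  # a group with 4 involved drugs and 10 novel DDIs reports 2.5 per drug
  cat <- drug_catalog(sprintf("d%02d", 1:8), sprintf("D%02d", 1:8),
                      groups = c(rep(list("menstrual"), 4),
                                 rep(list("non_gynecological"), 4)),
                      is_wrhd = rep(c(TRUE, FALSE), each = 4))
  pairs <- pair_index(cat)
  m1 <- matrix(0, 8, 8, dimnames = list(cat$drug_id, cat$drug_id))
  members <- sprintf("d%02d", 1:4)
  in_group <- pairs$drug_a %in% members | pairs$drug_b %in% members
  unified <- numeric(nrow(pairs))
  unified[which(in_group)[1:10]] <- 0.9
  preds <- call_novel(unified, pairs, m1, threshold = 0.5)
  g <- group_summary(preds, cat)
  row <- g[g$group == "menstrual", ]
  expect_equal(row$novel_count, 10)
  expect_equal(row$rate_per_drug, round(10 / row$n_drugs, 1))
})
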
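fake_sites <- function(n_pos, n_neg, seed = 1) {
  withr::local_seed(seed)
  sites <- sprintf("p:%d", seq_len(n_pos + n_neg))
  scores <- sample(0:196, n_pos + n_neg, replace = TRUE)
  names(scores) <- sites
  list(scores = scores, pos = sites[seq_len(n_pos)],
       neg = sites[n_pos + seq_len(n_neg)])
}

test_that("confusion counts implement the >= threshold prediction rule", {
  s <- c(a = 100, b = 97, c = 96, d = 0)
  cc <- confusion_at_threshold(s, c("a", "c"), c("b", "d"), 97)
  expect_equal(cc$tp, 1L); expect_equal(cc$fn, 1L)
  expect_equal(cc$fp, 1L); expect_equal(cc$tn, 1L)
  expect_equal(cc$tpr, 0.5); expect_equal(cc$fpr, 0.5)
  # extremes
  all_in <- confusion_at_threshold(s, c("a", "c"), c("b", "d"), -Inf)
  expect_equal(c(all_in$tpr, all_in$fpr), c(1, 1))
  none <- confusion_at_threshold(s, c("a", "c"), c("b", "d"), 1e6)
  expect_equal(c(none$tp, none$fp), c(0L, 0L))
})

test_that("a 72-of-97 positive split reproduces the 74.2% true positive rate", {
  scores <- c(rep(120, 72), rep(50, 25))
  names(scores) <- sprintf("s:%d", seq_along(scores))
  cc <- confusion_at_threshold(scores, names(scores), character(0), 97)
  expect_equal(round(100 * cc$tpr, 1), 74.2)
})

test_that("overlapping or unscored site sets are rejected", {
  s <- c(a = 1, b = 2)
  expect_error(confusion_at_threshold(s, "a", c("a", "b"), 1), "overlap")
  expect_error(confusion_at_threshold(s, c("a", "zzz"), "b", 1),
               "without a score")
})

test_that("ROC curves span (0,0) to (1,1) and are threshold-monotone", {
  x <- fake_sites(40, 60, seed = 3)
  roc <- roc_curve(x$scores, x$pos, x$neg)
  expect_true(all(diff(roc$threshold) > 0))
  expect_true(all(diff(roc$tpr) <= 0) && all(diff(roc$fpr) <= 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(1, 1))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(0, 0))
  expect_true(all(roc$tp + roc$fn == 40))
  expect_true(all(roc$fp + roc$tn == 60))
})

test_that("ROC points match a naive per-threshold recount", {
  x <- fake_sites(200, 800, seed = 9)
  roc <- roc_curve(x$scores, x$pos, x$neg)
  for (i in seq_len(nrow(roc))) {
    want <- naive_confusion(x$scores, x$pos, x$neg, roc$threshold[i])
    expect_equal(unlist(roc[i, c("tp", "fp", "fn", "tn")]), want,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate score distributions produce degenerate curves", {
  # perfect separation passes through (fpr 0, tpr 1)
  s <- c(p1 = 100, p2 = 100, n1 = 0, n2 = 0)
  roc <- roc_curve(s, c("p1", "p2"), c("n1", "n2"))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc(roc), 1)
  # no discrimination: only the two corner points remain
  s2 <- c(p1 = 50, n1 = 50)
  roc2 <- roc_curve(s2, "p1", "n1")
  expect_setequal(paste(roc2$fpr, roc2$tpr), c("1 1", "0 0"))
  expect_error(roc_curve(s2, character(0), "n1"), "at least one")
})

test_that("trapezoid AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  x <- fake_sites(120, 380, seed = 17)
  roc <- roc_curve(x$scores, x$pos, x$neg)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 120), rep(0, 380)),
    predictor = as.numeric(x$scores[c(x$pos, x$neg)]),
    quiet = TRUE, direction = "<"))
  expect_equal(roc_auc(roc), as.numeric(ref), tolerance = 1e-9)
})

test_that("template-derived evaluation builds disjoint aromatic site sets", {
  tm <- generate_template_set(12, length = 80, n_binding = 2, seed = 29)
  ev <- evaluate_binding_prediction(tm)
  expect_length(intersect(ev$positives, ev$negatives), 0L)
  expect_equal(length(ev$positives), 24L)  # 12 templates x 2 planted
  # planted motifs are heavy-flanked, so recall at 97 is total
  expect_equal(ev$at_threshold$tpr, 1)
  expect_gte(roc_auc(ev$roc), 0.5)
})

test_that("alignment summaries average percent identity and similarity", {
  a <- align_pair("GSWNP", "GSWNP")
  st <- summarize_alignment_stats(list(a, a))
  expect_equal(st$n, 2L)
  expect_equal(st$mean_identity, 100)
  b <- structure(list(target_id = "t", template_id = "p", t_row = "AAAAA",
                      p_row = "AAAAA", score = 0, ident = 1, sim = 2,
                      gap_openings = 0, n_columns = 5),
                 class = "pairwise_alignment")
  st2 <- summarize_alignment_stats(list(a, b))
  expect_equal(st2$mean_identity, mean(c(100, 20)))
  expect_equal(st2$mean_similarity, mean(c(100, 40)))
})

test_that("template-usage summaries count singles and doubles", {
  mk <- function(origin) structure(list(candidate_id = "x", origin = origin,
                                        template_ids = "x", z_score = 0),
                                   class = "model_candidate")
  sets <- list(list(mk("double"), mk("double"), mk("double"),
                    mk("single"), mk("single")))
  us <- summarize_template_usage(sets)
  expect_equal(us$pct_double, 60)
  expect_equal(us$pct_single, 40)
  expect_error(summarize_template_usage(list()), "length")
})
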
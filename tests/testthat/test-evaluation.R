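test_that("training-set balancing undersamples the majority class only", {
  segs <- toy_segments(n_per_class = 60, window = 100)
  unbal <- subset_segments(segs, c(1:60, 61:100))     # 60 vs 40
  bal <- balance_training_set(unbal, seed = 1)
  expect_equal(sum(bal$label == 0), 40)
  expect_equal(sum(bal$label == 1), 40)

  # already balanced: a permutation of the input
  bal2 <- balance_training_set(segs, seed = 2)
  expect_equal(length(bal2), length(segs))
  expect_equal(sort(table(bal2$label)), sort(table(segs$label)))

  # determinism
  expect_identical(balance_training_set(unbal, seed = 5)$data,
                   balance_training_set(unbal, seed = 5)$data)
  expect_false(identical(balance_training_set(unbal, seed = 5)$data,
                         balance_training_set(unbal, seed = 6)$data))

  only0 <- subset_segments(segs, segs$label == 0)
  expect_error(balance_training_set(only0), "balance error")
})

test_that("metrics implement the five formulas, including edge cases", {
  perfect <- compute_metrics(confusion_counts(rep(c(0, 1), each = 50),
                                              rep(c(0, 1), each = 50)))
  expect_equal(unname(perfect), rep(100, 5))

  worked <- compute_metrics(list(TP = 40, FN = 10, TN = 30, FP = 20))
  expect_equal(worked[["accuracy"]], 70)
  expect_equal(worked[["sensitivity"]], 80)
  expect_equal(worked[["specificity"]], 60)
  expect_equal(worked[["BA"]], 70)
  expect_equal(worked[["GM"]], 69.28, tolerance = 1e-3)

  degenerate <- compute_metrics(list(TP = 0, FN = 10, TN = 10, FP = 0))
  expect_equal(degenerate[["sensitivity"]], 0)
  expect_equal(degenerate[["GM"]], 0)
  expect_equal(degenerate[["BA"]], 50)

  undef <- compute_metrics(list(TP = 0, FN = 0, TN = 8, FP = 2))
  expect_true(is.na(undef[["sensitivity"]]))
  expect_true(is.na(undef[["BA"]]))
})

test_that("BA and GM identities hold on random confusion tables", {
  set.seed(123)
  for (i in 1:200) {
    cc <- list(TP = rpois(1, 30), FP = rpois(1, 20),
               TN = rpois(1, 30), FN = rpois(1, 20))
    if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
    m <- compute_metrics(cc)
    expect_equal(m[["BA"]], (m[["sensitivity"]] + m[["specificity"]]) / 2,
                 tolerance = 1e-9)
    expect_equal(m[["GM"]],
                 sqrt(m[["sensitivity"]] * m[["specificity"]]),
                 tolerance = 1e-9)
    expect_lte(m[["GM"]], m[["BA"]] + 1e-9)
    expect_equal(m[["accuracy"]],
                 100 * (cc$TP + cc$TN) / (cc$TP + cc$TN + cc$FP + cc$FN),
                 tolerance = 1e-12)
  }
})

test_that("BA and GM are invariant under class-prevalence changes", {
  base <- list(TP = 40, FN = 10, TN = 30, FP = 20)
  # duplicating the negative class preserves sensitivity and specificity
  dup <- list(TP = 40, FN = 10, TN = 90, FP = 60)
  m1 <- compute_metrics(base); m2 <- compute_metrics(dup)
  expect_equal(m1[["BA"]], m2[["BA"]])
  expect_equal(m1[["GM"]], m2[["GM"]])
  expect_false(isTRUE(all.equal(m1[["accuracy"]], m2[["accuracy"]])))
})

test_that("LOSO folds are subject-disjoint, reproducible and complete", {
  segs <- micro_segments()
  res <- loso_evaluate(segs, micro_spec(), seed = 3)
  expect_equal(nrow(res$per_subject), 3)
  expect_setequal(res$per_subject$subject_id, unique(segs$subject_id))
  # each fold tests the subject's full (imbalanced) segment set
  for (i in seq_len(nrow(res$per_subject))) {
    s <- res$per_subject$subject_id[i]
    expect_equal(res$per_subject$n_test[i], sum(segs$subject_id == s))
    cc <- res$confusion[[s]]
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, sum(segs$subject_id == s))
  }
  # aggregate recomputable from the stored per-subject reports
  expect_equal(unname(res$mean["accuracy"]),
               mean(res$per_subject$accuracy))
  expect_equal(unname(res$sd["BA"]), sd(res$per_subject$BA))

  res2 <- loso_evaluate(segs, micro_spec(), seed = 3)
  expect_identical(res$per_subject, res2$per_subject)
})

test_that("the window-length sweep re-segments, re-builds and flags short windows", {
  clean <- micro_clean()
  spec <- micro_spec()
  sw <- window_length_sweep(clean, spec, lengths_s = c(0.2, 2, 3), seed = 4)
  expect_equal(nrow(sw), 3)
  expect_match(sw$error[1], "architecture error")
  expect_true(all(is.na(sw$error[2:3])))
  expect_true(all(sw$mean_accuracy[2:3] >= 0 & sw$mean_accuracy[2:3] <= 100))

  # the minimal valid window length runs without an architecture error
  min_w <- deep4_min_input() / clean[[1]]$fs
  sw_min <- window_length_sweep(clean, micro_spec(max_epochs = 1), min_w,
                                seed = 4)
  expect_true(is.na(sw_min$error[1]))
})
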
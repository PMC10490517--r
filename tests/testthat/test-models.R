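test_that("built networks match the closed-form parameter arithmetic", {
  for (arch in c("data_fusion", "feature_fusion")) {
    for (sensors in c("eeg", "eeg+spr", "eeg+ecg", "eeg+spr+ecg")) {
      net <- build_network(model_spec(arch, sensors))
      expect_equal(count_trainable_parameters(net),
                   oracle_param_count(arch, sensors),
                   info = paste(arch, sensors))
    }
  }
  # counting itself on a bare dense layer: 10 x 2 weights + 2 biases
  tiny <- build_network(model_spec("data_fusion", "eeg"))
  dense <- tiny$head[[1]]
  expect_equal(length(dense$W) + length(dense$b),
               nrow(dense$W) * 2 + 2)
})

test_that("the parameter count is stable across rebuilds and window lengths", {
  s <- model_spec("feature_fusion", "eeg+spr+ecg", seed = 4)
  n1 <- count_trainable_parameters(build_network(s))
  n2 <- count_trainable_parameters(build_network(s))
  expect_identical(n1, n2)
  # the flatten width follows the conv/pool floor rule
  for (w in c(400, 600, 1000)) {
    sw <- model_spec("data_fusion", "eeg", window_samples = w)
    expect_equal(count_trainable_parameters(build_network(sw)),
                 oracle_param_count("data_fusion", "eeg", window = w))
  }
})

test_that("identical specs give identical initial weights", {
  s <- model_spec("data_fusion", "eeg+spr", seed = 11)
  a <- build_network(s); b <- build_network(s)
  expect_identical(a$branches[[1]]$ops[[1]]$W, b$branches[[1]]$ops[[1]]$W)
  expect_identical(a$head[[1]]$W, b$head[[1]]$W)
})

test_that("the time-length chain shrinks as documented and bounds the input", {
  expect_equal(deep4_time_chain(600),
               c(600, 596, 298, 294, 147, 143, 71, 67, 33))
  m <- deep4_min_input()
  expect_silent(deep4_time_chain(m))
  expect_error(deep4_time_chain(m - 1), "architecture error")
  expect_error(build_network(model_spec("data_fusion", "eeg",
                                        window_samples = 20)),
               "architecture error")
})

test_that("feature fusion without the hidden dense layer shrinks below the dense variant", {
  full <- count_trainable_parameters(
    build_network(model_spec("feature_fusion", "eeg+spr+ecg")))
  # ablation: branches + direct softmax head over the concatenated features
  branches <- oracle_branch_params(6, TRUE) + 2 * oracle_branch_params(1, FALSE)
  no_dense <- branches + 3 * 6600 * 2 + 2
  expect_lt(no_dense, full)
  expect_lt(no_dense, oracle_param_count("data_fusion", "eeg+spr+ecg") +
              2 * oracle_branch_params(1, FALSE) + 2 * 6600 * 2)
})

test_that("training separates a separable toy problem and predicts sanely", {
  segs <- toy_segments(n_per_class = 100, window = 100)
  fit <- engagement_net(segs, spec = model_spec(
    "data_fusion", "eeg+spr+ecg", window_samples = 100,
    max_epochs = 8, patience = 8, learning_rate = 3e-3, seed = 2))
  pred <- predict(fit, segs)
  expect_gt(mean(pred == segs$label), 0.9)

  prob <- predict(fit, segs, type = "prob")
  expect_true(all(prob >= 0 & prob <= 1))
  expect_equal(rowSums(prob), rep(1, length(segs)), tolerance = 1e-6)

  # duplicated input -> identical outputs at inference
  dup <- subset_segments(segs, c(1L, 1L))
  pd <- predict(fit, dup, type = "prob")
  expect_identical(pd[1, ], pd[2, ])

  # shape mismatch is caught
  expect_error(predict(fit, array(0, c(2, 50, 8))), "shape error")
})

test_that("label-permuted training stays at chance on held-out data", {
  segs <- toy_segments(n_per_class = 150, window = 100, seed = 8)
  set.seed(99)
  segs$label <- sample(segs$label)
  train <- subset_segments(segs, 1:200)
  heldout <- subset_segments(segs, 201:300)
  expect_error(engagement_net(subset_segments(segs, segs$label == 0)),
               "training error")
  fit <- engagement_net(train, spec = model_spec(
    "data_fusion", "eeg+spr+ecg", window_samples = 100,
    max_epochs = 6, patience = 6, learning_rate = 3e-3, seed = 3))
  acc <- mean(predict(fit, heldout) == heldout$label)
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.6)
})

test_that("training is reproducible under a fixed seed", {
  segs <- toy_segments(n_per_class = 40, window = 100, seed = 12)
  spec <- model_spec("feature_fusion", "eeg+spr+ecg", window_samples = 100,
                     max_epochs = 3, patience = 3, seed = 21)
  f1 <- engagement_net(segs, spec = spec)
  f2 <- engagement_net(segs, spec = spec)
  expect_identical(f1$history, f2$history)
  expect_identical(coef(f1)[["op01_tconv_W"]], coef(f2)[["op01_tconv_W"]])
})

test_that("fit objects print, summarize and plot", {
  segs <- toy_segments(n_per_class = 20, window = 100, seed = 13)
  fit <- engagement_net(segs, spec = micro_spec(window_samples = 100))
  expect_output(print(fit), "data_fusion")
  sm <- summary(fit)
  expect_equal(sm$total_params,
               oracle_param_count("data_fusion", "eeg+spr+ecg", 100))
  expect_output(print(sm), "trainable parameters")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
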
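test_that("fragment counts follow the overlap geometry", {
  s <- toy_session(n = 100L)
  expect_identical(nrow(compute_fragment_criteria(s, 21, FALSE)), 4L)
  expect_identical(nrow(compute_fragment_criteria(s, 21, TRUE)), 80L)
  s1 <- toy_session(n = 21L)
  expect_identical(nrow(compute_fragment_criteria(s1, 21, FALSE)), 1L)
  expect_identical(nrow(compute_fragment_criteria(s1, 21, TRUE)), 1L)
  expect_warning(out <- compute_fragment_criteria(toy_session(n = 8L), 21),
                 "shorter")
  expect_identical(nrow(out), 0L)
})

test_that("fragment criteria agree with direct windowed computation", {
  s <- sim_session(duration = 10)
  fr <- compute_fragment_criteria(s, 21, overlapping = TRUE)
  h <- build_kernel()
  for (i in c(1L, 7L, 50L, nrow(fr))) {
    w <- s$samples[i:(i + 20L), ]
    expect_equal(fr$s_acc[i], s_acc(w), tolerance = 1e-9)
    expect_equal(fr$s_flex[i], s_flex(w, h), tolerance = 1e-9)
  }
  expect_true(all(fr$s_acc >= 0))
  expect_true(all(fr$s_flex >= 0))
})

test_that("decision tree separates separable criteria and honours depth 3", {
  set.seed(4)
  sep <- data.frame(
    s_acc = c(runif(60, 11, 30), runif(60, 0, 1)),
    s_flex = runif(120, 0, 5),
    correct = rep(c(1L, 0L), each = 60))
  tree <- train_tree(sep)
  expect_identical(tree_predict(tree, sep), sep$correct)
  expect_identical(tree_depth(tree), 1L)    # one split suffices

  # depth never exceeds 3 on noisy random data
  noisy <- data.frame(s_acc = runif(400), s_flex = runif(400),
                      correct = sample(0:1, 400, TRUE))
  expect_lte(tree_depth(train_tree(noisy)), 3L)

  # degenerate: identical features, mixed labels -> majority-class leaf
  degen <- data.frame(s_acc = 1, s_flex = 1,
                      correct = rep(c(0L, 1L), c(3, 7)))
  tdeg <- train_tree(degen)
  expect_identical(tree_predict(tdeg, degen[1, ]), 1L)

  expect_error(train_tree(data.frame(s_acc = 1:4, s_flex = 1:4,
                                     correct = 1L)),
               "single class")
})

test_that("tree prediction agrees with manual traversal of its thresholds", {
  set.seed(8)
  dat <- data.frame(
    s_acc = c(runif(50, 0, 10), runif(50, 20, 30)),
    s_flex = runif(100, 0, 2),
    correct = rep(c(0L, 1L), each = 50))
  tree <- train_tree(dat, max_depth = 1L)
  fr <- tree$fit$frame
  expect_identical(as.character(fr$var[1]), "s_acc")
  thr <- unname(tree$fit$splits[1, "index"])
  ylevels <- attr(tree$fit, "ylevels")
  leaf_class <- as.integer(ylevels[fr$yval[c(2, 3)]])  # left, right leaves
  lt_goes_left <- tree$fit$splits[1, "ncat"] < 0
  manual <- function(v) {
    left <- if (lt_goes_left) v < thr else v >= thr
    if (left) leaf_class[1] else leaf_class[2]
  }
  probes <- data.frame(s_acc = c(0, thr - 1e-6, thr, thr + 1e-6, 100),
                       s_flex = 1)
  expect_identical(tree_predict(tree, probes),
                   vapply(probes$s_acc, manual, integer(1)))
  # all-zero criteria land in the leaf containing the origin
  expect_identical(tree_predict(tree, data.frame(s_acc = 0, s_flex = 0)),
                   manual(0))
})

test_that("network heads have the contracted output geometry", {
  set.seed(1)
  ex <- build_net("exercise", ns = 21, seed = 10)
  an <- build_net("anomaly", ns = 21, seed = 10)
  expect_lte(n_params(ex), 5000L)
  expect_lte(n_params(an), 5000L)
  # identical trunk shapes (warm-start contract); only the head differs
  for (k in c("W1", "b1", "W2", "b2", "W3", "b3")) {
    expect_identical(dim(ex$params[[k]]), dim(an$params[[k]]))
    expect_identical(length(ex$params[[k]]), length(an$params[[k]]))
  }
  expect_identical(ncol(ex$params$W4), 6L)
  expect_identical(ncol(an$params$W4), 1L)

  x <- array(runif(7 * 21 * 10), c(7, 21, 10))
  probs <- predict_exercise(ex, x)
  expect_identical(dim(probs), c(7L, 6L))
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, 7), tolerance = 1e-6)

  sc <- predict_anomaly(an, x)
  expect_true(all(sc > 0 & sc < 1))

  expect_error(predict_exercise(ex, matrix(0, 20, 10)), "shape")
  expect_error(predict_anomaly(an, array(0, c(2, 21, 9))), "shape")
  expect_error(build_net("exercise", ns = 8), ">= 10")
})

test_that("an untrained symmetric head is near-uniform", {
  net <- build_net("exercise", ns = 21, seed = 3)
  net$params$W4[] <- 0
  net$params$b4[] <- 0
  p <- predict_exercise(net, array(runif(21 * 10), c(1, 21, 10)))
  expect_equal(unname(p[1, ]), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("training is deterministic and learns separable anomaly data", {
  p <- subject_profile("s", seed = 2)
  mk <- function(mode, seed) {
    generate_session(p, "wrist_flexion_extension", mode,
                     duration = 8, seed = seed)
  }
  files <- list()
  for (i in 1:6) {
    files[[i]] <- list(id = paste0("c", i),
                       features = feature_matrix(mk("none", 100 + i)),
                       label = 1L)
    files[[6 + i]] <- list(id = paste0("a", i),
                           features = feature_matrix(mk("rest", 200 + i)),
                           label = 0L)
  }
  cfg <- train_config(epochs = 6, steps_per_epoch = 25, seed = 5)
  net1 <- train_net(build_net("anomaly", 21, seed = 9), files, cfg)
  net2 <- train_net(build_net("anomaly", 21, seed = 9), files, cfg)
  expect_identical(attr(net1, "loss_trace"), attr(net2, "loss_trace"))
  expect_identical(net1$params, net2$params)

  # training accuracy on the (separable) training windows
  correct <- 0; total <- 0
  for (f in files) {
    wins <- apply_scaler(extract_windows(f$features, 21), net1$scaler)
    pred <- binarize_anomaly(predict_anomaly(net1, wins))
    correct <- correct + sum(pred == f$label)
    total <- total + length(pred)
  }
  expect_gte(correct / total, 0.95)

  # leakage guard
  expect_error(train_net(build_net("anomaly", 21, seed = 1), files, cfg,
                         forbid = c("c3", "zzz")),
               "leakage.*c3")
})

test_that("an overfit single-file exercise model predicts its own class", {
  p <- subject_profile("s", seed = 6)
  s <- generate_session(p, "rolling", "none", duration = 10, seed = 77)
  files <- list(list(id = "only", features = feature_matrix(s),
                     label = "rolling"),
                list(id = "other",
                     features = feature_matrix(
                       generate_session(p, "basket", "none", duration = 10,
                                        seed = 78)),
                     label = "basket"))
  net <- train_net(build_net("exercise", 21, seed = 4), files,
                   train_config(epochs = 6, steps_per_epoch = 25, seed = 4))
  wins <- apply_scaler(extract_windows(files[[1]]$features, 21), net$scaler)
  probs <- predict_exercise(net, wins)
  top <- exercise_labels()[max.col(probs, ties.method = "first")]
  expect_gte(mean(top == "rolling"), 0.9)
})

test_that("warm-starting the anomaly trunk does not hurt convergence", {
  p <- subject_profile("s", seed = 11)
  mk <- function(ex, mode, seed) feature_matrix(
    generate_session(p, ex, mode, duration = 8, seed = seed))
  files_ex <- list(); files_an <- list()
  exs <- c("rolling", "basket", "hand_up_down", "hand_kneading")
  for (i in 1:4) {
    files_ex[[i]] <- list(id = paste0("e", i),
                          features = mk(exs[i], "none", 300 + i),
                          label = exs[i])
    files_an[[i]] <- list(id = paste0("ac", i),
                          features = mk(exs[i], "none", 400 + i), label = 1L)
    files_an[[4 + i]] <- list(id = paste0("aa", i),
                              features = mk(exs[i], "rest", 500 + i),
                              label = 0L)
  }
  ex_net <- train_net(build_net("exercise", 21, seed = 21), files_ex,
                      train_config(epochs = 4, steps_per_epoch = 20,
                                   seed = 21))
  deltas <- vapply(1:5, function(s) {
    cfg <- train_config(epochs = 3, steps_per_epoch = 15, seed = 600 + s)
    cold <- train_net(build_net("anomaly", 21, seed = 700 + s), files_an, cfg)
    warm <- train_net(build_net("anomaly", 21, seed = 700 + s), files_an, cfg,
                      init_from = ex_net)
    tail(attr(cold, "loss_trace"), 1) - tail(attr(warm, "loss_trace"), 1)
  }, numeric(1))
  # median over 5 seeds: warm start reaches at least the cold-start loss
  expect_gte(median(deltas), 0)
})

test_that("anomaly scores separate correct from anomalous windows", {
  p <- subject_profile("s", seed = 13)
  files <- list()
  for (i in 1:4) {
    files[[i]] <- list(id = paste0("c", i), label = 1L,
                       features = feature_matrix(
                         generate_session(p, "hand_kneading", "none",
                                          duration = 8, seed = 800 + i)))
    files[[4 + i]] <- list(id = paste0("a", i), label = 0L,
                           features = feature_matrix(
                             generate_session(p, "hand_kneading",
                                              "low_motion", duration = 8,
                                              seed = 900 + i)))
  }
  net <- train_net(build_net("anomaly", 21, seed = 31), files,
                   train_config(epochs = 6, steps_per_epoch = 25, seed = 31))
  mean_score <- function(f) {
    wins <- apply_scaler(extract_windows(f$features, 21), net$scaler)
    mean(predict_anomaly(net, wins))
  }
  m_correct <- mean(vapply(files[1:4], mean_score, numeric(1)))
  m_anom <- mean(vapply(files[5:8], mean_score, numeric(1)))
  expect_gt(m_correct, m_anom)

  expect_identical(binarize_anomaly(c(0.7, 0.5, 0.49)), c(1L, 1L, 0L))
})

test_that("model bundles roundtrip through disk", {
  net <- build_net("exercise", ns = 21, seed = 2)
  net$scaler <- fit_scaler(matrix(rnorm(40), 4, 10))
  dir <- withr::local_tempdir()
  save_model(net, dir)
  back <- load_model(dir)
  x <- array(runif(3 * 21 * 10), c(3, 21, 10))
  expect_equal(predict_exercise(back, x), predict_exercise(net, x),
               tolerance = 1e-12)
})
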
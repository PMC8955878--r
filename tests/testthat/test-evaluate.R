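test_that("five-fold plans partition files evenly and reproducibly", {
  mf <- data.frame(id = sprintf("f%03d", 1:292),
                   subject_id = rep(sprintf("s%d", 1:4), each = 73))
  plan <- plan_five_fold(mf, seed = 11)
  sizes <- vapply(plan$folds, function(f) length(f$test), integer(1))
  expect_length(plan$folds, 5L)
  expect_true(all(sizes %in% c(58L, 59L)))
  expect_identical(sum(sizes), 292L)
  tests <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(tests, mf$id)                 # union covers everything
  expect_identical(anyDuplicated(tests), 0L)    # pairwise disjoint
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), mf$id)
  }
  expect_identical(plan_five_fold(mf, seed = 11), plan)
  expect_false(identical(plan_five_fold(mf, seed = 12), plan))
  expect_error(plan_five_fold(mf[1:4, ]), "at least 5")
})

test_that("LOSO plans hold out exactly one subject per fold", {
  mf <- data.frame(id = sprintf("f%03d", 1:40),
                   subject_id = rep(c("zeta", "alpha", "mid", "beta"), 10))
  plan <- plan_loso(mf)
  expect_length(plan$folds, 4L)
  # deterministic sorted subject order
  expect_identical(vapply(plan$folds, `[[`, "", "subject"),
                   c("alpha", "beta", "mid", "zeta"))
  for (f in plan$folds) {
    test_subj <- unique(mf$subject_id[mf$id %in% f$test])
    expect_length(test_subj, 1L)
    expect_false(test_subj %in% mf$subject_id[mf$id %in% f$train])
  }
  expect_error(plan_loso(data.frame(id = "a", subject_id = "s1")),
               "at least 2")
})

test_that("ablation cases drop exactly the named channel groups", {
  fm <- matrix(rnorm(50 * 10), 50, 10)
  colnames(fm) <- c("ax", "ay", "az", "f1", "f2", "gx", "gy", "gz",
                    "roll", "pitch")
  expect_identical(apply_ablation(fm, "normal"), fm)
  expect_identical(colnames(apply_ablation(fm, "noimu")), c("f1", "f2"))
  expect_identical(ncol(apply_ablation(fm, "noangles")), 8L)
  expect_identical(ncol(apply_ablation(fm, "noflex")), 8L)
  expect_identical(ncol(apply_ablation(fm, "nogyro")), 7L)
  expect_identical(ncol(apply_ablation(fm, "noaccel")), 7L)
  expect_false("gx" %in% colnames(apply_ablation(fm, "nogyro")))
  expect_error(apply_ablation(fm, "nomagnet"), "unknown ablation")
  # window arrays are reduced along the channel axis
  wins <- extract_windows(fm, 10)
  expect_identical(dim(apply_ablation(wins, "noimu"))[3], 2L)
})

test_that("binary metrics match the hand-computed contingency example", {
  pred <- c(rep(1, 9), rep(1, 1), rep(0, 3), rep(0, 7))
  truth <- c(rep(1, 9), rep(0, 1), rep(1, 3), rep(0, 7))
  m <- classification_metrics(pred, truth, task = "anomaly")
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.8182, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.8)

  perfect <- classification_metrics(c(0, 1, 1), c(0, 1, 1), "anomaly")
  expect_equal(unlist(perfect), c(precision = 1, recall = 1, f1 = 1,
                                  accuracy = 1))
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
  expect_error(classification_metrics(1, c(1, 0)), "length")
})

test_that("weighted exercise metrics reduce to plain averages when balanced", {
  set.seed(3)
  lv <- exercise_labels()
  truth <- rep(lv, each = 30)
  pred <- truth
  flip <- sample(length(pred), 40)
  pred[flip] <- sample(lv, 40, TRUE)
  m <- classification_metrics(pred, truth, task = "exercise")
  # balanced supports: weighted average equals the plain per-class mean
  per_class <- vapply(lv, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    if (tp + fp > 0) tp / (tp + fp) else 0
  }, numeric(1))
  expect_equal(m$precision, mean(per_class), tolerance = 1e-12)
  expect_equal(m$accuracy, mean(pred == truth))
})

test_that("metrics agree with a confusion-matrix oracle on random vectors", {
  set.seed(41)
  lv <- exercise_labels()
  for (trial in 1:1000) {
    n <- sample(10:80, 1)
    truth <- sample(lv, n, TRUE)
    pred <- sample(lv, n, TRUE)
    m <- classification_metrics(pred, truth, task = "exercise")
    counts <- table(factor(truth, lv), factor(pred, lv))
    support <- rowSums(counts)
    prec_c <- diag(counts) / pmax(colSums(counts), 1)
    rec_c <- diag(counts) / pmax(support, 1)
    f1_c <- ifelse(prec_c + rec_c > 0,
                   2 * prec_c * rec_c / (prec_c + rec_c), 0)
    w <- support / sum(support)
    expect_equal(m$precision, sum(w * prec_c), tolerance = 1e-12)
    expect_equal(m$recall, sum(w * rec_c), tolerance = 1e-12)
    expect_equal(m$f1, sum(w * f1_c), tolerance = 1e-12)
    expect_equal(m$accuracy, sum(diag(counts)) / n, tolerance = 1e-12)
  }
})

test_that("confusion matrices are row-normalized with flagged empty rows", {
  lv <- exercise_labels()
  perfect <- confusion_normalized(rep(lv, 3), rep(lv, 3))
  expect_equal(unname(unclass(perfect)), diag(6))

  # hand-computed toy: 3 of 4 basket windows correct, 1 called rolling
  pred <- c("basket", "basket", "basket", "rolling", "rolling")
  truth <- c("basket", "basket", "basket", "basket", "rolling")
  suppressWarnings(cm <- confusion_normalized(pred, truth))
  expect_equal(unname(cm["basket", c("basket", "rolling")]), c(0.75, 0.25))
  expect_equal(unname(cm["rolling", "rolling"]), 1)
  occupied <- rowSums(cm) > 0
  expect_equal(unname(rowSums(cm)[occupied]), rep(1, sum(occupied)),
               tolerance = 1e-9)
  expect_warning(confusion_normalized(pred, truth), "zero-support")
})

test_that("experiment reports have the documented structure", {
  ds <- generate_dataset(n_subjects = 2, n_sessions = 14, n_anomalous = 4,
                         duration_mean = 20, seed = 21)
  cfg <- train_config(epochs = 2, steps_per_epoch = 8, seed = 1)
  rep <- suppressWarnings(
    run_experiment(ds, "cnn", "exercise", ns = 42, plan = NULL,
                   config = cfg, seed = 5))
  expect_s3_class(rep, "eval_report")
  expect_identical(nrow(rep$per_fold), 5L)
  expect_identical(rep$aggregate$metric,
                   c("precision", "recall", "f1", "accuracy"))
  expect_true(all(rep$per_fold$accuracy >= 0 & rep$per_fold$accuracy <= 1))
  expect_identical(dim(rep$confusion), c(6L, 6L))
  # mean/std across folds exactly as sample mean and (n-1) sd
  expect_equal(rep$aggregate$mean[4], mean(rep$per_fold$accuracy))
  expect_equal(rep$aggregate$sd[4], sd(rep$per_fold$accuracy))

  csv <- withr::local_tempfile(fileext = ".csv")
  md <- withr::local_tempfile(fileext = ".md")
  write_report(rep, csv, md)
  back <- read.csv(csv)
  expect_identical(nrow(back), 5L)
  expect_true(any(grepl("\\| cnn \\| exercise \\|", readLines(md))))
})

test_that("the tree ignores ablations not touching its two inputs", {
  ds <- generate_dataset(n_subjects = 2, n_sessions = 12, n_anomalous = 6,
                         duration_mean = 20, seed = 33)
  plan <- plan_five_fold(ds$manifest, seed = 2)
  base <- run_experiment(ds, "tree", "anomaly", ns = 21, plan = plan)
  same <- run_experiment(ds, "tree", "anomaly", ns = 21, plan = plan,
                         ablation = "nogyro")
  expect_identical(base$per_fold, same$per_fold)
  # flex-only and acc-only variants still run
  expect_s3_class(run_experiment(ds, "tree", "anomaly", ns = 21,
                                 plan = plan, ablation = "noimu"),
                  "eval_report")
  expect_error(run_experiment(ds, "tree", "exercise", ns = 21, plan = plan),
               "anomaly task")
})

test_that("raising inter-subject variance hurts LOSO more than pooled CV", {
  # three inter-subject variance settings on the full-size dataset; the
  # middle setting reuses the shared protocol runs
  s1 <- protocol_seeds()[1]
  five <- vapply(c(0.4, 1, 2.5), function(v) {
    protocol_accuracy(v, "cnn", "exercise", "five_fold", s1)
  }, numeric(1))
  loso <- vapply(c(0.4, 1, 2.5), function(v) {
    protocol_accuracy(v, "cnn", "exercise", "loso", s1)
  }, numeric(1))
  # LOSO accuracy strictly decreases as subjects grow more idiosyncratic
  expect_true(all(diff(loso) < 0))
  # pooled five-fold degrades less than LOSO over the same range
  expect_lt(five[1] - five[3], loso[1] - loso[3])
})
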
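#' Plan a five-fold file-level cross-validation split
#'
#' Files (whole sessions) are shuffled by seed and partitioned into five
#' test sets of near-equal size (differing by at most one); for each fold
#' the remaining 80% of files form the training set. Splitting at file
#' level prevents window-level leakage between train and test.
#'
#' @param manifest dataset manifest data.frame with an `id` column (and
#'   `subject_id` for LOSO).
#' @param seed shuffle seed.
#' @return Object of class `split_plan` with `scheme = "five_fold"` and a
#'   list of folds, each holding `train` and `test` id vectors.
#' @export
plan_five_fold <- function(manifest, seed = 1L) {
  ids <- as.character(manifest$id)
  n <- length(ids)
  if (n < 5L) stop("need at least 5 files for five-fold CV", call. = FALSE)
  set.seed(seed)
  shuffled <- sample(ids)
  cuts <- floor(seq(0, n, length.out = 6L))
  folds <- lapply(seq_len(5L), function(f) {
    test <- shuffled[(cuts[f] + 1L):cuts[f + 1L]]
    list(train = setdiff(ids, test), test = test)
  })
  structure(list(scheme = "five_fold", folds = folds), class = "split_plan")
}

#' Plan a leave-one-subject-out split
#'
#' One fold per subject (in sorted id order): all of that subject's files
#' are the test set, every other subject's files the training set. This
#' measures generalization to an unseen user.
#'
#' @inheritParams plan_five_fold
#' @return A `split_plan` with `scheme = "loso"`.
#' @export
plan_loso <- function(manifest) {
  subjects <- sort(unique(as.character(manifest$subject_id)))
  if (length(subjects) < 2L) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  ids <- as.character(manifest$id)
  folds <- lapply(subjects, function(s) {
    test <- ids[manifest$subject_id == s]
    list(train = setdiff(ids, test), test = test, subject = s)
  })
  structure(list(scheme = "loso", folds = folds), class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$test), integer(1L))
  cat(sprintf("<split_plan> %s, %d folds, test sizes: %s\n",
              x$scheme, length(x$folds), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Sensor-ablation channel sets
#'
#' Which feature channels each named ablation case retains, emulating a
#' simplified glove build: `noflex` drops the flex sensors, `nogyro` the
#' angular velocities, `noaccel` the accelerations, `noangles` the
#' filtered roll/pitch angles, `noimu` everything derived from the IMU
#' (leaving only the two flex channels); `normal` drops nothing.
#'
#' @param case one of `"normal", "noflex", "nogyro", "noaccel", "noangles",
#'   "noimu"`.
#' @return Character vector of retained channel names.
#' @export
ablation_channels <- function(case) {
  all <- feature_channels()
  dropped <- switch(case,
    normal = character(0),
    noflex = c("f1", "f2"),
    nogyro = c("gx", "gy", "gz"),
    noaccel = c("ax", "ay", "az"),
    noangles = c("roll", "pitch"),
    noimu = c("gx", "gy", "gz", "ax", "ay", "az", "roll", "pitch"),
    stop("unknown ablation case: ", case, call. = FALSE))
  setdiff(all, dropped)
}

#' Apply a sensor ablation to a feature matrix or window array
#'
#' Columns are physically removed (the model is rebuilt with the narrower
#' input), not masked: an absent sensor is absent at training time too.
#'
#' @param m feature matrix (`n x channels`, named columns) or 3-D window
#'   array.
#' @param case ablation case name, see [ablation_channels()].
#' @return The reduced matrix or array.
#' @export
apply_ablation <- function(m, case) {
  keep <- ablation_channels(case)
  if (is.matrix(m)) return(m[, keep, drop = FALSE])
  if (length(dim(m)) == 3L) return(m[, , keep, drop = FALSE])
  stop("m must be a matrix or a 3-D window array", call. = FALSE)
}

#' Classification quality metrics
#'
#' Precision, recall, f1 and accuracy. For the binary anomaly task the
#' positive class is correct exercising (label 1): precision =
#' TP / (TP + FP), recall = TP / (TP + FN), f1 their harmonic mean,
#' accuracy the overall fraction correct. For the six-way exercise task the
#' three former metrics are computed per class one-vs-rest and averaged
#' weighted by support (the number of true instances of each class).
#'
#' @param predictions predicted labels (0/1 for anomaly; exercise names or
#'   factor for exercise).
#' @param labels true labels, same length.
#' @param task `"anomaly"` or `"exercise"`.
#' @return Named list: `precision`, `recall`, `f1`, `accuracy`.
#' @export
classification_metrics <- function(predictions, labels,
                                   task = c("anomaly", "exercise")) {
  task <- match.arg(task)
  if (length(predictions) == 0L) stop("empty predictions", call. = FALSE)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  if (task == "anomaly") {
    p <- as.integer(predictions); y <- as.integer(labels)
    tp <- sum(p == 1L & y == 1L); fp <- sum(p == 1L & y == 0L)
    fn <- sum(p == 0L & y == 1L); tn <- sum(p == 0L & y == 0L)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    acc <- (tp + tn) / (tp + tn + fp + fn)
    return(list(precision = prec, recall = rec, f1 = f1, accuracy = acc))
  }
  lv <- exercise_labels()
  p <- factor(as.character(predictions), levels = lv)
  y <- factor(as.character(labels), levels = lv)
  support <- as.numeric(table(y))
  per_class <- vapply(lv, function(cl) {
    tp <- sum(p == cl & y == cl)
    fp <- sum(p == cl & y != cl)
    fn <- sum(p != cl & y == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3L))
  w <- support / sum(support)
  list(precision = sum(per_class[1L, ] * w),
       recall = sum(per_class[2L, ] * w),
       f1 = sum(per_class[3L, ] * w),
       accuracy = mean(p == y))
}

#' Row-normalized confusion matrix
#'
#' Cell `[i, j]` is the fraction of true class `i` windows predicted as
#' class `j`; occupied rows sum to 1. Rows for classes with zero support
#' are emitted as zeros with a warning rather than NaN.
#'
#' @param predictions,labels label vectors (exercise names).
#' @param levels class order; defaults to the canonical exercise order.
#' @return `length(levels)` square numeric matrix.
#' @export
confusion_normalized <- function(predictions, labels,
                                 levels = exercise_labels()) {
  p <- factor(as.character(predictions), levels = levels)
  y <- factor(as.character(labels), levels = levels)
  counts <- table(true = y, predicted = p)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    warning("zero-support classes in confusion matrix: ",
            paste(levels[rs == 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(unclass(counts), 1L, ifelse(rs == 0, 1, rs), "/")
  out
}

fold_seed <- function(seed, fold) {
  (as.integer(seed) * 1009L + fold * 9973L) %% (.Machine$integer.max - 1L) + 1L
}

#' Run the full cross-validation experiment
#'
#' The complete evaluation protocol for one configuration: per fold, models
#' are trained on the training files only (min-max scaler fitted per fold
#' on training data only), then evaluated on overlapping single-sample-
#' shifted test fragments; metrics are aggregated across folds as sample
#' mean and (n-1) standard deviation. The exercise task uses only sessions
#' of correct exercising (every file carries an exercise label, but
#' anomalous recordings such as a hand resting on the table carry no class
#' signal); the anomaly task uses all sessions with correct = positive.
#' The decision tree uses only the two hand-crafted criteria, so ablation
#' cases not touching acceleration or flex reduce to `normal` for it.
#'
#' @param dataset a `glove_dataset`.
#' @param model_kind `"cnn"` or `"tree"` (tree supports the anomaly task
#'   only).
#' @param task `"exercise"` or `"anomaly"`.
#' @param ns window length in samples.
#' @param ablation ablation case name.
#' @param plan a `split_plan`; defaults to five-fold on the manifest.
#' @param config a [train_config()] for CNN training.
#' @param seed master seed fanned out to per-fold init/batch seeds.
#' @param A complementary-filter constant for feature extraction.
#' @param features optional precomputed list of feature matrices keyed by
#'   session id (to share across experiments).
#' @return Object of class `eval_report`: `per_fold` data.frame, `aggregate`
#'   (mean/sd per metric), pooled `confusion` for the exercise task, and the
#'   configuration.
#' @export
run_experiment <- function(dataset, model_kind = c("cnn", "tree"),
                           task = c("exercise", "anomaly"), ns = 21L,
                           ablation = "normal", plan = NULL,
                           config = train_config(), seed = 1L, A = 0.98,
                           features = NULL) {
  model_kind <- match.arg(model_kind)
  task <- match.arg(task)
  if (model_kind == "tree" && task != "anomaly") {
    stop("the two-criteria tree only supports the anomaly task",
         call. = FALSE)
  }
  manifest <- dataset$manifest
  if (is.null(plan)) plan <- plan_five_fold(manifest, seed = seed)
  if (is.null(features) && model_kind == "cnn") {
    features <- lapply(dataset$sessions, feature_matrix, A = A)
  }
  info <- manifest
  rownames(info) <- info$id
  use_ids <- if (task == "exercise") info$id[!info$anomalous] else info$id

  fold_rows <- list()
  conf_pred <- character(0)
  conf_true <- character(0)
  for (fi in seq_along(plan$folds)) {
    fold <- plan$folds[[fi]]
    train_ids <- intersect(fold$train, use_ids)
    test_ids <- intersect(fold$test, use_ids)
    if (length(intersect(train_ids, test_ids))) {
      stop("split plan leaks files between train and test", call. = FALSE)
    }
    if (!length(train_ids) || !length(test_ids)) {
      stop("fold ", fi, " has an empty train or test set", call. = FALSE)
    }
    fseed <- fold_seed(seed, fi)
    if (model_kind == "tree") {
      res <- eval_fold_tree(dataset, info, train_ids, test_ids, ns, ablation)
    } else {
      res <- eval_fold_cnn(dataset, info, features, train_ids, test_ids,
                           task, ns, ablation, config, fseed)
    }
    m <- classification_metrics(res$pred, res$truth, task = task)
    fold_rows[[fi]] <- data.frame(
      fold = fi, n_test = length(res$pred),
      precision = m$precision, recall = m$recall,
      f1 = m$f1, accuracy = m$accuracy)
    if (task == "exercise") {
      conf_pred <- c(conf_pred, as.character(res$pred))
      conf_true <- c(conf_true, as.character(res$truth))
    }
  }
  per_fold <- do.call(rbind, fold_rows)
  metrics <- c("precision", "recall", "f1", "accuracy")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]]), numeric(1L)),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]]), numeric(1L)))
  confusion <- if (task == "exercise") {
    confusion_normalized(conf_pred, conf_true)
  } else NULL
  structure(list(task = task, model_kind = model_kind,
                 scheme = plan$scheme, ns = ns, ablation = ablation,
                 per_fold = per_fold, aggregate = aggregate,
                 confusion = confusion),
            class = "eval_report")
}

eval_fold_tree <- function(dataset, info, train_ids, test_ids, ns,
                           ablation) {
  keep <- ablation_channels(ablation)
  use_acc <- all(c("ax", "ay", "az") %in% keep)
  use_flex <- all(c("f1", "f2") %in% keep)
  if (!use_acc && !use_flex) {
    stop("ablation removes both tree inputs (acceleration and flex)",
         call. = FALSE)
  }
  feats <- c("s_acc", "s_flex")[c(use_acc, use_flex)]
  frag <- function(ids, overlapping) {
    do.call(rbind, lapply(ids, function(id) {
      compute_fragment_criteria(dataset$sessions[[id]], ns = ns,
                                overlapping = overlapping)
    }))
  }
  train <- frag(train_ids, overlapping = FALSE)
  test <- frag(test_ids, overlapping = TRUE)
  if (length(feats) == 1L) {
    # single-input tree: hold the other criterion constant at zero so the
    # split search can only use the retained one
    other <- setdiff(c("s_acc", "s_flex"), feats)
    train[[other]] <- 0
    test[[other]] <- 0
  }
  tree <- train_tree(train)
  list(pred = tree_predict(tree, test), truth = test$correct)
}

eval_fold_cnn <- function(dataset, info, features, train_ids, test_ids,
                          task, ns, ablation, config, fseed) {
  keep <- ablation_channels(ablation)
  get_feat <- function(id) features[[id]][, keep, drop = FALSE]
  label_of <- function(id) {
    if (task == "exercise") info[id, "exercise"]
    else as.integer(!info[id, "anomalous"])
  }
  train_files <- lapply(train_ids, function(id) {
    list(id = id, features = get_feat(id), label = label_of(id))
  })
  scaler <- fit_scaler(do.call(rbind, lapply(train_files, `[[`, "features")))
  net <- build_net(task, ns = ns, n_channels = length(keep), seed = fseed)
  cfg <- config
  cfg$seed <- fseed
  net <- train_net(net, train_files, config = cfg, scaler = scaler,
                   forbid = test_ids)
  preds <- character(0)
  truths <- character(0)
  pnum <- integer(0)
  tnum <- integer(0)
  for (id in test_ids) {
    wins <- extract_windows(get_feat(id), ns = ns, overlapping = TRUE)
    if (dim(wins)[1L] == 0L) next
    wins <- apply_scaler(wins, scaler)
    if (task == "exercise") {
      probs <- predict_exercise(net, wins)
      preds <- c(preds, exercise_labels()[max.col(probs, ties.method = "first")])
      truths <- c(truths, rep(info[id, "exercise"], dim(wins)[1L]))
    } else {
      sc <- predict_anomaly(net, wins)
      pnum <- c(pnum, binarize_anomaly(sc))
      tnum <- c(tnum, rep(as.integer(!info[id, "anomalous"]), dim(wins)[1L]))
    }
  }
  if (task == "exercise") list(pred = preds, truth = truths)
  else list(pred = pnum, truth = tnum)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s / %s | %s | ns = %d | ablation = %s\n",
              x$model_kind, x$task, x$scheme, x$ns, x$ablation))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-9s %.3f (%.3f)\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' @param report an `eval_report` (or list of them).
#' @param csv_path path for the per-fold CSV (one row per fold).
#' @param md_path optional path for a human-readable Markdown summary in
#'   the mean (sd) table layout.
#' @return `csv_path`, invisibly.
#' @export
write_report <- function(report, csv_path, md_path = NULL) {
  reports <- if (inherits(report, "eval_report")) list(report) else report
  rows <- do.call(rbind, lapply(reports, function(r) {
    cbind(model = r$model_kind, task = r$task, scheme = r$scheme,
          ns = r$ns, ablation = r$ablation, r$per_fold)
  }))
  utils::write.csv(rows, csv_path, row.names = FALSE)
  if (!is.null(md_path)) {
    lines <- c("| model | task | scheme | Ns | ablation | precision | recall | f1 | accuracy |",
               "|---|---|---|---|---|---|---|---|---|")
    for (r in reports) {
      a <- r$aggregate
      cell <- function(m) {
        i <- match(m, a$metric)
        sprintf("%.3f (%.3f)", a$mean[i], a$sd[i])
      }
      lines <- c(lines, sprintf("| %s | %s | %s | %d | %s | %s | %s | %s | %s |",
                                r$model_kind, r$task, r$scheme, r$ns,
                                r$ablation, cell("precision"), cell("recall"),
                                cell("f1"), cell("accuracy")))
    }
    writeLines(lines, md_path)
  }
  invisible(csv_path)
}
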
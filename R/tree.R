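#' Windowed two-criteria features for a session
#'
#' Cuts a session into fragments of `ns` samples and computes the two
#' hand-crafted anomaly criteria for each: `s_acc` (summed L1 acceleration)
#' and `s_flex` (summed absolute smoothed-difference of the flex signals).
#' Non-overlapping consecutive fragments (`floor(L / ns)` of them) are used
#' for decision-tree training; overlapping, single-sample-shifted fragments
#' (`L - ns + 1`) for testing.
#'
#' @param session a `glove_session`.
#' @param ns fragment length in samples.
#' @param overlapping stride-1 fragments if `TRUE`, disjoint if `FALSE`.
#' @param kernel smoothed-difference kernel for `s_flex`.
#' @return data.frame with columns `s_acc`, `s_flex`, `exercise`,
#'   `correct` (1 = correct exercising, 0 = anomalous); zero rows with a
#'   warning when the session is shorter than `ns`.
#' @export
compute_fragment_criteria <- function(session, ns, overlapping = FALSE,
                                      kernel = build_kernel()) {
  df <- session$samples
  n <- nrow(df)
  if (n < ns) {
    warning(sprintf("session shorter (%d) than fragment length (%d)", n, ns),
            call. = FALSE)
    return(data.frame(s_acc = numeric(0), s_flex = numeric(0),
                      exercise = character(0), correct = integer(0)))
  }
  starts <- if (overlapping) seq_len(n - ns + 1L)
            else seq.int(1L, by = ns, length.out = n %/% ns)
  h <- as.numeric(kernel)
  # vectorized: rolling sums via cumsum for s_acc, valid conv once for s_flex
  l1 <- abs(df$ax) + abs(df$ay) + abs(df$az)
  cl1 <- c(0, cumsum(l1))
  sacc <- cl1[starts + ns] - cl1[starts]
  fx <- abs(conv_valid(df$f1 + df$f2, h))   # position i covers rows i..i+3
  cfx <- c(0, cumsum(fx))
  nv <- ns - length(h) + 1L                  # valid positions per fragment
  sflex <- cfx[starts + nv] - cfx[starts]
  data.frame(s_acc = sacc, s_flex = sflex,
             exercise = session$exercise,
             correct = as.integer(!session$anomalous))
}

#' Train the depth-limited two-criteria decision tree
#'
#' CART with the Gini split criterion, maximum depth 3, over the two
#' features `s_acc` and `s_flex`, classifying fragments into correct (1)
#' versus anomalous (0) exercising. Fitted through \pkg{rpart} with pruning
#' disabled so the depth cap is the only complexity control.
#'
#' @param fragments data.frame with columns `s_acc`, `s_flex` and `correct`
#'   (0/1), as from [compute_fragment_criteria()]; both classes must be
#'   present.
#' @param max_depth depth cap (3 by default).
#' @return Object of class `glove_tree`.
#' @export
train_tree <- function(fragments, max_depth = 3L) {
  stopifnot(all(c("s_acc", "s_flex", "correct") %in% names(fragments)))
  if (length(unique(fragments$correct)) < 2L) {
    stop("training fragments contain a single class; need both correct ",
         "and anomalous examples", call. = FALSE)
  }
  dat <- data.frame(s_acc = fragments$s_acc, s_flex = fragments$s_flex,
                    correct = factor(fragments$correct, levels = c(0L, 1L)))
  fit <- rpart::rpart(
    correct ~ s_acc + s_flex, data = dat, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(maxdepth = max_depth, cp = 0,
                                   minsplit = 2L, minbucket = 1L,
                                   xval = 0L))
  structure(list(fit = fit, max_depth = as.integer(max_depth)),
            class = "glove_tree")
}

#' @export
print.glove_tree <- function(x, ...) {
  cat(sprintf("<glove_tree> depth %d (cap %d), %d leaves\n",
              tree_depth(x), x$max_depth,
              sum(x$fit$frame$var == "<leaf>")))
  invisible(x)
}

#' Structural depth of a trained tree
#'
#' Depth in split levels (a root-only tree has depth 0), computed from the
#' tree frame's node numbers; used to assert the depth cap structurally.
#'
#' @param tree a `glove_tree`.
#' @return Integer depth.
#' @export
tree_depth <- function(tree) {
  nodes <- as.integer(rownames(tree$fit$frame))
  as.integer(max(floor(log2(nodes))))
}

#' Classify fragments with the two-criteria tree
#'
#' Deterministic traversal; rpart routes values at a split threshold to the
#' left (<) branch.
#'
#' @param tree a `glove_tree`.
#' @param fragments data.frame with columns `s_acc`, `s_flex`.
#' @return Integer vector: 1 = correct exercising, 0 = anomaly.
#' @export
tree_predict <- function(tree, fragments) {
  stopifnot(inherits(tree, "glove_tree"))
  cls <- predict(tree$fit,
                 newdata = fragments[, c("s_acc", "s_flex"), drop = FALSE],
                 type = "class")
  as.integer(as.character(cls))
}
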
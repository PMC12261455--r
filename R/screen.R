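#' Balanced class subsample
#'
#' Virtual-screening bioassay sets are heavily unbalanced (far more
#' inactives than actives). This keeps every active molecule and subsamples
#' the inactives without replacement down to the active count, yielding a
#' balanced two-class set. Deterministic given `seed`.
#'
#' @param labels tibble with columns `name` and `label`
#'   (`active`/`inactive`), as from [read_labels()].
#' @param seed integer seed.
#' @return character vector of selected molecule names.
#' @export
balance_classes <- function(labels, seed) {
  act <- labels$name[labels$label == "active"]
  inact <- labels$name[labels$label == "inactive"]
  if (length(act) == 0L || length(inact) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (length(inact) < length(act)) {
    stop("fewer inactive than active molecules; cannot balance",
         call. = FALSE)
  }
  picked <- withr::with_seed(as.integer(seed), {
    sample(inact, length(act))
  })
  c(act, picked)
}

#' Stratified train/validation/test split
#'
#' Splits molecule names 70/15/15 (by default), stratified by class so each
#' split preserves the class balance to within one molecule.
#'
#' @param names molecule names to split.
#' @param classes class label per name.
#' @param seed integer seed.
#' @param fractions length-3 nonnegative numeric summing to 1.
#' @return list with character vectors `train`, `val`, `test` (disjoint,
#'   union = `names`) and the `seed` and `fractions` used.
#' @export
split_plan <- function(names, classes, seed,
                       fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(length(names) == length(classes), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  withr::with_seed(as.integer(seed), {
    tr <- va <- te <- character(0)
    for (cl in unique(classes)) {
      nm <- sample(names[classes == cl])
      nc <- length(nm)
      n_tr <- round(fractions[1L] * nc)
      n_va <- round(fractions[2L] * nc)
      n_tr <- min(n_tr, nc)
      n_va <- min(n_va, nc - n_tr)
      tr <- c(tr, nm[seq_len(n_tr)])
      va <- c(va, nm[n_tr + seq_len(n_va)])
      te <- c(te, nm[setdiff(seq_len(nc), seq_len(n_tr + n_va))])
    }
    list(train = tr, val = va, test = te, seed = as.integer(seed),
         fractions = fractions)
  })
}

# accuracy of a precomputed-kernel SVM trained on `tr`, scored on `sc`
svm_accuracy <- function(k, y, tr, sc, C) {
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(k[tr, tr, drop = FALSE]),
                       y[tr], kernel = "matrix", C = C, prob.model = FALSE)
  sv <- kernlab::SVindex(fit)
  pred <- kernlab::predict(
    fit,
    kernlab::as.kernelMatrix(k[sc, tr, drop = FALSE][, sv, drop = FALSE]))
  mean(pred == y[sc])
}

#' Repeated SVM evaluation of a kernel
#'
#' The screening harness: for each repeat, draw a balanced subsample,
#' split it 70/15/15 stratified by class, fit a precomputed-kernel SVM on
#' the training block for every `C` in the grid, pick the `C` with the best
#' validation accuracy (ties broken toward the smallest `C`), and record
#' the test accuracy of that model. Test labels are never consulted before
#' the final scoring. Reports the mean and sample standard deviation
#' (n - 1 denominator) over repeats.
#'
#' @param gram a [gram_matrix()] covering all labeled molecules.
#' @param labels tibble with `name`, `label` columns.
#' @param repeats number of repeats (default 20).
#' @param c_grid SVM cost grid (default `10^(-3:3)`).
#' @param seed integer seed; repeat `r` derives its own seed `seed + r`.
#' @param rebalance draw a fresh balanced subsample each repeat (default);
#'   `FALSE` freezes the subsample drawn with `seed`.
#' @return object of class `kernel_screen` with per-repeat results and
#'   summary statistics; see [tidy.kernel_screen()] and
#'   [glance.kernel_screen()].
#' @export
evaluate_kernel <- function(gram, labels, repeats = 20L,
                            c_grid = 10^(-3:3), seed = 1L,
                            rebalance = TRUE) {
  k <- gram$values
  missing <- setdiff(labels$name, rownames(k))
  if (length(missing) > 0L) {
    stop("gram matrix does not cover: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y_all <- setNames(factor(labels$label), labels$name)
  c_grid <- sort(c_grid)
  frozen <- if (!rebalance) balance_classes(labels, seed) else NULL
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rs <- as.integer(seed) + r
    sel <- if (rebalance) balance_classes(labels, rs) else frozen
    cls <- as.character(y_all[sel])
    sp <- NULL
    for (try in 0:9) {  # re-derive the seed if a split drops a class
      cand <- split_plan(sel, cls, rs + try * 1000L)
      ok <- length(unique(y_all[cand$train])) == 2L &&
        length(cand$val) > 0L && length(cand$test) > 0L
      if (ok) { sp <- cand; break }
      message(sprintf("repeat %d: degenerate split, re-deriving seed", r))
    }
    if (is.null(sp)) stop("could not produce a valid split", call. = FALSE)
    val_acc <- vapply(c_grid, function(C) {
      svm_accuracy(k, y_all, sp$train, sp$val, C)
    }, numeric(1))
    best_c <- c_grid[which.max(val_acc)]  # first max = smallest C
    acc <- svm_accuracy(k, y_all, sp$train, sp$test, best_c)
    rows[[r]] <- tibble::tibble(
      repeat_id = r, C = best_c, val_accuracy = max(val_acc),
      test_accuracy = acc,
      n_train = length(sp$train), n_val = length(sp$val),
      n_test = length(sp$test))
  }
  results <- dplyr::bind_rows(rows)
  structure(
    list(results = results,
         mean_accuracy = mean(results$test_accuracy),
         sd_accuracy = stats::sd(results$test_accuracy),
         repeats = repeats, seed = as.integer(seed),
         kernel = gram$config$kernel),
    class = "kernel_screen")
}

#' @export
print.kernel_screen <- function(x, ...) {
  cat(sprintf("<kernel_screen> %s: accuracy %.3f +/- %.3f over %d repeats\n",
              x$kernel, x$mean_accuracy,
              ifelse(is.na(x$sd_accuracy), 0, x$sd_accuracy), x$repeats))
  invisible(x)
}

#' Per-repeat screening results
#'
#' @param x a `kernel_screen` from [evaluate_kernel()].
#' @param ... unused.
#' @return tibble with one row per repeat: chosen `C`, validation and test
#'   accuracy, split sizes.
#' @export
tidy.kernel_screen <- function(x, ...) x$results

#' One-row screening summary
#'
#' @param x a `kernel_screen` from [evaluate_kernel()].
#' @param ... unused.
#' @return tibble with kernel name, repeats, mean and SD of test accuracy.
#' @export
glance.kernel_screen <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, repeats = x$repeats,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}

#' Plot per-repeat test accuracies
#'
#' @param object a `kernel_screen` from [evaluate_kernel()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kernel_screen <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repeat_id,
                                   y = .data$test_accuracy)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "repeat", y = "test accuracy",
                  title = sprintf("%s: %.3f +/- %.3f", object$kernel,
                                  object$mean_accuracy,
                                  object$sd_accuracy)) +
    ggplot2::theme_minimal()
}

#' Paired Wilcoxon signed-rank comparison of two kernels
#'
#' Two-sided signed-rank test on paired per-dataset accuracies. Pairs with
#' zero difference are dropped (the standard signed-rank convention). For
#' 14 or fewer informative pairs the p-value is computed by exact
#' enumeration of all sign assignments of the (mid)ranks, which remains
#' exact under tied differences; for larger samples the normal
#' approximation of [stats::wilcox.test()] is used.
#'
#' @param acc_a,acc_b paired accuracy vectors over the same datasets
#'   (length >= 5).
#' @return list with `p_value`, `statistic` (sum of positive-difference
#'   ranks), `n` (informative pairs) and `method`.
#' @export
compare_kernels <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  if (length(acc_a) < 5L) {
    stop("need at least 5 paired datasets", call. = FALSE)
  }
  d <- acc_a - acc_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_, n = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 14L) {
    # exact sign-flip null: distribution of the rank sum over all 2^n signs
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    p <- min(1, 2 * min(mean(sums <= v + 1e-9), mean(sums >= v - 1e-9)))
    list(p_value = p, statistic = v, n = n, method = "exact")
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(acc_a, acc_b, paired = TRUE)$p.value)
    list(p_value = p, statistic = v, n = n, method = "normal approximation")
  }
}
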
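#' Pixel confusion counts of a binary segmentation
#'
#' @param pred_mask logical/0-1 matrix of predicted positives.
#' @param ref_mask logical/0-1 matrix of reference positives; same dims.
#' @return list with `TP`, `FP`, `FN`, `TN` (pixel counts).
#' @export
confusion_counts <- function(pred_mask, ref_mask) {
  if (!all(dim(pred_mask) == dim(ref_mask)))
    stop("prediction and reference masks have different dims")
  p <- as.logical(pred_mask); r <- as.logical(ref_mask)
  list(TP = sum(p & r), FP = sum(p & !r), FN = sum(!p & r), TN = sum(!p & !r))
}

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, Dice similarity
#' coefficient `2TP/(2TP+FP+FN)` and intersection-over-union
#' `TP/(TP+FP+FN)`. A zero denominator yields `NA` for that score (an
#' undefined metric is signalled, never silently reported as 0); the identity
#' `dsc = 2 iou / (1 + iou)` holds whenever both are defined.
#'
#' @param counts a [confusion_counts] result (or any list with TP/FP/FN).
#' @return list with `precision`, `sensitivity`, `dsc`, `iou`.
#' @export
seg_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, FP, FN) < 0)) stop("negative counts")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(precision   = safe(TP, TP + FP),
       sensitivity = safe(TP, TP + FN),
       dsc         = safe(2 * TP, 2 * TP + FP + FN),
       iou         = safe(TP, TP + FP + FN))
}

#' Evaluate a predicted tumor mask against a reference
#'
#' Convenience wrapper: the positive class is the target (tumor) class only,
#' i.e. class-map label 2 when class maps rather than masks are supplied.
#'
#' @param pred predicted binary mask or integer class map.
#' @param ref reference binary mask or integer class map.
#' @return list with the four metric scores and the confusion counts.
#' @export
evaluate_masks <- function(pred, ref) {
  if (is.integer(pred) || max(pred) > 1) pred <- pred > 1
  if (is.integer(ref) || max(ref) > 1) ref <- ref > 1
  cc <- confusion_counts(pred, ref)
  c(seg_metrics(cc), list(counts = cc))
}

#' Slide-level data splits
#'
#' Partitions slide identifiers (never tiles: all tiles of a slide stay on
#' the same side) either into a train/test split by fraction or into `k`
#' cross-validation folds. Ids are sorted before the seeded shuffle, so the
#' assignment is invariant under input reordering; fold sizes differ by at
#' most one.
#'
#' @param slide_ids character or integer vector of slide identifiers.
#' @param train_fraction fraction of slides assigned to training (the count
#'   is rounded to the nearest slide); mutually exclusive with `k`.
#' @param k number of cross-validation folds.
#' @param seed RNG seed.
#' @return For a fraction: list with `train` and `test`. For `k`: a list of
#'   `k` character vectors (the folds).
#' @examples
#' split_slides(1:122, train_fraction = 0.377, seed = 1)  # 46 train, 76 test
#' @export
split_slides <- function(slide_ids, train_fraction = NULL, k = NULL, seed = 1L) {
  ids <- sort(as.character(unique(slide_ids)))
  n <- length(ids)
  set.seed(as.integer(seed))
  shuffled <- sample(ids)
  if (!is.null(train_fraction)) {
    if (train_fraction <= 0 || train_fraction >= 1) stop("train fraction must be in (0, 1)")
    n_train <- round(train_fraction * n)
    return(list(train = sort(shuffled[seq_len(n_train)]),
                test = sort(shuffled[-seq_len(n_train)])))
  }
  if (is.null(k)) stop("supply either train_fraction or k")
  k <- as.integer(k)
  if (k > n) stop(sprintf("cannot make %d folds from %d slides", k, n))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) sort(shuffled[fold_of == f]))
}

#' Fisher's least-significant-difference test
#'
#' One-way ANOVA across the groups followed by all pairwise comparisons using
#' the pooled mean-square error: for groups *i*, *j* the statistic is
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))` with the ANOVA
#' residual degrees of freedom and a two-sided p-value. No multiplicity
#' correction is applied — that is precisely what the LSD procedure is. With
#' exactly two groups the result coincides with a pooled two-sample t-test.
#'
#' @param groups named list of numeric score vectors (>= 2 groups, each with
#'   >= 2 values). `NA` scores (undefined metrics on empty-positive slides)
#'   are dropped with a message.
#' @param conf_level confidence level of the pairwise intervals.
#' @return An `lsd_result`: data frame `pairs` (group_i, group_j, mean_diff,
#'   std_error, t, p_value, ci_lower, ci_upper) plus attributes `mse` and
#'   `df_residual`.
#' @examples
#' lsd_test(list(A = c(0.90, 0.92, 0.88), B = c(0.50, 0.55, 0.45)))
#' @export
lsd_test <- function(groups, conf_level = 0.95) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  n_na <- sum(vapply(groups, function(g) sum(is.na(g)), numeric(1)))
  if (n_na > 0) {
    message(sprintf("dropping %d undefined score(s) from the LSD analysis", n_na))
    groups <- lapply(groups, function(g) g[!is.na(g)])
  }
  if (any(lengths(groups) < 2L)) stop("every group needs at least two scores")
  score <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  fit <- stats::aov(score ~ grp)
  df_res <- stats::df.residual(fit)
  mse <- stats::deviance(fit) / df_res
  if (!is.finite(mse) || mse <= 1e-10 * max(stats::var(score), .Machine$double.eps))
    stop("degenerate variance: pooled mean-square error is zero")
  means <- tapply(score, grp, mean)
  ns <- tapply(score, grp, length)
  cmb <- utils::combn(names(groups), 2L)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(p) {
    gi <- cmb[1L, p]; gj <- cmb[2L, p]
    diff <- unname(means[gi] - means[gj])
    se <- sqrt(mse * (1 / ns[[gi]] + 1 / ns[[gj]]))
    tval <- diff / se
    data.frame(group_i = gi, group_j = gj, mean_diff = diff, std_error = se,
               t = tval, p_value = 2 * stats::pt(-abs(tval), df_res),
               ci_lower = diff - tcrit * se, ci_upper = diff + tcrit * se)
  }))
  structure(list(pairs = pairs, mse = mse, df_residual = df_res,
                 means = means, n = unlist(ns)),
            class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("Fisher's LSD: %d groups, MSE = %.5g, residual df = %d\n",
              length(x$means), x$mse, x$df_residual))
  print(x$pairs, row.names = FALSE, digits = 4)
  invisible(x)
}
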
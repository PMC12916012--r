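#' Area under the ROC curve
#'
#' Rank-based AUC via the Mann-Whitney U identity, with average ranks for
#' ties. Scores are oriented so that larger means stronger evidence for the
#' positive class.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1, logical, or a factor with two levels).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_binary(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop("labels must be binary")
  labels
}

#' True-positive rate at a fixed false-positive rate
#'
#' The decision threshold is the empirical `(1 - fpr_target)` quantile of
#' the negative-class scores (type-1, i.e. an observed order statistic);
#' the returned value is the fraction of positives strictly above it. With
#' completely tied scores the threshold is unreachable and the TPR is 0 for
#' any `fpr_target < 1`.
#'
#' @inheritParams roc_auc
#' @param fpr_target Target false-positive rate in (0, 1).
#' @return TPR in `[0, 1]`.
#' @export
tpr_at_fpr <- function(scores, labels, fpr_target) {
  labels <- .as_binary(labels)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("both classes must be present")
  thr <- stats::quantile(scores[labels == 0], probs = 1 - fpr_target,
                         type = 1, names = FALSE)
  mean(scores[labels == 1] > thr)
}

#' Rediscovery rate between two ranked score tables
#'
#' The fraction of the training table's top-`n` items that also appear in
#' the test table's top-`n`, items ranked by descending score with a
#' deterministic tie-break on the item identifier. Symmetric in the two
#' tables.
#'
#' @param train_scores,test_scores Data.frames with columns `item_id` and
#'   `score`.
#' @param n Size of the top lists.
#' @return Overlap fraction in `[0, 1]`.
#' @export
rediscovery_rate <- function(train_scores, test_scores, n) {
  top_n <- function(tab) {
    if (n > nrow(tab)) stop("n exceeds table size")
    o <- order(-tab$score, as.character(tab$item_id))
    as.character(tab$item_id[o][seq_len(n)])
  }
  length(intersect(top_n(train_scores), top_n(test_scores))) / n
}

#' Score a replicate table for ranking-based evaluation
#'
#' Maps p-values to `-log10(p)` (larger = stronger colocalization
#' evidence) with the LRT statistic as a deterministic tie-break, the
#' orientation used for "top significant results" selection.
#'
#' @param pvalue,lambda Vectors from a replicate table.
#' @return Numeric score vector.
#' @export
coloc_score <- function(pvalue, lambda = NULL) {
  s <- -log10(pmax(pvalue, .Machine$double.xmin))
  if (!is.null(lambda)) s <- s + 1e-9 * lambda
  s
}

#' AUC as a function of the colocalization labeling threshold
#'
#' For each threshold `t`, replicates with `|true rG| >= t` are labeled
#' positive (for `t = 0`, positives are `rG != 0`) and the AUC of the
#' method's score is computed within each scenario cell defined by
#' `group_cols`. Cells where the labeling yields a single class are
#' reported with `NA` and a reason.
#'
#' @param records Replicate table carrying `rg_true`, `pvalue`, `lambda`
#'   (e.g. from [run_scenario()]).
#' @param thresholds Labeling thresholds.
#' @param group_cols Columns defining scenario cells (default `"h2_true"`,
#'   plus `"r0"` if present).
#' @return Data.frame with one row per cell x threshold: `threshold`,
#'   grouping columns, `auc`, `n_pos`, `n_neg`, `note`.
#' @export
auc_by_threshold <- function(records, thresholds = c(0.3, 0.5, 0.8),
                             group_cols = NULL) {
  if (is.null(group_cols))
    group_cols <- intersect(c("h2_true", "r0"), names(records))
  records <- records[is.finite(records$pvalue), , drop = FALSE]
  key <- if (length(group_cols))
    interaction(records[group_cols], drop = TRUE) else factor(rep(1, nrow(records)))
  out <- list()
  for (cell in levels(key)) {
    sub <- records[key == cell, , drop = FALSE]
    for (t in thresholds) {
      lab <- if (t > 0) as.integer(abs(sub$rg_true) >= t)
             else as.integer(sub$rg_true != 0)
      meta <- sub[1, group_cols, drop = FALSE]
      row <- cbind(data.frame(threshold = t), meta,
                   data.frame(auc = NA_real_, n_pos = sum(lab == 1),
                              n_neg = sum(lab == 0), note = ""))
      if (length(unique(lab)) < 2) {
        row$note <- "single class"
      } else {
        row$auc <- roc_auc(coloc_score(sub$pvalue, sub$lambda), lab)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Null-calibration summary of the LRT statistic
#'
#' For replicates generated at the boundary of the null, summarizes how the
#' observed statistics compare with the asymptotic 50:50 mixture of a point
#' mass at zero and a 1-df chi-square: the fraction of exact zeros (within
#' `1e-8`), empirical rejection rates of the chi-bar-square p-value at the
#' requested levels, and a QQ table of observed versus mixture quantiles.
#'
#' @param lambda Observed LRT statistics.
#' @param alpha Rejection levels to report.
#' @param qq_probs Probabilities for the QQ table.
#' @return List with `n`, `zero_mass`, `rejection` (named vector), and
#'   `qq` (data.frame with `prob`, `observed`, `expected`).
#' @export
null_calibration <- function(lambda, alpha = c(0.01, 0.05, 0.1),
                             qq_probs = seq(0.05, 0.95, by = 0.05)) {
  lambda <- lambda[is.finite(lambda)]
  if (!length(lambda)) stop("no usable statistics")
  p <- pvalue_chibar(pmax(lambda, 0))
  rejection <- vapply(alpha, function(a) mean(p <= a), 0)
  names(rejection) <- paste0("alpha_", alpha)
  # mixture quantile: 0 below the point mass, else chi^2_1 quantile
  mix_q <- function(pr) {
    q <- numeric(length(pr))
    hi <- pr > 0.5
    q[hi] <- stats::qchisq(2 * pr[hi] - 1, df = 1)
    q
  }
  qq <- data.frame(prob = qq_probs,
                   observed = stats::quantile(lambda, qq_probs, names = FALSE,
                                              type = 1),
                   expected = mix_q(qq_probs))
  list(n = length(lambda), zero_mass = mean(abs(lambda) <= 1e-8),
       rejection = rejection, qq = qq)
}

#' Read an external score table
#'
#' TSV with columns `item_id`, `method`, `score`, and optionally `truth`;
#' the exchange format that lets externally computed colocalization scores
#' be evaluated alongside this package's results. If `score_is_pvalue` the
#' scores are mapped to `-log10(p)` so that larger always means stronger
#' evidence.
#'
#' @param path TSV path.
#' @param score_is_pvalue Set `TRUE` if the score column holds p-values.
#' @return Data.frame with the table.
#' @export
read_score_table <- function(path, score_is_pvalue = FALSE) {
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("item_id", "method", "score")
  if (!all(need %in% names(dt)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(dt$score))) stop("scores must be finite")
  if (score_is_pvalue) dt$score <- coloc_score(dt$score)
  dt
}
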
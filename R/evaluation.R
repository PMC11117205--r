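#' Counting accuracy, RMSE and MAE
#'
#' The relative-error counting accuracy is
#' `(1/n) * sum(1 - |p - phat| / p) * 100` over images, where `p` is the
#' ground-truth count (must be positive) and `phat` the predicted count.
#' Accuracy is deliberately not clamped: a prediction off by more than the
#' ground truth makes its term negative. RMSE and MAE are the usual root
#' mean squared and mean absolute deviations of the per-image counts;
#' `countMAE <= countRMSE` always.
#'
#' @param gt integer vector of ground-truth counts, all `> 0` for accuracy.
#' @param pred integer vector of predicted counts, same length.
#' @return a single numeric value (accuracy in percent; RMSE/MAE in
#'   objects).
#' @examples
#' countAccuracy(1691, 1611)  # 95.27
#' countAccuracy(1935, 1888)  # 97.57
#' @export
countAccuracy <- function(gt, pred) {
  check_pairs(gt, pred)
  if (any(gt <= 0)) stop("ground-truth counts must be positive")
  mean(1 - abs(gt - pred) / gt) * 100
}

#' @rdname countAccuracy
#' @export
countRMSE <- function(gt, pred) {
  check_pairs(gt, pred)
  sqrt(mean((gt - pred)^2))
}

#' @rdname countAccuracy
#' @export
countMAE <- function(gt, pred) {
  check_pairs(gt, pred)
  mean(abs(gt - pred))
}

check_pairs <- function(gt, pred) {
  if (length(gt) == 0L) stop("empty list of evaluation pairs")
  if (length(gt) != length(pred)) stop("gt and pred must have equal length")
  if (anyNA(gt) || anyNA(pred)) stop("NA counts")
  invisible(NULL)
}

#' Per-group counting report
#'
#' One row of accuracy / RMSE / MAE per group (batch id or density level)
#' plus a `"Total"` row computed over the concatenated pairs — never the
#' mean of the per-group metrics.
#'
#' @param gt,pred per-image ground-truth and predicted counts.
#' @param group group label per image.
#' @return data.frame with columns `group`, `n_images`, `accuracy_percent`,
#'   `rmse`, `mae`; last row is `"Total"`.
#' @export
groupedCountReport <- function(gt, pred, group) {
  check_pairs(gt, pred)
  if (length(group) != length(gt)) stop("group must match gt length")
  keys <- unique(as.character(group))
  one <- function(g, p, key) data.frame(
    group = key, n_images = length(g),
    accuracy_percent = countAccuracy(g, p),
    rmse = countRMSE(g, p), mae = countMAE(g, p))
  rows <- lapply(keys, function(k) {
    i <- group == k
    one(gt[i], pred[i], k)
  })
  rows[[length(rows) + 1L]] <- one(gt, pred, "Total")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary of absolute counting errors
#'
#' Order statistics of `|p - phat|` across images, the numbers a box plot
#' of counting errors displays.
#'
#' @param gt,pred per-image counts.
#' @return named numeric vector `min`, `max`, `median`, `mean`.
#' @export
countErrorSummary <- function(gt, pred) {
  check_pairs(gt, pred)
  e <- abs(gt - pred)
  c(min = min(e), max = max(e), median = median(e), mean = mean(e))
}

#' Write a counting report as CSV or a Markdown table
#'
#' @param report data.frame from [groupedCountReport()].
#' @param path output file (.csv or .md).
#' @return `path`, invisibly.
#' @export
writeCountReport <- function(report, path) {
  if (grepl("\\.md$", path, ignore.case = TRUE)) {
    fmt <- function(x) ifelse(is.numeric(x), sprintf("%.2f", x), x)
    lines <- c("| Group | Images | Accuracy (%) | RMSE | MAE |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %.2f | %.2f |",
                       report$group, report$n_images,
                       report$accuracy_percent, report$rmse, report$mae))
    writeLines(lines, path)
  } else {
    write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
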
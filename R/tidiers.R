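#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a confusion matrix into a long tibble
#'
#' @param x A `pm_confusion`.
#' @param ... Unused.
#' @return Tibble with `true`, `decoded`, `n` and `pct` (row percentage).
#' @exportS3Method generics::tidy
tidy.pm_confusion <- function(x, ...) {
  m <- unclass(x)
  out <- tibble::tibble(
    true = rep(rownames(m), times = ncol(m)),
    decoded = rep(colnames(m), each = nrow(m)),
    n = as.integer(m)
  )
  tot <- rowSums(m)[out$true]
  out$pct <- ifelse(tot == 0, NA_real_, 100 * out$n / tot)
  out
}

#' One-row summary of a confusion matrix
#'
#' For 8-condition confusions this is [decode_summary()]; for 4-direction
#' confusions, overall accuracy.
#'
#' @inheritParams tidy.pm_confusion
#' @return One-row tibble of accuracies (%).
#' @exportS3Method generics::glance
glance.pm_confusion <- function(x, ...) {
  if (nrow(x) == 8) return(decode_summary(x))
  tibble::tibble(accuracy = 100 * sum(diag(x)) / sum(x))
}

#' Tidy a cross-temporal map into a long tibble
#'
#' @param x A `pm_xtmap`.
#' @param ... Unused.
#' @return Tibble with `train_start_ms`, `test_start_ms`, `accuracy`.
#' @exportS3Method generics::tidy
tidy.pm_xtmap <- function(x, ...) {
  g <- x$grid
  tibble::tibble(
    train_start_ms = rep(g$start_ms, times = nrow(g)),
    test_start_ms = rep(g$start_ms, each = nrow(g)),
    accuracy = as.numeric(x$accuracy)
  )
}

#' One-row summary of a cross-temporal map
#'
#' @inheritParams tidy.pm_xtmap
#' @return Tibble with the task, mean diagonal (same-window) accuracy over
#'   delay windows and mean off-diagonal accuracy between delay windows.
#' @exportS3Method generics::glance
glance.pm_xtmap <- function(x, ...) {
  d <- which(x$grid$is_delay)
  sub <- x$accuracy[d, d, drop = FALSE]
  tibble::tibble(task = x$task,
                 diag_accuracy = mean(diag(sub)),
                 offdiag_accuracy = mean(sub[row(sub) != col(sub)]))
}
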
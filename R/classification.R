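#' Confusion matrix of live/dead status from matched oysters
#'
#' Cross-tabulates video-assigned status against field-determined status
#' for individually matched oysters, with field status as the truth and
#' "living" as the positive class.
#'
#' @param records Data.frame with columns `field_status` and `video_status`,
#'   each the literal string `"living"` or `"dead"` (an `oyster_id` column,
#'   if present, must be unique).
#' @return An object of class `confusion_matrix`: a list with counts
#'   `n_ll` (field living, video living), `n_ld` (field living, video
#'   dead), `n_dl` (field dead, video living), `n_dd` and `total`.
#' @examples
#' m <- confusion_matrix(n_ll = 112, n_ld = 25, n_dl = 26, n_dd = 107)
#' classification_metrics(m)
#' @export
build_confusion <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("empty input: no matched oyster records", call. = FALSE)
  req <- c("field_status", "video_status")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  ok <- c("living", "dead")
  bad <- !(records$field_status %in% ok) | !(records$video_status %in% ok)
  if (any(bad))
    stop("non-binary status in rows ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         ' (statuses must be "living" or "dead")', call. = FALSE)
  if (!is.null(records$oyster_id) && anyDuplicated(records$oyster_id))
    stop("duplicated oyster_id", call. = FALSE)
  confusion_matrix(
    n_ll = sum(records$field_status == "living" &
                 records$video_status == "living"),
    n_ld = sum(records$field_status == "living" &
                 records$video_status == "dead"),
    n_dl = sum(records$field_status == "dead" &
                 records$video_status == "living"),
    n_dd = sum(records$field_status == "dead" &
                 records$video_status == "dead")
  )
}

#' @rdname build_confusion
#' @param n_ll,n_ld,n_dl,n_dd Cell counts (field status first: `n_ld` is
#'   field-living scored dead on video).
#' @export
confusion_matrix <- function(n_ll, n_ld, n_dl, n_dd) {
  x <- c(n_ll = n_ll, n_ld = n_ld, n_dl = n_dl, n_dd = n_dd)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("confusion-matrix cells must be non-negative integers",
         call. = FALSE)
  structure(c(as.list(x), list(total = sum(x))), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$n_ll, x$n_ld, x$n_dl, x$n_dd), 2, 2,
              dimnames = list(video = c("living", "dead"),
                              field = c("living", "dead")))
  cat("Confusion matrix (field status in columns, video status in rows)\n")
  print(m)
  cat(sprintf("total matched oysters: %d\n", x$total))
  invisible(x)
}

#' Classification-success statistics from a confusion matrix
#'
#' Computes the standard agreement statistics for live/dead scoring with
#' "living" as the positive class: correct classification rate
#' `(n_ll + n_dd) / total`; sensitivity `n_ll / (n_ll + n_ld)` (truly
#' living scored living); specificity `n_dd / (n_dl + n_dd)`; Cohen's
#' kappa `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = ccr` and
#' chance agreement `p_e` from the product of marginals; and the two error
#' shares `n_ld / total` (false negatives) and `n_dl / total` (false
#' positives).
#'
#' A statistic whose defining marginal is zero is returned as `NA` (with a
#' note in the `undefined` attribute) rather than failing the whole call.
#'
#' @param m A `confusion_matrix` (from [build_confusion()] or
#'   [confusion_matrix()]).
#' @return An object of class `classification_metrics`: named numeric
#'   vector with elements `ccr`, `sensitivity`, `specificity`, `kappa`,
#'   `false_negative_share`, `false_positive_share`.
#' @examples
#' classification_metrics(confusion_matrix(112, 25, 26, 107))
#' @export
classification_metrics <- function(m) {
  stopifnot(inherits(m, "confusion_matrix"))
  if (m$total <= 0)
    stop("empty confusion matrix: metrics undefined", call. = FALSE)
  tot <- m$total
  ccr <- (m$n_ll + m$n_dd) / tot
  pos <- m$n_ll + m$n_ld   # field living
  neg <- m$n_dl + m$n_dd   # field dead
  sens <- if (pos > 0) m$n_ll / pos else NA_real_
  spec <- if (neg > 0) m$n_dd / neg else NA_real_
  p_e <- (pos / tot) * ((m$n_ll + m$n_dl) / tot) +
    (neg / tot) * ((m$n_ld + m$n_dd) / tot)
  kappa <- if (p_e < 1) (ccr - p_e) / (1 - p_e) else NA_real_
  out <- c(ccr = ccr, sensitivity = sens, specificity = spec, kappa = kappa,
           false_negative_share = m$n_ld / tot,
           false_positive_share = m$n_dl / tot)
  undefined <- names(out)[is.na(out)]
  structure(out, undefined = undefined, class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, digits = 2, ...) {
  cat("Live/dead classification success (positive class: living)\n")
  lab <- c(ccr = "correct classification rate",
           sensitivity = "sensitivity",
           specificity = "specificity",
           kappa = "kappa",
           false_negative_share = "false-negative share",
           false_positive_share = "false-positive share")
  for (nm in names(lab))
    cat(sprintf("  %-28s %s\n", lab[[nm]],
                ifelse(is.na(x[[nm]]), "undefined",
                       formatC(x[[nm]], digits = digits, format = "f"))))
  invisible(x)
}
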
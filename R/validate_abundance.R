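#' Merge the living confidence categories of reading records
#'
#' Video scoring distinguishes "probably living" from "possibly living";
#' for abundance work the two are summed into a single "living" count
#' (the dead count passes through unchanged).
#'
#' @param readings Data.frame of reading records (columns
#'   `count_probably_living`, `count_possibly_living`, `count_dead`).
#' @return The input with an added `count_living` column.
#' @examples
#' merge_categories(data.frame(count_probably_living = 3,
#'                             count_possibly_living = 2,
#'                             count_dead = 1))$count_living  # 5
#' @export
merge_categories <- function(readings) {
  readings$count_living <-
    readings$count_probably_living + readings$count_possibly_living
  readings
}

section_key <- function(d) paste(d$site, d$transect, d$section, sep = ".")

#' Join per-section video means to the field census
#'
#' Averages each section's video counts over all observer-by-reading
#' replicates (or over a single observer with `observer =`) and joins them
#' to the field-determined truth, producing the per-section comparison
#' table behind correlation, recovery-rate and error-profile analyses.
#'
#' @param readings Data.frame of reading records.
#' @param truth Data.frame of section truth (columns `site`, `transect`,
#'   `section`, `true_living`, `true_dead`, optionally
#'   `vegetation_cover`).
#' @param observer Optional observer index; if supplied, means use that
#'   observer's readings only.
#' @return Data.frame with one row per section: `site`, `transect`,
#'   `section`, `field_living`, `field_dead`, `video_living_mean` (merged
#'   categories), `video_probably_mean`, `video_dead_mean`, and
#'   `vegetation_cover` when present in `truth`.
#' @export
build_comparison <- function(readings, truth, observer = NULL) {
  if (!is.null(observer))
    readings <- readings[readings$observer %in% observer, , drop = FALSE]
  readings <- merge_categories(readings)
  rk <- section_key(readings)
  tk <- section_key(truth)
  missing_keys <- setdiff(unique(rk), tk)
  if (length(missing_keys))
    stop("sections in readings absent from truth: ",
         paste(utils::head(missing_keys, 5), collapse = ", "),
         call. = FALSE)
  agg <- function(v) tapply(v, factor(rk, levels = tk), mean)
  out <- data.frame(
    site = truth$site, transect = truth$transect, section = truth$section,
    field_living = truth$true_living, field_dead = truth$true_dead,
    video_living_mean = as.numeric(agg(readings$count_living)),
    video_probably_mean = as.numeric(agg(readings$count_probably_living)),
    video_dead_mean = as.numeric(agg(readings$count_dead))
  )
  if (!is.null(truth$vegetation_cover))
    out$vegetation_cover <- truth$vegetation_cover
  out
}

#' Squared Pearson correlation between two abundance vectors
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return The squared Pearson correlation coefficient.
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need two vectors of equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a vector has zero variance", call. = FALSE)
  stats::cor(x, y)^2
}

#' Video recovery rate of a status category
#'
#' Total video-estimated count divided by the total field count for a
#' status — the complement of the video method's underestimation bias.
#' For living oysters the video side can be either the merged "living"
#' category or the higher-confidence "probably living" category alone.
#'
#' @param comparisons Output of [build_comparison()].
#' @param status `"living"` or `"dead"`.
#' @param category For living: `"merged"` (default) or `"probably"`.
#' @return A single fraction (1 = perfect recovery; < 1 = underestimate).
#' @export
recovery_rate <- function(comparisons, status = c("living", "dead"),
                          category = c("merged", "probably")) {
  status <- match.arg(status)
  category <- match.arg(category)
  if (status == "living") {
    field <- sum(comparisons$field_living)
    video <- if (category == "merged") sum(comparisons$video_living_mean)
             else sum(comparisons$video_probably_mean)
  } else {
    field <- sum(comparisons$field_dead)
    video <- sum(comparisons$video_dead_mean)
  }
  if (field <= 0)
    stop("undefined recovery rate: field total for status \"", status,
         "\" is zero", call. = FALSE)
  video / field
}

#' Per-section error profile of video abundance estimates
#'
#' Absolute error is the video mean minus the field count; relative error
#' divides by the field count and is flagged undefined (NA, with
#' `relative_defined = FALSE`) for field-zero sections rather than
#' reported as infinite.
#'
#' @param comparisons Output of [build_comparison()].
#' @param status `"living"` (merged categories) or `"dead"`.
#' @return Data.frame with `site`, `transect`, `section`, `field_count`,
#'   `absolute_error`, `relative_error`, `relative_defined`.
#' @export
error_profile <- function(comparisons, status = c("living", "dead")) {
  status <- match.arg(status)
  field <- if (status == "living") comparisons$field_living
           else comparisons$field_dead
  video <- if (status == "living") comparisons$video_living_mean
           else comparisons$video_dead_mean
  abs_err <- video - field
  defined <- field > 0
  rel_err <- ifelse(defined, abs_err / field, NA_real_)
  data.frame(
    site = comparisons$site, transect = comparisons$transect,
    section = comparisons$section, field_count = field,
    absolute_error = abs_err, relative_error = rel_err,
    relative_defined = defined
  )
}
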
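## Error propagation for survey planning: predicted variance of the mean
## abundance within a site, as a function of the design knobs
## a (transects), b (sections per transect), c (observers) and
## n (readings per observer).

check_query <- function(a, b, c, n) {
  q <- c(a = a, b = b, c = c, n = n)
  if (any(!is.finite(q)) || any(q < 1) || any(q != round(q)))
    stop("invalid query: a, b, c, n must be integers >= 1", call. = FALSE)
  invisible(q)
}

#' Predicted variance of a survey's mean abundance
#'
#' The propagation formula for the within-site variance of the mean count
#' per section under a design with `a` transects, `b` sections per
#' transect, `c` observers and `n` readings per observer:
#'
#' `V = s_tr2/a + s_se2/(a b) + s_ob2/c + s_e2/(a b c n)`
#'
#' Site-level variability is outside the formula's scope (it predicts
#' precision within a site-sized spatial unit, not across sites), and by
#' default the two small observer-by-spatial interaction components are
#' omitted as well; `include_interactions = TRUE` adds
#' `s_trob2/(a c) + s_seob2/(a b c)`, the full balanced-design variance.
#'
#' @param vc A [variance_components] object (counts per section squared).
#' @param a,b,c,n Design knobs (integers >= 1).
#' @param include_interactions Add the interaction terms (default FALSE).
#' @return Variance of the mean, in (counts per section)^2.
#' @examples
#' mean_variance(variance_components(), a = 1, b = 1, c = 1, n = 1) # 29.0
#' @export
mean_variance <- function(vc, a, b, c, n, include_interactions = FALSE) {
  vc <- as_variance_components(vc)
  check_query(a, b, c, n)
  v <- vc[["s_tr2"]] / a + vc[["s_se2"]] / (a * b) + vc[["s_ob2"]] / c +
    vc[["s_e2"]] / (a * b * c * n)
  if (include_interactions)
    v <- v + vc[["s_trob2"]] / (a * c) + vc[["s_seob2"]] / (a * b * c)
  v
}

#' Predicted standard error per square metre
#'
#' Converts the predicted standard error of the mean count per section
#' into a density standard error by dividing by the section area.
#'
#' @inheritParams mean_variance
#' @param design The [survey_design()] supplying the section area.
#' @return Standard error in counts per square metre.
#' @examples
#' # about 1 oyster / m^2 when ~10 m^2 are sampled
#' se_per_m2(variance_components(), a = 1, b = 3, c = 1, n = 1,
#'           design = survey_design())
#' @export
se_per_m2 <- function(vc, a, b, c, n, design,
                      include_interactions = FALSE) {
  if (design$section_area <= 0)
    stop("section area must be positive", call. = FALSE)
  sqrt(mean_variance(vc, a, b, c, n, include_interactions)) /
    design$section_area
}

#' Precision of a grid of candidate designs
#'
#' Evaluates the propagation formula over the Cartesian product of design
#' knobs, reporting the variance, the per-section and per-square-metre
#' standard errors, and the total area each design samples.
#'
#' @inheritParams se_per_m2
#' @param a_range,b_range,c_range,n_range Integer vectors of candidate
#'   values.
#' @return Data.frame sorted by `total_area` with columns `a`, `b`, `c`,
#'   `n`, `variance_of_mean`, `se_per_section`, `se_per_m2`, `total_area`.
#' @export
scenario_grid <- function(vc, a_range, b_range, c_range, n_range, design,
                          include_interactions = FALSE) {
  stopifnot(length(a_range) > 0, length(b_range) > 0, length(c_range) > 0,
            length(n_range) > 0)
  g <- expand.grid(a = a_range, b = b_range, c = c_range, n = n_range,
                   KEEP.OUT.ATTRS = FALSE)
  g$variance_of_mean <- mapply(function(a, b, c, n)
    mean_variance(vc, a, b, c, n, include_interactions),
    g$a, g$b, g$c, g$n)
  g$se_per_section <- sqrt(g$variance_of_mean)
  g$se_per_m2 <- g$se_per_section / design$section_area
  g$total_area <- g$a * g$b * design$section_area
  g[order(g$total_area, g$se_per_m2), , drop = FALSE]
}

divisors <- function(k) {
  d <- seq_len(k)
  d[k %% d == 0]
}

#' Standard error as a function of total area sampled
#'
#' For each total area in the grid, enumerates every split of the
#' corresponding number of sections into `a` transects of `b` sections
#' (integer factorisations) and reports the envelope (minimum and maximum)
#' of the predicted per-square-metre standard error. A narrow envelope
#' means precision is a function of total area only, not of how the area
#' is divided into transects.
#'
#' @inheritParams se_per_m2
#' @param area_grid Total areas in m^2; each is rounded to a whole number
#'   of sections. Defaults to 1..50 sections.
#' @return Data.frame with `total_area`, `n_sections`, `se_min`, `se_max`
#'   (counts per m^2) and the `a` of the best split.
#' @export
se_vs_area <- function(vc, design, area_grid = NULL, c = 1, n = 1,
                       include_interactions = FALSE) {
  if (is.null(area_grid))
    area_grid <- design$section_area * seq_len(50)
  if (any(area_grid <= 0)) stop("areas must be positive", call. = FALSE)
  rows <- lapply(area_grid, function(area) {
    k <- max(1L, as.integer(round(area / design$section_area)))
    se <- vapply(divisors(k), function(a)
      se_per_m2(vc, a, k %/% a, c, n, design, include_interactions),
      numeric(1))
    data.frame(total_area = k * design$section_area, n_sections = k,
               se_min = min(se), se_max = max(se),
               best_a = divisors(k)[which.min(se)])
  })
  do.call(rbind, rows)
}

#' Smallest sampled area achieving a target precision
#'
#' Inverts the precision-versus-area relationship: finds the smallest
#' number of sections (hence total area) whose best transect/section split
#' achieves a per-square-metre standard error at or below the target, for
#' fixed numbers of observers and readings. The observer component does
#' not shrink with area, so targets below the asymptotic floor
#' `sqrt(s_ob2 / c) / section_area` are infeasible and raise an error
#' naming the floor.
#'
#' @inheritParams se_per_m2
#' @param target_se_per_m2 Desired standard error (counts per m^2).
#' @param max_sections Search limit.
#' @return List with `total_area`, `a`, `b`, `se_per_m2` achieved.
#' @export
required_area <- function(vc, design, target_se_per_m2, c = 1, n = 1,
                          include_interactions = FALSE,
                          max_sections = 100000L) {
  vc <- as_variance_components(vc)
  floor_se <- sqrt(vc[["s_ob2"]] / c) / design$section_area
  if (target_se_per_m2 <= floor_se)
    stop(sprintf(
      "infeasible target: %.4g <= observer floor %.4g counts/m^2 (does not shrink with area)",
      target_se_per_m2, floor_se), call. = FALSE)
  for (k in seq_len(max_sections)) {
    # for fixed k = a*b only the transect (and trob) term depends on the
    # split, through 1/a, so the best split is always a = k, b = 1
    se <- se_per_m2(vc, k, 1, c, n, design, include_interactions)
    if (se <= target_se_per_m2)
      return(list(total_area = k * design$section_area,
                  a = k, b = 1L, se_per_m2 = se))
  }
  stop("target not reached within max_sections", call. = FALSE)
}

#' Count-to-density conversion
#'
#' @param count Number of organisms.
#' @param area Area in square metres (> 0).
#' @return Density in organisms per square metre.
#' @examples
#' density_per_m2(60, 16)   # 3.75
#' density_per_m2(40, 3.2)  # 12.5
#' @export
density_per_m2 <- function(count, area) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("area must be positive", call. = FALSE)
  count / area
}
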
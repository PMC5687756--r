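## Nested mixed-model ANOVA for the site/transect/section x observer layout.
##
## The supported model is exactly the survey's: Site fixed; Observer random
## and crossed with everything; Transect(Site) and Section(Transect, Site) a
## nested random chain; replicate readings as residual. Sums of squares are
## computed from cell and marginal means; because the only imbalance allowed
## is in transects-per-site (a nested factor, fully crossed with Observer),
## the decomposition below is orthogonal and the term SS add up to the total
## SS.

anova_terms <- c("ob", "si", "tr", "se", "obsi", "trob", "seob", "resid")

anova_term_labels <- c(
  ob = "Observer, = Ob", si = "Site, = Si", tr = "Transect(Si), = Tr(Si)",
  se = "Section(Tr, Si), = Se(Tr, Si)", obsi = "Ob*Si", trob = "Tr(Si)*Ob",
  seob = "Se(Tr, Si)*Ob", resid = "Residual")

#' Specification of the nested video-survey model
#'
#' Fixes the model fitted by [build_anova()] and [estimate_vc_reml()]:
#' response column, the factor structure (Site fixed; Observer,
#' Transect(Site) and Section(Transect, Site) random; all
#' observer-by-spatial interactions; replicate readings as residual) and
#' the expected-mean-square convention used for F-test denominators.
#'
#' Under the `"restricted"` convention (the default, following the
#' classical mixed-model ANOVA tradition) interactions between a random
#' factor and the fixed Site factor do not enter the random main effect's
#' expected mean square; `"unrestricted"` is the convention implied by the
#' independent-random-effects parameterisation that REML software fits.
#' The choice changes F-test denominators and method-of-moments estimates,
#' not the sums of squares.
#'
#' @param response Response column; `"count_living"` (the merged living
#'   category, computed on the fly via [merge_categories()] if absent),
#'   or any count column of the reading records.
#' @param convention `"restricted"` or `"unrestricted"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response = "count_living",
                       convention = c("restricted", "unrestricted")) {
  structure(list(response = response,
                 convention = match.arg(convention),
                 factors = list(
                   site = list(status = "fixed", nesting = character(0)),
                   observer = list(status = "random", nesting = character(0)),
                   transect = list(status = "random", nesting = "site"),
                   section = list(status = "random",
                                  nesting = c("transect", "site")))),
            class = "model_spec")
}

# validate completeness and pull the response vector
prepare_readings <- function(readings, spec, design) {
  if (spec$response == "count_living" &&
      is.null(readings[["count_living"]]))
    readings <- merge_categories(readings)
  if (is.null(readings[[spec$response]]))
    stop("response column not found: ", spec$response, call. = FALSE)
  full <- reading_grid(design)
  kf <- function(d) paste(d$site, d$transect, d$section, d$observer,
                          d$reading, sep = ".")
  have <- kf(readings)
  want <- kf(full)
  missing_cells <- setdiff(want, have)
  if (length(missing_cells))
    stop("incomplete design: missing reading cells ",
         paste(utils::head(missing_cells, 5), collapse = ", "),
         if (length(missing_cells) > 5) " ...", call. = FALSE)
  if (anyDuplicated(have))
    stop("duplicated reading cells in data", call. = FALSE)
  readings[match(want, have), , drop = FALSE]
}

#' Nested ANOVA table (SS, df, MS) for reading-level counts
#'
#' Decomposes the total sum of squares of per-section video counts into
#' the eight terms of the survey model. Degrees of freedom follow the
#' standard nested-factorial rules; with `a` sites, `t_i` transects per
#' site, `b` sections, `c` observers and `n` readings they are
#' `c-1`, `a-1`, `sum(t_i - 1)`, `sum(t_i) (b-1)`, `(c-1)(a-1)`,
#' `(c-1) sum(t_i - 1)`, `(c-1) sum(t_i) (b-1)` and `N - cells`.
#'
#' @param readings Reading records covering the full design (every section
#'   read by every observer the configured number of times).
#' @param design The [survey_design()].
#' @param spec A [model_spec()].
#' @return A data.frame of class `vc_anova` with columns `term`, `source`,
#'   `df`, `ss`, `ms`.
#' @examples
#' d <- survey_design()
#' r <- generate_vc_dataset(d, generator_config(seed = 1))
#' build_anova(r, d)$df  # 1 2 10 52 2 10 52 130
#' @export
build_anova <- function(readings, design, spec = model_spec()) {
  readings <- prepare_readings(readings, spec, design)
  y <- readings[[spec$response]]
  g <- readings

  mean_by <- function(...) {
    id <- interaction(..., drop = TRUE)
    stats::ave(y, id)
  }
  ybar <- mean(y)
  m_ob <- mean_by(g$observer)
  m_si <- mean_by(g$site)
  m_tr <- mean_by(g$site, g$transect)
  m_se <- mean_by(g$site, g$transect, g$section)
  m_obsi <- mean_by(g$observer, g$site)
  m_trob <- mean_by(g$observer, g$site, g$transect)
  m_seob <- mean_by(g$observer, g$site, g$transect, g$section)

  ss <- c(
    ob = sum((m_ob - ybar)^2),
    si = sum((m_si - ybar)^2),
    tr = sum((m_tr - m_si)^2),
    se = sum((m_se - m_tr)^2),
    obsi = sum((m_obsi - m_ob - m_si + ybar)^2),
    trob = sum((m_trob - m_tr - m_obsi + m_si)^2),
    seob = sum((m_seob - m_se - m_trob + m_tr)^2),
    resid = sum((y - m_seob)^2)
  )

  a <- design$n_sites
  t_i <- design$transects_per_site
  b <- design$sections_per_transect
  c_ <- design$observers
  n_ <- design$readings_per_observer
  df <- c(
    ob = c_ - 1L,
    si = a - 1L,
    tr = sum(t_i - 1L),
    se = sum(t_i) * (b - 1L),
    obsi = (c_ - 1L) * (a - 1L),
    trob = (c_ - 1L) * sum(t_i - 1L),
    seob = (c_ - 1L) * sum(t_i) * (b - 1L),
    resid = sum(t_i) * b * c_ * (n_ - 1L)
  )
  if (any(df < 1))
    stop("degenerate design: a term has zero degrees of freedom",
         call. = FALSE)
  out <- data.frame(term = anova_terms,
                    source = unname(anova_term_labels[anova_terms]),
                    df = as.integer(df[anova_terms]),
                    ss = unname(ss[anova_terms]))
  out$ms <- out$ss / out$df
  class(out) <- c("vc_anova", "data.frame")
  out
}

#' @export
print.vc_anova <- function(x, digits = 3, ...) {
  cat("Nested ANOVA of video counts\n")
  df <- as.data.frame(x)
  if (!is.null(df$ss)) df$ss <- signif(df$ss, digits + 2)
  if (!is.null(df$ms)) df$ms <- signif(df$ms, digits + 2)
  if (!is.null(df$f)) df$f <- round(df$f, 2)
  if (!is.null(df$p)) df$p <- round(df$p, 2)
  if (!is.null(df$vc)) df$vc <- round(df$vc, 1)
  print(df[, setdiff(names(df), "term")], row.names = FALSE)
  invisible(x)
}
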
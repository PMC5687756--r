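## Expected mean squares by the Cornfield-Tukey algorithm for the survey
## model, and the F-tests / method-of-moments estimators they imply.
##
## Subscript bookkeeping: O = observer, S = site (fixed), T = transect
## (nested in S), E = section (nested in T, S), R = replicate reading.
## A variance component appears in a term's EMS when the term's subscripts
## are a subset of the component's; under the restricted convention a
## component is struck out when any of its *live* (non-nesting) extra
## subscripts belongs to a fixed factor. Its coefficient is the number of
## observations per level combination of the component.

ems_subscripts <- list(
  ob = c("O"), si = c("S"), tr = c("S", "T"), se = c("S", "T", "E"),
  obsi = c("O", "S"), trob = c("O", "S", "T"), seob = c("O", "S", "T", "E"),
  resid = c("O", "S", "T", "E", "R")
)
# live (non-nesting) subscripts of each random component
ems_live <- list(
  s_ob2 = "O", s_tr2 = "T", s_se2 = "E", s_obsi2 = c("O", "S"),
  s_trob2 = c("O", "T"), s_seob2 = c("O", "E"),
  s_e2 = character(0)  # error: present in every EMS
)
ems_component_term <- c(
  s_ob2 = "ob", s_tr2 = "tr", s_se2 = "se", s_obsi2 = "obsi",
  s_trob2 = "trob", s_seob2 = "seob", s_e2 = "resid")

#' Expected mean squares for the survey design
#'
#' Derives, for every ANOVA term, the linear combination of variance
#' components (plus a fixed-site quadratic for the Site row) making up its
#' expected mean square, by the Cornfield-Tukey rules. With a balanced
#' design (`t` transects at every site) the coefficients are exact; when
#' transects-per-site differ, coefficients that involve the
#' transects-per-site count use its harmonic mean and the table is flagged
#' approximate (REML is then the authoritative estimator).
#'
#' @param design The [survey_design()].
#' @param convention `"restricted"` (default) or `"unrestricted"`; see
#'   [model_spec()].
#' @return An object of class `ems_table`: a list with `coef` (terms x
#'   components matrix), `site_quadratic` (logical per term), `convention`
#'   and `approx`.
#' @examples
#' e <- derive_ems(survey_design(transects_per_site = c(4, 4, 4)))
#' e$coef["se", ]  # s_e2 + n s_seob2 + c n s_se2
#' @export
derive_ems <- function(design, convention = c("restricted",
                                              "unrestricted")) {
  convention <- match.arg(convention)
  a <- design$n_sites
  t_i <- design$transects_per_site
  b <- design$sections_per_transect
  c_ <- design$observers
  n_ <- design$readings_per_observer
  approx <- length(unique(t_i)) > 1L
  if (approx)
    warning("unequal transects-per-site: EMS coefficients use the ",
            "harmonic-mean transect count and are approximate; ",
            "prefer estimate_vc_reml() for variance components",
            call. = FALSE)
  t_h <- length(t_i) / sum(1 / t_i)  # harmonic mean
  N <- sum(t_i) * b * c_ * n_

  # observations per level combination of each component's subscript set
  cells <- c(
    s_ob2 = N / c_,
    s_tr2 = b * c_ * n_,
    s_se2 = c_ * n_,
    s_obsi2 = t_h * b * n_,
    s_trob2 = b * n_,
    s_seob2 = n_,
    s_e2 = 1
  )
  site_cells <- t_h * b * c_ * n_  # per-site observations (quadratic coef)

  fixed_subs <- "S"
  coef <- matrix(0, length(anova_terms), length(vc_names),
                 dimnames = list(anova_terms, vc_names))
  for (u in anova_terms) {
    su <- ems_subscripts[[u]]
    for (comp in vc_names) {
      sc <- ems_subscripts[[ems_component_term[[comp]]]]
      if (!all(su %in% sc)) next
      extra_live <- setdiff(intersect(ems_live[[comp]], sc), su)
      if (comp == "s_e2") extra_live <- character(0)
      if (convention == "restricted" && any(extra_live %in% fixed_subs))
        next
      coef[u, comp] <- cells[[comp]]
    }
  }
  structure(list(coef = coef,
                 site_quadratic = stats::setNames(anova_terms == "si",
                                                  anova_terms),
                 site_quadratic_coef = site_cells,
                 convention = convention, approx = approx),
            class = "ems_table")
}

#' @export
print.ems_table <- function(x, ...) {
  cat(sprintf("Expected mean squares (%s convention%s)\n", x$convention,
              if (x$approx) ", approximate coefficients" else ""))
  comp_label <- sub("^s_(.*)2$", "\\1", colnames(x$coef))
  for (u in rownames(x$coef)) {
    nz <- which(x$coef[u, ] > 0)
    parts <- sprintf("%g*s2_%s", x$coef[u, nz], comp_label[nz])
    if (x$site_quadratic[[u]])
      parts <- c(parts, sprintf("%g*Q(Si)", x$site_quadratic_coef))
    cat(sprintf("  %-30s %s\n", anova_term_labels[[u]],
                paste(rev(parts), collapse = " + ")))
  }
  invisible(x)
}

# denominator of the F test for term u: linear combination of the other
# mean squares whose EMS equals EMS(u) minus the tested effect
ems_denominator <- function(ems, u) {
  target <- ems$coef[u, ]
  if (!ems$site_quadratic[[u]]) {
    own <- names(ems_component_term)[ems_component_term == u]
    target[own] <- 0
  }
  rows <- setdiff(anova_terms, c(u, "si"))
  A <- t(ems$coef[rows, , drop = FALSE])
  x <- qr.solve(A, target)
  x[abs(x) < 1e-10] <- 0
  if (max(abs(A %*% x - target)) > 1e-8)
    return(NULL)
  stats::setNames(x, rows)
}

#' F-tests for the nested ANOVA
#'
#' Fills in F statistics and p-values for every testable term. Each term's
#' denominator is the mean square — or linear combination of mean squares,
#' a quasi-F with Satterthwaite denominator degrees of freedom — whose
#' expectation equals the numerator's expected mean square with the tested
#' effect removed. Terms for which no denominator can be constructed, or
#' whose combined denominator turns out non-positive, are reported
#' untestable (`NA`).
#'
#' @param anova A `vc_anova` table from [build_anova()].
#' @param ems The matching [derive_ems()] table.
#' @return The ANOVA table with added columns `f`, `df_den`, `p` and
#'   `denominator` (a label naming the mean squares used).
#' @export
f_tests <- function(anova, ems) {
  stopifnot(inherits(anova, "vc_anova"), inherits(ems, "ems_table"))
  ms <- stats::setNames(anova$ms, anova$term)
  df <- stats::setNames(anova$df, anova$term)
  anova$f <- NA_real_
  anova$df_den <- NA_real_
  anova$p <- NA_real_
  anova$denominator <- NA_character_
  for (i in seq_len(nrow(anova))) {
    u <- anova$term[i]
    if (u == "resid") next
    w <- ems_denominator(ems, u)
    if (is.null(w)) next
    nz <- w[w != 0]
    den <- sum(nz * ms[names(nz)])
    if (!is.finite(den) || den <= 0) next
    df_den <- den^2 / sum((nz * ms[names(nz)])^2 / df[names(nz)])
    anova$f[i] <- ms[[u]] / den
    anova$df_den[i] <- df_den
    anova$p[i] <- stats::pf(anova$f[i], df[[u]], df_den, lower.tail = FALSE)
    anova$denominator[i] <- paste(
      sprintf("%+g*MS[%s]", nz, names(nz)), collapse = " ")
  }
  anova
}

#' Method-of-moments variance components from the ANOVA table
#'
#' Solves the linear system `MS = EMS(VC)` over the seven random terms for
#' the variance components (the classical ANOVA estimator). Negative
#' solutions are truncated to zero; the raw values are kept in the `raw`
#' attribute — on balanced designs the raw estimates coincide with REML
#' whenever they are all non-negative (under the unrestricted convention
#' that REML fits).
#'
#' @inheritParams f_tests
#' @return A [variance_components] object (`method = "MoM"`), with
#'   attribute `raw` holding the untruncated solution.
#' @export
estimate_vc_mom <- function(anova, ems) {
  stopifnot(inherits(anova, "vc_anova"), inherits(ems, "ems_table"))
  rows <- setdiff(anova_terms, "si")
  A <- ems$coef[rows, vc_names, drop = FALSE]
  ms <- stats::setNames(anova$ms, anova$term)[rows]
  raw <- tryCatch(stats::setNames(as.numeric(solve(A, ms)), vc_names),
                  error = function(e)
                    stop("singular EMS system for this design",
                         call. = FALSE))
  vc <- as_variance_components(pmax(raw, 0), method = "MoM")
  attr(vc, "raw") <- raw
  vc
}
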
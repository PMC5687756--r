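#' REML estimation of the survey variance components
#'
#' Fits the Gaussian mixed model of the survey (Site fixed; Observer,
#' Transect(Site), Section(Transect, Site) and all observer-by-spatial
#' interactions as independent random intercepts) by restricted maximum
#' likelihood via [lme4::lmer()], and maps the fitted variances onto the
#' package's component names. REML handles the transects-per-site
#' imbalance exactly and is therefore the authoritative estimator for
#' unbalanced surveys; components driven to the boundary are reported as
#' exactly 0.
#'
#' Degenerate layouts shrink the model: with a single site the Site fixed
#' effect and the observer-by-site interaction are dropped (the latter is
#' then indistinguishable from the observer main effect and reported 0),
#' and with a single observer all observer terms are dropped.
#'
#' @param readings Reading records covering the full design.
#' @param design The [survey_design()].
#' @param spec A [model_spec()] (only the response column is used; REML
#'   always fits the unrestricted parameterisation).
#' @return A [variance_components] object (`method = "REML"`) with the
#'   restricted log-likelihood in the `logLik` attribute.
#' @examples
#' d <- survey_design()
#' r <- generate_vc_dataset(d, generator_config(seed = 1))
#' estimate_vc_reml(r, d)
#' @export
estimate_vc_reml <- function(readings, design, spec = model_spec()) {
  readings <- prepare_readings(readings, spec, design)
  dat <- data.frame(
    y = readings[[spec$response]],
    site = factor(readings$site),
    ob = factor(readings$observer),
    tr = interaction(readings$site, readings$transect, drop = TRUE),
    se = interaction(readings$site, readings$transect, readings$section,
                     drop = TRUE)
  )
  dat$obsi <- interaction(dat$ob, dat$site, drop = TRUE)
  dat$trob <- interaction(dat$ob, dat$tr, drop = TRUE)
  dat$seob <- interaction(dat$ob, dat$se, drop = TRUE)

  multi_site <- nlevels(dat$site) > 1L
  multi_ob <- nlevels(dat$ob) > 1L
  terms <- c(
    if (multi_ob) "(1 | ob)",
    "(1 | tr)", "(1 | se)",
    if (multi_ob && multi_site) "(1 | obsi)",
    if (multi_ob) "(1 | trob)", if (multi_ob) "(1 | seob)"
  )
  fixed <- if (multi_site) "y ~ site" else "y ~ 1"
  form <- stats::as.formula(paste(c(fixed, terms), collapse = " + "))

  fit <- suppressMessages(lme4::lmer(
    form, data = dat, REML = TRUE,
    control = lme4::lmerControl(optimizer = "bobyqa",
                                optCtrl = list(rhoend = 1e-12),
                                check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  vc_tab <- as.data.frame(lme4::VarCorr(fit))
  est <- stats::setNames(vc_tab$vcov, vc_tab$grp)
  pick <- function(nm) if (nm %in% names(est)) est[[nm]] else 0
  vc <- variance_components(
    s_ob2 = pick("ob"), s_tr2 = pick("tr"), s_se2 = pick("se"),
    s_obsi2 = pick("obsi"), s_trob2 = pick("trob"),
    s_seob2 = pick("seob"), s_e2 = pick("Residual"),
    method = "REML")
  attr(vc, "logLik") <- as.numeric(stats::logLik(fit))
  vc
}

#' Full variance-component report for a survey dataset
#'
#' Convenience wrapper producing the standard analysis table: nested ANOVA
#' (df, MS), EMS-based F-tests, and REML variance components, in one
#' data.frame shaped like a published variance-component table.
#'
#' @inheritParams estimate_vc_reml
#' @param convention EMS convention for the F-tests (see [model_spec()]).
#' @return A `vc_anova` data.frame with columns `source`, `df`, `ms`, `f`,
#'   `p` and `vc` (REML estimates; `NA` for the fixed Site row), carrying
#'   the [variance_components] in the `vc` attribute.
#' @export
fit_variance_components <- function(readings, design, spec = model_spec(),
                                    convention = spec$convention) {
  anova <- build_anova(readings, design, spec)
  ems <- derive_ems(design, convention)
  anova <- f_tests(anova, ems)
  vc <- estimate_vc_reml(readings, design, spec)
  slot <- stats::setNames(rep(NA_real_, nrow(anova)), anova$term)
  for (comp in vc_names)
    slot[[ems_component_term[[comp]]]] <- vc[[comp]]
  anova$vc <- unname(slot[anova$term])
  attr(anova, "vc") <- vc
  anova
}
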
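# observations per level combination of each component, counted directly
# on the design lattice
counting_oracle <- function(design) {
  g <- towvid:::reading_grid(design)
  cells <- list(
    s_ob2 = g$observer,
    s_tr2 = paste(g$site, g$transect),
    s_se2 = paste(g$site, g$transect, g$section),
    s_obsi2 = paste(g$observer, g$site),
    s_trob2 = paste(g$observer, g$site, g$transect),
    s_seob2 = paste(g$observer, g$site, g$transect, g$section),
    s_e2 = seq_len(nrow(g))
  )
  vapply(cells, function(k) nrow(g) / length(unique(k)), numeric(1))
}

test_that("EMS coefficients equal observations per component level", {
  d <- balanced_design(t = 4, b = 5, c = 2, n = 2)
  ems <- derive_ems(d)
  oracle <- counting_oracle(d)
  for (comp in names(oracle)) {
    col <- ems$coef[, comp]
    expect_true(all(col[col > 0] == oracle[[comp]]),
                info = comp)
  }
  # residual EMS is the error variance alone
  expect_equal(ems$coef["resid", ], c(s_ob2 = 0, s_tr2 = 0, s_se2 = 0,
                                      s_obsi2 = 0, s_trob2 = 0,
                                      s_seob2 = 0, s_e2 = 1))
})

test_that("the section row is s_e2 + n s_seob2 + c n s_se2", {
  d <- balanced_design(t = 5, b = 5, c = 2, n = 2)
  ems <- derive_ems(d)
  expect_equal(ems$coef["se", ],
               c(s_ob2 = 0, s_tr2 = 0, s_se2 = 4, s_obsi2 = 0,
                 s_trob2 = 0, s_seob2 = 2, s_e2 = 1))
  # transect row additionally carries trob and the transect component
  expect_equal(ems$coef["tr", ],
               c(s_ob2 = 0, s_tr2 = 20, s_se2 = 4, s_obsi2 = 0,
                 s_trob2 = 10, s_seob2 = 2, s_e2 = 1))
})

test_that("the conventions differ exactly on fixed-crossed interactions", {
  d <- balanced_design(t = 4, b = 4, c = 2, n = 2)
  res <- derive_ems(d, "restricted")$coef
  unr <- derive_ems(d, "unrestricted")$coef
  diff <- which(res != unr, arr.ind = TRUE)
  # only the observer main-effect row gains the observer-by-site component
  expect_equal(nrow(diff), 1L)
  expect_equal(rownames(res)[diff[1, "row"]], "ob")
  expect_equal(colnames(res)[diff[1, "col"]], "s_obsi2")
})

test_that("unequal transects-per-site flags the EMS table approximate", {
  expect_warning(e <- derive_ems(study_design()), "harmonic")
  expect_true(e$approx)
  expect_false(derive_ems(balanced_design())$approx)
})

test_that("F denominators follow the EMS subtraction rule", {
  d <- balanced_design(t = 4, b = 4, c = 2, n = 2)
  ems <- derive_ems(d)
  ms <- c(ob = 12, si = 80, tr = 30, se = 25, obsi = 2, trob = 3,
          seob = 1.5, resid = 1.2)
  df <- c(ob = 1, si = 2, tr = 9, se = 36, obsi = 2, trob = 9, seob = 36,
          resid = 96)
  tab <- f_tests(manual_anova(df, ms), ems)
  den <- stats::setNames(tab$denominator, tab$term)
  expect_match(den[["seob"]], "MS\\[resid\\]")
  expect_match(den[["ob"]], "MS\\[trob\\]")
  expect_match(den[["trob"]], "MS\\[seob\\]")
  expect_equal(tab$f[tab$term == "seob"], 1.5 / 1.2)
  expect_equal(tab$f[tab$term == "ob"], 12 / 3)
  # the quasi-F for site combines three mean squares
  expect_equal(den[["si"]], "+1*MS[tr] +1*MS[obsi] -1*MS[trob]")
  expect_equal(tab$f[tab$term == "si"], 80 / (30 + 2 - 3))
})

test_that("published-style table reproduces its significance pattern", {
  # df and 1-dp mean squares of a surveyed 3-site design; the p column
  # recomputed from them agrees with the published rounding to within the
  # input's own rounding error
  ems <- suppressWarnings(derive_ems(study_design()))
  tab <- manual_anova(c(1, 2, 10, 52, 2, 10, 52, 130),
                      c(18.3, 345.0, 128.5, 106.3, 0.8, 2.7, 1.4, 1.7))
  out <- f_tests(tab, ems)
  expected_p <- c(0.03, 0.12, 0.31, 0.00, 0.74, 0.07, 0.75)
  expect_true(all(abs(out$p[1:7] - expected_p) < 0.04))
  expect_true(is.na(out$p[out$term == "resid"]))
})

test_that("method-of-moments inverts the EMS system exactly", {
  d <- balanced_design(t = 3, b = 4, c = 2, n = 2)
  ems <- derive_ems(d, "unrestricted")
  vc_true <- c(s_ob2 = 0.4, s_tr2 = 1.2, s_se2 = 9, s_obsi2 = 0.3,
               s_trob2 = 0.6, s_seob2 = 0.2, s_e2 = 2)
  ms <- drop(ems$coef[towvid:::anova_terms != "si", ] %*% vc_true)
  df <- c(ob = 1, tr = 6, se = 27, obsi = 2, trob = 6, seob = 27,
          resid = 144)
  tab <- manual_anova(c(df[1], 2, df[2:7]),
                      c(ms[1], 50, ms[2:7]))
  vc_hat <- estimate_vc_mom(tab, ems)
  expect_equal(unclass(vc_hat)[names(vc_true)], vc_true, tolerance = 1e-10)

  # negatives are truncated but the raw solution is preserved
  ms2 <- ms; ms2[["tr"]] <- 0.1
  tab2 <- manual_anova(c(df[1], 2, df[2:7]), c(ms2[1], 50, ms2[2:7]))
  vc2 <- estimate_vc_mom(tab2, ems)
  expect_equal(vc2[["s_tr2"]], 0)
  expect_lt(attr(vc2, "raw")[["s_tr2"]], 0)
})

test_that("F-test type-I error is calibrated under a null component", {
  d <- survey_design(n_sites = 2, transects_per_site = c(3, 3),
                     sections_per_transect = 3, observers = 2,
                     readings_per_observer = 2)
  ems <- derive_ems(d)
  cfg <- generator_config(site_effects = c(-1, 1),
                          vc = variance_components(
                            s_ob2 = 0.5, s_tr2 = 1, s_se2 = 4,
                            s_obsi2 = 0.2, s_trob2 = 0, s_seob2 = 0.5,
                            s_e2 = 1), seed = NULL)
  set.seed(123)
  rej <- mean(replicate(1000, {
    r <- generate_vc_dataset(d, cfg)
    tab <- f_tests(build_anova(r, d), ems)
    tab$p[tab$term == "trob"] < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})
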
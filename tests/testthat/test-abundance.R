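test_that("category merging is additive and monotone", {
  r <- data.frame(count_probably_living = 3, count_possibly_living = 2,
                  count_dead = 1)
  expect_equal(merge_categories(r)$count_living, 5)
  z <- data.frame(count_probably_living = 0, count_possibly_living = 0,
                  count_dead = 0)
  expect_equal(merge_categories(z)$count_living, 0)
  set.seed(5)
  rr <- data.frame(count_probably_living = rpois(50, 3),
                   count_possibly_living = rpois(50, 2),
                   count_dead = rpois(50, 2))
  expect_true(all(merge_categories(rr)$count_living >=
                    rr$count_probably_living))
})

test_that("section comparison averages replicates and validates the join", {
  d <- tiny_design()
  cfg <- generator_config(mode = "mechanistic", grand_mean = 6,
                          site_effects = c(0, 0), seed = 9)
  truth <- generate_field_truth(d, cfg)
  video <- generate_video_observations(truth, d, cfg)
  comp <- build_comparison(video$readings, truth$sections)
  expect_equal(nrow(comp), nrow(truth$sections))
  # the mean over the 2x2 observer/reading replicates, by hand
  r <- merge_categories(video$readings)
  k1 <- r$site == 1 & r$transect == 1 & r$section == 1
  expect_equal(comp$video_living_mean[comp$site == 1 & comp$transect == 1 &
                                        comp$section == 1],
               mean(r$count_living[k1]))
  # single-observer means differ in general
  comp1 <- build_comparison(video$readings, truth$sections, observer = 1)
  expect_equal(nrow(comp1), nrow(comp))
  # unmatched section key is named in the error
  bad <- video$readings
  bad$section[1] <- 99
  expect_error(build_comparison(bad, truth$sections), "1.1.99")
})

test_that("squared correlation behaves at its limits and under rescaling", {
  x <- c(1, 3, 5, 7, 11)
  expect_equal(correlation_r2(x, x), 1)
  expect_equal(correlation_r2(x, 2 - 3 * x), 1)
  set.seed(12)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(correlation_r2(a, b), 0.01)
  y <- x + c(0.1, -0.2, 0.3, 0, -0.1)
  expect_equal(correlation_r2(x, y), correlation_r2(5 * x - 2, y / 3 + 1))
  expect_error(correlation_r2(x, rep(1, 5)), "zero variance")
  expect_error(correlation_r2(1:2, 1:2), "length")
})

test_that("recovery rates track detection and category merging", {
  d <- tiny_design()
  perfect <- generator_config(mode = "mechanistic", grand_mean = 8,
                              site_effects = c(0, 0), p_detect_living = 1,
                              p_detect_dead = 1, p_live_classified_dead = 0,
                              p_dead_classified_living = 0, seed = 31)
  truth <- generate_field_truth(d, perfect)
  video <- generate_video_observations(truth, d, perfect)
  comp <- build_comparison(video$readings, truth$sections)
  expect_equal(recovery_rate(comp, "living", "merged"), 1)
  expect_equal(recovery_rate(comp, "dead"), 1)

  # p = 0.8 with no misclassification: merged recovery ~ 0.8
  big <- survey_design(n_sites = 1, transects_per_site = 2,
                       sections_per_transect = 50, observers = 2,
                       readings_per_observer = 2)
  cfg <- generator_config(mode = "mechanistic", grand_mean = 50,
                          site_effects = 0, p_detect_living = 0.8,
                          p_live_classified_dead = 0,
                          p_dead_classified_living = 0, seed = 32)
  tr2 <- generate_field_truth(big, cfg)
  v2 <- generate_video_observations(tr2, big, cfg)
  c2 <- build_comparison(v2$readings, tr2$sections)
  expect_lt(abs(recovery_rate(c2, "living", "merged") - 0.8), 0.02)
  expect_gte(recovery_rate(c2, "living", "merged"),
             recovery_rate(c2, "living", "probably"))
  # zero field total is an error
  empty <- c2
  empty$field_dead <- 0
  expect_error(recovery_rate(empty, "dead"), "undefined")
})

test_that("error profiles keep exact bookkeeping and flag field-zero sections", {
  comp <- data.frame(site = 1, transect = 1, section = 1:4,
                     field_living = c(10, 0, 5, 2),
                     field_dead = c(1, 1, 1, 1),
                     video_living_mean = c(8, 1.5, 5, 2),
                     video_probably_mean = 0, video_dead_mean = 1)
  ep <- error_profile(comp, "living")
  expect_equal(ep$absolute_error, c(-2, 1.5, 0, 0))
  expect_equal(ep$relative_error[1], -0.2)
  expect_true(is.na(ep$relative_error[2]) && !ep$relative_defined[2])
  expect_equal(sum(ep$absolute_error),
               sum(comp$video_living_mean) - sum(comp$field_living))
  # video = field everywhere -> all zero errors
  same <- comp
  same$video_living_mean <- same$field_living
  expect_true(all(error_profile(same, "living")$absolute_error == 0))
})

test_that("constant detection gives flat relative and growing absolute error", {
  big <- survey_design(n_sites = 1, transects_per_site = 4,
                       sections_per_transect = 50, observers = 2,
                       readings_per_observer = 2)
  cfg <- generator_config(mode = "mechanistic", grand_mean = 20,
                          site_effects = 0,
                          vc = variance_components(0, 0, 100, 0, 0, 0, 0),
                          p_detect_living = 0.7, p_live_classified_dead = 0,
                          p_dead_classified_living = 0, seed = 77)
  truth <- generate_field_truth(big, cfg)
  video <- generate_video_observations(truth, big, cfg)
  ep <- error_profile(build_comparison(video$readings, truth$sections),
                      "living")
  ep <- ep[ep$relative_defined & ep$field_count >= 3, ]
  lo <- ep$field_count <= stats::median(ep$field_count)
  # relative error ~ p - 1 in both abundance strata; absolute error grows
  expect_lt(abs(mean(ep$relative_error[lo]) - (-0.3)), 0.05)
  expect_lt(abs(mean(ep$relative_error[!lo]) - (-0.3)), 0.05)
  expect_gt(mean(abs(ep$absolute_error[!lo])),
            mean(abs(ep$absolute_error[lo])))
})
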
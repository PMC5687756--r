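test_that("gaussian-vc generator has the design's shape and exact degeneracies", {
  d <- study_design()
  cfg0 <- generator_config(grand_mean = 4, site_effects = c(-1, 0, 1),
                           vc = variance_components(0, 0, 0, 0, 0, 0, 0),
                           seed = 1)
  r <- generate_vc_dataset(d, cfg0)
  expect_equal(nrow(r), 260)
  expect_equal(nrow(towvid:::section_grid(d)), 65)
  # zero variance: every reading is exactly its site mean
  expect_equal(r$count_probably_living, 4 + c(-1, 0, 1)[r$site])
})

test_that("fixing the seed reproduces a dataset exactly", {
  d <- tiny_design()
  cfg <- generator_config(site_effects = c(-1, 1), seed = 7)
  expect_identical(generate_vc_dataset(d, cfg), generate_vc_dataset(d, cfg))
  cfg2 <- generator_config(site_effects = c(-1, 1), seed = 8)
  expect_false(identical(generate_vc_dataset(d, cfg),
                         generate_vc_dataset(d, cfg2)))

  mc <- generator_config(mode = "mechanistic", site_effects = c(0, 0),
                         seed = 7)
  t1 <- generate_field_truth(d, mc)
  t2 <- generate_field_truth(d, mc)
  expect_identical(t1, t2)
  expect_identical(generate_video_observations(t1, d, mc),
                   generate_video_observations(t2, d, mc))
})

test_that("zero-variance mechanistic census is exactly constant", {
  d <- study_design()
  cfg <- generator_config(mode = "mechanistic", grand_mean = 4,
                          site_effects = c(0, 0, 0),
                          vc = variance_components(0, 0, 0, 0, 0, 0, 0),
                          seed = 3)
  truth <- generate_field_truth(d, cfg, count_model = "deterministic")
  expect_equal(nrow(truth$sections), 65)
  expect_true(all(truth$sections$true_living == 4))
  expect_equal(nrow(truth$oysters), sum(truth$sections$true_living) +
                 sum(truth$sections$true_dead))
})

test_that("between-section variance of the census matches its configuration", {
  # large mean so the zero floor never bites; deterministic counts so the
  # only integer distortion is rounding (variance 1/12)
  d <- survey_design(n_sites = 1, transects_per_site = 4,
                     sections_per_transect = 2500, observers = 1,
                     readings_per_observer = 1)
  cfg <- generator_config(mode = "mechanistic", grand_mean = 50,
                          site_effects = 0,
                          vc = variance_components(0, 0, 25, 0, 0, 0, 0),
                          dead_grand_mean = 1, seed = 11)
  truth <- generate_field_truth(d, cfg, count_model = "deterministic")
  within_var <- with(truth$sections,
                     mean(tapply(true_living, transect, var)))
  expect_lt(abs(within_var - 25) / 25, 0.10)
})

test_that("a perfect observer reproduces the field census in every reading", {
  d <- tiny_design()
  cfg <- generator_config(mode = "mechanistic", grand_mean = 6,
                          site_effects = c(-2, 2),
                          p_detect_living = 1, p_detect_dead = 1,
                          p_live_classified_dead = 0,
                          p_dead_classified_living = 0, seed = 5)
  truth <- generate_field_truth(d, cfg)
  video <- generate_video_observations(truth, d, cfg)
  r <- merge_categories(video$readings)
  key <- towvid:::section_key(r)
  tkey <- towvid:::section_key(truth$sections)
  expect_equal(unname(r$count_living),
               truth$sections$true_living[match(key, tkey)])
  expect_equal(unname(r$count_dead),
               truth$sections$true_dead[match(key, tkey)])
  # every oyster matched, no status error
  expect_equal(nrow(video$oysters), nrow(truth$oysters))
  expect_equal(video$oysters$video_status, video$oysters$field_status)
})

test_that("detection is status-conditional and converges to its probability", {
  # ~10,000 living oysters in one big transect
  d <- survey_design(n_sites = 1, transects_per_site = 1,
                     sections_per_transect = 100, observers = 1,
                     readings_per_observer = 1)
  cfg <- generator_config(mode = "mechanistic", grand_mean = 100,
                          site_effects = 0,
                          vc = variance_components(0, 0, 0, 0, 0, 0, 0),
                          dead_grand_mean = 100,
                          dead_vc = variance_components(0, 0, 0, 0, 0, 0, 0),
                          p_detect_living = 0.8, p_detect_dead = 0.5,
                          p_live_classified_dead = 0,
                          p_dead_classified_living = 0, seed = 13)
  truth <- generate_field_truth(d, cfg, count_model = "deterministic")
  video <- generate_video_observations(truth, d, cfg)
  r <- merge_categories(video$readings)
  live_rate <- sum(r$count_living) / sum(truth$sections$true_living)
  dead_rate <- sum(r$count_dead) / sum(truth$sections$true_dead)
  expect_lt(abs(live_rate - 0.8), 0.02)
  expect_lt(abs(dead_rate - 0.5), 0.02)
})

test_that("study-like detection preset recovers 70-80% of living oysters", {
  d <- study_design()
  set.seed(17)
  rates <- replicate(20, {
    cfg <- generator_config(mode = "mechanistic", seed = NULL)
    truth <- generate_field_truth(d, cfg)
    video <- generate_video_observations(truth, d, cfg)
    comp <- build_comparison(video$readings, truth$sections)
    recovery_rate(comp, "living", "merged")
  })
  expect_gt(mean(rates), 0.70)
  expect_lt(mean(rates), 0.80)
})
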
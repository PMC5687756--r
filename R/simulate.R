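## Synthetic survey generation.
##
## Two generating processes, deliberately distinct:
##  * gaussian-vc  — the Gaussian mixed model that the variance-component
##    analysis assumes, used for parameter-recovery and error-propagation
##    checks (values may be non-integer);
##  * mechanistic  — integer field truth (latent hierarchical mean feeding a
##    Poisson count per section, individual oysters materialised) plus
##    per-oyster Bernoulli detection and live/dead misclassification during
##    video reading, used for classification and recovery-rate checks.

with_config_seed <- function(config, offset = 0L) {
  if (!is.null(config$seed)) set.seed(config$seed + as.integer(offset))
  invisible(NULL)
}

# one row per (site, transect, section)
section_grid <- function(design) {
  site <- rep(seq_len(design$n_sites), design$transects_per_site)
  transect <- unlist(lapply(design$transects_per_site, seq_len))
  b <- design$sections_per_transect
  data.frame(
    site = rep(site, each = b),
    transect = rep(transect, each = b),
    section = rep(seq_len(b), times = length(site))
  )
}

# one row per (site, transect, section, observer, reading)
reading_grid <- function(design) {
  sec <- section_grid(design)
  c_ <- design$observers
  n_ <- design$readings_per_observer
  out <- sec[rep(seq_len(nrow(sec)), each = c_ * n_), , drop = FALSE]
  out$observer <- rep(rep(seq_len(c_), each = n_), times = nrow(sec))
  out$reading <- rep(seq_len(n_), times = nrow(sec) * c_)
  rownames(out) <- NULL
  out
}

#' Simulate reading-level data from the Gaussian mixed model
#'
#' Draws one complete reading-level dataset directly from the model the
#' nested ANOVA assumes: `y = grand_mean + site + Tr(Si) + Se(Tr,Si) + Ob +
#' Ob:Si + Ob:Tr(Si) + Ob:Se(Tr,Si) + e`, every random term Normal with the
#' variance configured in `config$vc`. This is the exact data-generating
#' process of the variance-component estimators, so it is the right source
#' for parameter-recovery experiments and for Monte-Carlo validation of the
#' precision model. Values are emitted in `count_probably_living` and are
#' generally non-integer.
#'
#' @param design A [survey_design()].
#' @param config A [generator_config()] with `mode = "gaussian-vc"`.
#' @return A data.frame of reading records: `site`, `transect`, `section`,
#'   `observer`, `reading`, `count_probably_living`,
#'   `count_possibly_living`, `count_dead`.
#' @examples
#' d <- survey_design()
#' r <- generate_vc_dataset(d, generator_config(seed = 1))
#' nrow(r)  # 260
#' @export
generate_vc_dataset <- function(design, config = generator_config()) {
  if (config$mode != "gaussian-vc")
    stop("generate_vc_dataset requires mode = \"gaussian-vc\"", call. = FALSE)
  check_config_design(config, design)
  with_config_seed(config)
  g <- reading_grid(design)
  vc <- config$vc

  tr_id <- interaction(g$site, g$transect, drop = TRUE)
  se_id <- interaction(g$site, g$transect, g$section, drop = TRUE)
  ob_id <- factor(g$observer)
  obsi_id <- interaction(g$observer, g$site, drop = TRUE)
  trob_id <- interaction(g$observer, g$site, g$transect, drop = TRUE)
  seob_id <- interaction(g$observer, g$site, g$transect, g$section,
                         drop = TRUE)

  draw <- function(id, s2) stats::rnorm(nlevels(id), 0, sqrt(s2))[id]
  y <- config$grand_mean + config$site_effects[g$site] +
    draw(tr_id, vc[["s_tr2"]]) + draw(se_id, vc[["s_se2"]]) +
    draw(ob_id, vc[["s_ob2"]]) + draw(obsi_id, vc[["s_obsi2"]]) +
    draw(trob_id, vc[["s_trob2"]]) + draw(seob_id, vc[["s_seob2"]]) +
    stats::rnorm(nrow(g), 0, sqrt(vc[["s_e2"]]))

  g$count_probably_living <- y
  g$count_possibly_living <- 0
  g$count_dead <- 0
  g
}

# latent hierarchical section mean, floored at zero
latent_section_mean <- function(design, grand_mean, site_effects, vc) {
  sec <- section_grid(design)
  tr_id <- interaction(sec$site, sec$transect, drop = TRUE)
  mu <- grand_mean + site_effects[sec$site] +
    stats::rnorm(nlevels(tr_id), 0, sqrt(vc[["s_tr2"]]))[tr_id] +
    stats::rnorm(nrow(sec), 0, sqrt(vc[["s_se2"]]))
  pmax(mu, 0)
}

#' Simulate the field census of a mechanistic survey
#'
#' Generates integer ground truth for every section of the design: a latent
#' hierarchical mean (grand mean + fixed site effect + Normal transect and
#' section effects, floored at zero) feeds a Poisson draw per section, and
#' the resulting counts are materialised as individual oysters. Dead-oyster
#' counts come from an analogous, independently parameterised latent
#' process (`dead_*` config fields). Each oyster optionally carries
#' cluster/cover flags that can down-weight its detection probability
#' during video reading.
#'
#' Set `count_model = "deterministic"` to skip the Poisson stage and round
#' the latent mean instead — with all variance components at zero this
#' yields an exactly constant census, useful for degeneracy checks.
#'
#' @inheritParams generate_vc_dataset
#' @param config A [generator_config()] with `mode = "mechanistic"`.
#' @param count_model `"poisson"` (default: latent mean is the Poisson
#'   rate, giving overdispersed integer counts) or `"deterministic"`
#'   (counts are the rounded latent mean).
#' @return A list with components `sections` (one row per section: `site`,
#'   `transect`, `section`, `true_living`, `true_dead`,
#'   `vegetation_cover`) and `oysters` (one row per individual:
#'   `oyster_id`, `site`, `transect`, `section`, `status`, `in_cluster`,
#'   `covered`).
#' @export
generate_field_truth <- function(design, config,
                                 count_model = c("poisson",
                                                 "deterministic")) {
  if (config$mode != "mechanistic")
    stop("generate_field_truth requires mode = \"mechanistic\"",
         call. = FALSE)
  count_model <- match.arg(count_model)
  check_config_design(config, design)
  with_config_seed(config)

  sec <- section_grid(design)
  mu_live <- latent_section_mean(design, config$grand_mean,
                                 config$site_effects, config$vc)
  mu_dead <- latent_section_mean(design, config$dead_grand_mean,
                                 config$dead_site_effects, config$dead_vc)
  if (count_model == "poisson") {
    sec$true_living <- stats::rpois(nrow(sec), mu_live)
    sec$true_dead <- stats::rpois(nrow(sec), mu_dead)
  } else {
    sec$true_living <- as.integer(round(mu_live))
    sec$true_dead <- as.integer(round(mu_dead))
  }
  sec$vegetation_cover <- stats::rbeta(nrow(sec), 2, 2)

  n_oy <- sec$true_living + sec$true_dead
  idx <- rep(seq_len(nrow(sec)), n_oy)
  status <- unlist(mapply(function(l, d) rep(c("living", "dead"), c(l, d)),
                          sec$true_living, sec$true_dead,
                          SIMPLIFY = FALSE), use.names = FALSE)
  if (is.null(status)) status <- character(0)
  oysters <- data.frame(
    oyster_id = seq_along(idx),
    site = sec$site[idx],
    transect = sec$transect[idx],
    section = sec$section[idx],
    status = status,
    in_cluster = stats::runif(length(idx)) < config$p_cluster,
    covered = stats::runif(length(idx)) < config$p_covered
  )
  list(sections = sec, oysters = oysters)
}

#' Simulate video reading of a mechanistic survey
#'
#' For every oyster, observer and reading pass: the oyster is detected with
#' probability `p_detect_living` or `p_detect_dead` according to its true
#' status (multiplied by the cluster/cover factors where flagged); a
#' detected oyster is assigned the wrong status with probability
#' `p_live_classified_dead` / `p_dead_classified_living`; oysters scored as
#' living are split into the "probably living" and "possibly living"
#' confidence categories by `p_probably_given_detected_living`. Per-oyster
#' outcomes are aggregated into section-level reading records.
#'
#' The matched-oyster table pairs each oyster's field status with the video
#' status from the first reading of the first observer (undetected oysters
#' cannot be matched and are omitted), mirroring how individually
#' relocatable oysters are scored once in a validation study.
#'
#' @param truth Output of [generate_field_truth()].
#' @inheritParams generate_field_truth
#' @return A list with `readings` (reading records as in
#'   [generate_vc_dataset()], integer counts) and `oysters` (matched
#'   records: `oyster_id`, `field_status`, `video_status`).
#' @export
generate_video_observations <- function(truth, design, config) {
  if (config$mode != "mechanistic")
    stop("generate_video_observations requires mode = \"mechanistic\"",
         call. = FALSE)
  check_config_design(config, design)
  with_config_seed(config, offset = 1L)

  oy <- truth$oysters
  c_ <- design$observers
  n_ <- design$readings_per_observer
  n_pass <- c_ * n_
  n_oy <- nrow(oy)

  p_det <- ifelse(oy$status == "living", config$p_detect_living,
                  config$p_detect_dead)
  p_det <- p_det *
    ifelse(oy$in_cluster, config$cluster_detection_factor, 1) *
    ifelse(oy$covered, config$covered_detection_factor, 1)

  # one row per oyster x observer x reading
  oi <- rep(seq_len(n_oy), each = n_pass)
  observer <- rep(rep(seq_len(c_), each = n_), times = n_oy)
  reading <- rep(seq_len(n_), times = n_oy * c_)
  detected <- stats::runif(n_oy * n_pass) < p_det[oi]

  status <- oy$status[oi]
  p_wrong <- ifelse(status == "living", config$p_live_classified_dead,
                    config$p_dead_classified_living)
  wrong <- stats::runif(n_oy * n_pass) < p_wrong
  scored_living <- detected &
    ((status == "living") != wrong)  # misclassification flips the status
  scored_dead <- detected & !scored_living
  probably <- scored_living &
    (stats::runif(n_oy * n_pass) < config$p_probably_given_detected_living)

  g <- reading_grid(design)
  key <- function(site, transect, section, observer, reading)
    paste(site, transect, section, observer, reading, sep = ".")
  gk <- key(g$site, g$transect, g$section, g$observer, g$reading)
  ok <- key(oy$site[oi], oy$transect[oi], oy$section[oi], observer, reading)
  okf <- factor(ok, levels = gk)
  g$count_probably_living <- as.integer(tabulate(okf[probably], nlevels(okf)))
  g$count_possibly_living <-
    as.integer(tabulate(okf[scored_living & !probably], nlevels(okf)))
  g$count_dead <- as.integer(tabulate(okf[scored_dead], nlevels(okf)))

  first <- observer == 1L & reading == 1L
  matched <- first & detected
  oyster_records <- data.frame(
    oyster_id = oy$oyster_id[oi[matched]],
    field_status = status[matched],
    video_status = ifelse(scored_living[matched], "living", "dead")
  )
  list(readings = g, oysters = oyster_records)
}
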
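#' Hierarchical survey design
#'
#' Describes the nested layout of a towed-video survey: sites, transects
#' within sites, contiguous sections within transects, and the video-reading
#' replication (observers, repeated readings per observer). The default is
#' the layout this package was developed around: 3 sites with 5, 3 and 5
#' transects, each transect a 20 m x 0.8 m strip split into five 4-m
#' sections of 3.2 m^2, read twice by each of two observers.
#'
#' @param n_sites Number of sites.
#' @param transects_per_site Integer vector of length `n_sites`: transects
#'   surveyed at each site.
#' @param sections_per_transect Sections per transect (`b` in the precision
#'   model).
#' @param observers Number of observers scoring each video (`c`).
#' @param readings_per_observer Complete scoring passes per observer per
#'   section (`n`).
#' @param section_length,section_width Section geometry in metres; their
#'   product is the section area used to convert counts per section into
#'   densities per square metre.
#'
#' @return An object of class `survey_design`.
#' @examples
#' d <- survey_design()
#' n_sections(d)   # 65
#' n_readings(d)   # 260
#' @export
survey_design <- function(n_sites = 3,
                          transects_per_site = c(5, 3, 5),
                          sections_per_transect = 5,
                          observers = 2,
                          readings_per_observer = 2,
                          section_length = 4,
                          section_width = 0.8) {
  n_sites <- as.integer(n_sites)
  transects_per_site <- as.integer(transects_per_site)
  if (length(transects_per_site) == 1L && n_sites > 1L)
    transects_per_site <- rep(transects_per_site, n_sites)
  counts <- c(n_sites, transects_per_site, sections_per_transect,
              observers, readings_per_observer)
  if (any(!is.finite(counts)) || any(counts < 1))
    stop("invalid design: all counts must be >= 1", call. = FALSE)
  if (length(transects_per_site) != n_sites)
    stop("invalid design: transects_per_site must have one entry per site",
         call. = FALSE)
  if (!is.finite(section_length) || !is.finite(section_width) ||
      section_length <= 0 || section_width <= 0)
    stop("invalid design: section dimensions must be positive", call. = FALSE)
  structure(
    list(
      n_sites = n_sites,
      transects_per_site = transects_per_site,
      sections_per_transect = as.integer(sections_per_transect),
      observers = as.integer(observers),
      readings_per_observer = as.integer(readings_per_observer),
      section_length = section_length,
      section_width = section_width,
      section_area = section_length * section_width
    ),
    class = "survey_design"
  )
}

#' @rdname survey_design
#' @param design A `survey_design`.
#' @export
n_sections <- function(design) {
  sum(design$transects_per_site) * design$sections_per_transect
}

#' @rdname survey_design
#' @export
n_readings <- function(design) {
  n_sections(design) * design$observers * design$readings_per_observer
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Towed-video survey design\n")
  cat(sprintf("  sites: %d; transects per site: %s; sections per transect: %d\n",
              x$n_sites, paste(x$transects_per_site, collapse = ", "),
              x$sections_per_transect))
  cat(sprintf("  observers: %d; readings per observer: %d\n",
              x$observers, x$readings_per_observer))
  cat(sprintf("  section: %.1f m x %.1f m = %.2f m^2; %d sections, %d readings in total\n",
              x$section_length, x$section_width, x$section_area,
              n_sections(x), n_readings(x)))
  invisible(x)
}

#' Variance components of the nested video-survey model
#'
#' Container for the seven random-effect variances of the mixed model
#' `y = mu + Site + Tr(Si) + Se(Tr,Si) + Ob + Ob:Si + Ob:Tr(Si) +
#' Ob:Se(Tr,Si) + e` fitted to per-section video counts. All components are
#' variances of counts per section, i.e. in (counts per section)^2. The
#' residual is the variability between replicate readings by the same
#' observer. The defaults are the estimates for the flat-oyster surveys the
#' package was built around.
#'
#' @param s_ob2 Between-observer variance.
#' @param s_tr2 Between-transect (within site) variance.
#' @param s_se2 Between-section (within transect) variance.
#' @param s_obsi2 Observer-by-site interaction variance.
#' @param s_trob2 Observer-by-transect interaction variance.
#' @param s_seob2 Observer-by-section interaction variance.
#' @param s_e2 Residual (between replicate readings) variance.
#' @param method Optional label for how the components were estimated
#'   (e.g. `"REML"`, `"MoM"`).
#'
#' @return An object of class `variance_components`: a named numeric vector
#'   with optional attributes `method`, `raw` (untruncated method-of-moments
#'   values) and `logLik`.
#' @examples
#' vc <- variance_components()
#' vc_shares(vc)           # section component dominates
#' @export
variance_components <- function(s_ob2 = 0.1, s_tr2 = 1.1, s_se2 = 26.2,
                                s_obsi2 = 0.0, s_trob2 = 0.1,
                                s_seob2 = 0.0, s_e2 = 1.6,
                                method = NULL) {
  x <- c(s_ob2 = s_ob2, s_tr2 = s_tr2, s_se2 = s_se2, s_obsi2 = s_obsi2,
         s_trob2 = s_trob2, s_seob2 = s_seob2, s_e2 = s_e2)
  if (any(!is.finite(x)) || any(x < 0))
    stop("variance components must be finite and >= 0", call. = FALSE)
  structure(x, method = method, class = "variance_components")
}

vc_names <- c("s_ob2", "s_tr2", "s_se2", "s_obsi2", "s_trob2", "s_seob2",
              "s_e2")

as_variance_components <- function(x, method = NULL) {
  if (inherits(x, "variance_components")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 7L) names(x) <- vc_names
  miss <- setdiff(vc_names, names(x))
  if (length(miss))
    stop("missing variance components: ", paste(miss, collapse = ", "),
         call. = FALSE)
  do.call(variance_components, c(as.list(x[vc_names]), list(method = method)))
}

#' @export
print.variance_components <- function(x, digits = 3, ...) {
  m <- attr(x, "method")
  cat("Variance components (counts per section)^2",
      if (!is.null(m)) sprintf(" [%s]", m), "\n", sep = "")
  print(round(unclass(x), digits))
  if (!is.null(attr(x, "logLik")))
    cat(sprintf("  REML log-likelihood: %.3f\n", attr(x, "logLik")))
  invisible(x)
}

#' Share of total random variability per component
#'
#' Each variance component divided by the sum of all seven random
#' components — the decomposition used to say, e.g., that small-scale
#' section-to-section variability dominates a survey's uncertainty.
#'
#' @param vc A [variance_components] object (or named vector coercible to
#'   one).
#' @return Named numeric vector of fractions summing to 1.
#' @examples
#' round(100 * vc_shares(variance_components()))  # section share 90%
#' @export
vc_shares <- function(vc) {
  vc <- as_variance_components(vc)
  tot <- sum(vc)
  if (tot <= 0) stop("total of variance components is zero; shares undefined",
                     call. = FALSE)
  unclass(vc) / tot
}

#' Configuration of the synthetic survey generator
#'
#' Parameters of the two synthetic data-generating processes (see
#' [generate_vc_dataset()] and [generate_field_truth()]).
#' `mode = "gaussian-vc"` draws reading-level values directly from the
#' Gaussian mixed model that the variance-component analysis assumes.
#' `mode = "mechanistic"` builds integer field truth (latent hierarchical
#' mean feeding a Poisson count per section, individual oysters
#' materialised) and then simulates video reading as per-oyster Bernoulli
#' detection plus live/dead misclassification.
#'
#' Detection defaults emulate the validation study the package grew from:
#' about 80% of living oysters detected per reading and about half of the
#' dead ones, with live/dead confusion rates near 18% and 20%, so that the
#' merged "living" video category recovers 70-80% of the living oysters
#' and the higher-confidence "probably living" category alone about 40%.
#'
#' @param mode `"gaussian-vc"` or `"mechanistic"`.
#' @param grand_mean Mean living-oyster count per section.
#' @param site_effects Fixed per-site offsets (counts per section); length
#'   must match the design's number of sites.
#' @param vc [variance_components] of the living-count process.
#' @param dead_grand_mean,dead_site_effects,dead_vc The independently
#'   parameterised latent process for dead-oyster counts (mechanistic mode).
#' @param p_detect_living,p_detect_dead Per-reading detection probability of
#'   a living / dead oyster.
#' @param p_live_classified_dead,p_dead_classified_living Probability that a
#'   detected oyster is assigned the wrong status.
#' @param p_probably_given_detected_living Split of correctly classified
#'   detected living oysters into "probably living" (vs "possibly living").
#' @param cluster_detection_factor,covered_detection_factor Multipliers
#'   (<= 1) on detection probability for oysters growing in clusters or
#'   largely covered by algae/sediment.
#' @param p_cluster,p_covered Fraction of oysters flagged as clustered /
#'   covered in the field truth.
#' @param seed Root seed; every stochastic draw descends from it. `NULL`
#'   leaves the RNG state untouched.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(mode = c("gaussian-vc", "mechanistic"),
                             grand_mean = 4,
                             site_effects = c(-1.5, 0, 1.5),
                             vc = variance_components(),
                             dead_grand_mean = 3.5,
                             dead_site_effects = site_effects,
                             dead_vc = variance_components(
                               s_ob2 = 0.1, s_tr2 = 1.0, s_se2 = 20,
                               s_obsi2 = 0, s_trob2 = 0.1, s_seob2 = 0,
                               s_e2 = 1.5),
                             p_detect_living = 0.8,
                             p_detect_dead = 0.5,
                             p_live_classified_dead = 0.18,
                             p_dead_classified_living = 0.20,
                             p_probably_given_detected_living = 0.55,
                             cluster_detection_factor = 1,
                             covered_detection_factor = 1,
                             p_cluster = 0.18,
                             p_covered = 0.14,
                             seed = NULL) {
  mode <- match.arg(mode)
  probs <- c(p_detect_living, p_detect_dead, p_live_classified_dead,
             p_dead_classified_living, p_probably_given_detected_living,
             cluster_detection_factor, covered_detection_factor,
             p_cluster, p_covered)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("invalid config: probabilities must lie in [0, 1]", call. = FALSE)
  vc <- as_variance_components(vc)
  dead_vc <- as_variance_components(dead_vc)
  if (!is.null(seed)) {
    seed <- suppressWarnings(as.integer(seed))
    if (is.na(seed)) stop("invalid config: seed must be an integer",
                          call. = FALSE)
  }
  structure(
    list(mode = mode, grand_mean = grand_mean, site_effects = site_effects,
         vc = vc, dead_grand_mean = dead_grand_mean,
         dead_site_effects = dead_site_effects, dead_vc = dead_vc,
         p_detect_living = p_detect_living, p_detect_dead = p_detect_dead,
         p_live_classified_dead = p_live_classified_dead,
         p_dead_classified_living = p_dead_classified_living,
         p_probably_given_detected_living = p_probably_given_detected_living,
         cluster_detection_factor = cluster_detection_factor,
         covered_detection_factor = covered_detection_factor,
         p_cluster = p_cluster, p_covered = p_covered, seed = seed),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic survey generator config (mode: %s)\n", x$mode))
  cat(sprintf("  grand mean %.2f / section; site effects: %s\n",
              x$grand_mean, paste(x$site_effects, collapse = ", ")))
  if (x$mode == "mechanistic")
    cat(sprintf("  detection: living %.2f, dead %.2f; misclassification: %.2f / %.2f\n",
                x$p_detect_living, x$p_detect_dead,
                x$p_live_classified_dead, x$p_dead_classified_living))
  invisible(x)
}

check_config_design <- function(config, design) {
  if (length(config$site_effects) != design$n_sites)
    stop("invalid config: site_effects must have one entry per site",
         call. = FALSE)
  if (config$mode == "mechanistic" &&
      config$grand_mean + min(config$site_effects) < 0)
    stop("invalid config: grand_mean + min(site_effects) must be >= 0 ",
         "in mechanistic mode", call. = FALSE)
  invisible(TRUE)
}
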
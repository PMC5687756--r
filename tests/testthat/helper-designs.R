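# shared fixtures, built in code

study_design <- function() survey_design()

balanced_design <- function(t = 4, b = 4, c = 3, n = 2, a = 3)
  survey_design(n_sites = a, transects_per_site = rep(t, a),
                sections_per_transect = b, observers = c,
                readings_per_observer = n)

tiny_design <- function()
  survey_design(n_sites = 2, transects_per_site = c(2, 2),
                sections_per_transect = 2, observers = 2,
                readings_per_observer = 2)

table3_vc <- function()
  variance_components(s_ob2 = 0.1, s_tr2 = 1.1, s_se2 = 26.2,
                      s_obsi2 = 0.0, s_trob2 = 0.1, s_seob2 = 0.0,
                      s_e2 = 1.6)

# vc_anova shell from externally supplied df/MS (for EMS/F-test checks)
manual_anova <- function(df, ms) {
  tab <- data.frame(term = towvid:::anova_terms,
                    source = unname(towvid:::anova_term_labels),
                    df = df, ss = df * ms, ms = ms)
  class(tab) <- c("vc_anova", "data.frame")
  tab
}
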
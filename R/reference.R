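#' Reference %SRX values for porcine and human ventricular myofibrils
#'
#' The published per-zone corrected %SRX percentages, bootstrap 95% CIs and
#' event counts for the four experimental groups this package's defaults
#' are calibrated to: untreated and PKA-treated porcine left-ventricular
#' myofibrils, and mutation-negative control versus *MYBPC3*-c.772G>A
#' (cMyBP-C haploinsufficient) human myectomy myofibrils. The untreated
#' porcine zonal fractions are also the [kinetic_scheme()] simulator
#' defaults. Event counts include nonspecific ATP binding events.
#'
#' @return data frame with columns `group`, `zone` (P, C, D, all),
#'   `srx_percent`, `ci_low`, `ci_high`, `n_events`.
#' @export
reference_srx_values <- function() {
  data.frame(
    group = rep(c("porcine_untreated", "porcine_pka",
                  "human_control", "human_mutant"), each = 4L),
    zone = rep(c("P", "C", "D", "all"), times = 4L),
    srx_percent = c(56.7, 53.7, 44.1, 46.2,
                    46.5, 37.4, 59.0, 46.3,
                    48.0, 63.4, 36.2, 51.3,
                    40.8, 44.3, 52.2, 44.2),
    ci_low = c(54.6, 51.6, 40.1, 42.9,
               39.3, 31.3, 50.1, 41.7,
               43.5, 55.3, 29.1, 47.8,
               31.1, 39.5, 47.8, 37.8),
    ci_high = c(58.7, 56.3, 47.6, 50.8,
                53.3, 43.8, 73.9, 52.7,
                52.0, 80.3, 43.2, 54.7,
                53.5, 50.0, 58.5, 50.0),
    n_events = c(714L, 1183L, 1741L, 3638L,
                 224L, 528L, 711L, 1463L,
                 285L, 341L, 535L, 1161L,
                 404L, 591L, 818L, 1813L),
    stringsAsFactors = FALSE
  )
}
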
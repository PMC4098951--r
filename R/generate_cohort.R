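#' Specification of a synthetic survival cohort
#'
#' Describes a cohort of patients with per-patient tumour-budding (TB),
#' lymphatic-vessel-invasion (LVI) and lymphatic-vessel-density (LVD)
#' features and a proportional-hazards survival model in which patients
#' above a planted cut-off quantile of a designated feature have their
#' hazard multiplied by `exp(log_hr)`.
#'
#' Feature scales echo a colorectal invasive-front cohort: TB totals in the
#' low hundreds (negative binomial), LVI event totals in the tens (negative
#' binomial), LVD as a small percentage of stroma (gamma). A shared latent
#' "aggressiveness" factor induces positive correlation between the three
#' features, as observed between budding and invasion in practice.
#'
#' @param n_patients Number of patients (at least 10).
#' @param fields_per_patient Fields captured per patient (bookkeeping only).
#' @param feature_distributions Named list with elements `tb = list(mu, size)`
#'   and `lvi = list(mu, size)` (negative binomial mean / dispersion) and
#'   `lvd = list(shape, rate)` (gamma). Zero-variance settings are rejected.
#' @param hazard_feature The feature driving survival: one of `"tb_total"`,
#'   `"lvi_total"`, `"lvd_mean_percent"`.
#' @param cutoff_quantile Quantile of the realised feature values above which
#'   the hazard increment applies.
#' @param log_hr Log-hazard increment for the above-cut-off group; 0 plants a
#'   null cohort.
#' @param baseline_rate Baseline exponential event rate (per unit time).
#' @param censoring_rate Target fraction censored (in `[0, 1)`); independent
#'   exponential censoring with the matching rate. 0 disables censoring.
#' @param latent_sd Standard deviation of the shared log-scale latent factor
#'   coupling the three features (0 = independent features).
#' @param seed Integer seed.
#'
#' @return A `cohort_spec` object.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_patients = 50L,
                        fields_per_patient = 15L,
                        feature_distributions = list(
                          tb = list(mu = 250, size = 4),
                          lvi = list(mu = 12, size = 3),
                          lvd = list(shape = 2, rate = 2.5)
                        ),
                        hazard_feature = "tb_total",
                        cutoff_quantile = 0.6,
                        log_hr = log(3),
                        baseline_rate = 0.08,
                        censoring_rate = 0.3,
                        latent_sd = 0.3,
                        seed = 1L) {
  if (n_patients < 10) {
    abort("n_patients must be at least 10.", class = "budquant_spec_error")
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1).", class = "budquant_spec_error")
  }
  fd <- feature_distributions
  if (fd$tb$mu <= 0 || fd$tb$size <= 0 || fd$lvi$mu < 0 || fd$lvi$size <= 0 ||
      fd$lvd$shape <= 0 || fd$lvd$rate <= 0) {
    abort("Degenerate (zero-variance) feature distributions are not allowed.",
          class = "budquant_spec_error")
  }
  if (!hazard_feature %in% c("tb_total", "lvi_total", "lvd_mean_percent")) {
    abort("hazard_feature must be one of tb_total, lvi_total, lvd_mean_percent.",
          class = "budquant_spec_error")
  }
  if (cutoff_quantile <= 0 || cutoff_quantile >= 1) {
    abort("cutoff_quantile must lie strictly inside (0, 1).",
          class = "budquant_spec_error")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         fields_per_patient = as.integer(fields_per_patient),
         feature_distributions = fd,
         hazard_feature = hazard_feature,
         cutoff_quantile = cutoff_quantile,
         log_hr = log_hr,
         baseline_rate = baseline_rate,
         censoring_rate = censoring_rate,
         latent_sd = latent_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic patient cohort with a planted feature-hazard link
#'
#' Draws per-patient TB/LVI/LVD features, plants a cut-off at the requested
#' quantile of the designated feature, multiplies the hazard of above-cut-off
#' patients by `exp(log_hr)`, draws exponential survival times under that
#' proportional-hazards model and applies independent exponential censoring.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `features` (tibble: `patient_id`, `tb_total`,
#'   `lvi_total`, `lvd_mean_percent`, `n_fields_used`), `survival` (tibble:
#'   `patient_id`, `time`, `event`) and `truth` (planted cut-off value and
#'   quantile, hazard feature, true hazard ratio, above-group indicator).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(n_patients = 20, seed = 3))
#' head(coh$features)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    fd <- spec$feature_distributions
    z <- rnorm(n, 0, spec$latent_sd)
    tb <- rnbinom(n, mu = fd$tb$mu * exp(z), size = fd$tb$size)
    lvi <- rnbinom(n, mu = pmax(fd$lvi$mu * exp(z), 1e-8), size = fd$lvi$size)
    lvd <- rgamma(n, shape = fd$lvd$shape, rate = fd$lvd$rate) * exp(0.5 * z)

    features <- tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      tb_total = as.integer(tb),
      lvi_total = as.integer(lvi),
      lvd_mean_percent = lvd,
      n_fields_used = spec$fields_per_patient
    )

    x <- features[[spec$hazard_feature]]
    cutoff <- as.numeric(quantile(x, spec$cutoff_quantile, type = 1))
    above <- x > cutoff
    rate <- spec$baseline_rate * exp(spec$log_hr * above)
    t_event <- rexp(n, rate)
    if (spec$censoring_rate > 0) {
      c_rate <- spec$baseline_rate * spec$censoring_rate /
        (1 - spec$censoring_rate)
      t_cens <- rexp(n, c_rate)
    } else {
      t_cens <- rep(Inf, n)
    }
    survival_tbl <- tibble::tibble(
      patient_id = features$patient_id,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )

    truth <- list(hazard_feature = spec$hazard_feature,
                  cutoff = cutoff,
                  cutoff_quantile = spec$cutoff_quantile,
                  hazard_ratio = exp(spec$log_hr),
                  above = above)
    list(features = features, survival = survival_tbl, truth = truth)
  })
}
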
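#' Specification of a synthetic BPD cohort
#'
#' Describes a cohort of preterm subjects with bronchopulmonary dysplasia
#' (BPD) severity grades, clinical covariates and a 78-entry lung feature
#' vector per subject. Planted feature effects are standardized mean shifts
#' per severity-grade step, so `effect_sizes` of zero makes the lung
#' features statistically independent of the grade.
#'
#' Covariates follow the field's grouping: patient attributes
#' (P: gestational age, birth weight, body size, sex) and postnatal
#' clinical adaptation (C: 5-minute Apgar, early-onset infection, postnatal
#' steroids). Continuous BPD indicators (ventilation and oxygen days) are
#' drawn from negative-binomial distributions with grade-dependent means -
#' overdispersed day counts, deliberately misspecified for a Poisson model.
#'
#' @param n_subjects number of subjects.
#' @param class_proportions length-4 fractions over the grades
#'   none/mild/moderate/severe; must sum to 1.
#' @param effect_sizes named numeric vector of standardized mean shifts per
#'   grade step, names drawn from the 78-feature manifest
#'   ([feature_manifest()]). The default plants effects on lung volumes
#'   (positive), elongation (negative), AP centroid displacement and
#'   surface roughness (positive).
#' @param seed integer; fully determines the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200L,
                        class_proportions = c(none = 0.38, mild = 0.28,
                                              moderate = 0.12, severe = 0.22),
                        effect_sizes = c(
                          left_volume_mm3 = 0.7, right_volume_mm3 = 0.7,
                          left_elongation = -0.6, right_elongation = -0.6,
                          left_centroid_disp_ap = 0.5,
                          right_centroid_disp_ap = 0.5,
                          left_roughness = 0.5, right_roughness = 0.5
                        ),
                        seed = 1L) {
  assert_that(n_subjects >= 8, "n_subjects must be >= 8")
  assert_that(length(class_proportions) == 4 &&
                isTRUE(all.equal(sum(class_proportions), 1)) &&
                all(class_proportions >= 0),
              "class_proportions must be 4 nonnegative fractions summing to 1")
  nm <- feature_manifest()$name
  if (length(effect_sizes)) {
    assert_that(!is.null(names(effect_sizes)) &&
                  all(names(effect_sizes) %in% nm),
                "effect_sizes names must be valid feature names")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         class_proportions = class_proportions,
         effect_sizes = effect_sizes,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

bpd_grades <- function() c("none", "mild", "moderate", "severe")

# plausible raw scales per feature, keyed on units in the manifest
feature_base_scales <- function(manifest) {
  mean_of <- function(name, units) {
    switch(units,
           "mm3" = 38000, "mm2" = 9500, "mm" = 60, "mm^-1" = 0.25,
           "mm^2" = 400, "a.u." = 0.3, "bits" = 3,
           if (grepl("elongation", name)) 1.8
           else if (grepl("roughness", name)) 1.1
           else if (grepl("solidity", name)) 0.96
           else 0)
  }
  sd_of <- function(name, units) {
    switch(units,
           "mm3" = 7000, "mm2" = 1600, "mm" = 11, "mm^-1" = 0.05,
           "mm^2" = 90, "a.u." = 0.06, "bits" = 0.5,
           if (grepl("elongation", name)) 0.25
           else if (grepl("roughness", name)) 0.05
           else if (grepl("solidity", name)) 0.015
           else 1)
  }
  data.frame(
    name = manifest$name,
    mu = mapply(mean_of, manifest$name, manifest$units),
    sigma = mapply(sd_of, manifest$name, manifest$units),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic BPD cohort
#'
#' One row per subject: P and C covariates, severity grade, continuous BPD
#' indicators, and the 78 lung features with the planted per-grade shifts.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `subject_id`, `severity` (ordered factor
#'   none < mild < moderate < severe), the P group (`gestational_age_wk`,
#'   `birth_weight_g`, `body_size_cm`, `sex`), the C group (`apgar5`,
#'   `early_infection`, `steroids`), the indicators `ventilation_days` and
#'   `oxygen_days`, and the 78 feature columns of [feature_manifest()].
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_subjects = 50, seed = 3))
#' dplyr::count(co, severity)
generate_cohort <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  manifest <- feature_manifest()
  scales <- feature_base_scales(manifest)
  n <- spec$n_subjects
  with_seed(spec$seed, {
    grade <- sample(0:3, n, replace = TRUE, prob = spec$class_proportions)
    clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    ga <- clamp(30.5 - 1.1 * grade + stats::rnorm(n, sd = 1.8), 23, 34)
    bw <- clamp(-2600 + 125 * ga + stats::rnorm(n, sd = 160), 380, Inf)
    size <- 9 + 0.85 * ga + stats::rnorm(n, sd = 1.6)
    sex <- stats::rbinom(n, 1, 0.5)
    apgar <- clamp(round(8.6 - 0.5 * grade + stats::rnorm(n, sd = 1.2)), 0, 10)
    infection <- stats::rbinom(n, 1, stats::plogis(-1.6 + 0.45 * grade))
    steroids <- stats::rbinom(n, 1, stats::plogis(-2.1 + 0.9 * grade))
    vent <- stats::rnbinom(n, size = 1.5, mu = exp(0.4 + 1.0 * grade))
    oxy <- stats::rnbinom(n, size = 1.8, mu = exp(1.3 + 0.9 * grade))

    z <- matrix(stats::rnorm(n * nrow(manifest)), nrow = n)
    colnames(z) <- manifest$name
    for (f in names(spec$effect_sizes)) {
      z[, f] <- z[, f] + spec$effect_sizes[[f]] * grade
    }
    feats <- sweep(sweep(z, 2, scales$sigma, "*"), 2, scales$mu, "+")

    out <- tibble::tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      severity = factor(bpd_grades()[grade + 1], levels = bpd_grades(),
                        ordered = TRUE),
      gestational_age_wk = ga,
      birth_weight_g = bw,
      body_size_cm = size,
      sex = sex,
      apgar5 = as.numeric(apgar),
      early_infection = infection,
      steroids = steroids,
      ventilation_days = vent,
      oxygen_days = oxy
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(feats))
    attr(out, "effect_sizes") <- spec$effect_sizes
    attr(out, "seed") <- spec$seed
    out
  })
}

#' @importFrom stats plogis
NULL
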
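#' Published part-worth utilities used as simulation defaults
#'
#' Main-effects conditional-logit coefficients from the nationwide Indian
#' COVID-19 vaccine DCE that this package's synthetic world emulates, in the
#' coded column order of [covid_vaccine_attributes]. The cost coefficient is
#' the value implied by the published WTP ratios (-0.000649 per INR); the
#' printed coefficient is the rounded -0.0006.
#'
#' @return named numeric vector over [coded_columns] of the default grid.
#' @export
published_part_worths <- function() {
  c(effectiveness_70    =  0.658,
    effectiveness_90    =  1.005,
    duration_1y         =  0.335,
    duration_2y         =  0.225,
    duration_5y         =  0.381,
    injections_one      =  0.049,
    injections_two      =  0.045,
    side_effects_local  = -0.123,
    side_effects_systemic = -0.073,
    serious_risk_lakh   = -0.063,
    origin_indian       =  0.233,
    cost                = -0.000649)
}

#' Default respondent covariate prevalences
#'
#' Marginal prevalences of the simulated respondent covariates, matching the
#' socio-demographic profile of the emulated survey (n = 8759): 61.03% male,
#' 63.69% married and living with spouse, 58.23% city dwellers, 14.8%
#' healthcare workers, socio-economic status upper/middle/lower =
#' 3.56/53.69/42.74% (the three-class grouping used in the hesitancy model:
#' "middle" pools the upper-middle, middle and lower-middle strata of the
#' underlying five-class SES scale), 14.2% prior
#' COVID-19, 14.4% family COVID-19, and comorbidity rates diabetes 5.4%,
#' hypertension 4.9%, heart disease 2.2%, asthma 3.2%. Vaccination status:
#' both doses 77.3%, one dose 17.3%, none 5.4%. Age is drawn from a normal
#' with mean 36.32 and SD 12.61 years, truncated at 18.
#'
#' @return named list of prevalence parameters.
#' @export
default_covariate_prevalences <- function() {
  list(
    male = 0.6103,
    married = 0.6369,
    city = 0.5823,
    healthcare_worker = 0.1480,
    ses = c(upper = 0.0356, middle = 0.5369, lower = 0.4274),
    prior_covid = 0.142,
    family_covid = 0.144,
    diabetes = 0.054,
    hypertension = 0.049,
    heart_disease = 0.022,
    asthma = 0.032,
    vaccination = c(both = 0.773, one = 0.173, none = 0.054),
    age_mean = 36.32,
    age_sd = 12.61,
    age_min = 18
  )
}

#' Default covariate effects on hesitancy propensity (log odds ratios)
#'
#' Adjusted odds ratios from the emulated study's multivariate logistic
#' regression of vaccine hesitancy on respondent covariates, stored on the
#' log scale. Age is per year. Hypertension had no reported adjusted effect
#' and defaults to null.
#'
#' @return named numeric vector of log odds ratios.
#' @export
default_hesitancy_log_or <- function() {
  log(c(age = 1.02,
        male = 1.17,
        married = 1.11,
        city = 0.64,
        healthcare_worker = 0.85,
        ses_upper = 1.89,
        ses_middle = 1.91,
        prior_covid = 0.82,
        diabetes = 1.34,
        hypertension = 1.00,
        heart_disease = 1.44,
        asthma = 2.34,
        family_covid = 0.70))
}
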
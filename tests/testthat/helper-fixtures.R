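# Shared fixtures: cheap specs and designs used across test files.

preset_names <- c("hydrochlorothiazide", "donepezil", "amlodipine")

# small synthetic one-compartment drug for fast unit tests
toy_spec <- function(Ka = 0.02, ClF = 150, V1F = 4e5, dose = 1e4,
                     times = c(0, 15, 30, 60, 90, 120, 180, 240, 360,
                               480, 720, 1080, 1440)) {
  drug_spec("toy", "one_compartment_oral", dose = dose, Ka = Ka,
            ClF = ClF, V1F = V1F, sampling_times = times)
}

no_var <- function() variability_model(cv_between = 0, cv_within = 0,
                                       sigma_residual = 0)

small_design <- function(n = 12, ratio = 1, ...)
  design_spec(n_subjects = n, ratio_kat_kar = ratio, ...)

# independent log-linear slope for oracle use (no shared code with the
# package's terminal_slope)
ls_slope <- function(x, y) {
  fit <- lm(y ~ x)
  unname(coef(fit)[2])
}
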
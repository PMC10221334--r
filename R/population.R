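#' Variability model for virtual subjects
#'
#' Describes the three stochastic layers of the simulation: lognormal
#' between-subject variability applied once per subject to every model
#' parameter, lognormal within-subject (inter-occasion) variability applied
#' independently per period, and a proportional residual error on each
#' observed concentration. A coefficient of variation `cv` maps to the
#' lognormal scale as \eqn{\sigma^2 = \log(1 + cv^2)}.
#'
#' @param cv_between Between-subject CV (fraction) for every model
#'   parameter; study default 0.10.
#' @param cv_within Within-subject CV (fraction) per parameter and
#'   occasion; the study explores 0.05, 0.10 and 0.20.
#' @param sigma_residual Proportional residual error SD (fraction) on
#'   observed concentrations.
#' @return An object of class `variability_model`.
#' @export
variability_model <- function(cv_between = 0.10, cv_within = 0.10,
                              sigma_residual = 0.05) {
  stopifnot(cv_between >= 0, cv_within >= 0, sigma_residual >= 0)
  structure(list(cv_between = cv_between, cv_within = cv_within,
                 sigma_residual = sigma_residual),
            class = "variability_model")
}

.lognorm_sigma <- function(cv) sqrt(log(1 + cv^2))

#' 2x2 crossover design settings
#'
#' @param n_subjects Even number of subjects; randomized 1:1 to sequences
#'   TR and RT. The study uses 12/24/48 for the Monte Carlo sweeps and 100
#'   for the PCA dataset.
#' @param ratio_kat_kar Test/Reference ratio of the absorption rate
#'   constant Ka; the reference keeps the population value.
#' @param limits Bioequivalence acceptance limits on the ratio scale
#'   (closed interval); presets in regulatory use are `c(0.80, 1.25)`
#'   (default), `c(0.75, 1.33)` and `c(0.70, 1.43)`.
#' @param alpha One-sided significance level; 0.05 yields the conventional
#'   90% confidence interval.
#' @param n_trials Number of Monte Carlo trial replicates for sweeps.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 24, ratio_kat_kar = 1,
                        limits = c(0.80, 1.25), alpha = 0.05,
                        n_trials = 10000) {
  if (n_subjects < 4 || n_subjects %% 2 != 0)
    stop("n_subjects must be even and >= 4", call. = FALSE)
  if (ratio_kat_kar <= 0) stop("ratio_kat_kar must be > 0", call. = FALSE)
  stopifnot(length(limits) == 2, limits[1] < 1, limits[2] > 1,
            alpha > 0, alpha < 0.5, n_trials >= 1)
  structure(list(n_subjects = n_subjects, ratio_kat_kar = ratio_kat_kar,
                 limits = limits, alpha = alpha, n_trials = n_trials),
            class = "design_spec")
}

.param_names <- function(spec) {
  if (spec$model_kind == "two_compartment_oral_lag")
    c("Tlag", "Ka", "ClF", "QF", "V1F", "V2F")
  else c("Ka", "ClF", "V1F")
}

#' Draw subject-level PK parameters
#'
#' Each model parameter is drawn independently as
#' \eqn{p_i = \theta_i e^{\eta_i}}, \eqn{\eta_i \sim N(0, \log(1+cv_b^2))},
#' so the population value is the subject-level median.
#'
#' @param spec A [drug_spec()] giving the population values.
#' @param var A [variability_model()].
#' @return Named numeric vector of subject-level parameters.
#' @export
draw_subject_parameters <- function(spec, var) {
  nm <- .param_names(spec)
  theta <- unlist(spec[nm])
  sig <- .lognorm_sigma(var$cv_between)
  theta * exp(rnorm(length(theta), 0, sig))
}

#' Perturb subject parameters for one occasion
#'
#' Applies independent within-subject (inter-occasion) lognormal noise to a
#' subject-level parameter vector: \eqn{p_{ij} = p_i e^{\kappa_{ij}}} with
#' \eqn{\kappa_{ij} \sim N(0, \log(1+cv_w^2))}, drawn fresh for every
#' period.
#'
#' @param subject_params Named vector from [draw_subject_parameters()].
#' @param var A [variability_model()].
#' @return Named numeric vector of occasion-level parameters.
#' @export
draw_period_parameters <- function(subject_params, var) {
  sig <- .lognorm_sigma(var$cv_within)
  subject_params * exp(rnorm(length(subject_params), 0, sig))
}

#' Apply proportional residual error
#'
#' Observed concentrations are \eqn{C_{obs} = C (1 + \epsilon)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}. Negative results are truncated to
#' zero, and the pre-dose sample (time-zero concentration of exactly 0)
#' receives no error.
#'
#' @param conc Noise-free concentrations (>= 0).
#' @param sigma_residual Proportional error SD (fraction).
#' @return Observed concentrations, non-negative.
#' @export
apply_residual_error <- function(conc, sigma_residual) {
  if (sigma_residual == 0) return(conc)
  obs <- conc * (1 + rnorm(length(conc), 0, sigma_residual))
  obs[conc == 0] <- 0
  pmax(obs, 0)
}

#' Simulate one 2x2 crossover concentration dataset
#'
#' Generates `n_subjects` virtual subjects, randomizes them 1:1 to the TR
#' and RT sequences, and produces one Test and one Reference observed
#' profile per subject on the drug's sampling schedule. Test and Reference
#' share every population parameter except Ka: the Test profile uses
#' `ratio_kat_kar` times the subject's (occasion-perturbed) Ka.
#'
#' Draws are taken from R's global random number stream; call `set.seed()`
#' first (or use the `seed` argument) for reproducibility.
#'
#' @param spec A [drug_spec()].
#' @param design A [design_spec()].
#' @param var A [variability_model()].
#' @param seed Optional integer seed set before simulating.
#' @return A tidy data frame with columns `subject_id`, `sequence`
#'   (`"TR"`/`"RT"`), `period` (1/2), `formulation` (`"T"`/`"R"`),
#'   `time_min`, `conc`.
#' @export
#' @examples
#' ds <- simulate_crossover(drug_preset("donepezil"),
#'                          design_spec(n_subjects = 12),
#'                          variability_model(), seed = 1)
#' head(ds)
simulate_crossover <- function(spec, design, var, seed = NULL) {
  stopifnot(inherits(spec, "drug_spec"), inherits(design, "design_spec"),
            inherits(var, "variability_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n_subjects
  times <- spec$sampling_times
  nt <- length(times)
  seqs <- sample(rep(c("TR", "RT"), each = n / 2))

  conc_all <- numeric(2L * n * nt)
  form_all <- character(2L * n)
  for (i in seq_len(n)) {
    subj <- draw_subject_parameters(spec, var)
    for (period in 1:2) {
      form <- if (seqs[i] == "TR") c("T", "R")[period] else c("R", "T")[period]
      p <- draw_period_parameters(subj, var)
      if (form == "T") p[["Ka"]] <- p[["Ka"]] * design$ratio_kat_kar
      conc <- apply_residual_error(.conc_params(spec, as.list(p), times),
                                   var$sigma_residual)
      j <- 2L * (i - 1L) + period
      conc_all[((j - 1L) * nt + 1L):(j * nt)] <- conc
      form_all[j] <- form
    }
  }
  data.frame(subject_id = rep(seq_len(n), each = 2L * nt),
             sequence = rep(seqs, each = 2L * nt),
             period = rep(rep(1:2, each = nt), n),
             formulation = rep(form_all, each = nt),
             time_min = rep(times, 2L * n),
             conc = conc_all)
}
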
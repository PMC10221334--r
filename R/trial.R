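# Metrics that enter the BE assessment; Tmax is reported but not tested.
.BE_METRICS <- c("Cmax", "AUC", "AUCinf", "AS", "ASw")

#' Crossover ANOVA for one log-transformed metric
#'
#' Fits the classical fixed-effects linear model for a 2x2 crossover
#' (sequence, subject within sequence, period, formulation) to
#' log-transformed metric values and returns the Test-minus-Reference
#' formulation effect on the log scale, the residual mean square, and the
#' residual degrees of freedom \eqn{n_1 + n_2 - 2}.
#'
#' Subjects missing either period (or excluded upstream for non-positive
#' values) must already be removed; the model requires two observations
#' per subject.
#'
#' @param log_table Data frame with columns `subject_id`, `sequence`
#'   (`"TR"`/`"RT"`), `period` (1/2), `formulation` (`"T"`/`"R"`), and
#'   `log_value` (natural log of the metric).
#' @return List with `effect` (log T/R), `mse`, `df`, and the per-sequence
#'   subject counts `n1` (TR), `n2` (RT).
#' @export
anova_2x2 <- function(log_table) {
  need <- c("subject_id", "sequence", "period", "formulation", "log_value")
  miss <- setdiff(need, names(log_table))
  if (length(miss))
    stop("log_table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- log_table
  n_sub <- length(unique(tab$subject_id))
  if (n_sub < 3) stop("trial invalid: fewer than 3 analyzable subjects",
                      call. = FALSE)
  if (nrow(tab) != 2 * n_sub)
    stop("expected exactly two observations per subject", call. = FALSE)
  if (length(unique(tab$sequence[!duplicated(tab$subject_id)])) < 2)
    stop("both sequences must be represented", call. = FALSE)

  fit <- lm(log_value ~ sequence + factor(subject_id) + factor(period) +
              formulation,
            data = transform(tab,
                             formulation = factor(formulation,
                                                  levels = c("R", "T"))))
  cf <- coef(fit)[["formulationT"]]
  df <- fit$df.residual
  mse <- sum(fit$residuals^2) / df
  first <- !duplicated(tab$subject_id)
  list(effect = cf, mse = mse, df = df,
       n1 = sum(tab$sequence[first] == "TR"),
       n2 = sum(tab$sequence[first] == "RT"))
}

#' Geometric mean ratio and its 90% confidence interval
#'
#' \deqn{GMR = e^{effect}, \quad
#'   CI = \exp\left(effect \mp t_{1-\alpha,\,n_1+n_2-2}
#'   \sqrt{\frac{MSE}{2}\left(\frac{1}{n_1}+\frac{1}{n_2}\right)}\right)}
#'
#' @param effect Log-scale T-R formulation effect.
#' @param mse Residual mean square from [anova_2x2()].
#' @param n1,n2 Subjects per sequence.
#' @param alpha One-sided level (0.05 gives the 90% interval).
#' @return Named vector `c(gmr, lower, upper)`.
#' @export
gmr_ci <- function(effect, mse, n1, n2, alpha = 0.05) {
  stopifnot(mse >= 0, n1 >= 2, n2 >= 2)
  half <- qt(1 - alpha, n1 + n2 - 2) * sqrt(mse / 2 * (1 / n1 + 1 / n2))
  c(gmr = exp(effect), lower = exp(effect - half), upper = exp(effect + half))
}

#' Average-bioequivalence decision
#'
#' Accepts bioequivalence when the confidence interval lies inside the
#' closed acceptance interval (default 0.80-1.25).
#'
#' @param lower,upper Confidence interval bounds on the ratio scale.
#' @param limits Length-2 acceptance limits.
#' @return Logical.
#' @export
be_decision <- function(lower, upper, limits = c(0.80, 1.25)) {
  stopifnot(length(limits) == 2, limits[1] < limits[2])
  lower >= limits[1] && upper <= limits[2]
}

# Fast metric extraction: simulate, then slice the contiguous per-profile
# blocks of the dataset rather than re-splitting it.
.simulate_metric_matrix <- function(spec, design, var) {
  ds <- simulate_crossover(spec, design, var)
  nt <- length(spec$sampling_times)
  nprof <- 2L * design$n_subjects
  head_rows <- seq.int(1L, by = nt, length.out = nprof)
  met <- matrix(NA_real_, nprof, 8,
                dimnames = list(NULL, c("Cmax", "Tmax", "AUC", "AUCinf",
                                        "AS", "ASw", "lambda_z",
                                        "n_absorption_points")))
  for (j in seq_len(nprof)) {
    rr <- ((j - 1L) * nt + 1L):(j * nt)
    met[j, ] <- nca_metrics(ds$time_min[rr], ds$conc[rr])
  }
  list(metrics = met,
       subject_id = ds$subject_id[head_rows],
       sequence = ds$sequence[head_rows],
       period = ds$period[head_rows],
       formulation = ds$formulation[head_rows],
       dataset = ds)
}

.analyze_metric <- function(sim, metric, design) {
  v <- sim$metrics[, metric]
  ok_profile <- is.finite(v) & v > 0
  bad_subjects <- unique(sim$subject_id[!ok_profile])
  keep <- !(sim$subject_id %in% bad_subjects)
  n_excluded <- length(bad_subjects)
  tab <- data.frame(subject_id = sim$subject_id[keep],
                    sequence = sim$sequence[keep],
                    period = sim$period[keep],
                    formulation = sim$formulation[keep],
                    log_value = log(v[keep]))
  av <- anova_2x2(tab)
  ci <- gmr_ci(av$effect, av$mse, av$n1, av$n2, design$alpha)
  data.frame(metric = metric, gmr = ci[["gmr"]], lower = ci[["lower"]],
             upper = ci[["upper"]],
             be = be_decision(ci[["lower"]], ci[["upper"]], design$limits),
             mse = av$mse, df = av$df, n_excluded = n_excluded)
}

#' Simulate and analyze one 2x2 crossover bioequivalence trial
#'
#' Chains dataset simulation, per-profile NCA, and the log-scale
#' ANOVA / 90% CI / acceptance decision for each assessed metric (Cmax,
#' AUC, AUCinf, AS, ASw; Tmax is computed but not BE-tested). Subjects
#' with a non-positive or inestimable value of a metric are excluded from
#' that metric's analysis only, and counted.
#'
#' @inheritParams simulate_crossover
#' @return A data frame of class `trial_result`, one row per metric, with
#'   columns `metric`, `gmr`, `lower`, `upper`, `be`, `mse`, `df`,
#'   `n_excluded`. The simulated dataset is attached as attribute
#'   `"dataset"`.
#' @export
#' @examples
#' run_trial(drug_preset("donepezil"), design_spec(n_subjects = 12),
#'           variability_model(), seed = 42)
run_trial <- function(spec, design, var, seed = NULL) {
  stopifnot(inherits(spec, "drug_spec"), inherits(design, "design_spec"),
            inherits(var, "variability_model"))
  if (!is.null(seed)) set.seed(seed)
  sim <- .simulate_metric_matrix(spec, design, var)
  out <- do.call(rbind, lapply(.BE_METRICS, .analyze_metric,
                               sim = sim, design = design))
  rownames(out) <- NULL
  attr(out, "dataset") <- sim$dataset
  attr(out, "design") <- design
  class(out) <- c("trial_result", class(out))
  out
}
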
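make_log_table <- function(n = 6, effect = 0, seed = 1) {
  set.seed(seed)
  seqs <- rep(c("TR", "RT"), each = n / 2)
  subj_eff <- rnorm(n, 0, 0.3)
  rows <- lapply(seq_len(n), function(i) {
    forms <- if (seqs[i] == "TR") c("T", "R") else c("R", "T")
    data.frame(subject_id = i, sequence = seqs[i], period = 1:2,
               formulation = forms,
               log_value = subj_eff[i] + ifelse(forms == "T", effect, 0) +
                 rnorm(2, 0, 0.15))
  })
  do.call(rbind, rows)
}

test_that("constant T/R ratio yields effect = log r with zero residual", {
  tab <- make_log_table(6)
  r <- 1.1
  tab$log_value <- ifelse(tab$formulation == "T",
                          log(r) + tab$subject_id * 0.2,
                          tab$subject_id * 0.2)
  av <- anova_2x2(tab)
  expect_equal(av$effect, log(r), tolerance = 1e-10)
  expect_equal(av$mse, 0, tolerance = 1e-20)
  expect_equal(av$df, 4)
  expect_equal(c(av$n1, av$n2), c(3, 3))
})

test_that("crossover ANOVA matches an independent normal-equations solution", {
  tab <- make_log_table(6, effect = 0.08, seed = 21)
  av <- anova_2x2(tab)
  # from-scratch least squares: build the design matrix by hand
  # (the sequence contrast is aliased with the subject dummies and is
  # absorbed by them, so it is omitted; the fit is identical)
  Xr <- cbind(1,
              sapply(2:6, function(s) as.numeric(tab$subject_id == s)),
              as.numeric(tab$period == 2),
              as.numeric(tab$formulation == "T"))
  beta <- solve(t(Xr) %*% Xr, t(Xr) %*% tab$log_value)
  resid <- tab$log_value - Xr %*% beta
  df <- nrow(Xr) - ncol(Xr)
  expect_equal(av$effect, beta[nrow(beta)], tolerance = 1e-10)
  expect_equal(av$mse, sum(resid^2) / df, tolerance = 1e-10)
  expect_equal(av$df, df)
})

test_that("relabelling T and R negates the effect and preserves the MSE", {
  tab <- make_log_table(8, effect = 0.1, seed = 31)
  av <- anova_2x2(tab)
  flip <- tab
  flip$formulation <- ifelse(tab$formulation == "T", "R", "T")
  flip$sequence <- ifelse(tab$sequence == "TR", "RT", "TR")
  av2 <- anova_2x2(flip)
  expect_equal(av2$effect, -av$effect, tolerance = 1e-12)
  expect_equal(av2$mse, av$mse, tolerance = 1e-12)
  # GMR inverts, decision is unchanged under log-symmetric limits
  ci <- gmr_ci(av$effect, av$mse, av$n1, av$n2)
  ci2 <- gmr_ci(av2$effect, av2$mse, av2$n2, av2$n1)
  expect_equal(ci2[["gmr"]], 1 / ci[["gmr"]], tolerance = 1e-12)
  expect_equal(be_decision(ci[["lower"]], ci[["upper"]]),
               be_decision(ci2[["lower"]], ci2[["upper"]]))
})

test_that("the 90% CI formula reproduces a direct t-table computation", {
  ci <- gmr_ci(log(1.05), mse = 0.04, n1 = 12, n2 = 12)
  half <- qt(0.95, 22) * sqrt(0.04 / 2 * (2 / 12))
  expect_equal(unname(ci), exp(log(1.05) + c(0, -1, 1) * half))
  # degenerate: zero MSE collapses the interval onto the point estimate
  ci0 <- gmr_ci(log(1.02), 0, 6, 6)
  expect_equal(ci0[["lower"]], ci0[["gmr"]])
  expect_equal(ci0[["upper"]], ci0[["gmr"]])
  # symmetric about 1 on the log scale under a null effect
  cin <- gmr_ci(0, 0.05, 10, 10)
  expect_equal(log(cin[["upper"]]), -log(cin[["lower"]]))
})

test_that("acceptance limits are closed intervals", {
  expect_true(be_decision(0.85, 1.10))
  expect_false(be_decision(0.79, 1.10))
  expect_true(be_decision(0.80, 1.25))
  expect_false(be_decision(0.95, 1.2501))
  expect_true(be_decision(0.71, 1.42, limits = c(0.70, 1.43)))
})

test_that("run_trial chains simulation, NCA and statistics coherently", {
  spec <- drug_preset("hydrochlorothiazide")
  tr <- run_trial(spec, small_design(12, ratio = 1), variability_model(),
                  seed = 77)
  expect_s3_class(tr, "trial_result")
  expect_setequal(tr$metric, c("Cmax", "AUC", "AUCinf", "AS", "ASw"))
  expect_true(all(tr$lower < tr$gmr & tr$gmr < tr$upper))
  expect_equal(tr$df, 12 - tr$n_excluded - 2)  # df = n1 + n2 - 2
  # same seed twice: identical result
  tr2 <- run_trial(spec, small_design(12, ratio = 1), variability_model(),
                   seed = 77)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  # the attached dataset reproduces one metric's analysis end to end
  ds <- attr(tr, "dataset")
  met <- nca_table(ds)
  tab <- data.frame(subject_id = met$subject_id, sequence = met$sequence,
                    period = met$period, formulation = met$formulation,
                    log_value = log(met$Cmax))
  av <- anova_2x2(tab)
  ci <- gmr_ci(av$effect, av$mse, av$n1, av$n2)
  expect_equal(tr$gmr[tr$metric == "Cmax"], ci[["gmr"]], tolerance = 1e-12)
})

test_that("zero variability at ratio 1 gives unit GMR and universal acceptance", {
  for (d in preset_names) {
    tr <- run_trial(drug_preset(d), small_design(4, ratio = 1), no_var(),
                    seed = 5)
    expect_equal(tr$gmr, rep(1, 5), tolerance = 1e-8)
    expect_true(all(tr$be))
  }
})

test_that("zero variability at ratio 1.5 separates rate metrics from extent metrics", {
  tr <- run_trial(drug_preset("hydrochlorothiazide"),
                  small_design(4, ratio = 1.5), no_var(), seed = 5)
  gmr <- setNames(tr$gmr, tr$metric)
  expect_equal(gmr[["AUC"]], 1, tolerance = 0.01)
  expect_gt(gmr[["AS"]], gmr[["Cmax"]])
  expect_gt(gmr[["Cmax"]], 1)
})
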
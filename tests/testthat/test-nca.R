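test_that("cmax_tmax takes the maximum with earliest-time tie-break", {
  expect_equal(cmax_tmax(c(0, 60, 120, 240), c(0, 5, 9, 7)),
               c(Cmax = 9, Tmax = 120))
  expect_equal(cmax_tmax(c(0, 60, 120, 240), c(0, 9, 9, 7))[["Tmax"]], 60)
  expect_error(cmax_tmax(c(0, 10), c(0, 0)), "degenerate")
})

test_that("noise-free donepezil grid Tmax is the sample nearest below the continuous peak", {
  spec <- drug_preset("donepezil")
  m <- cmax_tmax(spec$sampling_times, pk_profile(spec))
  expect_equal(m[["Tmax"]], 180)
})

test_that("trapezoidal AUC matches hand values and adaptive quadrature", {
  expect_equal(auc_trapezoid(c(0, 10), c(0, 2)), 10)
  expect_equal(auc_trapezoid(seq(0, 100, 10), rep(1, 11)), 100)

  spec <- drug_preset("donepezil")  # smooth everywhere (no absorption lag)
  tt <- spec$sampling_times
  auc <- auc_trapezoid(tt, pk_profile(spec))
  truth <- integrate(function(t) pk_profile(spec, t), 0, max(tt),
                     rel.tol = 1e-10, subdivisions = 500)$value
  # trapezoid error bound: sum over intervals of h^3/12 * max|C''|
  h <- diff(tt)
  cpp <- sapply(seq_along(h), function(i) {
    g <- seq(tt[i], tt[i + 1], length.out = 25)
    max(abs(diff(pk_profile(spec, g), differences = 2))) / diff(g)[1]^2
  })
  bound <- sum(h^3 / 12 * cpp)
  expect_lt(abs(auc - truth), bound * 1.01)
})

test_that("terminal slope recovers exact and model rate constants", {
  tt <- seq(0, 600, by = 30)
  expect_equal(terminal_slope(tt, exp(-0.01 * tt) * c(0.1, rep(1, 20))),
               0.01, tolerance = 1e-10)

  spec <- drug_preset("donepezil")
  lz <- terminal_slope(spec$sampling_times, pk_profile(spec))
  expect_equal(lz, spec$ClF / spec$V1F, tolerance = 0.05)

  # too few points after Tmax
  expect_true(is.na(terminal_slope(c(0, 10, 20, 30), c(0, 5, 3, 2))))
})

test_that("AUCinf obeys its defining identity and the dose/clearance relation", {
  tt <- seq(0, 600, by = 5)
  conc <- exp(-0.01 * tt)  # bolus-like decay from C(0) = 1; analytic 1/lambda
  expect_equal(auc_inf(tt, conc), 100, tolerance = 0.02)

  spec <- drug_preset("donepezil")
  prof <- pk_profile(spec)
  lz <- terminal_slope(spec$sampling_times, prof)
  expect_equal(auc_inf(spec$sampling_times, prof, lz) -
                 auc_trapezoid(spec$sampling_times, prof),
               prof[length(prof)] / lz)
  expect_equal(auc_inf(spec$sampling_times, prof), spec$dose / spec$ClF,
               tolerance = 0.02)
})

test_that("AS and ASw match hand arithmetic and degenerate identities", {
  expect_equal(average_slope(c(0, 1, 2), c(0, 2, 6)), 3)
  expect_equal(weighted_average_slope(c(0, 1, 2), c(0, 2, 6)), 2)
  # single interval before Tmax: weight 1 makes ASw = AS
  expect_equal(weighted_average_slope(c(0, 30, 60), c(0, 7, 3)),
               average_slope(c(0, 30, 60), c(0, 7, 3)))
  expect_error(average_slope(c(0, 10, 20), c(5, 3, 1)), "first sample")
})

test_that("equal spacing makes AS telescope to the chord slope", {
  set.seed(5)
  for (i in 1:20) {
    n_up <- sample(3:8, 1)
    h <- runif(1, 5, 60)
    tt <- seq(0, by = h, length.out = n_up + 3)
    rise <- cumsum(runif(n_up, 0.1, 2))
    conc <- c(0, rise, rise[n_up] * c(0.8, 0.5))
    expect_equal(average_slope(tt, conc),
                 (max(conc) - conc[1]) / (tt[which.max(conc)] - tt[1]))
  }
})

test_that("ASw is bounded by AS on nondecreasing rises", {
  set.seed(6)
  for (i in 1:20) {
    tt <- c(0, sort(runif(5, 1, 100)), 120, 150)
    conc <- c(cumsum(runif(7, 0, 2)), 0.5)
    as_v <- average_slope(tt, conc)
    asw_v <- weighted_average_slope(tt, conc)
    expect_gte(asw_v, 0)
    expect_lte(asw_v, as_v)
  }
})

test_that("hydrochlorothiazide AS matches a cell-by-cell spreadsheet computation", {
  spec <- drug_preset("hydrochlorothiazide")
  tt <- spec$sampling_times
  conc <- pk_profile(spec)
  # independent spreadsheet-style oracle: explicit cells and a running sum
  i_tmax <- which.max(conc)
  total <- 0; k <- 0
  for (i in seq_len(i_tmax - 1)) {
    slope_cell <- (conc[i + 1] - conc[i]) / (tt[i + 1] - tt[i])
    total <- total + slope_cell
    k <- k + 1
  }
  expect_equal(average_slope(tt, conc), total / k)
  totw <- 0
  for (i in seq_len(i_tmax - 1))
    totw <- totw + (tt[i_tmax] - tt[i]) / tt[i_tmax] *
      (conc[i + 1] - conc[i]) / (tt[i + 1] - tt[i])
  expect_equal(weighted_average_slope(tt, conc), totw / k)
})

test_that("AS increases strictly with Ka on noise-free one-compartment profiles", {
  base <- drug_preset("donepezil")
  as_vals <- sapply(seq(0.5, 2, by = 0.25), function(f) {
    s <- base; s$Ka <- base$Ka * f
    average_slope(s$sampling_times, pk_profile(s))
  })
  expect_true(all(diff(as_vals) > 0))
})

test_that("metrics are scale-equivariant and unit-covariant", {
  spec <- drug_preset("amlodipine")
  tt <- spec$sampling_times
  conc <- pk_profile(spec)
  m <- nca_metrics(tt, conc)
  m10 <- nca_metrics(tt, conc * 10)
  expect_equal(m10[c("Cmax", "AUC", "AUCinf", "AS", "ASw")],
               10 * m[c("Cmax", "AUC", "AUCinf", "AS", "ASw")])
  expect_equal(m10[["Tmax"]], m[["Tmax"]])

  mh <- nca_metrics(tt / 60, conc)  # minutes -> hours
  expect_equal(mh[["AS"]], 60 * m[["AS"]])
  expect_equal(mh[["ASw"]], 60 * m[["ASw"]])
  expect_equal(mh[["AUC"]], m[["AUC"]] / 60)
  expect_equal(mh[["Tmax"]], m[["Tmax"]] / 60)
  expect_equal(mh[["lambda_z"]], 60 * m[["lambda_z"]], tolerance = 1e-8)
})

test_that("nca_table is deterministic and complete on a fixed dataset", {
  ds <- simulate_crossover(drug_preset("donepezil"), small_design(6),
                           variability_model(), seed = 8)
  a <- nca_table(ds)
  b <- nca_table(ds)
  expect_identical(a, b)
  expect_equal(nrow(a), 12)
  expect_true(all(is.finite(a$AS)))
  expect_true(all(a$n_absorption_points >= 2))
})
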
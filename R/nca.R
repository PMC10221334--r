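#' Peak concentration and its time
#'
#' @param time Sampling times (min), strictly increasing.
#' @param conc Observed concentrations (same length).
#' @return Named numeric vector `c(Cmax, Tmax)`. Ties in the maximum are
#'   broken to the earliest time.
#' @export
cmax_tmax <- function(time, conc) {
  .check_profile(time, conc)
  if (all(conc <= 0)) stop("degenerate profile: all concentrations zero",
                           call. = FALSE)
  i <- which.max(conc)  # first occurrence on ties
  c(Cmax = conc[i], Tmax = time[i])
}

.check_profile <- function(time, conc) {
  if (length(time) < 2 || length(time) != length(conc))
    stop("profile needs >= 2 matched time/concentration samples",
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  invisible(TRUE)
}

#' Area under the curve by the linear trapezoidal rule
#'
#' AUC from the first to the last sample, linear trapezoids throughout.
#'
#' @inheritParams cmax_tmax
#' @return AUC in ug.min/mL.
#' @export
auc_trapezoid <- function(time, conc) {
  .check_profile(time, conc)
  sum(diff(time) * (conc[-1] + conc[-length(conc)])) / 2
}

#' Terminal elimination rate constant (lambda_z)
#'
#' Log-linear regression on the terminal portion of the profile. Candidate
#' fits use the last `k` positive-concentration samples strictly after
#' Tmax, for `k` from `min_points` up to all such samples; the fit with
#' the highest adjusted R-squared wins (ties within 1e-4 go to the fit
#' with more points, the usual best-fit convention). Alternatively a fixed
#' number of terminal points can be requested.
#'
#' @inheritParams cmax_tmax
#' @param min_points Minimum number of terminal points (default 3).
#' @param fixed_k If non-`NULL`, skip the adjusted-R-squared search and use
#'   exactly the last `fixed_k` eligible points.
#' @return `lambda_z` (1/min), or `NA_real_` when fewer than `min_points`
#'   eligible samples exist or the estimated slope is non-negative.
#' @export
terminal_slope <- function(time, conc, min_points = 3, fixed_k = NULL) {
  .check_profile(time, conc)
  tmx <- cmax_tmax(time, conc)[["Tmax"]]
  keep <- time > tmx & conc > 0
  tt <- time[keep]; lc <- log(conc[keep])
  m <- length(tt)
  if (m < min_points) return(NA_real_)
  if (!is.null(fixed_k)) {
    if (fixed_k < 2 || fixed_k > m) return(NA_real_)
    ks <- fixed_k
  } else {
    ks <- min_points:m
  }
  best_k <- NA_integer_; best_adj <- -Inf
  for (k in ks) {
    idx <- (m - k + 1):m
    x <- tt[idx]; y <- lc[idx]
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    r2 <- if (sum((y - mean(y))^2) == 0) 1 else
      (b^2 * sxx) / sum((y - mean(y))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (adj > best_adj + 1e-4 ||
        (abs(adj - best_adj) <= 1e-4 && !is.na(best_k) && k > best_k)) {
      best_adj <- adj; best_k <- k
    }
  }
  if (is.na(best_k)) return(NA_real_)
  idx <- (m - best_k + 1):m
  x <- tt[idx]; y <- lc[idx]
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  lz <- -slope
  if (!is.finite(lz) || lz <= 0) NA_real_ else lz
}

#' AUC extrapolated to infinity
#'
#' \eqn{AUC_{inf} = AUC_{0-t} + C_{last}/\lambda_z}.
#'
#' @inheritParams cmax_tmax
#' @param lambda_z Terminal rate constant; computed via [terminal_slope()]
#'   when omitted.
#' @return AUCinf (ug.min/mL), or `NA_real_` if `lambda_z` is not
#'   estimable or the last concentration is not positive.
#' @export
auc_inf <- function(time, conc, lambda_z = NULL) {
  .check_profile(time, conc)
  if (is.null(lambda_z)) lambda_z <- terminal_slope(time, conc)
  clast <- conc[length(conc)]
  if (is.na(lambda_z) || clast <= 0) return(NA_real_)
  auc_trapezoid(time, conc) + clast / lambda_z
}

.absorption_slopes <- function(time, conc) {
  tmx <- cmax_tmax(time, conc)[["Tmax"]]
  keep <- time <= tmx
  tt <- time[keep]; cc <- conc[keep]
  n <- length(tt)
  if (n < 2)
    stop("average slope undefined: Tmax at the first sample", call. = FALSE)
  list(slopes = diff(cc) / diff(tt), t_left = tt[-n], tmax = tmx, n = n)
}

#' Average slope (AS) of the rising limb
#'
#' The mean of the successive chord slopes of the concentration-time curve
#' from the pre-dose sample up to and including Tmax:
#' \deqn{AS = \frac{1}{n-1}\sum_{i=1}^{n-1}
#'   \frac{C_{i+1}-C_i}{t_{i+1}-t_i}}
#' where \eqn{n} is the number of samples with \eqn{t \le T_{max}}
#' (the time-zero sample counts). AS carries genuine rate units
#' (concentration/time) and rises with the absorption rate constant.
#'
#' @inheritParams cmax_tmax
#' @return AS in ug/mL/min.
#' @export
average_slope <- function(time, conc) {
  .check_profile(time, conc)
  a <- .absorption_slopes(time, conc)
  mean(a$slopes)
}

#' Weighted average slope (ASw)
#'
#' As [average_slope()], but each interval slope is weighted by
#' \eqn{(T_{max}-t_i)/T_{max}} evaluated at the interval's left endpoint,
#' emphasizing the earliest part of the rise where absorption dominates:
#' \deqn{ASw = \frac{1}{n-1}\sum_{i=1}^{n-1}
#'   \frac{T_{max}-t_i}{T_{max}}\cdot\frac{C_{i+1}-C_i}{t_{i+1}-t_i}}
#'
#' @inheritParams cmax_tmax
#' @return ASw in ug/mL/min. Equals AS when only one interval precedes
#'   Tmax.
#' @export
weighted_average_slope <- function(time, conc) {
  .check_profile(time, conc)
  a <- .absorption_slopes(time, conc)
  if (a$tmax <= 0) stop("ASw requires Tmax > 0", call. = FALSE)
  mean((a$tmax - a$t_left) / a$tmax * a$slopes)
}

#' All six bioequivalence metrics for one profile
#'
#' @inheritParams cmax_tmax
#' @param lambda_z_min_points Passed to [terminal_slope()].
#' @return Named numeric vector with `Cmax`, `Tmax`, `AUC`, `AUCinf`,
#'   `AS`, `ASw`, `lambda_z`, `n_absorption_points`. Inestimable entries
#'   are `NA`.
#' @export
#' @examples
#' spec <- drug_preset("hydrochlorothiazide")
#' nca_metrics(spec$sampling_times, pk_profile(spec))
nca_metrics <- function(time, conc, lambda_z_min_points = 3) {
  .check_profile(time, conc)
  if (all(conc <= 0)) {
    out <- rep(NA_real_, 8)
    names(out) <- c("Cmax", "Tmax", "AUC", "AUCinf", "AS", "ASw",
                    "lambda_z", "n_absorption_points")
    return(out)
  }
  ct <- cmax_tmax(time, conc)
  lz <- terminal_slope(time, conc, min_points = lambda_z_min_points)
  auc <- auc_trapezoid(time, conc)
  aucinf <- auc_inf(time, conc, lambda_z = lz)
  as_val <- asw_val <- NA_real_
  n_abs <- sum(time <= ct[["Tmax"]])
  if (n_abs >= 2) {
    a <- .absorption_slopes(time, conc)
    as_val <- mean(a$slopes)
    asw_val <- mean((a$tmax - a$t_left) / a$tmax * a$slopes)
  }
  c(Cmax = ct[["Cmax"]], Tmax = ct[["Tmax"]], AUC = auc, AUCinf = aucinf,
    AS = as_val, ASw = asw_val, lambda_z = lz,
    n_absorption_points = n_abs)
}

#' Per-profile NCA over a crossover dataset
#'
#' Applies [nca_metrics()] to every subject/formulation profile of a tidy
#' concentration dataset (as produced by [simulate_crossover()] or read
#' via [read_profiles()]).
#'
#' @param dataset Data frame with columns `subject_id`, `sequence`,
#'   `period`, `formulation`, `time_min`, `conc`.
#' @return Data frame with one row per profile: the identifier columns
#'   plus the eight [nca_metrics()] values.
#' @export
nca_table <- function(dataset) {
  need <- c("subject_id", "sequence", "period", "formulation",
            "time_min", "conc")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- paste(dataset$subject_id, dataset$period, sep = "\r")
  idx <- split(seq_len(nrow(dataset)), key)
  res <- lapply(idx, function(ii) {
    ii <- ii[order(dataset$time_min[ii])]
    m <- nca_metrics(dataset$time_min[ii], dataset$conc[ii])
    cbind(data.frame(subject_id = dataset$subject_id[ii[1]],
                     sequence = dataset$sequence[ii[1]],
                     period = dataset$period[ii[1]],
                     formulation = dataset$formulation[ii[1]]),
          as.data.frame(as.list(m)))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$subject_id, out$period), ]
  rownames(out) <- NULL
  out
}
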
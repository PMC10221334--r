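.PCA_METRICS <- c("Cmax", "Tmax", "AUC", "AUCinf", "AS", "ASw")

#' Standardized metric matrix for PCA
#'
#' Pools the Test and Reference records of a per-profile NCA table (there
#' is no reason to distinguish formulations when studying how the metrics
#' co-vary), drops any record with an inestimable metric, and z-score
#' standardizes each of the six metric columns (population SD,
#' denominator n).
#'
#' @param metrics A [nca_table()] result (or any data frame containing the
#'   six metric columns).
#' @return Numeric matrix, one row per record, columns `Cmax`, `Tmax`,
#'   `AUC`, `AUCinf`, `AS`, `ASw`; each column has mean 0 and SD 1.
#'   Attribute `"n_dropped"` counts removed records.
#' @export
build_metric_matrix <- function(metrics) {
  miss <- setdiff(.PCA_METRICS, names(metrics))
  if (length(miss))
    stop("metrics table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(metrics[, .PCA_METRICS])
  keep <- apply(is.finite(m), 1, all)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 7)
    stop("need at least 7 complete records for the 6-metric PCA",
         call. = FALSE)
  ctr <- colMeans(m)
  sds <- sqrt(colMeans(sweep(m, 2, ctr)^2))
  if (any(sds == 0)) stop("constant metric column: PCA undefined",
                          call. = FALSE)
  z <- sweep(sweep(m, 2, ctr), 2, sds, "/")
  attr(z, "n_dropped") <- sum(!keep)
  z
}

#' Principal component analysis of the bioequivalence metrics
#'
#' Singular value decomposition of the standardized metric matrix. All six
#' components are retained; explained-variance fractions are
#' \eqn{s_k^2 / \sum s^2}. For a reproducible biplot orientation the axes
#' are signed so that Cmax loads positively on PC1 and AS negatively on
#' PC2 (pairwise vector angles do not depend on this convention).
#'
#' @param z A [build_metric_matrix()] output (any column-standardized
#'   numeric matrix works).
#' @return Object of class `pk_pca`: list with `loadings` (6 metrics x 6
#'   components, orthonormal columns), `explained` (variance fractions),
#'   `scores` (records x components), `n_records`.
#' @export
#' @examples
#' ds <- simulate_crossover(drug_preset("donepezil"),
#'                          design_spec(n_subjects = 16),
#'                          variability_model(), seed = 3)
#' fit <- pca_metrics(build_metric_matrix(nca_table(ds)))
#' fit$explained
pca_metrics <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) <= ncol(z))
    stop("need more records than metrics", call. = FALSE)
  sv <- svd(z)
  explained <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v
  scores <- sv$u %*% diag(sv$d)
  rownames(loadings) <- colnames(z)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  colnames(scores) <- colnames(loadings)
  # deterministic axis orientation (SVD sign freedom)
  nm <- rownames(loadings)
  flip <- rep(1, ncol(loadings))
  if ("Cmax" %in% nm && loadings["Cmax", 1] < 0) flip[1] <- -1
  if ("AS" %in% nm && ncol(loadings) >= 2 && loadings["AS", 2] > 0)
    flip[2] <- -1
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- sweep(scores, 2, flip, "*")
  structure(list(loadings = loadings, explained = explained,
                 scores = scores, n_records = nrow(z)),
            class = "pk_pca")
}

#' @export
print.pk_pca <- function(x, ...) {
  cat("<pk_pca>", x$n_records, "records,",
      sprintf("PC1+PC2 = %.1f%% of variance\n", 100 * sum(x$explained[1:2])))
  print(round(x$loadings[, 1:2], 3))
  invisible(x)
}

#' Biplot vector angles of the metric loadings
#'
#' Treats each metric's first two loadings as a 2-D vector. Reports the
#' angle of each vector to the PC1 axis (`atan2(l2, l1)`, degrees,
#' (-180, 180]), the pairwise angle between every two metric vectors
#' (arccos of the normalized inner product, [0, 180] degrees, invariant
#' under axis sign flips), and each metric's angle to the reflected Tmax
#' vector (-Tmax), which is the natural comparison for absorption-rate
#' behaviour since Tmax falls as absorption speeds up.
#'
#' @param fit A [pca_metrics()] result.
#' @return List with `axis_angles` (named vector, degrees), `pairwise`
#'   (symmetric matrix, degrees), `to_minus_tmax` (named vector, degrees).
#' @export
loading_angles <- function(fit) {
  stopifnot(inherits(fit, "pk_pca"))
  L <- fit$loadings[, 1:2, drop = FALSE]
  len <- sqrt(rowSums(L^2))
  if (any(len < 1e-12))
    warning("zero-length loading vector: angles undefined for ",
            paste(rownames(L)[len < 1e-12], collapse = ", "))
  axis_angles <- atan2(L[, 2], L[, 1]) * 180 / pi
  U <- L / len
  cosm <- pmin(pmax(U %*% t(U), -1), 1)
  pairwise <- acos(cosm) * 180 / pi
  to_minus_tmax <- NULL
  if ("Tmax" %in% rownames(L)) {
    cosr <- pmin(pmax(U %*% (-U["Tmax", ]), -1), 1)
    to_minus_tmax <- setNames(as.vector(acos(cosr) * 180 / pi), rownames(L))
  }
  list(axis_angles = axis_angles, pairwise = pairwise,
       to_minus_tmax = to_minus_tmax)
}

#' Scree data (explained variance percentages)
#'
#' @param fit A [pca_metrics()] result.
#' @return Numeric vector of per-component explained-variance percentages,
#'   non-increasing, summing to 100.
#' @export
scree_data <- function(fit) {
  stopifnot(inherits(fit, "pk_pca"))
  100 * fit$explained
}

#' Full PCA pipeline on a simulated crossover dataset
#'
#' Simulates a null 2x2 crossover (KaT/KaR = 1, both formulations drawn
#' from the same population), computes per-profile NCA, pools the 2N
#' records, and runs [pca_metrics()]. The study default is 100 subjects
#' (200 records) with 10% between- and within-subject variability.
#'
#' @inheritParams run_trial
#' @param n_subjects Number of virtual subjects.
#' @return A `pk_pca` object; the metric table is attached as attribute
#'   `"metrics"`.
#' @export
run_pca <- function(spec, n_subjects = 100, var = variability_model(),
                    seed = NULL) {
  design <- design_spec(n_subjects = n_subjects, ratio_kat_kar = 1)
  ds <- simulate_crossover(spec, design, var, seed = seed)
  met <- nca_table(ds)
  fit <- pca_metrics(build_metric_matrix(met))
  attr(fit, "metrics") <- met
  fit
}
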
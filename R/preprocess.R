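#' Clamp PSI values away from the boundaries
#'
#' Inclusion fractions of exactly 0 or 1 are reset to `lo` / `hi` so that the
#' logit-like PSI transform stays finite:
#' \deqn{X_m = 0.01 \text{ if } X_m = 0;\quad X_m \text{ if } X_m \in (0,1);
#'       \quad 0.99 \text{ if } X_m = 1.}
#' Interior values pass through unchanged, so the operation is idempotent.
#' Missing values are preserved.
#'
#' @param v Numeric vector of inclusion fractions in \eqn{[0, 1]}.
#' @param lo,hi Replacement values for exact 0 / exact 1.
#' @return Numeric vector in \eqn{[lo, hi]} (NA preserved).
#' @export
clamp_psi <- function(v, lo = 0.01, hi = 0.99) {
  bad <- is.finite(v) & (v < 0 | v > 1)
  if (any(bad))
    stop(sprintf("PSI value %g outside [0, 1]", v[bad][1L]), call. = FALSE)
  v[is.finite(v) & v == 0] <- lo
  v[is.finite(v) & v == 1] <- hi
  v
}

#' Log-transform expression values
#'
#' `log2(v + 1)`, the scale on which the interaction model is fit.
#'
#' @param v Non-negative numeric vector (NA allowed).
#' @return `log2(v + 1)`.
#' @export
transform_expression <- function(v) {
  bad <- is.finite(v) & v < 0
  if (any(bad))
    stop(sprintf("negative expression value %g", v[bad][1L]), call. = FALSE)
  log2(v + 1)
}

#' Transform clamped PSI values
#'
#' `log2(v / (1 - v) + 1)`: a strictly increasing map of the inclusion odds.
#' Defined on the open interval (0, 1); exact 0 / 1 values (where the odds
#' are degenerate) must be reset by [clamp_psi()] first.
#'
#' @param v Numeric vector of inclusion fractions in `(0, 1)`.
#' @return Transformed values; strictly increasing in `v`. NA preserved.
#' @export
transform_psi <- function(v) {
  bad <- is.finite(v) & (v <= 0 | v >= 1)
  if (any(bad))
    stop(sprintf("PSI value %g outside (0, 1); apply clamp_psi() first",
                 v[bad][1L]), call. = FALSE)
  log2(v / (1 - v) + 1)
}

#' Per-gene expression outlier mask
#'
#' Flags, on the raw (untransformed) scale, which samples of a gene's
#' expression vector lie within `mean +/- n_sd * std` of that gene's finite
#' values. Mean and std use the finite entries only; std is the sample
#' (n - 1) estimator. A constant vector (std = 0) keeps every sample.
#'
#' @param values Numeric vector (one gene across samples; NA allowed).
#' @param n_sd Width of the band in standard deviations.
#' @return Logical vector: `TRUE` = keep, `FALSE` = outlier, `NA` where the
#'   input was missing.
#' @export
outlier_mask <- function(values, n_sd = 3) {
  fin <- is.finite(values)
  if (!any(fin)) stop("all values missing; cannot compute outlier bounds",
                      call. = FALSE)
  if (sum(fin) < 2L) stop("need >= 2 finite values for outlier bounds",
                          call. = FALSE)
  m <- mean(values[fin])
  s <- stats::sd(values[fin])
  keep <- rep(NA, length(values))
  keep[fin] <- if (s == 0) TRUE else abs(values[fin] - m) <= n_sd * s
  names(keep) <- names(values)
  keep
}

#' @keywords internal
#' @noRd
triplet_skip <- function(reason, n = NA_integer_) {
  structure(list(skipped = TRUE, reason = reason, n = n),
            class = "triplet_skip")
}

#' Assemble the analysis-ready vectors for one triplet
#'
#' Intersects the samples with finite values in all three inputs (TF
#' expression, target expression, event PSI), drops samples whose TF *or*
#' target expression is an outlier under [outlier_mask()] (masks computed per
#' gene over the gene's full finite vector, raw scale, before any log
#' transform), then clamps and transforms PSI and log-transforms both
#' expression vectors. Sample order in the output is lexicographic, so the
#' result is invariant to input column ordering.
#'
#' @param expr Expression matrix (genes x samples), from [read_expression()].
#' @param psi PSI matrix (events x samples), from [read_psi()].
#' @param target,tf Gene identifiers (rows of `expr`).
#' @param event Event identifier (row of `psi`).
#' @param min_n Minimum retained samples; below it the triplet is flagged
#'   skipped (a `"triplet_skip"` object), not an error.
#' @param outlier_sd Band width for [outlier_mask()].
#' @param psi_clamp Length-2 clamp range passed to [clamp_psi()].
#' @return A `"triplet_vectors"` list with `sample_ids`, `x_tf`, `y_target`,
#'   `x_m` (all transformed, no missing values) and `n`; or a
#'   `"triplet_skip"` object with a reason.
#' @export
assemble_triplet <- function(expr, psi, target, tf, event,
                             min_n = 30, outlier_sd = 3,
                             psi_clamp = c(0.01, 0.99)) {
  for (g in c(tf, target)) {
    if (!g %in% rownames(expr))
      stop(sprintf("gene '%s' not in expression matrix", g), call. = FALSE)
  }
  if (!event %in% rownames(psi))
    stop(sprintf("event '%s' not in PSI matrix", event), call. = FALSE)

  common <- sort(intersect(colnames(expr), colnames(psi)), method = "radix")
  vt <- expr[tf, ]
  vy <- expr[target, ]
  vm <- psi[event, ]
  keep_t <- outlier_mask(vt, outlier_sd)[common]
  keep_y <- outlier_mask(vy, outlier_sd)[common]
  vt <- vt[common]; vy <- vy[common]; vm <- vm[common]

  ok <- is.finite(vt) & is.finite(vy) & is.finite(vm) &
    !is.na(keep_t) & keep_t & !is.na(keep_y) & keep_y
  n <- sum(ok)
  if (n < min_n)
    return(triplet_skip(sprintf("n = %d below minimum %d", n, min_n), n))

  structure(list(
    sample_ids = common[ok],
    x_tf = unname(transform_expression(vt[ok])),
    y_target = unname(transform_expression(vy[ok])),
    x_m = unname(transform_psi(clamp_psi(vm[ok], psi_clamp[1L],
                                         psi_clamp[2L]))),
    n = as.integer(n)
  ), class = "triplet_vectors")
}
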
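#' Fit the interaction model for one triplet
#'
#' Ordinary least squares for
#' \deqn{Y'_{target} = \beta_0 + \beta_1 X'_{tf} + \beta_2 X'_m +
#'       \beta_3 X'_{tf} X'_m + \epsilon}
#' on the transformed vectors of a triplet. The interaction coefficient
#' \eqn{\beta_3} is tested two-sided against 0 with a t statistic on
#' \eqn{n - 4} degrees of freedom. A rank-deficient design (e.g. constant PSI
#' after transform) or fewer than 5 samples yields an `"unfit"` record, never
#' an error.
#'
#' @param tv A `"triplet_vectors"` object from [assemble_triplet()] (or any
#'   list with numeric `x_tf`, `y_target`, `x_m` of equal length `n`).
#' @return A list: `status` (`"fit"` or `"unfit"`), `reason` (for unfit),
#'   `n`, `beta` (named length-4 vector), `se3`, `t3`, `p3`.
#' @export
fit_triplet <- function(tv) {
  n <- length(tv$y_target)
  unfit <- function(reason) list(status = "unfit", reason = reason,
                                 n = as.integer(n),
                                 beta = rep(NA_real_, 4L),
                                 se3 = NA_real_, t3 = NA_real_, p3 = NA_real_)
  if (n < 5L) return(unfit("fewer than 5 samples (no residual df)"))

  X <- cbind(1, tv$x_tf, tv$x_m, tv$x_tf * tv$x_m)
  y <- tv$y_target
  qrX <- qr(X)
  if (qrX$rank < 4L)
    return(unfit("rank-deficient design (constant or collinear regressor)"))

  beta <- qr.coef(qrX, y)
  res <- y - qr.fitted(qrX, y)
  df <- n - 4L
  sigma2 <- sum(res^2) / df
  V <- matrix(NA_real_, 4L, 4L)
  piv <- qrX$pivot
  V[piv, piv] <- chol2inv(qr.R(qrX))   # (X'X)^{-1}, un-pivoted
  se3 <- sqrt(sigma2 * V[4L, 4L])
  if (se3 == 0) {                      # exact fit: residuals identically 0
    t3 <- if (beta[4L] == 0) 0 else sign(beta[4L]) * Inf
    p3 <- if (beta[4L] == 0) 1 else 0
  } else {
    t3 <- beta[4L] / se3
    p3 <- 2 * stats::pt(abs(t3), df, lower.tail = FALSE)
  }
  list(status = "fit", reason = NA_character_, n = as.integer(n),
       beta = stats::setNames(as.numeric(beta),
                              c("beta0", "beta1", "beta2", "beta3")),
       se3 = se3, t3 = t3, p3 = p3)
}

#' Scan every (TF, target) pair against every splicing event
#'
#' Runs [assemble_triplet()] and [fit_triplet()] for each pair x event
#' combination, in deterministic (tf, target, event) lexicographic order.
#' Genes with fewer than `min_samples_gene` non-missing expression samples
#' are considered ineligible and their triplets recorded as skipped; the same
#' holds for identifiers absent from the matrices and for triplets whose
#' retained sample count falls below `min_samples_triplet`. Every attempted
#' combination yields exactly one row.
#'
#' @inheritParams assemble_triplet
#' @param pairs Data frame with columns `tf`, `target` ([read_pairs()]).
#' @param events Event identifiers to scan (default: all rows of `psi`).
#' @param min_samples_gene Minimum non-missing expression samples for a gene
#'   (TF or target) to enter the scan.
#' @param min_samples_triplet Minimum retained samples per triplet.
#' @param exclude_self Drop pairs where the TF is its own target.
#' @param exclude_host Skip triplets where the event's host gene equals the
#'   TF or the target (self-modulation).
#' @param verbose Log scan counts with `message()`.
#' @return A data frame (one row per attempted triplet) with columns
#'   `tf, target, event, event_gene, status, reason, n, beta0..beta3, se3,
#'   t3, p3` plus placeholder `q3, significant, sign` columns filled by
#'   [correct_fdr()]. `status` is one of `"fit"`, `"unfit"`, `"skipped"`.
#' @export
scan_all <- function(expr, psi, pairs, events = rownames(psi),
                     min_samples_gene = 400, min_samples_triplet = 30,
                     outlier_sd = 3, psi_clamp = c(0.01, 0.99),
                     exclude_self = FALSE, exclude_host = FALSE,
                     verbose = FALSE) {
  stopifnot(is.matrix(expr), is.matrix(psi),
            all(c("tf", "target") %in% names(pairs)))
  pairs <- unique(as.data.frame(pairs)[, c("tf", "target")])
  if (exclude_self) pairs <- pairs[pairs$tf != pairs$target, , drop = FALSE]
  if (!nrow(pairs)) {
    warning("empty TF-target pair list; nothing to scan", call. = FALSE)
    return(empty_results())
  }
  pairs <- pairs[order(pairs$tf, pairs$target, method = "radix"), ,
                 drop = FALSE]
  events <- sort(unique(events), method = "radix")
  ev_gene <- attr(psi, "event_gene")

  common <- sort(intersect(colnames(expr), colnames(psi)), method = "radix")
  if (!length(common)) stop("expression and PSI matrices share no samples",
                            call. = FALSE)

  # Per-gene cache: non-missing count (full matrix), keep-mask and
  # transformed values restricted to the common samples.
  genes <- intersect(unique(c(pairs$tf, pairs$target)), rownames(expr))
  gcache <- new.env(parent = emptyenv())
  for (g in genes) {
    v_full <- expr[g, ]
    fin_full <- is.finite(v_full)
    v <- v_full[common]
    fin <- is.finite(v)
    keep <- fin
    if (sum(fin_full) >= 2L) {
      km <- outlier_mask(v_full, outlier_sd)[common]
      keep <- fin & !is.na(km) & km
    }
    tr <- rep(NA_real_, length(v))
    tr[fin] <- log2(v[fin] + 1)
    assign(g, list(count = sum(fin_full), keep = keep, trans = tr),
           envir = gcache)
  }
  # Per-event cache over common samples.
  ecache <- new.env(parent = emptyenv())
  for (e in intersect(events, rownames(psi))) {
    v <- psi[e, common]
    fin <- is.finite(v)
    tr <- rep(NA_real_, length(v))
    tr[fin] <- transform_psi(clamp_psi(v[fin], psi_clamp[1L], psi_clamp[2L]))
    assign(e, list(fin = fin, trans = tr), envir = ecache)
  }

  n_rows <- nrow(pairs) * length(events)
  out <- list(
    tf = character(n_rows), target = character(n_rows),
    event = character(n_rows), event_gene = rep(NA_character_, n_rows),
    status = character(n_rows), reason = rep(NA_character_, n_rows),
    n = rep(NA_integer_, n_rows),
    beta0 = rep(NA_real_, n_rows), beta1 = rep(NA_real_, n_rows),
    beta2 = rep(NA_real_, n_rows), beta3 = rep(NA_real_, n_rows),
    se3 = rep(NA_real_, n_rows), t3 = rep(NA_real_, n_rows),
    p3 = rep(NA_real_, n_rows)
  )

  i <- 0L
  for (p in seq_len(nrow(pairs))) {
    tf <- pairs$tf[p]; tg <- pairs$target[p]
    pair_reason <- NULL
    if (!tf %in% genes) pair_reason <- "tf not in expression matrix"
    else if (!tg %in% genes) pair_reason <- "target not in expression matrix"
    else {
      ctf <- get(tf, envir = gcache); ctg <- get(tg, envir = gcache)
      if (ctf$count < min_samples_gene)
        pair_reason <- sprintf("tf has %d non-missing samples (< %d)",
                               ctf$count, min_samples_gene)
      else if (ctg$count < min_samples_gene)
        pair_reason <- sprintf("target has %d non-missing samples (< %d)",
                               ctg$count, min_samples_gene)
    }
    for (e in events) {
      i <- i + 1L
      out$tf[i] <- tf; out$target[i] <- tg; out$event[i] <- e
      hg <- if (!is.null(ev_gene)) unname(ev_gene[e]) else NA_character_
      out$event_gene[i] <- hg
      if (!is.null(pair_reason)) {
        out$status[i] <- "skipped"; out$reason[i] <- pair_reason
        next
      }
      if (!exists(e, envir = ecache)) {
        out$status[i] <- "skipped"; out$reason[i] <- "event not in PSI matrix"
        next
      }
      if (exclude_host && !is.na(hg) && hg %in% c(tf, tg)) {
        out$status[i] <- "skipped"
        out$reason[i] <- "event host gene equals tf or target"
        next
      }
      ce <- get(e, envir = ecache)
      ok <- ctf$keep & ctg$keep & ce$fin
      n <- sum(ok)
      if (n < min_samples_triplet) {
        out$status[i] <- "skipped"
        out$reason[i] <- sprintf("n = %d below minimum %d", n,
                                 min_samples_triplet)
        out$n[i] <- n
        next
      }
      fit <- fit_triplet(list(x_tf = ctf$trans[ok], y_target = ctg$trans[ok],
                              x_m = ce$trans[ok]))
      out$status[i] <- fit$status
      out$reason[i] <- fit$reason
      out$n[i] <- fit$n
      out$beta0[i] <- fit$beta[1L]; out$beta1[i] <- fit$beta[2L]
      out$beta2[i] <- fit$beta[3L]; out$beta3[i] <- fit$beta[4L]
      out$se3[i] <- fit$se3; out$t3[i] <- fit$t3; out$p3[i] <- fit$p3
    }
  }

  res <- as.data.frame(out, stringsAsFactors = FALSE)
  res$q3 <- NA_real_
  res$significant <- NA
  res$sign <- NA_character_
  if (verbose) {
    message(sprintf("scan: %d attempted, %d fit, %d skipped, %d unfit",
                    nrow(res), sum(res$status == "fit"),
                    sum(res$status == "skipped"),
                    sum(res$status == "unfit")))
  }
  res
}

#' @keywords internal
#' @noRd
empty_results <- function() {
  cols <- triplet_columns()
  out <- lapply(cols, function(tp) switch(tp,
                                          character = character(),
                                          integer = integer(),
                                          numeric = numeric(),
                                          logical = logical()))
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Multiple-testing correction across the triplet scan
#'
#' Benjamini-Hochberg step-up applied once over all fit triplets jointly
#' (the whole scan pooled), or per TF with `by_tf = TRUE`. Significance is
#' `q3 < alpha` in `"fdr"` mode, or the uncorrected `p3 < alpha` in
#' `"pvalue"` mode. For significant triplets `sign` records the direction of
#' the interaction coefficient (`"positive"` iff `beta3 > 0`).
#'
#' @param results Scan result data frame from [scan_all()].
#' @param alpha Significance level (default 0.05; for `"pvalue"` mode a
#'   practitioner might use 0.01).
#' @param mode `"fdr"` (BH-adjusted q-values) or `"pvalue"` (raw p-values).
#' @param by_tf Apply the correction within each TF separately instead of
#'   pooling the whole scan.
#' @return `results` with `q3`, `significant`, `sign` filled for fit rows.
#' @export
correct_fdr <- function(results, alpha = 0.05, mode = c("fdr", "pvalue"),
                        by_tf = FALSE) {
  mode <- match.arg(mode)
  fit <- which(results$status == "fit")
  results$q3 <- rep(NA_real_, nrow(results))
  results$significant <- rep(NA, nrow(results))
  results$sign <- rep(NA_character_, nrow(results))
  if (!length(fit)) return(results)

  q <- rep(NA_real_, length(fit))
  if (by_tf) {
    for (grp in split(seq_along(fit), results$tf[fit]))
      q[grp] <- stats::p.adjust(results$p3[fit[grp]], method = "BH")
  } else {
    q <- stats::p.adjust(results$p3[fit], method = "BH")
  }
  results$q3[fit] <- q
  sig <- if (mode == "fdr") q < alpha else results$p3[fit] < alpha
  results$significant[fit] <- sig
  results$sign[fit][sig] <- ifelse(results$beta3[fit][sig] > 0,
                                   "positive", "negative")
  results
}
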
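#' Split samples into low- and high-PSI groups
#'
#' Takes the bottom and top `floor(fraction * n)` samples by raw
#' (pre-clamp, pre-transform) PSI. Ties are broken by sample identifier in
#' lexicographic order, so the split is deterministic; monotone transforms of
#' PSI cannot change the membership.
#'
#' @param psi_vector Named numeric vector of raw PSI values (NA dropped).
#' @param fraction Group size as a fraction of the non-missing samples
#'   (default 0.30: the top/bottom 30 percent).
#' @return List with character vectors `low` and `high` (disjoint sample
#'   sets, each of size `floor(fraction * n)`).
#' @export
split_by_psi <- function(psi_vector, fraction = 0.30) {
  stopifnot(!is.null(names(psi_vector)), fraction > 0, fraction < 1)
  v <- psi_vector[is.finite(psi_vector)]
  n <- length(v)
  k <- floor(fraction * n)
  if (k < 1L)
    stop(sprintf("need at least %d non-missing PSI samples for fraction %g",
                 ceiling(1 / fraction), fraction), call. = FALSE)
  if (2L * k > n)
    stop("low and high PSI groups would overlap; too few samples",
         call. = FALSE)
  if (length(unique(v)) == 1L)
    warning("all PSI values equal; split is tie-broken by sample id",
            call. = FALSE)
  ord <- order(v, names(v), method = "radix")
  list(low = names(v)[ord[seq_len(k)]],
       high = names(v)[ord[seq.int(n - k + 1L, n)]])
}

#' Correlation state of a TF-target pair within a sample group
#'
#' Pearson correlation of the (transformed) TF and target expression
#' restricted to `samples`, with the usual two-sided t test. The state is
#' `"+"` if significantly positive, `"-"` if significantly negative, and
#' `"Non-sig"` otherwise. A zero-variance vector gives `"Non-sig"` with an
#' undefined (NA) correlation.
#'
#' @param x_tf,y_target Named numeric vectors (transformed expression).
#' @param samples Sample identifiers to restrict to (length >= 3).
#' @param alpha_corr Significance level for calling a `"+"`/`"-"` state.
#' @return List with `r`, `p`, `state`.
#' @export
correlation_state <- function(x_tf, y_target, samples, alpha_corr = 0.05) {
  stopifnot(length(samples) >= 3L)
  x <- x_tf[samples]
  y <- y_target[samples]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, state = "Non-sig"))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- ct$p.value
  state <- if (is.na(p) || p >= alpha_corr) "Non-sig"
           else if (r > 0) "+" else "-"
  list(r = r, p = p, state = state)
}

#' @keywords internal
#' @noRd
call_category <- function(state_low, state_high) {
  if (state_low == "Non-sig" && state_high == "Non-sig") return("Uncalled")
  if (state_low != "Non-sig" && state_high != "Non-sig") {
    if (state_low == state_high) return("Repress")
    return("Inverts")
  }
  "Active"
}

#' Mode-of-action call for one significant triplet
#'
#' Compares the TF-target correlation state between the low- and high-PSI
#' sample groups ([split_by_psi()]) and categorizes the transition:
#' *Inverts* when the state flips sign (`+ -> -` or `- -> +`), *Repress*
#' when both groups share the same significant sign, *Active* when exactly
#' one side is `Non-sig`; a `Non-sig -> Non-sig` transition is *Uncalled*.
#' The modulation `sign` is the sign of the triplet's interaction
#' coefficient. For Repress calls, `reduced` records whether the correlation
#' magnitude shrank from the low to the high group.
#'
#' @param tv `"triplet_vectors"` from [assemble_triplet()] (transformed
#'   expression; the correlation scale).
#' @param psi_raw Named raw PSI vector covering `tv$sample_ids`.
#' @param beta3 The triplet's fitted interaction coefficient.
#' @param fraction Group fraction for [split_by_psi()].
#' @param alpha_corr Level for the correlation states.
#' @param min_group Minimum samples per group to call (default 3).
#' @return List with `sign`, `r_low`, `p_low`, `state_low`, `r_high`,
#'   `p_high`, `state_high`, `transition` (e.g. `"Non-sig->+"`), `category`
#'   (`Active`/`Repress`/`Inverts`/`Uncalled`), `reduced`, `reason`.
#' @export
classify_triplet <- function(tv, psi_raw, beta3, fraction = 0.30,
                             alpha_corr = 0.05, min_group = 3L) {
  uncalled <- function(reason) {
    list(sign = if (is.na(beta3)) NA_character_
                else if (beta3 > 0) "positive" else "negative",
         r_low = NA_real_, p_low = NA_real_, state_low = NA_character_,
         r_high = NA_real_, p_high = NA_real_, state_high = NA_character_,
         transition = NA_character_, category = "Uncalled",
         reduced = NA, reason = reason)
  }
  ids <- tv$sample_ids
  psi <- psi_raw[ids]
  grp <- tryCatch(split_by_psi(psi, fraction), error = function(e) NULL)
  if (is.null(grp)) return(uncalled("too few samples to form PSI groups"))
  if (length(grp$low) < min_group || length(grp$high) < min_group)
    return(uncalled(sprintf("group size below %d", min_group)))

  x <- stats::setNames(tv$x_tf, ids)
  y <- stats::setNames(tv$y_target, ids)
  lo <- correlation_state(x, y, grp$low, alpha_corr)
  hi <- correlation_state(x, y, grp$high, alpha_corr)
  category <- call_category(lo$state, hi$state)
  reduced <- if (category == "Repress") abs(hi$r) < abs(lo$r) else NA
  list(sign = if (beta3 > 0) "positive" else "negative",
       r_low = lo$r, p_low = lo$p, state_low = lo$state,
       r_high = hi$r, p_high = hi$p, state_high = hi$state,
       transition = paste0(lo$state, "->", hi$state),
       category = category, reduced = reduced,
       reason = if (category == "Uncalled")
         "no significant correlation in either group" else NA_character_)
}

#' Classify every significant triplet of a scan
#'
#' Re-assembles each significant triplet with the same preprocessing as the
#' scan, calls [classify_triplet()], and tabulates the calls into the
#' 2 x 3 (sign x category) mode-of-action summary, with Uncalled counted
#' separately.
#'
#' @inheritParams scan_all
#' @param results FDR-corrected scan results ([correct_fdr()]).
#' @param fraction,alpha_corr,min_group Passed to [classify_triplet()].
#' @return List with `calls` (one data-frame row per significant triplet)
#'   and `summary` (data frame: `sign` x `Active`, `Repress`, `Inverts`,
#'   `Uncalled` counts).
#' @export
classify_all <- function(results, expr, psi, fraction = 0.30,
                         alpha_corr = 0.05, min_group = 3L,
                         min_samples_triplet = 30, outlier_sd = 3,
                         psi_clamp = c(0.01, 0.99)) {
  sig <- which(!is.na(results$significant) & results$significant)
  rows <- vector("list", length(sig))
  for (j in seq_along(sig)) {
    i <- sig[j]
    tv <- assemble_triplet(expr, psi, results$target[i], results$tf[i],
                           results$event[i], min_n = min_samples_triplet,
                           outlier_sd = outlier_sd, psi_clamp = psi_clamp)
    if (inherits(tv, "triplet_skip")) {
      cl <- list(sign = results$sign[i], r_low = NA_real_, p_low = NA_real_,
                 state_low = NA_character_, r_high = NA_real_,
                 p_high = NA_real_, state_high = NA_character_,
                 transition = NA_character_, category = "Uncalled",
                 reduced = NA, reason = tv$reason)
    } else {
      cl <- classify_triplet(tv, psi[results$event[i], ], results$beta3[i],
                             fraction, alpha_corr, min_group)
    }
    rows[[j]] <- data.frame(tf = results$tf[i], target = results$target[i],
                            event = results$event[i], cl,
                            stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), target = character(), event = character(),
               sign = character(), r_low = numeric(), p_low = numeric(),
               state_low = character(), r_high = numeric(),
               p_high = numeric(), state_high = character(),
               transition = character(), category = character(),
               reduced = logical(), reason = character(),
               stringsAsFactors = FALSE)
  list(calls = calls, summary = summarize_modes(calls))
}

#' Tabulate mode-of-action calls
#'
#' @param calls The `calls` data frame from [classify_all()].
#' @return Data frame with rows `positive` / `negative` and columns
#'   `Active`, `Repress`, `Inverts`, `Uncalled`.
#' @export
summarize_modes <- function(calls) {
  signs <- c("positive", "negative")
  cats <- c("Active", "Repress", "Inverts", "Uncalled")
  m <- matrix(0L, 2L, 4L, dimnames = list(signs, cats))
  if (nrow(calls)) {
    tab <- table(factor(calls$sign, signs), factor(calls$category, cats))
    m[rownames(tab), colnames(tab)] <- tab
  }
  data.frame(sign = signs, as.data.frame.matrix(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The mode-of-action transition labels
#'
#' The eight low-to-high correlation-state transitions that receive a
#' category: four *Active* (one side `Non-sig`), two *Repress* (same
#' significant sign on both sides) and two *Inverts* (sign flip).
#'
#' @return Character vector of transition labels, `"<low>" -> "<high>"`.
#' @export
moa_transitions <- function() {
  c("Non-sig->+", "-->Non-sig", "-->-", "-->+",
    "+->Non-sig", "Non-sig->-", "+->+", "+->-")
}
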
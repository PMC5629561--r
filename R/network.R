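#' Aggregate triplet calls into TF-modulator edges
#'
#' One edge per (TF, event) pair with at least one tested (fit) triplet.
#' `pct_influenced` is 100 x (significant triplets) / (fit triplets) for that
#' pair's targets; skipped and unfit triplets are excluded from the
#' denominator. Influenced counts are split by interaction sign.
#'
#' @param results FDR-corrected scan results ([correct_fdr()]).
#' @return Data frame with columns `tf`, `event`, `event_gene`,
#'   `n_targets_tested`, `n_influenced`, `n_positive`, `n_negative`,
#'   `pct_influenced`, `ppi_supported` (NA until [filter_ppi()] runs),
#'   ordered by (tf, event).
#' @export
summarize_edges <- function(results) {
  fit <- results[results$status == "fit", , drop = FALSE]
  if (!nrow(fit)) {
    return(data.frame(tf = character(), event = character(),
                      event_gene = character(), n_targets_tested = integer(),
                      n_influenced = integer(), n_positive = integer(),
                      n_negative = integer(), pct_influenced = numeric(),
                      ppi_supported = logical(), stringsAsFactors = FALSE))
  }
  if (all(is.na(fit$significant)))
    stop("results carry no significance calls; run correct_fdr() first",
         call. = FALSE)
  key <- paste(fit$tf, fit$event, sep = "\r")
  grp <- split(seq_len(nrow(fit)), key)
  rows <- lapply(grp, function(idx) {
    sig <- fit$significant[idx] %in% TRUE
    data.frame(tf = fit$tf[idx[1L]], event = fit$event[idx[1L]],
               event_gene = fit$event_gene[idx[1L]],
               n_targets_tested = length(idx),
               n_influenced = sum(sig),
               n_positive = sum(sig & fit$beta3[idx] > 0),
               n_negative = sum(sig & fit$beta3[idx] < 0),
               pct_influenced = 100 * sum(sig) / length(idx),
               ppi_supported = NA, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tf, out$event, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold the TF-modulator network
#'
#' Keeps edges whose influence percentage strictly exceeds `min_pct`
#' ("more than" semantics, so an edge at exactly the threshold is dropped).
#'
#' @param edges Edge data frame from [summarize_edges()].
#' @param min_pct Percentage threshold (e.g. 30, 20, 10).
#' @param verbose Report retained TF / modulator counts with `message()`.
#' @return The retained edges; attributes `n_tfs` and `n_modulators` give the
#'   distinct node counts.
#' @export
threshold_network <- function(edges, min_pct, verbose = FALSE) {
  keep <- edges[edges$pct_influenced > min_pct, , drop = FALSE]
  rownames(keep) <- NULL
  attr(keep, "n_tfs") <- length(unique(keep$tf))
  attr(keep, "n_modulators") <- length(unique(keep$event))
  if (verbose)
    message(sprintf("network: %d edge(s) > %g%% (%d TFs, %d modulators)",
                    nrow(keep), min_pct, attr(keep, "n_tfs"),
                    attr(keep, "n_modulators")))
  keep
}

#' Flag (and optionally require) protein-interaction support
#'
#' An edge is supported when the unordered pair (TF, event host gene) occurs
#' in the PPI edge list. Events without a host-gene annotation are
#' unsupported, with a warning. Percentages are never altered, only the
#' `ppi_supported` flag (and, with `require_ppi`, membership).
#'
#' @param edges Edge data frame from [summarize_edges()].
#' @param ppi PPI edge list from [read_ppi()].
#' @param require_ppi Drop unsupported edges instead of just flagging them.
#' @return `edges` with `ppi_supported` set (subset if `require_ppi`).
#' @export
filter_ppi <- function(edges, ppi, require_ppi = FALSE) {
  if (!nrow(edges)) return(edges)
  host <- edges$event_gene
  if (anyNA(host))
    warning(sprintf("%d edge(s) lack a host-gene annotation; marked unsupported",
                    sum(is.na(host))), call. = FALSE)
  ppi_key <- paste(ppi$protein1, ppi$protein2, sep = "\r")
  edge_key <- paste(pmin(edges$tf, host), pmax(edges$tf, host), sep = "\r")
  edges$ppi_supported <- !is.na(host) & edge_key %in% ppi_key
  if (require_ppi) {
    edges <- edges[edges$ppi_supported, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}
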
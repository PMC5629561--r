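#' @keywords internal
#' @noRd
read_tsv_matrix <- function(path, missing_tokens = c("", "NA"),
                            what = "matrix", gene_col = c("auto", "none")) {
  gene_col <- match.arg(gene_col)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = NULL, quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop(sprintf("%s file '%s': malformed header, need an id column plus >= 1 sample column",
                 what, path), call. = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("%s file '%s': duplicate row identifier(s): %s",
                 what, path, paste(dup, collapse = ", ")), call. = FALSE)
  }
  df <- df[, -1L, drop = FALSE]

  event_gene <- NULL
  if (gene_col == "auto" && ncol(df) >= 1L &&
      tolower(names(df)[1L]) %in% c("event_gene", "gene", "host_gene")) {
    event_gene <- df[[1L]]
    event_gene[event_gene %in% missing_tokens] <- NA_character_
    names(event_gene) <- ids
    df <- df[, -1L, drop = FALSE]
    if (ncol(df) < 1L)
      stop(sprintf("%s file '%s': no sample columns after host-gene column",
                   what, path), call. = FALSE)
  }
  samples <- names(df)
  if (anyDuplicated(samples))
    stop(sprintf("%s file '%s': duplicate sample identifier(s): %s", what, path,
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
         call. = FALSE)

  chr <- as.matrix(df)
  chr[chr %in% missing_tokens] <- NA_character_
  num <- suppressWarnings(array(as.numeric(chr), dim = dim(chr)))
  bad <- is.na(num) & !is.na(chr)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s file '%s': non-numeric value '%s' at row '%s', sample '%s'",
                 what, path, chr[ij[1L], ij[2L]], ids[ij[1L]], samples[ij[2L]]),
         call. = FALSE)
  }
  dimnames(num) <- list(ids, samples)
  list(values = num, event_gene = event_gene)
}

#' Read a gene-expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds sample identifiers and
#' whose first column holds gene identifiers; remaining cells are non-negative
#' expression values (counts or normalized abundance). Empty cells and the
#' token \code{"NA"} are read as missing. Identifiers are opaque,
#' case-sensitive strings; no symbol normalization is applied.
#'
#' @param path Path to the TSV file.
#' @param missing_tokens Character vector of cell values treated as missing.
#' @return A numeric matrix, genes x samples, with unique dimnames. Missing
#'   entries are `NA`; all finite entries are `>= 0`.
#' @export
read_expression <- function(path, missing_tokens = c("", "NA")) {
  parsed <- read_tsv_matrix(path, missing_tokens, what = "expression",
                            gene_col = "none")
  m <- parsed$values
  neg <- which(is.finite(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("expression file '%s': negative value %g at gene '%s', sample '%s'",
                 path, m[neg[1L, 1L], neg[1L, 2L]],
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]),
         call. = FALSE)
  }
  m
}

#' Read a PSI (percent spliced in) matrix from TSV
#'
#' Same dialect as [read_expression()]: rows are splicing events, columns are
#' samples, values are inclusion fractions in \eqn{[0, 1]} with missing
#' allowed. An optional second column named \code{event_gene} (or
#' \code{gene} / \code{host_gene}) gives the modulator host gene per event and
#' is attached as the `"event_gene"` attribute (a named character vector).
#'
#' @inheritParams read_expression
#' @return A numeric matrix, events x samples, values in \eqn{[0, 1]}, with an
#'   optional `"event_gene"` attribute.
#' @export
read_psi <- function(path, missing_tokens = c("", "NA")) {
  parsed <- read_tsv_matrix(path, missing_tokens, what = "PSI",
                            gene_col = "auto")
  m <- parsed$values
  bad <- which(is.finite(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("PSI file '%s': value %g outside [0, 1] at event '%s', sample '%s'",
                 path, m[bad[1L, 1L], bad[1L, 2L]],
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  }
  if (!is.null(parsed$event_gene)) attr(m, "event_gene") <- parsed$event_gene
  m
}

#' @keywords internal
#' @noRd
read_two_column <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  lineno <- which(keep)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop(sprintf("%s file '%s': line %d has %d field(s), expected 2",
                 what, path, lineno[i], nf[i]), call. = FALSE)
  }
  if (!length(fields)) {
    warning(sprintf("%s file '%s' is empty", what, path), call. = FALSE)
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(a = vapply(fields, `[`, "", 1L),
             b = vapply(fields, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Read a TF -> target pair list
#'
#' Two whitespace- or tab-separated identifier columns per line (TF, then
#' target); lines starting with `#` and blank lines are ignored. Duplicate
#' pairs collapse to one. Self-pairs (a TF listed as its own target) are kept
#' unless `drop_self = TRUE`.
#'
#' @param path Path to the pair file.
#' @param drop_self Drop pairs where TF and target are the same identifier.
#' @return A data frame with character columns `tf` and `target`, unique rows.
#' @export
read_pairs <- function(path, drop_self = FALSE) {
  df <- read_two_column(path, "TF-target pair")
  names(df) <- c("tf", "target")
  df <- unique(df)
  if (drop_self) df <- df[df$tf != df$target, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a protein-protein interaction edge list
#'
#' Two identifier columns per line; edges are unordered, so `(a, b)` and
#' `(b, a)` are the same edge and are stored once with the lexicographically
#' smaller protein first. Self-loops are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @return A data frame with character columns `protein1`, `protein2`
#'   (`protein1 <= protein2`), unique rows.
#' @export
read_ppi <- function(path) {
  df <- read_two_column(path, "PPI edge")
  self <- df$a == df$b
  if (any(self)) {
    warning(sprintf("dropping %d self-loop(s) from PPI edge list", sum(self)),
            call. = FALSE)
    df <- df[!self, , drop = FALSE]
  }
  out <- unique(data.frame(protein1 = pmin(df$a, df$b),
                           protein2 = pmax(df$a, df$b),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# Columns of a triplet-result table, with their storage types.
triplet_columns <- function() {
  c(tf = "character", target = "character", event = "character",
    event_gene = "character", status = "character", reason = "character",
    n = "integer",
    beta0 = "numeric", beta1 = "numeric", beta2 = "numeric",
    beta3 = "numeric", se3 = "numeric", t3 = "numeric", p3 = "numeric",
    q3 = "numeric", significant = "logical", sign = "character")
}

#' @keywords internal
#' @noRd
format_cell <- function(x) {
  out <- rep("NA", length(x))
  if (is.numeric(x) && !is.integer(x)) {
    ok <- !is.na(x)
    # %.17g survives a write/read round trip bit-exactly for finite doubles
    out[ok] <- sprintf("%.17g", x[ok])
  } else {
    ok <- !is.na(x)
    out[ok] <- as.character(x[ok])
  }
  out
}

#' @keywords internal
#' @noRd
write_tsv_typed <- function(df, path) {
  cells <- vapply(df, format_cell, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) apply(cells, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a triplet scan result table
#'
#' The TSV carries one row per attempted triplet with the fitted coefficients
#' (`beta0`..`beta3`), the interaction-term standard error, t statistic and
#' p-value (`se3`, `t3`, `p3`), the BH-adjusted `q3`, the significance call
#' and the `sign` of the interaction. Finite numeric values round-trip
#' bit-exactly; missing values are written as `NA`.
#'
#' @param results A triplet result data frame from [scan_all()] /
#'   [correct_fdr()].
#' @param path Output (or input) TSV path.
#' @return `write_triplets()` returns `path` invisibly; `read_triplets()`
#'   returns the typed data frame.
#' @export
write_triplets <- function(results, path) {
  cols <- triplet_columns()
  missing_cols <- setdiff(names(cols), names(results))
  for (nm in missing_cols) {
    results[[nm]] <- switch(cols[[nm]],
                            character = NA_character_,
                            integer = NA_integer_,
                            numeric = NA_real_,
                            logical = NA)
  }
  write_tsv_typed(results[names(cols)], path)
}

#' @rdname write_triplets
#' @export
read_triplets <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          na.strings = "NA", quote = "", comment.char = "")
  cols <- triplet_columns()
  missing_cols <- setdiff(names(cols), names(df))
  if (length(missing_cols))
    stop(sprintf("triplet file '%s': missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (nm in names(cols)) {
    df[[nm]] <- switch(cols[[nm]],
                       character = df[[nm]],
                       integer = as.integer(df[[nm]]),
                       numeric = as.numeric(df[[nm]]),
                       logical = as.logical(df[[nm]]))
  }
  df
}

#' Write a TF-modulator network edge table
#'
#' Plain edge-list TSV: one row per (TF, event) with the number of tested and
#' influenced targets, the split of influenced targets by interaction sign,
#' the influence percentage, and (when PPI filtering was applied) the
#' `ppi_supported` flag.
#'
#' @param edges Edge data frame from [summarize_edges()] or
#'   [threshold_network()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  cols <- c("tf", "event", "event_gene", "n_targets_tested", "n_influenced",
            "n_positive", "n_negative", "pct_influenced", "ppi_supported")
  keep <- intersect(cols, names(edges))
  write_tsv_typed(edges[keep], path)
}

#' Write an expression or PSI matrix as TSV
#'
#' Inverse of [read_expression()] / [read_psi()]: first column holds row
#' identifiers under `id_name`, then (for PSI matrices carrying an
#' `"event_gene"` attribute) a host-gene column, then one column per sample.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output TSV path.
#' @param id_name Header label for the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_name
  ev <- attr(m, "event_gene")
  if (!is.null(ev)) df$event_gene <- unname(ev[rownames(m)])
  vals <- as.data.frame(m, stringsAsFactors = FALSE)
  names(vals) <- colnames(m)
  write_tsv_typed(cbind(df, vals), path)
}
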
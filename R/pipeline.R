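#' Write a simulated dataset to a directory of TSV files
#'
#' Emits `expression.tsv`, `psi.tsv` (with host-gene column), `pairs.tsv`
#' and `truth.tsv` in the formats the readers of this package consume.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             psi = file.path(dir, "psi.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_matrix(sim$expression, paths[["expression"]], id_name = "gene_id")
  write_matrix(sim$psi, paths[["psi"]], id_name = "event_id")
  writeLines(paste(sim$pairs$tf, sim$pairs$target, sep = "\t"),
             paths[["pairs"]])
  write_tsv_typed(sim$truth, paths[["truth"]])
  invisible(paths)
}
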
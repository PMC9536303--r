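#' Registered target-prediction tool dialects
#'
#' Column layouts for the five supported miRNA-target prediction tool exports.
#' Extra columns in an export (scores, site counts) are ignored.
#'
#' @return Named list of descriptors with `mirna_col` and `gene_col`.
#' @export
target_tool_dialects <- function() {
  list(
    microt_cds = list(mirna_col = "mirna", gene_col = "gene_symbol"),
    targetscan = list(mirna_col = "miR",   gene_col = "Gene"),
    mirdb      = list(mirna_col = "miRNA", gene_col = "GeneSymbol"),
    pictar     = list(mirna_col = "mirna", gene_col = "gene"),
    miranda    = list(mirna_col = "mir",   gene_col = "target_gene"),
    synthetic  = list(mirna_col = "mirna", gene_col = "gene")
  )
}

#' Read per-tool miRNA-target prediction tables
#'
#' Reads one TSV per tool, deduplicates within each tool (a tool export listing
#' the same miRNA-gene pair twice contributes one vote), normalizes miRNA
#' names, and concatenates.
#'
#' @param paths Named character vector or list mapping tool identifier to file
#'   path. Tool identifiers must be unique and registered in `registry` (or
#'   share the `synthetic` two-column layout).
#' @param registry Tool dialect registry, default [target_tool_dialects()].
#' @param species_prefix Prefix for miRNA name normalization.
#' @return Tibble with columns `mirna`, `gene`, `tool`.
#' @export
read_target_predictions <- function(paths, registry = target_tool_dialects(),
                                    species_prefix = "hsa") {
  paths <- as.list(paths)
  if (is.null(names(paths)) || anyDuplicated(names(paths)) > 0 ||
      any(!nzchar(names(paths)))) {
    stop("paths must be uniquely named by tool identifier", call. = FALSE)
  }
  purrr::imap(paths, function(path, tool) {
    spec <- registry[[tool]]
    if (is.null(spec)) spec <- registry[["synthetic"]]
    raw <- readr::read_tsv(path,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    missing_cols <- setdiff(c(spec$mirna_col, spec$gene_col), names(raw))
    if (length(missing_cols) > 0) {
      stop("tool '", tool, "' file ", path, " lacks column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    if (nrow(raw) == 0) {
      return(tibble::tibble(mirna = character(), gene = character(),
                            tool = character()))
    }
    tibble::tibble(
      mirna = vapply(raw[[spec$mirna_col]], normalize_mirna_name,
                     character(1), species_prefix = species_prefix,
                     USE.NAMES = FALSE),
      gene = toupper(trimws(raw[[spec$gene_col]])),
      tool = tool
    ) |> dplyr::distinct()
  }) |> dplyr::bind_rows()
}

#' Consensus target map by distinct-tool vote counting
#'
#' A gene is retained as a target of a miRNA when at least `min_tools` distinct
#' tools predict the pair. Votes count distinct tools, never rows. With the
#' default five-tool panel and `min_tools = 4` this realizes the
#' "more than three tools" consensus rule.
#'
#' @param preds Tibble from [read_target_predictions()].
#' @param min_tools Minimum distinct-tool support (default 4).
#' @param n_tools_available Number of tools in the panel; defaults to the
#'   number of distinct tools observed in `preds`. `min_tools` may not exceed
#'   it.
#' @return A `consensus_targets` tibble with columns `mirna`, `gene`,
#'   `n_tools`, carrying the target sets as an attribute-free long table;
#'   use [target_sets()] to view it as miRNA -> gene-set mapping.
#' @export
consensus_targets <- function(preds, min_tools = 4, n_tools_available = NULL) {
  stopifnot(min_tools >= 1)
  if (is.null(n_tools_available)) {
    n_tools_available <- dplyr::n_distinct(preds$tool)
  }
  if (nrow(preds) > 0 && min_tools > n_tools_available) {
    stop("min_tools (", min_tools, ") exceeds the number of tools (",
         n_tools_available, ")", call. = FALSE)
  }
  out <- preds |>
    dplyr::distinct(.data$mirna, .data$gene, .data$tool) |>
    dplyr::count(.data$mirna, .data$gene, name = "n_tools") |>
    dplyr::filter(.data$n_tools >= min_tools) |>
    dplyr::arrange(.data$mirna, .data$gene)
  class(out) <- c("consensus_targets", class(out))
  attr(out, "min_tools") <- min_tools
  out
}

#' View a consensus map as miRNA -> gene-set mapping
#'
#' @param consensus A `consensus_targets` tibble.
#' @return Named list of sorted gene character vectors, one per miRNA.
#' @export
target_sets <- function(consensus) {
  split(consensus$gene, consensus$mirna) |> lapply(sort)
}
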
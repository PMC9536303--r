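#' Registered association-table dialects
#'
#' Each miRNA-disease association database exports a differently shaped table.
#' A dialect declares which columns carry the miRNA identifier and the raw
#' disease label; remaining columns are ignored. The `synthetic` dialect is the
#' canonical layout written by [simulate_association_world()].
#'
#' @return A named list of dialect descriptors, each with elements
#'   `mirna_col` and `disease_col`.
#' @export
#' @examples
#' names(association_dialects())
association_dialects <- function() {
  list(
    mir2disease = list(mirna_col = "miRNA_ID",  disease_col = "Disease"),
    mircancer   = list(mirna_col = "mirId",     disease_col = "Cancer"),
    dbdemc      = list(mirna_col = "miRNA",     disease_col = "CancerType"),
    hmdd        = list(mirna_col = "mir",       disease_col = "disease"),
    synthetic   = list(mirna_col = "mirna",     disease_col = "disease_term")
  )
}

#' Sentinel group label for unmapped disease terms
#' @export
UNMAPPED <- "UNMAPPED"

#' Read one miRNA-disease association table
#'
#' Reads a TSV export in one of the registered source dialects and returns a
#' tibble of raw association records. Disease terms are kept verbatim; the
#' `group` column is set to the [UNMAPPED] sentinel until [map_to_group()] is
#' applied. Rows with an empty miRNA or disease field, or whose miRNA name has
#' no recognizable miR/let token, are skipped with a warning naming the row.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect One of `names(association_dialects())`, or any name present
#'   in `registry`.
#' @param registry Dialect registry; defaults to [association_dialects()].
#'   Supply a modified list to register a custom export layout.
#' @param species_prefix Species prefix enforced on miRNA names ("hsa").
#' @return A tibble with columns `mirna`, `disease_term`, `group`, `source`.
#' @export
read_association_table <- function(path, dialect,
                                   registry = association_dialects(),
                                   species_prefix = "hsa") {
  if (!dialect %in% names(registry)) {
    stop("unknown association dialect: '", dialect, "' (registered: ",
         paste(names(registry), collapse = ", "), ")", call. = FALSE)
  }
  spec <- registry[[dialect]]
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(c(spec$mirna_col, spec$disease_col), names(raw))
  if (length(missing_cols) > 0) {
    stop("file ", path, " lacks column(s) ", paste(missing_cols, collapse = ", "),
         " required by dialect '", dialect, "'", call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(mirna = character(), disease_term = character(),
                          group = character(), source = character()))
  }
  mirna_raw <- raw[[spec$mirna_col]]
  disease <- raw[[spec$disease_col]]
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (is.na(mirna_raw[i]) || is.na(disease[i]) ||
        !nzchar(trimws(mirna_raw[i])) || !nzchar(trimws(disease[i]))) {
      warning("skipping malformed row ", i, " in ", path, call. = FALSE)
      next
    }
    canon <- tryCatch(normalize_mirna_name(mirna_raw[i], species_prefix),
                      error = function(e) NA_character_)
    if (is.na(canon)) {
      warning("skipping row ", i, " in ", path, ": unrecognizable miRNA name '",
              mirna_raw[i], "'", call. = FALSE)
      next
    }
    out[[i]] <- tibble::tibble(mirna = canon,
                               disease_term = trimws(disease[i]),
                               group = UNMAPPED,
                               source = dialect)
  }
  dplyr::bind_rows(out)
}

#' Normalize a miRNA name to canonical miRBase-style form
#'
#' Canonical form carries the species prefix (lower case), a "miR"-cased mature
#' token (or lower-case "let"/"mir" only where the family name itself is
#' lower case, i.e. let-7), and preserves arm suffixes (-5p/-3p) and precursor
#' indices verbatim. The function is idempotent on its own output.
#'
#' @param raw Raw miRNA label, e.g. `"hsa-mir-320a-3p"` or `"miR-34a"`.
#' @param species_prefix Prefix to prepend when absent (default "hsa").
#' @return Canonical name, e.g. `"hsa-miR-320a-3p"`.
#' @export
#' @examples
#' normalize_mirna_name("hsa-mir-320a-3p") # "hsa-miR-320a-3p"
#' normalize_mirna_name("miR-34a")         # "hsa-miR-34a"
normalize_mirna_name <- function(raw, species_prefix = "hsa") {
  stopifnot(is.character(raw), length(raw) == 1)
  s <- trimws(raw)
  if (!nzchar(s)) stop("empty miRNA name", call. = FALSE)
  low <- tolower(s)
  # recognize a mir/let token anywhere in the dash-separated name
  if (!stringr::str_detect(low, "(^|-)(mir|let)[-0-9]")) {
    stop("no recognizable miR/let token in '", raw, "'", call. = FALSE)
  }
  tokens <- stringr::str_split(low, "-")[[1]]
  # prepend species prefix when the first token is already the mir/let token
  if (tokens[1] %in% c("mir", "let")) {
    tokens <- c(tolower(species_prefix), tokens)
  }
  tokens[1] <- tolower(tokens[1])
  # mature names carry the miR casing; let- family names stay lower case
  tokens <- ifelse(tokens == "mir", "miR", tokens)
  paste(tokens, collapse = "-")
}

#' Load a disease-term to neoplasm-group mapping table
#'
#' The mapping is the curated assignment of raw disease labels to broader
#' neoplasm groups (ICD-11 terms rolled up to MeSH-style classes). Lookup keys
#' are normalized (lower case, punctuation and repeated whitespace collapsed),
#' so spelling variants that differ only in case or punctuation share a key.
#' A key mapping to more than one group is ambiguous: it is dropped with a
#' warning and later lookups return [UNMAPPED] for it.
#'
#' @param path TSV with columns `disease_term`, `group`.
#' @param groups Optional character vector restricting the group universe;
#'   rows whose group is outside it raise an error.
#' @return A `group_map` object (named character vector keyed by normalized
#'   term, with an `ambiguous` attribute listing dropped keys).
#' @export
read_group_map <- function(path, groups = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("disease_term", "group") %in% names(raw))) {
    stop("group map must have columns disease_term, group", call. = FALSE)
  }
  disease_group_map(stats::setNames(raw$group, raw$disease_term), groups = groups)
}

#' Build a disease-term to neoplasm-group map from a named vector
#'
#' @param x Named character vector: names are disease terms, values groups.
#' @param groups Optional allowed group universe.
#' @return A `group_map` object.
#' @export
disease_group_map <- function(x, groups = NULL) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (!is.null(groups)) {
    bad <- setdiff(unique(x), groups)
    if (length(bad) > 0) {
      stop("group(s) outside the configured universe: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  key <- normalize_disease_term(names(x))
  tab <- tibble::tibble(key = key, group = unname(x)) |>
    dplyr::distinct() |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_groups = dplyr::n_distinct(.data$group),
                     group = dplyr::first(.data$group), .groups = "drop")
  ambiguous <- tab$key[tab$n_groups > 1]
  if (length(ambiguous) > 0) {
    warning("dropping ambiguous disease term(s): ",
            paste(ambiguous, collapse = ", "), call. = FALSE)
  }
  tab <- tab[tab$n_groups == 1, ]
  out <- stats::setNames(tab$group, tab$key)
  attr(out, "ambiguous") <- ambiguous
  class(out) <- c("group_map", class(out))
  out
}

#' Normalize a disease term for map lookup
#'
#' Lower-cases, strips punctuation, and collapses whitespace so that labels
#' differing only in case or punctuation collide on one key.
#'
#' @param term Character vector of raw disease labels.
#' @return Character vector of normalized keys.
#' @export
normalize_disease_term <- function(term) {
  term |>
    tolower() |>
    stringr::str_replace_all("[[:punct:]]+", " ") |>
    stringr::str_squish()
}

#' Map a disease term to its neoplasm group
#'
#' Exact lookup on the normalized key; terms absent from the map (including
#' terms dropped as ambiguous) return the [UNMAPPED] sentinel. Groups are never
#' invented.
#'
#' @param disease_term Character vector of raw disease labels.
#' @param gmap A `group_map` object.
#' @return Character vector of group labels or [UNMAPPED].
#' @export
map_to_group <- function(disease_term, gmap) {
  stopifnot(inherits(gmap, "group_map"))
  key <- normalize_disease_term(disease_term)
  out <- unname(unclass(gmap)[key])
  out[is.na(out)] <- UNMAPPED
  out
}

#' Attach neoplasm groups to association records
#'
#' Applies [map_to_group()] to the `disease_term` column and drops records
#' whose term is unmapped or ambiguous (reported in a single warning), so that
#' no [UNMAPPED] record survives into downstream stages.
#'
#' @param records Tibble from [read_association_table()].
#' @param gmap A `group_map`.
#' @param drop_unmapped Drop unmapped rows (default TRUE).
#' @return Tibble with `group` filled in.
#' @export
assign_groups <- function(records, gmap, drop_unmapped = TRUE) {
  records$group <- map_to_group(records$disease_term, gmap)
  if (drop_unmapped) {
    n_bad <- sum(records$group == UNMAPPED)
    if (n_bad > 0) {
      warning("dropping ", n_bad, " record(s) with unmapped disease terms",
              call. = FALSE)
      records <- records[records$group != UNMAPPED, , drop = FALSE]
    }
  }
  records
}

#' Deduplicate miRNA-group associations
#'
#' Collapses records to unique (miRNA, group) pairs, merging the contributing
#' source databases into a sorted, semicolon-joined `sources` field. Output
#' ordering is deterministic: by group, then miRNA.
#'
#' @param records Tibble of mapped association records (no [UNMAPPED] rows).
#' @return Tibble with columns `mirna`, `group`, `sources`, `n_sources`.
#' @export
deduplicate_associations <- function(records) {
  stopifnot(all(c("mirna", "group") %in% names(records)),
            "source" %in% names(records) || "sources" %in% names(records))
  if (!"source" %in% names(records) && "sources" %in% names(records)) {
    # already deduplicated shape: re-split so the operation is idempotent
    records <- records |>
      dplyr::mutate(source = stringr::str_split(.data$sources, ";")) |>
      tidyr::unnest("source")
  }
  if (any(records$group == UNMAPPED)) {
    stop("deduplicate_associations() received UNMAPPED records; ",
         "run assign_groups() first", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$mirna, .data$group) |>
    dplyr::summarise(sources = paste(sort(unique(.data$source)), collapse = ";"),
                     .groups = "drop") |>
    dplyr::mutate(n_sources = stringr::str_count(.data$sources, ";") + 1L) |>
    dplyr::arrange(.data$group, .data$mirna)
}

#' Per-group association summary
#'
#' One row per neoplasm group with its distinct-miRNA count, plus a `Total`
#' row counting distinct miRNAs across all groups.
#'
#' @param records Deduplicated association tibble.
#' @return Tibble with columns `group`, `n_mirnas`.
#' @export
association_summary <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(group = character(), n_mirnas = integer()))
  }
  per_group <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_mirnas = dplyr::n_distinct(.data$mirna), .groups = "drop") |>
    dplyr::arrange(.data$group)
  dplyr::bind_rows(per_group,
                   tibble::tibble(group = "Total",
                                  n_mirnas = dplyr::n_distinct(records$mirna)))
}
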
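#' Assemble a pipeline configuration
#'
#' All stage knobs in one serializable list. Defaults follow the standard
#' settings of the workflow: consensus at four of five tools, similarity
#' cutoff 0.6, top-decile (90th percentile) pruning, modules of at least
#' three miRNAs, 999 permutation replicates at FDR 0.05.
#'
#' @param associations Named character vector: dialect -> association TSV path.
#' @param group_map Path to the disease-term -> group mapping TSV.
#' @param tools Named character vector: tool -> prediction TSV path (may be
#'   `NULL` when `edge_scores` is supplied).
#' @param obo,annotations Ontology and annotation paths (may be `NULL` when
#'   `edge_scores` is supplied).
#' @param edge_scores Optional path to a precomputed similarity score TSV
#'   (`mirna_a`, `mirna_b`, `weight`); when set, the GO-based similarity
#'   stage is skipped and these scores feed the symmetric source directly.
#' @param min_tools,sim_threshold,prune_percentile,min_module_size,n_perm,alpha
#'   Stage parameters (defaults 4, 0.6, 90, 3, 999, 0.05).
#' @param sim_method Term-similarity method for the symmetric source.
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(associations, group_map, tools = NULL,
                            obo = NULL, annotations = NULL, edge_scores = NULL,
                            min_tools = 4, sim_threshold = 0.6,
                            prune_percentile = 90, min_module_size = 3,
                            n_perm = 999, alpha = 0.05,
                            sim_method = "lin", seed = 1,
                            out_dir = "mirsignet_out") {
  cfg <- list(associations = associations, group_map = group_map,
              tools = tools, obo = obo, annotations = annotations,
              edge_scores = edge_scores, min_tools = min_tools,
              sim_threshold = sim_threshold,
              prune_percentile = prune_percentile,
              min_module_size = min_module_size, n_perm = n_perm,
              alpha = alpha, sim_method = sim_method, seed = seed,
              out_dir = out_dir)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

#' Run the full pipeline from files to reports
#'
#' Stages, in order: harmonize associations (read the four dialect tables,
#' normalize names, map disease terms to groups, drop unmapped, deduplicate);
#' consensus targets; miRNA-miRNA similarity (GO-based symmetric and
#' asymmetric sources, or precomputed scores); thresholded edge set; one
#' network per group, pruned to the top weight decile; topology reports;
#' signature-module selection. Every stage logs its record count and writes
#' its table under `out_dir`; a run manifest records the configuration, seed
#' and stage counts. An empty association input short-circuits with a warning
#' and empty outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (`associations`, `consensus`, `edges`, `networks`, `topology`,
#'   `modules`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[mirsignet] ", ...)
  manifest <- list(package_version = as.character(utils::packageVersion("mirsignet")),
                   r_version = as.character(getRversion()),
                   config = config[setdiff(names(config), "out_dir")],
                   counts = list(), partial = FALSE)
  finish <- function(result) {
    manifest$counts <- result$counts
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(result)
  }

  ## harmonize
  for (p in c(config$associations, config$group_map)) {
    if (!file.exists(p)) stop("stage harmonize: missing input ", p, call. = FALSE)
  }
  records <- purrr::imap(as.list(config$associations), function(path, dialect) {
    read_association_table(path, dialect)
  }) |> dplyr::bind_rows()
  gmap <- read_group_map(config$group_map)
  assoc <- if (nrow(records) > 0) {
    assign_groups(records, gmap) |> deduplicate_associations()
  } else {
    tibble::tibble(mirna = character(), group = character(),
                   sources = character(), n_sources = integer())
  }
  log_stage("harmonize: ", nrow(records), " raw rows -> ", nrow(assoc),
            " deduplicated (miRNA, group) pairs")
  readr::write_tsv(assoc, file.path(config$out_dir, "associations_dedup.tsv"),
                   progress = FALSE)
  readr::write_tsv(association_summary(assoc),
                   file.path(config$out_dir, "association_summary.tsv"),
                   progress = FALSE)
  counts <- list(raw_association_rows = nrow(records),
                 dedup_pairs = nrow(assoc))
  if (nrow(assoc) == 0) {
    warning("no mapped associations; downstream outputs are empty",
            call. = FALSE)
    manifest$partial <- TRUE
    empty_modules <- select_signature_modules_empty()
    readr::write_tsv(empty_modules, file.path(config$out_dir, "modules.tsv"),
                     progress = FALSE)
    return(finish(list(associations = assoc, consensus = NULL, edges = NULL,
                       networks = list(), topology = NULL,
                       modules = empty_modules, counts = counts)))
  }

  ## similarity sources
  mirnas <- sort(unique(assoc$mirna))
  consensus <- NULL
  if (!is.null(config$edge_scores)) {
    sym_scores <- readr::read_tsv(config$edge_scores,
                                  col_types = readr::cols(
                                    mirna_a = readr::col_character(),
                                    mirna_b = readr::col_character(),
                                    weight = readr::col_double()),
                                  progress = FALSE)
    asym_scores <- NULL
    log_stage("similarity: ", nrow(sym_scores), " precomputed scores loaded")
  } else {
    for (p in c(config$tools, config$obo, config$annotations)) {
      if (!file.exists(p)) stop("stage similarity: missing input ", p,
                                call. = FALSE)
    }
    preds <- read_target_predictions(config$tools)
    consensus <- consensus_targets(preds, min_tools = config$min_tools)
    log_stage("targets: ", nrow(preds), " predictions -> ", nrow(consensus),
              " consensus pairs (>= ", config$min_tools, " tools)")
    readr::write_tsv(consensus, file.path(config$out_dir, "consensus_targets.tsv"),
                     progress = FALSE)
    counts$consensus_pairs <- nrow(consensus)
    dag <- parse_obo(config$obo)
    corpus <- information_content(dag, read_annotations(config$annotations))
    tsets <- target_sets(consensus)
    tsets <- tsets[names(tsets) %in% mirnas]
    tsets <- lapply(tsets, intersect, names(corpus$gene_terms))
    tsets <- tsets[lengths(tsets) > 0]
    scored <- score_mirna_pairs(tsets, corpus, dag, method = config$sim_method)
    sym_scores <- scored$sym
    asym_scores <- scored$asym
    log_stage("similarity: ", length(tsets), " miRNAs with annotated ",
              "consensus targets, ", nrow(sym_scores), " scored pairs")
  }
  edges <- build_edge_set(sym_scores, asym_scores,
                          threshold = config$sim_threshold)
  log_stage("edges: ", nrow(edges), " pairs at threshold >= ",
            config$sim_threshold)
  readr::write_tsv(edges, file.path(config$out_dir, "similarity_edges.tsv"),
                   progress = FALSE)
  counts$edges <- nrow(edges)

  ## networks
  groups <- sort(unique(assoc$group))
  net_dir <- file.path(config$out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  networks <- stats::setNames(vector("list", length(groups)), groups)
  topology <- list()
  for (grp in groups) {
    raw_net <- build_neoplasm_network(grp, assoc, edges)
    pruned <- prune_top_decile(raw_net, percentile = config$prune_percentile)
    networks[[grp]] <- pruned
    slug <- gsub("[^A-Za-z0-9]+", "_", grp)
    write_network(raw_net, tsv_path = file.path(net_dir, paste0(slug, "_raw.tsv")))
    write_network(pruned,
                  tsv_path = file.path(net_dir, paste0(slug, "_pruned.tsv")),
                  graphml_path = file.path(net_dir, paste0(slug, "_pruned.graphml")))
    topology[[grp]] <- glance(pruned)
  }
  topology <- dplyr::bind_rows(topology)
  readr::write_tsv(topology, file.path(config$out_dir, "topology.tsv"),
                   progress = FALSE)
  log_stage("networks: ", length(groups), " groups, pruned at the ",
            config$prune_percentile, "th percentile")
  counts$groups <- length(groups)

  ## modules
  modules <- select_signature_modules(networks,
                                      min_size = config$min_module_size,
                                      alpha = config$alpha,
                                      n_perm = config$n_perm,
                                      seed = config$seed)
  log_stage("modules: ", nrow(modules), " mutually exclusive signature ",
            "module(s) at FDR <= ", config$alpha)
  readr::write_tsv(modules, file.path(config$out_dir, "modules.tsv"),
                   progress = FALSE)
  jsonlite::write_json(modules, file.path(config$out_dir, "modules.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  counts$modules <- nrow(modules)

  finish(list(associations = assoc, consensus = consensus, edges = edges,
              networks = networks, topology = topology, modules = modules,
              counts = counts))
}

select_signature_modules_empty <- function() {
  out <- tibble::tibble(group = character(), members = character(),
                        size = integer(), density = numeric(),
                        host_count = integer(), p_value = numeric(),
                        q_value = numeric())
  class(out) <- c("mirna_modules", class(out))
  out
}

#' Score all miRNA pairs by both similarity sources
#'
#' Computes the symmetric (best-match-average of gene similarities) and
#' asymmetric (significance-weighted closure-affinity) scores for every
#' unordered pair of miRNAs with annotated consensus targets, caching the
#' gene-gene similarity matrix and the term-affinity matrix across pairs.
#'
#' @param target_sets Named list: miRNA -> character vector of annotated
#'   target genes.
#' @param corpus,dag Annotation corpus and DAG.
#' @param method Term-similarity method for the symmetric source.
#' @return List of two tibbles `sym` and `asym` (`mirna_a`, `mirna_b`,
#'   `weight`).
#' @export
score_mirna_pairs <- function(target_sets, corpus, dag, method = "lin") {
  mirnas <- sort(names(target_sets))
  empty <- tibble::tibble(mirna_a = character(), mirna_b = character(),
                          weight = numeric())
  if (length(mirnas) < 2) return(list(sym = empty, asym = empty))
  genes <- unique(unlist(target_sets, use.names = FALSE))
  gcache <- gene_similarity_matrix(genes, corpus, dag, method)
  all_terms <- unique(unlist(corpus$gene_terms[genes], use.names = FALSE))
  all_terms <- all_terms[!is.na(corpus$ic[all_terms]) & corpus$ic[all_terms] > 0]
  acache <- term_affinity_matrix(dag, all_terms)
  pairs <- utils::combn(mirnas, 2)
  sym <- asym <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sym[i] <- gosemsim_mirna_similarity(target_sets[[a]], target_sets[[b]],
                                        corpus, dag, method,
                                        gene_sim_cache = gcache)
    asym[i] <- as.numeric(mirgofs_like_similarity(target_sets[[a]],
                                                  target_sets[[b]],
                                                  corpus, dag,
                                                  affinity_cache = acache))
  }
  list(sym = tibble::tibble(mirna_a = pairs[1, ], mirna_b = pairs[2, ],
                            weight = sym),
       asym = tibble::tibble(mirna_a = pairs[1, ], mirna_b = pairs[2, ],
                             weight = asym))
}

#' Load the bundled reference tables
#'
#' Two plain-text tables ship with the package: a per-group summary of a
#' published miRNA-neoplasm network compendium (30 neoplasm groups with
#' their distinct-miRNA and miRNA-pair counts) and the signature-module
#' listing reported for that compendium (17 neoplasm groups with
#' comma-separated module member lists). Both are validated structurally on
#' load; a malformed fixture is an error.
#'
#' @return List with `neoplasm_counts` (tibble `group`, `n_mirnas`,
#'   `n_pairs`) and `signature_modules` (tibble `group`, `members`, `size`).
#' @export
load_fixture_tables <- function() {
  counts_path <- system.file("extdata", "neoplasm_mirna_counts.tsv",
                             package = "mirsignet", mustWork = TRUE)
  modules_path <- system.file("extdata", "neoplasm_signature_modules.tsv",
                              package = "mirsignet", mustWork = TRUE)
  counts <- readr::read_tsv(counts_path,
                            col_types = readr::cols(
                              group = readr::col_character(),
                              n_mirnas = readr::col_integer(),
                              n_pairs = readr::col_integer()),
                            progress = FALSE)
  if (!identical(names(counts), c("group", "n_mirnas", "n_pairs")) ||
      anyNA(counts) || nrow(counts) == 0) {
    stop("neoplasm count fixture failed validation", call. = FALSE)
  }
  modules <- readr::read_tsv(modules_path,
                             col_types = readr::cols(
                               group = readr::col_character(),
                               members = readr::col_character()),
                             progress = FALSE)
  if (!identical(names(modules), c("group", "members")) || anyNA(modules) ||
      nrow(modules) == 0) {
    stop("signature module fixture failed validation", call. = FALSE)
  }
  modules$size <- lengths(strsplit(modules$members, ",\\s*"))
  list(neoplasm_counts = counts, signature_modules = modules)
}

#' Structural statistics of a signature-module table
#'
#' @param modules Tibble with `group` and comma-separated `members` (the
#'   `signature_modules` element of [load_fixture_tables()]).
#' @return One-row tibble: `n_modules`, `min_size`, `max_size`,
#'   `max_multiplicity` (the largest number of modules any single miRNA
#'   belongs to).
#' @export
module_table_stats <- function(modules) {
  member_lists <- strsplit(modules$members, ",\\s*")
  sizes <- lengths(member_lists)
  multiplicity <- table(unlist(member_lists, use.names = FALSE))
  tibble::tibble(n_modules = nrow(modules),
                 min_size = min(sizes), max_size = max(sizes),
                 max_multiplicity = as.integer(max(multiplicity)))
}
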
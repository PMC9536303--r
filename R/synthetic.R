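#' Simulate a layered GO-like ontology with gene annotations
#'
#' Builds one layered random DAG per namespace: a single root, then layers
#' whose width grows by `branching`, each non-root term drawing one or two
#' parents from the layer above (so the graph is acyclic by construction and
#' every term reaches its namespace root). Genes are annotated to random
#' leaf-layer terms; propagation to ancestors is left to
#' [information_content()], mirroring the real annotation flow.
#'
#' @param n_terms Terms per namespace (>= 3).
#' @param n_genes Number of genes (>= 2).
#' @param branching Layer growth factor (> 1); must allow at least two layers
#'   for the requested `n_terms`.
#' @param n_namespaces Number of namespaces, 1-3 (biological_process,
#'   molecular_function, cellular_component).
#' @param annotations_per_gene Mean number of direct annotations per gene.
#' @param seed Integer seed; fixed seed gives an identical world.
#' @return List with `dag` (a [go_dag]) and `gene_terms` (named list of
#'   direct annotations).
#' @export
simulate_ontology_world <- function(n_terms = 40, n_genes = 30, branching = 2,
                                    n_namespaces = 2, annotations_per_gene = 3,
                                    seed = 1) {
  stopifnot(n_terms >= 3, n_genes >= 2, n_namespaces %in% 1:3)
  if (branching <= 1) stop("branching must exceed 1", call. = FALSE)
  set.seed(seed)
  namespaces <- c("biological_process", "molecular_function",
                  "cellular_component")[seq_len(n_namespaces)]
  ids <- character(0); names_ <- character(0); nss <- character(0)
  parents <- list()
  leaf_terms <- list()
  counter <- 0
  for (nsp in namespaces) {
    sizes <- c(1)
    while (sum(sizes) < n_terms) {
      sizes <- c(sizes, min(ceiling(utils::tail(sizes, 1) * branching),
                            n_terms - sum(sizes)))
    }
    if (length(sizes) < 2) {
      stop("branching ", branching, " infeasible for ", n_terms, " terms",
           call. = FALSE)
    }
    layers <- list()
    for (li in seq_along(sizes)) {
      layer_ids <- sprintf("GO:%07d", counter + seq_len(sizes[li]))
      counter <- counter + sizes[li]
      layers[[li]] <- layer_ids
      ids <- c(ids, layer_ids)
      names_ <- c(names_, paste0("synthetic term ", layer_ids))
      nss <- c(nss, rep(nsp, sizes[li]))
      if (li == 1) next
      above <- layers[[li - 1]]
      for (t in layer_ids) {
        n_par <- sample(1:2, 1)
        parents[[t]] <- sample(above, min(n_par, length(above)))
      }
    }
    leaf_terms[[nsp]] <- layers[[length(layers)]]
  }
  dag <- go_dag(tibble::tibble(id = ids, name = names_, namespace = nss),
                parents)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  gene_terms <- stats::setNames(lapply(genes, function(g) {
    n_ann <- max(1, stats::rpois(1, annotations_per_gene))
    pool <- unlist(leaf_terms, use.names = FALSE)
    sample(pool, min(n_ann, length(pool)))
  }), genes)
  list(dag = dag, gene_terms = gene_terms)
}

#' Write a DAG as an OBO 1.2 file
#'
#' @param dag A [go_dag].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "ontology: synthetic", "")
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    lines <- c(lines, "[Term]",
               paste0("id: ", id),
               paste0("name: ", dag$terms$name[i]),
               paste0("namespace: ", dag$terms$namespace[i]),
               paste0("is_a: ", dag$parents[[id]],
                      " ! parent")[seq_along(dag$parents[[id]])],
               "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write gene annotations as a two-column TSV
#'
#' @param gene_terms Named list: gene -> character vector of term ids.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(gene_terms, path) {
  tbl <- tibble::tibble(
    gene = rep(names(gene_terms), lengths(gene_terms)),
    go_term = unlist(gene_terms, use.names = FALSE)
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Simulate per-tool target predictions with a planted consensus core
#'
#' Plants a consensus set of miRNA-gene pairs into at least `min_tools`
#' randomly chosen tools each, and a disjoint noise set into fewer than
#' `min_tools` tools each, so the vote-count filter provably separates the
#' two: recovery precision and recall are 1 by construction at any seed.
#'
#' @param mirnas,genes Character vectors of miRNA and gene identifiers.
#' @param n_tools Number of tools (>= `min_tools`).
#' @param consensus_rate,noise_rate Fractions in [0, 1] of the miRNA-gene
#'   grid planted as consensus / noise pairs.
#' @param min_tools Vote threshold the consensus must clear (default 4).
#' @param seed Integer seed.
#' @return List with `predictions` (tibble `mirna`, `gene`, `tool`) and
#'   `truth` (tibble `mirna`, `gene`, `planted`, `n_tools`).
#' @export
simulate_target_predictions <- function(mirnas, genes, n_tools = 5,
                                        consensus_rate = 0.05,
                                        noise_rate = 0.05, min_tools = 4,
                                        seed = 1) {
  stopifnot(n_tools >= min_tools, min_tools >= 2)
  if (consensus_rate < 0 || consensus_rate > 1 || noise_rate < 0 || noise_rate > 1) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  tools <- paste0("tool", seq_len(n_tools))
  grid <- tidyr::expand_grid(mirna = mirnas, gene = genes)
  n_total <- nrow(grid)
  n_consensus <- round(consensus_rate * n_total)
  n_noise <- round(noise_rate * n_total)
  idx <- sample(n_total, n_consensus + n_noise)
  consensus <- grid[idx[seq_len(n_consensus)], , drop = FALSE]
  noise <- grid[idx[n_consensus + seq_len(n_noise)], , drop = FALSE]
  plant <- function(pairs, votes_fn) {
    if (nrow(pairs) == 0) {
      return(tibble::tibble(mirna = character(), gene = character(),
                            tool = character(), n_tools = integer()))
    }
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      n_votes <- votes_fn()
      tibble::tibble(mirna = pairs$mirna[i], gene = pairs$gene[i],
                     tool = sample(tools, n_votes), n_tools = n_votes)
    })
  }
  cons_rows <- plant(consensus, function() sample(min_tools:n_tools, 1))
  noise_rows <- plant(noise, function() sample(seq_len(min_tools - 1), 1))
  predictions <- dplyr::bind_rows(cons_rows, noise_rows) |>
    dplyr::select("mirna", "gene", "tool") |>
    dplyr::arrange(.data$mirna, .data$gene, .data$tool)
  truth <- dplyr::bind_rows(
    dplyr::distinct(cons_rows, .data$mirna, .data$gene, .data$n_tools) |>
      dplyr::mutate(planted = "consensus"),
    dplyr::distinct(noise_rows, .data$mirna, .data$gene, .data$n_tools) |>
      dplyr::mutate(planted = "noise")
  ) |> dplyr::select("mirna", "gene", "planted", "n_tools")
  list(predictions = predictions, truth = truth)
}

#' Simulate a multi-group association world with planted exclusive modules
#'
#' Generates the tabular inputs the analysis consumes, with known truth.
#' Each neoplasm group receives one planted module of exclusive miRNAs whose
#' pairwise similarities are drawn above every other weight in that group's
#' context (so the module survives top-decile pruning as a clique); a pool of
#' background miRNAs is shared across random subsets of groups with mid-range
#' similarities passing the edge threshold; per-group filler miRNAs carry only
#' sub-threshold similarity and drop out of the pruned networks. Similarity is
#' planted directly as scores — the ontology world exercises the GO-based
#' similarity path separately, which keeps the module-recovery test sharp.
#' Association rows are spread over the four source dialects with injected
#' cross-source duplicates so deduplication is always exercised.
#'
#' @param n_groups Number of neoplasm groups (default 10).
#' @param group_size miRNAs per group (default 60; must fit module +
#'   background + at least one filler).
#' @param n_background Size of the shared background pool (default 30).
#' @param planted_module_sizes Sizes cycled over groups (default 3:6; all
#'   >= 3). Use `integer(0)` for a null world with no planted modules.
#' @param background_membership Probability a background miRNA joins a given
#'   group (default 1: the background is fully shared, mirroring the
#'   ubiquitously associated miRNAs observed across neoplasm groups; values
#'   below 1 are a sensitivity knob and force membership in at least 2
#'   groups).
#' @param similarity_profile List of weight ranges: `module` (default
#'   c(0.95, 1)), `background` (default c(0.6, 0.9)), `filler` (default
#'   c(0.2, 0.5), below the 0.6 edge threshold).
#' @param duplicate_rate Fraction of association rows re-emitted through a
#'   second source dialect (default 0.15).
#' @param seed Integer seed.
#' @return List with `associations` (named list of four dialect tibbles in
#'   their dialect column layouts), `group_map` (tibble `disease_term`,
#'   `group`), `sym_scores` (tibble `mirna_a`, `mirna_b`, `weight`),
#'   `truth` (planted modules, background set, association pairs, config).
#' @export
simulate_association_world <- function(n_groups = 10, group_size = 60,
                                       n_background = 30,
                                       planted_module_sizes = 3:6,
                                       background_membership = 1,
                                       similarity_profile = list(
                                         module = c(0.95, 1),
                                         background = c(0.6, 0.9),
                                         filler = c(0.2, 0.5)),
                                       duplicate_rate = 0.15, seed = 1) {
  stopifnot(n_groups >= 2, n_background >= 3)
  if (length(planted_module_sizes) > 0) {
    stopifnot(all(planted_module_sizes >= 3),
              group_size >= max(planted_module_sizes) + 3)
  }
  if (length(planted_module_sizes) > 0) {
    # every planted clique must fit strictly inside its network's top weight
    # decile: the module's edge count may not exceed the number of edges the
    # nearest-rank pruning retains
    e_bg <- choose(n_background, 2)
    for (s in planted_module_sizes) {
      e_mod <- choose(s, 2)
      retained <- (e_bg + e_mod) - ceiling(0.9 * (e_bg + e_mod))
      if (e_mod > retained) {
        stop("inconsistent sizes: a planted module of size ", s, " (", e_mod,
             " edges) cannot clear the top-decile cutoff over a background of ",
             n_background, " miRNAs (", retained, " edges retained)",
             call. = FALSE)
      }
    }
  }
  set.seed(seed)
  groups <- sprintf("Group%02d", seq_len(n_groups))
  background <- sprintf("hsa-miR-bg%03d", seq_len(n_background))

  # background membership: each background miRNA joins >= 2 random groups
  bg_member <- matrix(stats::runif(n_background * n_groups) < background_membership,
                      nrow = n_background,
                      dimnames = list(background, groups))
  for (i in seq_len(n_background)) {
    if (sum(bg_member[i, ]) < 2) {
      bg_member[i, sample(n_groups, 2)] <- TRUE
    }
  }

  planted <- list()
  memberships <- list()
  filler_all <- character(0)
  sizes <- planted_module_sizes
  for (gi in seq_len(n_groups)) {
    grp <- groups[gi]
    mod <- character(0)
    if (length(sizes) > 0) {
      s <- sizes[((gi - 1) %% length(sizes)) + 1]
      mod <- sprintf("hsa-miR-g%02dm%02d", gi, seq_len(s))
      planted[[grp]] <- sort(mod)
    }
    bg <- background[bg_member[, gi]]
    n_filler <- max(1, group_size - length(mod) - length(bg))
    filler <- sprintf("hsa-miR-g%02df%02d", gi, seq_len(n_filler))
    filler_all <- c(filler_all, filler)
    memberships[[grp]] <- c(mod, bg, filler)
  }

  # planted similarity scores (symmetric source)
  rng <- function(range, n) stats::runif(n, range[1], range[2])
  pair_rows <- function(members, range) {
    if (length(members) < 2) {
      return(tibble::tibble(mirna_a = character(), mirna_b = character(),
                            weight = numeric()))
    }
    pr <- t(utils::combn(sort(members), 2))
    tibble::tibble(mirna_a = pr[, 1], mirna_b = pr[, 2],
                   weight = rng(range, nrow(pr)))
  }
  score_rows <- list(pair_rows(background, similarity_profile$background))
  for (grp in names(planted)) {
    score_rows[[length(score_rows) + 1]] <-
      pair_rows(planted[[grp]], similarity_profile$module)
  }
  # sub-threshold filler edges: each filler miRNA gets a few weak links
  for (gi in seq_len(n_groups)) {
    grp <- groups[gi]
    members <- memberships[[grp]]
    filler <- grep("f[0-9]+$", members, value = TRUE)
    if (length(filler) == 0) next
    partners <- sample(members, min(3 * length(filler), length(members)),
                       replace = TRUE)
    fl <- sample(filler, length(partners), replace = TRUE)
    keep <- fl != partners
    score_rows[[length(score_rows) + 1]] <- tibble::tibble(
      mirna_a = pmin(fl[keep], partners[keep]),
      mirna_b = pmax(fl[keep], partners[keep]),
      weight = rng(similarity_profile$filler, sum(keep))
    )
  }
  sym_scores <- dplyr::bind_rows(score_rows) |>
    dplyr::group_by(.data$mirna_a, .data$mirna_b) |>
    dplyr::summarise(weight = max(.data$weight), .groups = "drop")

  # association rows: 2 disease-term spelling variants per group
  gmap <- tibble::tibble(
    disease_term = c(paste0(tolower(groups), " carcinoma"),
                     paste0(toupper(groups), " NEOPLASM")),
    group = rep(groups, 2)
  )
  assoc <- purrr::map_dfr(groups, function(grp) {
    terms <- gmap$disease_term[gmap$group == grp]
    tibble::tibble(mirna = memberships[[grp]],
                   disease_term = sample(terms, length(memberships[[grp]]),
                                         replace = TRUE),
                   group = grp)
  })
  dialects <- c("mir2disease", "mircancer", "dbdemc", "hmdd")
  assoc$source <- sample(dialects, nrow(assoc), replace = TRUE)
  dup_idx <- sample(nrow(assoc), round(duplicate_rate * nrow(assoc)))
  dups <- assoc[dup_idx, , drop = FALSE]
  dups$source <- vapply(dups$source, function(s) sample(setdiff(dialects, s), 1),
                        character(1))
  assoc_all <- dplyr::bind_rows(assoc, dups)

  reg <- association_dialects()
  assoc_tables <- stats::setNames(lapply(dialects, function(d) {
    rows <- assoc_all[assoc_all$source == d, , drop = FALSE]
    out <- tibble::tibble(rows$mirna, rows$disease_term)
    names(out) <- c(reg[[d]]$mirna_col, reg[[d]]$disease_col)
    out
  }), dialects)

  truth <- list(
    planted_modules = planted,
    background_mirnas = background,
    association_pairs = dplyr::distinct(assoc, .data$mirna, .data$group),
    generator_config = list(n_groups = n_groups, group_size = group_size,
                            n_background = n_background,
                            planted_module_sizes = planted_module_sizes,
                            background_membership = background_membership,
                            similarity_profile = similarity_profile,
                            duplicate_rate = duplicate_rate, seed = seed)
  )
  list(associations = assoc_tables, group_map = gmap,
       sym_scores = sym_scores, truth = truth)
}

#' Write a simulated association world to a directory
#'
#' Emits the four dialect association TSVs, the group map, the planted
#' similarity scores, and the truth as JSON (round-trips losslessly via
#' [read_truth()]).
#'
#' @param world Output of [simulate_association_world()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_association_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(world$associations)) {
    readr::write_tsv(world$associations[[d]], file.path(dir, paste0(d, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(world$group_map, file.path(dir, "group_map.tsv"),
                   progress = FALSE)
  readr::write_tsv(world$sym_scores, file.path(dir, "similarity_scores.tsv"),
                   progress = FALSE)
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a serialized synthetic truth
#'
#' @param path Path to `truth.json` written by [write_association_world()].
#' @return The truth list with planted modules as named list of sorted
#'   character vectors.
#' @export
read_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$planted_modules <- lapply(truth$planted_modules, sort)
  truth$association_pairs <- tibble::as_tibble(truth$association_pairs)
  truth
}

#' Run the analysis pipeline on an in-memory association world
#'
#' Convenience harness used by the recovery tests: harmonizes the four
#' dialect tables, builds the thresholded edge set from the planted scores,
#' constructs and prunes one network per group, and selects signature
#' modules.
#'
#' @param world Output of [simulate_association_world()].
#' @param threshold,percentile,min_size,alpha,n_perm,seed Pipeline knobs with
#'   the standard defaults (0.6, 90, 3, 0.05, 999).
#' @return List with `associations` (deduplicated), `networks` (pruned),
#'   `modules` (a `mirna_modules` tibble).
#' @export
run_association_world <- function(world, threshold = 0.6, percentile = 90,
                                  min_size = 3, alpha = 0.05, n_perm = 999,
                                  seed = 1) {
  reg <- association_dialects()
  records <- purrr::imap(world$associations, function(tbl, dialect) {
    spec <- reg[[dialect]]
    tibble::tibble(mirna = tbl[[spec$mirna_col]],
                   disease_term = tbl[[spec$disease_col]],
                   group = UNMAPPED, source = dialect)
  }) |> dplyr::bind_rows()
  gmap <- disease_group_map(stats::setNames(world$group_map$group,
                                    world$group_map$disease_term))
  assoc <- records |>
    assign_groups(gmap) |>
    deduplicate_associations()
  edges <- build_edge_set(sym_scores = world$sym_scores, threshold = threshold)
  groups <- sort(unique(assoc$group))
  networks <- stats::setNames(lapply(groups, function(grp) {
    prune_top_decile(build_neoplasm_network(grp, assoc, edges),
                     percentile = percentile)
  }), groups)
  modules <- select_signature_modules(networks, min_size = min_size,
                                      alpha = alpha, n_perm = n_perm,
                                      seed = seed)
  list(associations = assoc, networks = networks, modules = modules)
}

#' Precision and recall of recovered modules against planted truth
#'
#' A planted module counts as recovered when it is reported for its own group
#' with exactly its member set; a reported module is a true positive under
#' the same identity. Groups with no planted module contribute only potential
#' false positives.
#'
#' @param modules A `mirna_modules` tibble.
#' @param planted Named list: group -> sorted character vector (truth).
#' @return Tibble with `precision`, `recall`, `n_reported`, `n_planted`.
#' @export
module_recovery <- function(modules, planted) {
  truth_keys <- vapply(names(planted), function(grp) {
    paste(grp, paste(planted[[grp]], collapse = ";"), sep = "|")
  }, character(1))
  found_keys <- paste(modules$group, modules$members, sep = "|")
  tp <- sum(found_keys %in% truth_keys)
  tibble::tibble(
    precision = if (length(found_keys) == 0) NA_real_ else tp / length(found_keys),
    recall = if (length(truth_keys) == 0) NA_real_ else tp / length(truth_keys),
    n_reported = length(found_keys), n_planted = length(truth_keys)
  )
}
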
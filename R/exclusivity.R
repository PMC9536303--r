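#' Group-unique miRNAs across a network collection
#'
#' A miRNA is unique to a group when it occurs in that group's node set and in
#' no other network of the collection.
#'
#' @param networks Named list of `neoplasm_network` objects (names = groups).
#' @return Named list: group -> character vector of unique miRNAs (possibly
#'   empty).
#' @export
unique_mirnas <- function(networks) {
  stopifnot(length(networks) >= 1)
  membership <- table(unlist(lapply(networks, function(n) unique(n$nodes)),
                             use.names = FALSE))
  singles <- names(membership)[membership == 1]
  lapply(networks, function(n) sort(intersect(n$nodes, singles)))
}

#' Enumerate candidate modules as maximal cliques
#'
#' Candidate signature modules of a pruned network are its maximal cliques of
#' at least `min_size` miRNAs: sets of miRNAs that are all pairwise connected
#' and cannot be extended — density and maximality realized deterministically.
#' Output is deterministic: members sorted within each clique, cliques sorted
#' by size (descending) then lexicographically.
#'
#' @param net A pruned `neoplasm_network`.
#' @param min_size Minimum module size, default 3 (a lone miRNA pair is not a
#'   module).
#' @return List of sorted character vectors.
#' @export
enumerate_candidate_modules <- function(net, min_size = 3) {
  stopifnot(inherits(net, "neoplasm_network"), min_size >= 3)
  if (!net$pruned) stop("candidate modules are enumerated on pruned networks",
                        call. = FALSE)
  if (length(net$nodes) == 0) return(list())
  g <- as_igraph(net)
  cliques <- igraph::max_cliques(g, min = min_size)
  members <- lapply(cliques, function(cl) sort(igraph::V(g)$name[cl]))
  key <- vapply(members, paste, character(1), collapse = ";")
  members[order(-lengths(members), key)]
}

# edge-key lookup set of a network (sorted endpoint pairs)
edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  paste(pmin(net$edges$mirna_a, net$edges$mirna_b),
        pmax(net$edges$mirna_a, net$edges$mirna_b), sep = "\r")
}

# is `members` a clique of the network given its precomputed key set?
is_clique_in <- function(members, nodes, keys) {
  if (!all(members %in% nodes)) return(FALSE)
  pairs <- utils::combn(sort(members), 2)
  all(paste(pairs[1, ], pairs[2, ], sep = "\r") %in% keys)
}

#' Count the networks hosting a module as a clique
#'
#' Membership of all miRNAs in a network is necessary but not sufficient: the
#' census requires every member pair to be an edge. Exclusivity is the
#' set-level property `host_count == 1`; individual member miRNAs may well
#' occur — and belong to modules — in several groups.
#'
#' @param module Character vector of at least 3 miRNAs.
#' @param networks Named list of `neoplasm_network` objects.
#' @return Integer host count.
#' @export
exclusivity_census <- function(module, networks) {
  stopifnot(length(module) >= 3)
  sum(vapply(networks, function(net) {
    is_clique_in(module, net$nodes, edge_keys(net))
  }, logical(1)))
}

# degree-preserving rewiring of one network (10*E double-edge-swap attempts);
# uses the session RNG, so callers seed for determinism
rewire_network <- function(net, swap_factor = 10) {
  e <- nrow(net$edges)
  if (e < 2) return(net)
  g <- as_igraph(net)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = swap_factor * e))
  el <- igraph::as_edgelist(g2)
  edges <- tibble::tibble(mirna_a = pmin(el[, 1], el[, 2]),
                          mirna_b = pmax(el[, 1], el[, 2]),
                          w_combined = net$edges$w_combined)
  new_neoplasm_network(net$group, net$nodes, edges, pruned = net$pruned,
                       cutoff = net$cutoff)
}

#' Permutation significance of a module's mutual exclusivity
#'
#' Under the null, every network other than the module's host is replaced by a
#' degree-preserving rewiring (double-edge swaps, `10 * E` attempts). The
#' p-value is the add-one fraction of replicates in which the module occurs as
#' a clique in at least one rewired non-host network:
#' `p = (1 + hits) / (n_perm + 1)`. Networks that do not contain all module
#' members as nodes can never host the clique (rewiring preserves the node
#' set), so replicates are only simulated for networks where all members are
#' present.
#'
#' @param module Character vector of at least 3 miRNAs, exclusive in the
#'   observed collection.
#' @param networks Named list of pruned `neoplasm_network` objects.
#' @param n_perm Number of permutation replicates, default 999.
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return p-value in (0, 1].
#' @export
permutation_significance <- function(module, networks, n_perm = 999, seed = 1) {
  stopifnot(n_perm >= 1)
  hosts <- vapply(networks, function(net) {
    is_clique_in(module, net$nodes, edge_keys(net))
  }, logical(1))
  if (sum(hosts) != 1) {
    stop("module is hosted by ", sum(hosts),
         " networks; permutation significance applies to exclusive modules",
         call. = FALSE)
  }
  # only non-host networks containing every member can ever host the clique
  eligible <- networks[!hosts]
  eligible <- eligible[vapply(eligible, function(net) all(module %in% net$nodes),
                              logical(1))]
  if (length(eligible) == 0) return(1 / (n_perm + 1))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    appeared <- FALSE
    for (net in eligible) {
      rn <- rewire_network(net)
      if (is_clique_in(module, rn$nodes, edge_keys(rn))) { appeared <- TRUE; break }
    }
    if (appeared) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

# internal edge fraction of a member set within a network
module_density <- function(members, net) {
  keys <- edge_keys(net)
  pairs <- utils::combn(sort(members), 2)
  mean(paste(pairs[1, ], pairs[2, ], sep = "\r") %in% keys)
}

#' Select mutually exclusive signature modules across a network collection
#'
#' The full selection procedure: enumerate maximal-clique candidates of at
#' least `min_size` miRNAs in every pruned network, keep those hosted as a
#' clique by exactly one network of the collection, attach degree-preserving
#' permutation p-values, apply Benjamini-Hochberg correction across all kept
#' candidates, report candidates with `q <= alpha`, drop any reported module
#' nested inside another reported module of the same group, and rank by
#' (q ascending, density descending, size descending).
#'
#' Permutation replicates are shared: in each replicate every network is
#' rewired once and all candidates are scored against the same rewired
#' collection, which keeps the procedure identical to per-module
#' [permutation_significance()] in distribution while doing the rewiring work
#' once.
#'
#' @param networks Named list of pruned `neoplasm_network` objects.
#' @param min_size Minimum module size (default 3).
#' @param alpha FDR level on BH-adjusted q-values (default 0.05).
#' @param n_perm Permutation replicates (default 999).
#' @param seed Integer seed for the permutation null.
#' @param unique_filter If `TRUE`, only candidates containing at least one
#'   group-unique miRNA are considered (off by default).
#' @return A `mirna_modules` tibble: `group`, `members` (semicolon-joined,
#'   sorted), `size`, `density`, `host_count`, `p_value`, `q_value`.
#' @export
select_signature_modules <- function(networks, min_size = 3, alpha = 0.05,
                                     n_perm = 999, seed = 1,
                                     unique_filter = FALSE) {
  stopifnot(length(networks) >= 1, !is.null(names(networks)))
  empty <- tibble::tibble(group = character(), members = character(),
                          size = integer(), density = numeric(),
                          host_count = integer(), p_value = numeric(),
                          q_value = numeric())
  class(empty) <- c("mirna_modules", class(empty))

  uniq <- if (unique_filter) unique_mirnas(networks) else NULL
  cand <- list()
  for (grp in names(networks)) {
    mods <- enumerate_candidate_modules(networks[[grp]], min_size = min_size)
    if (unique_filter) {
      mods <- mods[vapply(mods, function(m) length(intersect(m, uniq[[grp]])) > 0,
                          logical(1))]
    }
    for (m in mods) cand[[length(cand) + 1]] <- list(group = grp, members = m)
  }
  if (length(cand) == 0) {
    message("no candidate modules of size >= ", min_size, " in any network")
    return(empty)
  }

  node_sets <- lapply(networks, function(n) n$nodes)
  key_sets <- lapply(networks, edge_keys)
  host_counts <- vapply(cand, function(cd) {
    sum(vapply(names(networks), function(grp) {
      is_clique_in(cd$members, node_sets[[grp]], key_sets[[grp]])
    }, logical(1)))
  }, integer(1))
  cand <- cand[host_counts == 1]
  if (length(cand) == 0) {
    message("no mutually exclusive candidate modules")
    return(empty)
  }

  # shared permutation replicates: rewire each network once per replicate
  # and score every candidate against the same rewired collection. Candidates
  # whose members never co-occur in a non-host network keep the floor p-value
  # without simulation (rewiring preserves node sets).
  eligible_of <- lapply(cand, function(cd) {
    others <- setdiff(names(networks), cd$group)
    others[vapply(others, function(grp) all(cd$members %in% node_sets[[grp]]),
                  logical(1))]
  })
  needs_sim <- lengths(eligible_of) > 0
  hits <- integer(length(cand))
  if (any(needs_sim)) {
    sim_groups <- unique(unlist(eligible_of))
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      rewired_keys <- lapply(networks[sim_groups], function(net) {
        edge_keys(rewire_network(net))
      })
      for (i in which(needs_sim)) {
        appeared <- any(vapply(eligible_of[[i]], function(grp) {
          is_clique_in(cand[[i]]$members, node_sets[[grp]], rewired_keys[[grp]])
        }, logical(1)))
        if (appeared) hits[i] <- hits[i] + 1L
      }
    }
  }
  p <- (1 + hits) / (n_perm + 1)
  q <- stats::p.adjust(p, method = "BH")

  out <- tibble::tibble(
    group = vapply(cand, `[[`, character(1), "group"),
    members = vapply(cand, function(cd) paste(cd$members, collapse = ";"),
                     character(1)),
    size = vapply(cand, function(cd) length(cd$members), integer(1)),
    density = vapply(seq_along(cand), function(i) {
      module_density(cand[[i]]$members, networks[[cand[[i]]$group]])
    }, numeric(1)),
    host_count = 1L, p_value = p, q_value = q
  ) |>
    dplyr::filter(.data$q_value <= alpha)

  if (nrow(out) == 0) {
    message("no modules pass FDR <= ", alpha)
    return(empty)
  }

  # drop modules nested in a larger reported module of the same group
  keep <- rep(TRUE, nrow(out))
  sets <- strsplit(out$members, ";")
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j && keep[j] && out$group[i] == out$group[j] &&
          length(sets[[i]]) < length(sets[[j]]) &&
          all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE] |>
    dplyr::arrange(.data$q_value, dplyr::desc(.data$density),
                   dplyr::desc(.data$size), .data$group, .data$members)
  class(out) <- c("mirna_modules", class(out))
  out
}

#' @export
glance.mirna_modules <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x),
                 n_groups = dplyr::n_distinct(x$group),
                 min_size = if (nrow(x)) min(x$size) else NA_integer_,
                 max_size = if (nrow(x)) max(x$size) else NA_integer_,
                 min_q = if (nrow(x)) min(x$q_value) else NA_real_)
}

#' Plot reported module sizes per group
#'
#' @param modules A `mirna_modules` tibble.
#' @return A ggplot bar chart of module sizes by group.
#' @export
plot_module_sizes <- function(modules) {
  ggplot2::ggplot(modules,
                  ggplot2::aes(x = stats::reorder(.data$group, .data$size),
                               y = .data$size)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "module size (miRNAs)",
                  title = "Signature module sizes per neoplasm group") +
    ggplot2::theme_minimal()
}
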
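#' Construct the miRNA similarity network of one neoplasm group
#'
#' Nodes are the miRNAs associated with the group; edges are the globally
#' computed similarity edges restricted to those nodes. Edges are computed
#' once across the whole miRNA universe and shared by all group networks, so
#' a miRNA pair carries the same weight wherever both members occur.
#'
#' @param group Neoplasm-group label; must occur in `associations$group`.
#' @param associations Deduplicated association tibble
#'   ([deduplicate_associations()]).
#' @param edges Global edge tibble from [build_edge_set()].
#' @return A `neoplasm_network` object.
#' @export
build_neoplasm_network <- function(group, associations, edges) {
  if (!group %in% associations$group) {
    stop("unknown neoplasm group: ", group, call. = FALSE)
  }
  nodes <- sort(unique(associations$mirna[associations$group == group]))
  sub <- edges |>
    dplyr::filter(.data$mirna_a %in% nodes & .data$mirna_b %in% nodes)
  new_neoplasm_network(group, nodes, sub, pruned = FALSE)
}

new_neoplasm_network <- function(group, nodes, edges, pruned, cutoff = NA_real_) {
  structure(list(group = group, nodes = nodes,
                 edges = tibble::as_tibble(edges),
                 pruned = pruned, cutoff = cutoff),
            class = "neoplasm_network")
}

#' @export
print.neoplasm_network <- function(x, ...) {
  cat("<neoplasm_network> group '", x$group, "': ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges",
      if (x$pruned) sprintf(" (pruned, cutoff %.4g)", x$cutoff) else "",
      "\n", sep = "")
  invisible(x)
}

#' Convert a neoplasm network to an igraph graph
#'
#' @param net A `neoplasm_network`.
#' @return An undirected weighted igraph object (weight = `w_combined`).
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "neoplasm_network"))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna_a", "mirna_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  igraph::E(g)$weight <- net$edges$w_combined
  g
}

#' Nearest-rank percentile pruning to the top weight decile
#'
#' The cutoff is the nearest-rank percentile of the combined edge weights:
#' the value at rank `ceiling(percentile/100 * E)` of the ascending sort.
#' Only edges with weight strictly above the cutoff survive (ties at the
#' cutoff are all dropped, which keeps the rule deterministic and
#' order-independent); nodes left without any edge are removed. With E
#' distinct weights this retains exactly `E - ceiling(percentile/100 * E)`
#' edges — e.g. 2,415 distinct-weight edges pruned at the 90th percentile
#' leave 241.
#'
#' @param net An unpruned `neoplasm_network`.
#' @param percentile Percentile in (0, 100), default 90.
#' @param weight_col Edge column to prune on, default `"w_combined"`.
#' @return The pruned `neoplasm_network` (flag set, cutoff recorded).
#' @export
prune_top_decile <- function(net, percentile = 90, weight_col = "w_combined") {
  stopifnot(inherits(net, "neoplasm_network"))
  if (net$pruned) stop("network for group '", net$group,
                       "' is already pruned", call. = FALSE)
  stopifnot(percentile > 0, percentile < 100)
  w <- net$edges[[weight_col]]
  if (length(w) == 0) {
    return(new_neoplasm_network(net$group, character(0), net$edges,
                                pruned = TRUE))
  }
  cutoff <- sort(w)[ceiling(percentile / 100 * length(w))]
  kept <- net$edges[w > cutoff, , drop = FALSE]
  nodes <- sort(unique(c(kept$mirna_a, kept$mirna_b)))
  new_neoplasm_network(net$group, nodes, kept, pruned = TRUE, cutoff = cutoff)
}

#' Local clustering coefficients and their average
#'
#' Local coefficient of a node = 2 * triangles / (deg * (deg - 1)); nodes of
#' degree < 2 score 0. The network average is the mean over all nodes (0 with
#' a warning for an empty network).
#'
#' @param net A `neoplasm_network`.
#' @return List with `per_node` (tibble `mirna`, `clustering`) and `average`.
#' @export
clustering_coefficients <- function(net) {
  if (length(net$nodes) == 0) {
    warning("empty network: average clustering reported as 0", call. = FALSE)
    return(list(per_node = tibble::tibble(mirna = character(),
                                          clustering = numeric()),
                average = 0))
  }
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  per_node <- tibble::tibble(mirna = igraph::V(g)$name, clustering = cc) |>
    dplyr::arrange(.data$mirna)
  list(per_node = per_node, average = mean(cc))
}

#' Degree-distribution topology report
#'
#' Summarizes a network's degree structure: histogram, dispersion index
#' (variance/mean of degrees; 1 under a Poisson law, 0 for a regular graph,
#' far above 1 for hub-dominated graphs) and a chi-square goodness-of-fit
#' p-value against Poisson(mean degree), with adjacent bins pooled until every
#' expected count is at least 5. A report with fewer than three pooled bins
#' has no testable fit and carries `poisson_gof_p = NA`.
#'
#' @param net A `neoplasm_network` with at least 2 nodes.
#' @return A one-row `topology_report` tibble: `group`, `n_nodes`, `n_edges`,
#'   `avg_clustering`, `dispersion_index`, `poisson_gof_p`, and
#'   `degree_histogram` (list column: named count vector, degree -> count).
#' @export
degree_distribution_fit <- function(net) {
  stopifnot(inherits(net, "neoplasm_network"))
  if (length(net$nodes) < 2) stop("need at least 2 nodes", call. = FALSE)
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  n <- length(deg)
  mean_deg <- mean(deg)
  dispersion <- if (mean_deg == 0) 0 else stats::var(deg) / mean_deg
  hist_tab <- table(factor(deg, levels = 0:max(deg)))
  p_gof <- poisson_gof(deg)
  out <- tibble::tibble(
    group = net$group, n_nodes = n, n_edges = nrow(net$edges),
    avg_clustering = clustering_coefficients(net)$average,
    dispersion_index = dispersion, poisson_gof_p = p_gof,
    degree_histogram = list(stats::setNames(as.integer(hist_tab),
                                            names(hist_tab)))
  )
  class(out) <- c("topology_report", class(out))
  out
}

# chi-square GOF of observed degrees against Poisson(mean), pooling adjacent
# bins left-to-right until each expected count >= 5 (last bin takes the tail)
poisson_gof <- function(deg) {
  n <- length(deg)
  lambda <- mean(deg)
  if (lambda == 0) return(NA_real_)
  kmax <- max(deg)
  probs <- c(stats::dpois(0:(kmax - 1), lambda),
             stats::ppois(kmax - 1, lambda, lower.tail = FALSE))
  if (kmax == 0) probs <- 1
  obs <- as.integer(table(factor(deg, levels = 0:kmax)))
  exp_cnt <- n * probs
  # pool adjacent bins until expected >= 5
  pooled_obs <- numeric(0); pooled_exp <- numeric(0)
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(exp_cnt)) {
    acc_o <- acc_o + obs[i]; acc_e <- acc_e + exp_cnt[i]
    if (acc_e >= 5) {
      pooled_obs <- c(pooled_obs, acc_o); pooled_exp <- c(pooled_exp, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {
    if (length(pooled_exp) == 0) return(NA_real_)
    pooled_obs[length(pooled_obs)] <- pooled_obs[length(pooled_obs)] + acc_o
    pooled_exp[length(pooled_exp)] <- pooled_exp[length(pooled_exp)] + acc_e
  }
  df <- length(pooled_exp) - 2L  # mean estimated from the data
  if (df < 1) return(NA_real_)
  stat <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' @export
#' @importFrom generics tidy
tidy.neoplasm_network <- function(x, ...) {
  x$edges
}

#' @export
#' @importFrom generics glance
glance.neoplasm_network <- function(x, ...) {
  if (length(x$nodes) < 2) {
    return(tibble::tibble(group = x$group, n_nodes = length(x$nodes),
                          n_edges = nrow(x$edges), avg_clustering = NA_real_,
                          dispersion_index = NA_real_, poisson_gof_p = NA_real_,
                          pruned = x$pruned))
  }
  rep <- degree_distribution_fit(x)
  tibble::tibble(group = x$group, n_nodes = rep$n_nodes, n_edges = rep$n_edges,
                 avg_clustering = rep$avg_clustering,
                 dispersion_index = rep$dispersion_index,
                 poisson_gof_p = rep$poisson_gof_p, pruned = x$pruned)
}

#' Plot a neoplasm network
#'
#' Force-directed layout with edge alpha scaled by combined weight.
#'
#' @param object A `neoplasm_network`.
#' @param seed Layout seed for reproducibility.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neoplasm_network <- function(object, seed = 42, ...) {
  g <- as_igraph(object)
  withr_seed <- function(expr) { # local, avoid touching the session RNG
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  xy <- withr_seed(igraph::layout_with_fr(g))
  nodes <- tibble::tibble(mirna = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(nodes, by = c(mirna_a = "mirna")) |>
    dplyr::rename(xa = "x", ya = "y") |>
    dplyr::left_join(nodes, by = c(mirna_b = "mirna")) |>
    dplyr::rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       alpha = .data$w_combined),
                          colour = "grey40") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2, colour = "#2166ac") +
    ggplot2::scale_alpha(range = c(0.15, 0.9), guide = "none") +
    ggplot2::labs(title = paste0(object$group,
                                 if (object$pruned) " (pruned)" else ""),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Export a network as TSV edge list and GraphML
#'
#' @param net A `neoplasm_network`.
#' @param tsv_path,graphml_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the edge tibble written.
#' @export
write_network <- function(net, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(net$edges, tsv_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  }
  invisible(net$edges)
}
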
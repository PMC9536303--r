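# Shared fixture builders. Everything is generated in code at test time.

# small 4-term DAG with analytically known ICs:
# root R -> {A, B}; A -> C. Annotating g1:C, g2:A, g3:B, g4:B gives
# p(A) = p(B) = 1/2, p(C) = 1/4.
toy_dag <- function() {
  go_dag(tibble::tibble(id = c("R", "A", "B", "C"),
                        name = c("root", "a", "b", "c"),
                        namespace = "biological_process"),
         list(A = "R", B = "R", C = "A"))
}

toy_corpus <- function(dag = toy_dag()) {
  information_content(dag, list(g1 = "C", g2 = "A", g3 = "B", g4 = "B"))
}

# write a TSV fixture and return its path (session-lifetime tempfile)
write_tsv_fixture <- function(df, name = "fixture.tsv") {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# a complete-graph network over n nodes with the given weights (by pair order)
complete_network <- function(n, weights, group = "G") {
  nodes <- sprintf("hsa-miR-t%03d", seq_len(n))
  pr <- t(utils::combn(nodes, 2))
  stopifnot(length(weights) == nrow(pr))
  edges <- tibble::tibble(mirna_a = pr[, 1], mirna_b = pr[, 2],
                          w_sym = weights, w_asym = NA_real_,
                          w_combined = weights)
  assoc <- tibble::tibble(mirna = nodes, group = group, sources = "hmdd")
  build_neoplasm_network(group, assoc, edges)
}

# network from an explicit edge list (equal weights unless given)
network_from_pairs <- function(pairs, group = "G", weights = NULL,
                               extra_nodes = character(0), pruned = FALSE) {
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  edges <- tibble::tibble(mirna_a = pmin(pairs[, 1], pairs[, 2]),
                          mirna_b = pmax(pairs[, 1], pairs[, 2]),
                          w_sym = weights, w_asym = NA_real_,
                          w_combined = weights)
  nodes <- sort(unique(c(pairs[, 1], pairs[, 2], extra_nodes)))
  if (length(nodes) == 0) {
    net <- mirsignet:::new_neoplasm_network(group, nodes, edges, pruned = FALSE)
    if (pruned) net$pruned <- TRUE
    return(net)
  }
  assoc <- tibble::tibble(mirna = nodes, group = group, sources = "hmdd")
  net <- build_neoplasm_network(group, assoc, edges)
  if (pruned) net$pruned <- TRUE
  net
}

# brute-force maximal clique enumeration over all vertex subsets
brute_force_max_cliques <- function(nodes, edge_pairs, min_size = 3) {
  has_edge <- function(a, b) {
    any((edge_pairs[, 1] == a & edge_pairs[, 2] == b) |
          (edge_pairs[, 1] == b & edge_pairs[, 2] == a))
  }
  is_clique <- function(members) {
    if (length(members) < 2) return(TRUE)
    pr <- utils::combn(members, 2)
    all(vapply(seq_len(ncol(pr)), function(i) has_edge(pr[1, i], pr[2, i]),
               logical(1)))
  }
  out <- list()
  for (k in seq_along(nodes)) {
    for (idx in utils::combn(length(nodes), k, simplify = FALSE)) {
      members <- nodes[idx]
      if (!is_clique(members)) next
      extendable <- any(vapply(setdiff(nodes, members), function(v) {
        is_clique(c(members, v))
      }, logical(1)))
      if (!extendable && length(members) >= min_size) {
        out[[length(out) + 1]] <- sort(members)
      }
    }
  }
  key <- vapply(out, paste, character(1), collapse = ";")
  out[order(-lengths(out), key)]
}

# brute-force Lin/Resnik term similarity over all common ancestors
brute_force_term_sim <- function(corpus, dag, t1, t2, method) {
  anc <- function(t) {
    out <- t
    frontier <- t
    while (length(frontier) > 0) {
      nxt <- unique(unlist(dag$parents[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, out)
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  if (dag$namespace[[t1]] != dag$namespace[[t2]]) return(0)
  common <- intersect(anc(t1), anc(t2))
  ics <- corpus$ic[common]
  ic_mica <- if (all(is.na(ics))) 0 else max(ics, na.rm = TRUE)
  ic1 <- corpus$ic[[t1]]; ic2 <- corpus$ic[[t2]]
  if (method == "lin") {
    if (ic1 + ic2 <= 0) return(0)
    2 * ic_mica / (ic1 + ic2)
  } else {
    mx <- corpus$max_ic[[dag$namespace[[t1]]]]
    if (mx <= 0) return(0) else min(1, ic_mica / mx)
  }
}

# brute-force BMA
brute_force_bma <- function(m) {
  row_best <- vapply(seq_len(nrow(m)), function(i) max(m[i, ]), numeric(1))
  col_best <- vapply(seq_len(ncol(m)), function(j) max(m[, j]), numeric(1))
  (mean(row_best) + mean(col_best)) / 2
}

# exact hypergeometric upper tail by summing the mass function
brute_force_hyper_tail <- function(x, m, n_univ, k) {
  kk <- x:min(m, k)
  sum(choose(m, kk) * choose(n_univ - m, k - kk)) / choose(n_univ, k)
}
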
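#' Symmetric miRNA-miRNA functional similarity
#'
#' Best-match-average over the gene-similarity matrix of two miRNAs' target
#' gene sets: the more functionally related the targets, the more similar the
#' miRNAs. Symmetric by construction.
#'
#' @param targets_a,targets_b Non-empty character vectors of target genes,
#'   all annotated in `corpus`.
#' @param corpus An [information_content()] corpus.
#' @param dag A [go_dag].
#' @param method Term-similarity method, `"lin"` (default) or `"resnik"`.
#' @param gene_sim_cache Optional precomputed symmetric gene-similarity matrix
#'   (dimnames = gene symbols) covering both sets; see
#'   [gene_similarity_matrix()]. Avoids recomputation across many miRNA pairs.
#' @return Similarity in [0, 1].
#' @export
gosemsim_mirna_similarity <- function(targets_a, targets_b, corpus, dag,
                                      method = c("lin", "resnik"),
                                      gene_sim_cache = NULL) {
  method <- match.arg(method)
  if (length(targets_a) == 0) stop("empty target set (first miRNA)", call. = FALSE)
  if (length(targets_b) == 0) stop("empty target set (second miRNA)", call. = FALSE)
  targets_a <- unique(targets_a); targets_b <- unique(targets_b)
  if (!is.null(gene_sim_cache)) {
    m <- gene_sim_cache[targets_a, targets_b, drop = FALSE]
  } else {
    m <- matrix(0, length(targets_a), length(targets_b))
    for (i in seq_along(targets_a)) for (j in seq_along(targets_b)) {
      m[i, j] <- gene_similarity(corpus, dag, targets_a[i], targets_b[j], method)
    }
  }
  bma(m)
}

#' Pairwise gene-similarity matrix
#'
#' Symmetric matrix of [gene_similarity()] over a gene panel, with the
#' diagonal computed like any other entry. Used as a cache when scoring many
#' miRNA pairs over overlapping target sets.
#'
#' @inheritParams gosemsim_mirna_similarity
#' @param genes Character vector of annotated genes.
#' @return Numeric matrix with `genes` as dimnames.
#' @export
gene_similarity_matrix <- function(genes, corpus, dag, method = c("lin", "resnik")) {
  method <- match.arg(method)
  genes <- unique(genes)
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- gene_similarity(corpus, dag, genes[i], genes[j], method)
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Hypergeometric significance weights for GO terms of a target set
#'
#' For every term annotated (after propagation) in at least one target gene,
#' computes the hypergeometric upper-tail probability of drawing at least the
#' observed number of term-annotated genes when sampling `|targets|` genes
#' from the universe, and converts it to a weight
#' `min(1, -log10(p) / cap)` with `cap = log10(|universe|)` — the cap anchors
#' full weight at the smallest p-value achievable in a universe of that size,
#' so a single vanishing p cannot dominate a weighted average.
#'
#' @param target_genes Character vector, subset of `universe`.
#' @param corpus An [information_content()] corpus (propagated annotations).
#' @param universe Character vector of annotated genes; must be non-empty.
#' @return Named numeric vector: term -> weight in [0, 1].
#' @export
term_significance_weights <- function(target_genes, corpus, universe) {
  if (length(universe) == 0) stop("empty gene universe", call. = FALSE)
  if (!all(target_genes %in% universe)) {
    stop("target genes outside the universe: ",
         paste(setdiff(target_genes, universe), collapse = ", "), call. = FALSE)
  }
  ann <- corpus$gene_terms
  missing_genes <- setdiff(universe, names(ann))
  if (length(missing_genes) > 0) {
    stop("unannotated universe gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  n_univ <- length(universe)
  k <- length(target_genes)
  target_counts <- table(unlist(ann[target_genes], use.names = FALSE))
  univ_counts <- table(unlist(ann[universe], use.names = FALSE))
  cap <- log10(n_univ)
  terms <- names(target_counts)
  x <- as.integer(target_counts)
  m <- as.integer(univ_counts[terms])
  p <- stats::phyper(x - 1L, m, n_univ - m, k, lower.tail = FALSE)
  w <- pmin(1, -log10(pmax(p, .Machine$double.xmin)) / cap)
  stats::setNames(w, terms)
}

# Jaccard affinity of two terms' combined up+down closures
term_affinity <- function(dag, t1, t2) {
  c1 <- union(dag$ancestors[[t1]], dag$descendants[[t1]])
  c2 <- union(dag$ancestors[[t2]], dag$descendants[[t2]])
  length(intersect(c1, c2)) / length(union(c1, c2))
}

#' Pairwise term-affinity matrix (closure Jaccard)
#'
#' @param dag A [go_dag].
#' @param terms Character vector of term ids.
#' @return Symmetric matrix of Jaccard affinities of the terms' combined
#'   ancestor+descendant closures.
#' @export
term_affinity_matrix <- function(dag, terms) {
  terms <- unique(terms)
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  closures <- lapply(terms, function(t) union(dag$ancestors[[t]], dag$descendants[[t]]))
  for (i in seq_len(n)) {
    for (j in i:n) {
      a <- closures[[i]]; b <- closures[[j]]
      m[i, j] <- m[j, i] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  m
}

#' Asymmetric significance-weighted miRNA similarity
#'
#' A declared approximation of the published asymmetric miRNA functional
#' similarity family: term-term affinity is the Jaccard index of the two
#' terms' combined ancestor-and-descendant closures (so both shared ancestry
#' and shared progeny raise affinity); the directed score S(A -> B) averages,
#' over the informative GO terms of A's targets, each term's best affinity in
#' B's term set, weighted by the term's hypergeometric significance in A's
#' target set; the reported value symmetrizes the two directions. Internals
#' are isolated behind this function so a faithful port of the published
#' measure can replace it.
#'
#' @inheritParams gosemsim_mirna_similarity
#' @param universe Gene universe for significance weighting; defaults to all
#'   corpus genes.
#' @param affinity_cache Optional precomputed [term_affinity_matrix()]
#'   covering both term sets.
#' @return Symmetrized similarity in [0, 1]. The unsymmetrized directed scores
#'   are attached as attribute `"directed"` (length-2 numeric, A->B and B->A).
#' @export
mirgofs_like_similarity <- function(targets_a, targets_b, corpus, dag,
                                    universe = names(corpus$gene_terms),
                                    affinity_cache = NULL) {
  if (length(targets_a) == 0) stop("empty target set (first miRNA)", call. = FALSE)
  if (length(targets_b) == 0) stop("empty target set (second miRNA)", call. = FALSE)
  term_set <- function(targets) {
    ts <- unique(unlist(corpus$gene_terms[unique(targets)], use.names = FALSE))
    ts[!is.na(corpus$ic[ts]) & corpus$ic[ts] > 0]
  }
  ta <- term_set(targets_a)
  tb <- term_set(targets_b)
  if (length(ta) == 0 || length(tb) == 0) return(structure(0, directed = c(0, 0)))
  wa <- term_significance_weights(unique(targets_a), corpus, universe)
  wb <- term_significance_weights(unique(targets_b), corpus, universe)
  directed <- function(from, to, w) {
    best <- vapply(from, function(t1) {
      if (!is.null(affinity_cache)) {
        max(affinity_cache[t1, to])
      } else {
        max(vapply(to, function(t2) term_affinity(dag, t1, t2), numeric(1)))
      }
    }, numeric(1))
    wt <- unname(w[from]); wt[is.na(wt)] <- 0
    if (sum(wt) <= 0) mean(best) else sum(wt * best) / sum(wt)
  }
  s_ab <- directed(ta, tb, wa)
  s_ba <- directed(tb, ta, wb)
  structure((s_ab + s_ba) / 2, directed = c(s_ab, s_ba))
}

#' Build the thresholded miRNA similarity edge set
#'
#' Applies the robustness cutoff per source, then unions: an unordered miRNA
#' pair becomes an edge when its symmetric-source weight or its
#' asymmetric-source weight reaches `threshold` (inclusive). A weight below
#' the cutoff for its own source is treated as absent (`NA`) on the edge;
#' `w_combined` is the maximum of the present weights. One edge per pair,
#' endpoints ordered `mirna_a < mirna_b`, no self-loops.
#'
#' @param sym_scores,asym_scores Tibbles with columns `mirna_a`, `mirna_b`,
#'   `weight` (either may be `NULL` or empty); unordered pairs, duplicates
#'   resolved by maximum weight.
#' @param threshold Inclusive cutoff in [0, 1], default 0.6.
#' @return Tibble with columns `mirna_a`, `mirna_b`, `w_sym`, `w_asym`,
#'   `w_combined`, sorted by the pair.
#' @export
build_edge_set <- function(sym_scores = NULL, asym_scores = NULL, threshold = 0.6) {
  stopifnot(threshold >= 0, threshold <= 1)
  canon <- function(df, col) {
    if (!is.null(df) && nrow(df) > 0) {
      stopifnot(all(c("mirna_a", "mirna_b", "weight") %in% names(df)))
      df <- dplyr::filter(df, .data$mirna_a != .data$mirna_b)
    }
    if (is.null(df) || nrow(df) == 0) {
      return(tibble::tibble(mirna_a = character(), mirna_b = character(),
                            "{col}" := numeric()))
    }
    df |>
      dplyr::mutate(a = pmin(.data$mirna_a, .data$mirna_b),
                    b = pmax(.data$mirna_a, .data$mirna_b)) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::filter(.data$weight >= threshold) |>
      dplyr::select(mirna_a = "a", mirna_b = "b", "{col}" := "weight")
  }
  merged <- dplyr::full_join(canon(sym_scores, "w_sym"),
                             canon(asym_scores, "w_asym"),
                             by = c("mirna_a", "mirna_b"))
  merged |>
    dplyr::mutate(w_combined = pmax(.data$w_sym, .data$w_asym, na.rm = TRUE)) |>
    dplyr::arrange(.data$mirna_a, .data$mirna_b)
}
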
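#' Construct a GO-style DAG object
#'
#' Internal constructor shared by [parse_obo()] and the ontology simulator.
#' Validates acyclicity, single-root-per-namespace, and computes reflexive
#' ancestor/descendant closures once (the DAGs handled here are small enough
#' that full closures are cheap and make similarity queries O(set size)).
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of parent ids
#'   (is_a / part_of collapsed).
#' @return A `go_dag` object.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  ids <- terms$id
  if (anyDuplicated(ids) > 0) stop("duplicate term ids", call. = FALSE)
  parents <- parents[intersect(names(parents), ids)]
  parents <- lapply(parents, intersect, ids)
  full_parents <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  full_parents[names(parents)] <- parents

  # Kahn topological sort doubles as the cycle check
  indeg <- vapply(full_parents, length, integer(1))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) for (p in full_parents[[t]]) children[[p]] <- c(children[[p]], t)
  queue <- ids[indeg == 0]
  topo <- character(0)
  indeg_work <- indeg
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg_work[ch] <- indeg_work[ch] - 1L
      if (indeg_work[ch] == 0) queue <- c(queue, ch)
    }
  }
  if (length(topo) != length(ids)) {
    stop("cycle detected involving term(s): ",
         paste(setdiff(ids, topo), collapse = ", "), call. = FALSE)
  }

  ns <- stats::setNames(terms$namespace, terms$id)
  roots <- character(0)
  for (nsp in unique(terms$namespace)) {
    ns_ids <- ids[ns[ids] == nsp]
    ns_roots <- ns_ids[indeg[ns_ids] == 0]
    if (length(ns_roots) != 1) {
      stop("namespace '", nsp, "' must have exactly one root, found ",
           length(ns_roots), call. = FALSE)
    }
    roots[nsp] <- ns_roots
  }

  # reflexive transitive closures in topological order
  ancestors <- stats::setNames(vector("list", length(ids)), ids)
  for (t in topo) {
    anc <- t
    for (p in full_parents[[t]]) anc <- c(anc, ancestors[[p]])
    ancestors[[t]] <- unique(anc)
  }
  descendants <- stats::setNames(vector("list", length(ids)), ids)
  for (t in rev(topo)) {
    dec <- t
    for (ch in children[[t]]) dec <- c(dec, descendants[[ch]])
    descendants[[t]] <- unique(dec)
  }

  structure(list(terms = tibble::as_tibble(terms),
                 parents = full_parents, children = children,
                 namespace = ns, roots = roots,
                 ancestors = ancestors, descendants = descendants),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", nrow(x$terms), " terms, ",
      length(x$roots), " namespace(s): ",
      paste(names(x$roots), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Parse an OBO 1.2/1.4 ontology file into a DAG
#'
#' Reads `[Term]` stanzas, keeping `is_a` and `relationship: part_of` edges as
#' parent links. Obsolete terms are excluded, as are edges pointing at excluded
#' terms. Cycles and namespaces without a unique root are format errors.
#'
#' @param path Path to an OBO file.
#' @return A [go_dag] object.
#' @export
parse_obo <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ids <- character(0); names_ <- character(0); nss <- character(0)
  parents <- list()
  cur <- NULL
  flush <- function() {
    if (is.null(cur) || isTRUE(cur$obsolete) || is.null(cur$id)) return()
    ids <<- c(ids, cur$id)
    names_ <<- c(names_, cur$name %||% cur$id)
    nss <<- c(nss, cur$namespace %||% "default")
    parents[[cur$id]] <<- unique(cur$parents)
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(parents = character(0)); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$namespace <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_obsolete:")) cur$obsolete <- grepl("true", ln)
    else if (startsWith(ln, "is_a:")) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$parents <- c(cur$parents, tgt)
    } else if (startsWith(ln, "relationship:")) {
      body <- trimws(sub("!.*$", "", sub("^relationship:", "", ln)))
      parts <- strsplit(body, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$parents <- c(cur$parents, parts[2])
      }
    }
  }
  flush()
  if (length(ids) == 0) stop("no [Term] stanzas found in ", path, call. = FALSE)
  go_dag(tibble::tibble(id = ids, name = names_, namespace = nss), parents)
}

#' Reflexive transitive closure of a term
#'
#' @param dag A [go_dag].
#' @param term Term id present in the DAG.
#' @param direction `"up"` for ancestors, `"down"` for descendants; the query
#'   term itself is always included.
#' @return Character vector of term ids.
#' @export
term_closure <- function(dag, term, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!term %in% dag$terms$id) stop("unknown term: ", term, call. = FALSE)
  if (direction == "up") dag$ancestors[[term]] else dag$descendants[[term]]
}

#' Read a gene -> GO term annotation table
#'
#' Accepts a plain two-column TSV (`gene`, `go_term`) or, via `gene_col` /
#' `term_col`, the relevant column subset of a GAF-like export.
#'
#' @param path Path to a TSV with a header row.
#' @param gene_col,term_col Column names carrying the gene symbol and term id.
#' @return Named list: gene -> character vector of directly annotated terms.
#' @export
read_annotations <- function(path, gene_col = "gene", term_col = "go_term") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c(gene_col, term_col) %in% names(raw))) {
    stop("annotation file must have columns ", gene_col, ", ", term_col,
         call. = FALSE)
  }
  split(raw[[term_col]], raw[[gene_col]]) |> lapply(unique)
}

#' Build an annotation corpus with information content
#'
#' Propagates every gene's annotations to all ancestors (the true-path rule),
#' then estimates, per namespace, each term's annotation probability
#' p(t) = (genes annotated at or below t) / (genes annotated in the namespace)
#' and its information content IC(t) = -ln p(t). Genes none of whose terms
#' exist in the DAG are dropped with a warning.
#'
#' @param dag A [go_dag].
#' @param gene_terms Named list: gene -> character vector of term ids
#'   (direct annotations; propagation is handled here).
#' @return An `annotation_corpus` object with elements `gene_terms`
#'   (propagated), `term_freq`, `ic`, `max_ic` (per namespace), `n_genes`
#'   (per namespace).
#' @export
information_content <- function(dag, gene_terms) {
  valid <- dag$terms$id
  propagated <- lapply(gene_terms, function(terms) {
    terms <- intersect(terms, valid)
    if (length(terms) == 0) return(character(0))
    unique(unlist(dag$ancestors[terms], use.names = FALSE))
  })
  empty <- vapply(propagated, length, integer(1)) == 0
  if (any(empty)) {
    warning("dropping gene(s) with no valid annotation: ",
            paste(names(propagated)[empty], collapse = ", "), call. = FALSE)
    propagated <- propagated[!empty]
  }
  if (length(propagated) == 0) stop("no annotated genes", call. = FALSE)

  ns_of <- dag$namespace
  # per-namespace gene universe sizes
  n_genes <- sapply(names(dag$roots), function(nsp) {
    sum(vapply(propagated, function(ts) any(ns_of[ts] == nsp), logical(1)))
  })
  counts <- table(unlist(propagated, use.names = FALSE))
  term_freq <- numeric(0)
  for (t in names(counts)) {
    denom <- n_genes[[ns_of[[t]]]]
    term_freq[t] <- as.numeric(counts[[t]]) / denom
  }
  ic <- -log(term_freq)
  max_ic <- sapply(names(dag$roots), function(nsp) {
    v <- ic[names(ic)[ns_of[names(ic)] == nsp]]
    if (length(v) == 0) 0 else max(v)
  })
  structure(list(gene_terms = propagated, term_freq = term_freq, ic = ic,
                 max_ic = max_ic, n_genes = n_genes),
            class = "annotation_corpus")
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat("<annotation_corpus> ", length(x$gene_terms), " genes, ",
      length(x$ic), " annotated terms\n", sep = "")
  invisible(x)
}

#' Information-content term-term similarity
#'
#' Lin similarity 2*IC(MICA)/(IC(t1)+IC(t2)) or Resnik similarity normalized
#' to [0,1] by the corpus-wide maximal IC of the namespace, where MICA is the
#' common ancestor (reflexive) with maximal IC. Cross-namespace pairs have no
#' common ancestor and score 0 with a warning.
#'
#' @param corpus An [information_content()] corpus.
#' @param dag A [go_dag].
#' @param t1,t2 Term ids.
#' @param method `"lin"` or `"resnik"`.
#' @return Similarity in [0, 1].
#' @export
term_similarity <- function(corpus, dag, t1, t2, method = c("lin", "resnik")) {
  method <- match.arg(method)
  for (t in c(t1, t2)) {
    if (!t %in% dag$terms$id) stop("unknown term: ", t, call. = FALSE)
  }
  if (dag$namespace[[t1]] != dag$namespace[[t2]]) {
    warning("cross-namespace term pair (", t1, ", ", t2, "): similarity 0",
            call. = FALSE)
    return(0)
  }
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  ic <- corpus$ic
  ic1 <- unname(ic[t1]); ic2 <- unname(ic[t2])
  if (is.na(ic1) || is.na(ic2)) {
    stop("term without annotation-derived IC: ",
         paste(c(t1, t2)[c(is.na(ic1), is.na(ic2))], collapse = ", "),
         call. = FALSE)
  }
  ic_common <- ic[common]
  ic_common <- ic_common[!is.na(ic_common)]
  ic_mica <- if (length(ic_common) == 0) 0 else max(ic_common)
  if (method == "lin") {
    if (ic1 + ic2 <= 0) return(0)
    2 * ic_mica / (ic1 + ic2)
  } else {
    mx <- corpus$max_ic[[dag$namespace[[t1]]]]
    if (mx <= 0) return(0)
    min(1, ic_mica / mx)
  }
}

#' Best-match-average aggregation of a similarity matrix
#'
#' (mean of row maxima + mean of column maxima) / 2; symmetric under
#' transposition.
#'
#' @param m Numeric matrix with entries in [0, 1]; must be non-empty.
#' @return Value in [0, 1].
#' @export
bma <- function(m) {
  m <- as.matrix(m)
  if (length(m) == 0 || nrow(m) == 0 || ncol(m) == 0) {
    stop("bma() of an empty matrix is undefined", call. = FALSE)
  }
  (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
}

# informative (IC > 0) propagated terms of a gene, split by namespace
informative_terms <- function(corpus, dag, gene) {
  ts <- corpus$gene_terms[[gene]]
  if (is.null(ts)) stop("unannotated gene: ", gene, call. = FALSE)
  ts <- ts[!is.na(corpus$ic[ts]) & corpus$ic[ts] > 0]
  split(ts, dag$namespace[ts])
}

#' Gene-gene functional similarity
#'
#' Best-match-average over the term-similarity matrix of the two genes'
#' propagated informative term sets (roots and other IC = 0 terms are
#' uninformative and excluded), computed per namespace and averaged over the
#' namespaces in which both genes have informative terms. Genes with no shared
#' namespace score 0.
#'
#' @inheritParams term_similarity
#' @param gene_a,gene_b Gene identifiers present in the corpus.
#' @return Similarity in [0, 1].
#' @export
gene_similarity <- function(corpus, dag, gene_a, gene_b, method = c("lin", "resnik")) {
  method <- match.arg(method)
  ta <- informative_terms(corpus, dag, gene_a)
  tb <- informative_terms(corpus, dag, gene_b)
  shared_ns <- intersect(names(ta), names(tb))
  if (length(shared_ns) == 0) return(0)
  per_ns <- vapply(shared_ns, function(nsp) {
    a <- ta[[nsp]]; b <- tb[[nsp]]
    m <- matrix(0, length(a), length(b))
    for (i in seq_along(a)) for (j in seq_along(b)) {
      m[i, j] <- term_similarity(corpus, dag, a[i], b[j], method)
    }
    bma(m)
  }, numeric(1))
  mean(per_ns)
}
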
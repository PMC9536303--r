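test_that("symmetric miRNA similarity is the BMA of the gene matrix", {
  dag <- toy_dag(); corp <- toy_corpus()
  expect_equal(gosemsim_mirna_similarity(c("g1", "g2"), c("g1", "g2"),
                                         corp, dag), 1)
  # hand-built 2x2 gene matrix via the cache: BMA oracle
  cache <- matrix(c(1.0, 0.4, 0.2, 0.6), 2, 2,
                  dimnames = list(c("g1", "g2"), c("g3", "g4")))
  expect_equal(gosemsim_mirna_similarity(c("g1", "g2"), c("g3", "g4"),
                                         corp, dag, gene_sim_cache = cache),
               0.8, tolerance = 1e-12)
  # symmetry on real computations
  s_ab <- gosemsim_mirna_similarity(c("g1", "g2"), c("g3", "g4"), corp, dag)
  s_ba <- gosemsim_mirna_similarity(c("g3", "g4"), c("g1", "g2"), corp, dag)
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  expect_error(gosemsim_mirna_similarity(character(0), "g1", corp, dag),
               "empty target set")
  # genes in disjoint namespaces: all gene sims 0 -> similarity 0
  dag2 <- go_dag(tibble::tibble(
    id = c("R1", "B1", "R2", "M1"), name = "x",
    namespace = c("biological_process", "biological_process",
                  "molecular_function", "molecular_function")),
    list(B1 = "R1", M1 = "R2"))
  corp2 <- information_content(dag2, list(ga = "B1", gb = "M1", gc = "B1",
                                          gd = "M1"))
  expect_identical(gosemsim_mirna_similarity("ga", "gb", corp2, dag2), 0)
})

test_that("significance weights match the exact hypergeometric tail", {
  # universe of 10 genes, 4 carry T, 5 targets of which 3 carry T
  dag <- go_dag(tibble::tibble(id = c("R", "T"), name = c("r", "t"),
                               namespace = "biological_process"),
                list(T = "R"))
  genes <- paste0("g", 1:10)
  ann <- stats::setNames(as.list(rep("R", 10)), genes)
  for (g in genes[1:4]) ann[[g]] <- "T"
  corp <- information_content(dag, ann)
  targets <- genes[c(1, 2, 3, 5, 6)]
  w <- term_significance_weights(targets, corp, genes)
  p_expected <- brute_force_hyper_tail(3, 4, 10, 5)
  expect_equal(p_expected, 66 / 252, tolerance = 1e-12)
  expect_equal(unname(w["T"]), min(1, -log10(p_expected) / log10(10)),
               tolerance = 1e-12)
  # a term annotating the whole universe has p = 1 and minimal weight
  expect_equal(unname(w["R"]), 0)
  # all targets and only targets carry T: the smallest p for that
  # configuration, beyond the 1/|universe| cap, so the weight saturates at 1
  ann2 <- stats::setNames(as.list(rep("R", 10)), genes)
  for (g in genes[1:5]) ann2[[g]] <- "T"
  corp2 <- information_content(dag, ann2)
  w2 <- term_significance_weights(genes[1:5], corp2, genes)
  p_min <- brute_force_hyper_tail(5, 5, 10, 5)
  expect_lt(p_min, 1 / 10)
  expect_equal(unname(w2["T"]), min(1, -log10(p_min) / log10(10)),
               tolerance = 1e-9)
  expect_equal(unname(w2["T"]), 1)
  expect_error(term_significance_weights("gx", corp, character(0)), "empty")
  # random instances against the enumeration oracle
  set.seed(3)
  for (rep in 1:20) {
    n_univ <- sample(6:12, 1)
    genes_r <- paste0("u", seq_len(n_univ))
    ann_r <- stats::setNames(as.list(rep("R", n_univ)), genes_r)
    with_t <- sample(genes_r, sample(1:n_univ, 1))
    for (g in with_t) ann_r[[g]] <- "T"
    corp_r <- information_content(dag, ann_r)
    k <- sample(1:n_univ, 1)
    targets_r <- sample(genes_r, k)
    x <- length(intersect(targets_r, with_t))
    if (x == 0) next
    w_r <- term_significance_weights(targets_r, corp_r, genes_r)
    p_brute <- brute_force_hyper_tail(x, length(with_t), n_univ, k)
    expect_equal(unname(w_r["T"]),
                 min(1, -log10(p_brute) / log10(n_univ)), tolerance = 1e-9)
  }
})

test_that("asymmetric similarity realizes closure affinity, weighting, asymmetry", {
  dag <- toy_dag(); corp <- toy_corpus()
  genes <- names(corp$gene_terms)
  # identical sets score 1; symmetrized output is symmetric
  expect_equal(as.numeric(mirgofs_like_similarity(c("g1", "g2"), c("g1", "g2"),
                                                  corp, dag)), 1)
  s1 <- mirgofs_like_similarity("g1", "g3", corp, dag)
  s2 <- mirgofs_like_similarity("g3", "g1", corp, dag)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)

  # brute-force directed sums on the toy fixture
  # g1 informative terms {A, C}; g3 informative terms {B}
  aff <- function(t1, t2) {
    c1 <- union(term_closure(dag, t1, "up"), term_closure(dag, t1, "down"))
    c2 <- union(term_closure(dag, t2, "up"), term_closure(dag, t2, "down"))
    length(intersect(c1, c2)) / length(union(c1, c2))
  }
  w_g1 <- term_significance_weights("g1", corp, genes)
  w_g3 <- term_significance_weights("g3", corp, genes)
  best_a <- c(aff("A", "B"), aff("C", "B"))        # A-side terms {A, C}
  wt_a <- unname(w_g1[c("A", "C")])
  s_ab <- if (sum(wt_a) > 0) sum(wt_a * best_a) / sum(wt_a) else mean(best_a)
  best_b <- max(aff("B", "A"), aff("B", "C"))
  wt_b <- unname(w_g3["B"])
  s_ba <- if (sum(wt_b) > 0) sum(wt_b * best_b) / sum(wt_b) else mean(best_b)
  expect_equal(as.numeric(s1), (s_ab + s_ba) / 2, tolerance = 1e-12)

  # disjoint namespaces score 0
  dag2 <- go_dag(tibble::tibble(
    id = c("R1", "B1", "R2", "M1"), name = "x",
    namespace = c("biological_process", "biological_process",
                  "molecular_function", "molecular_function")),
    list(B1 = "R1", M1 = "R2"))
  corp2 <- information_content(dag2, list(ga = "B1", gb = "M1", gc = "B1",
                                          gd = "M1"))
  expect_identical(as.numeric(mirgofs_like_similarity("ga", "gb", corp2, dag2)),
                   0)
})

test_that("subset targets dominate the directed score toward their superset", {
  # one miRNA's targets strictly contain another's: under near-uniform
  # weights S(subset -> superset) >= S(superset -> subset)
  for (seed in 1:5) {
    world <- simulate_ontology_world(n_terms = 12, n_genes = 10,
                                     n_namespaces = 1, seed = seed)
    corp <- information_content(world$dag, world$gene_terms)
    genes <- names(corp$gene_terms)
    if (length(genes) < 4) next
    sub <- genes[1:2]; super <- genes[1:4]
    s <- mirgofs_like_similarity(sub, super, corp, world$dag)
    d <- attr(s, "directed")
    expect_gte(d[1] + 1e-9, d[2])
  }
})

test_that("edge thresholding is inclusive, per source, union-merged, deduplicated", {
  sym <- tibble::tibble(mirna_a = c("hsa-miR-1", "hsa-miR-1", "hsa-miR-2"),
                        mirna_b = c("hsa-miR-2", "hsa-miR-3", "hsa-miR-3"),
                        weight = c(0.59, 0.60, 0.85))
  asym <- tibble::tibble(mirna_a = c("hsa-miR-2", "hsa-miR-2"),
                         mirna_b = c("hsa-miR-1", "hsa-miR-3"),
                         weight = c(0.59, 0.70))
  edges <- build_edge_set(sym, asym, threshold = 0.6)
  # 0.59/0.59 pair excluded on both sources
  expect_false(any(edges$mirna_a == "hsa-miR-1" & edges$mirna_b == "hsa-miR-2"))
  # exactly 0.6 is included
  e13 <- edges[edges$mirna_a == "hsa-miR-1" & edges$mirna_b == "hsa-miR-3", ]
  expect_identical(nrow(e13), 1L)
  expect_equal(e13$w_sym, 0.6)
  # pair present in both sources carries both weights, combined = max
  e23 <- edges[edges$mirna_a == "hsa-miR-2" & edges$mirna_b == "hsa-miR-3", ]
  expect_identical(nrow(e23), 1L)
  expect_equal(e23$w_sym, 0.85)
  expect_equal(e23$w_asym, 0.70)
  expect_equal(e23$w_combined, 0.85)
  # endpoints are ordered, no self loops
  expect_true(all(edges$mirna_a < edges$mirna_b))
  loops <- tibble::tibble(mirna_a = "hsa-miR-1", mirna_b = "hsa-miR-1",
                          weight = 0.99)
  expect_identical(nrow(build_edge_set(loops)), 0L)
})

test_that("raising the threshold never adds edges", {
  set.seed(13)
  sym <- tibble::tibble(mirna_a = sample(paste0("m", 1:10), 40, replace = TRUE),
                        mirna_b = sample(paste0("m", 1:10), 40, replace = TRUE),
                        weight = runif(40))
  prev <- NULL
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- build_edge_set(sym, threshold = thr)
    if (!is.null(prev)) {
      expect_true(all(paste(cur$mirna_a, cur$mirna_b) %in%
                        paste(prev$mirna_a, prev$mirna_b)))
    }
    prev <- cur
  }
})
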
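test_that("OBO parsing builds the DAG with closures, multi-parents, obsoletes", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: A", "name: root", "namespace: biological_process", "",
    "[Term]", "id: B", "name: b", "namespace: biological_process",
    "is_a: A ! root", "",
    "[Term]", "id: C", "name: c", "namespace: biological_process",
    "is_a: A ! root", "",
    "[Term]", "id: D", "name: d", "namespace: biological_process",
    "is_a: B ! b", "",
    "[Term]", "id: E", "name: e", "namespace: biological_process",
    "is_a: B ! b", "relationship: part_of C ! c", "",
    "[Term]", "id: Z", "name: gone", "namespace: biological_process",
    "is_a: A ! root", "is_obsolete: true", ""
  ), obo)
  dag <- parse_obo(obo)
  expect_identical(sort(dag$terms$id), c("A", "B", "C", "D", "E"))
  expect_true(all(c("B", "C", "A") %in% term_closure(dag, "E", "up")))
  expect_setequal(dag$parents[["E"]], c("B", "C"))  # both parent kinds kept
  expect_identical(unname(dag$roots["biological_process"]), "A")

  # minimal one-term ontology is a root-only DAG
  mini <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X", "name: only",
               "namespace: molecular_function"), mini)
  expect_identical(parse_obo(mini)$terms$id, "X")

  # cycles are format errors naming an offender
  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "namespace: bp", "is_a: B ! b", "",
               "[Term]", "id: B", "namespace: bp", "is_a: A ! a"), cyc)
  expect_error(parse_obo(cyc), "cycle")
})

test_that("term closures are reflexive and direction-correct", {
  dag <- toy_dag()
  expect_identical(term_closure(dag, "R", "up"), "R")
  expect_setequal(term_closure(dag, "C", "up"), c("C", "A", "R"))
  expect_setequal(term_closure(dag, "R", "down"), c("R", "A", "B", "C"))
  expect_error(term_closure(dag, "nope", "up"), "unknown term")
})

test_that("information content follows annotation propagation", {
  corp <- toy_corpus()
  expect_identical(unname(corp$ic["R"]), 0)                 # root p = 1
  expect_equal(unname(corp$ic["C"]), log(4), tolerance = 1e-12)
  expect_equal(unname(corp$ic["A"]), log(2), tolerance = 1e-12)
  # annotation propagation preserves gene counts
  expect_identical(length(corp$gene_terms), 4L)
  # gene with no valid terms dropped with warning
  expect_warning(
    corp2 <- information_content(toy_dag(), list(g1 = "C", gx = "NOT_A_TERM")),
    "no valid annotation")
  expect_identical(names(corp2$gene_terms), "g1")
})

test_that("IC is monotone non-decreasing from parent to child on random corpora", {
  for (seed in 1:10) {
    world <- simulate_ontology_world(n_terms = 15, n_genes = 12,
                                     n_namespaces = 1, seed = seed)
    corp <- information_content(world$dag, world$gene_terms)
    for (t in names(corp$ic)) {
      for (p in world$dag$parents[[t]]) {
        if (!is.na(corp$ic[p])) {
          expect_gte(corp$ic[[t]], corp$ic[[p]])
        }
      }
    }
  }
})

test_that("Lin and Resnik similarities match hand computations", {
  dag <- toy_dag(); corp <- toy_corpus()
  # lin(C, A): MICA = A, IC(A) = ln 2, IC(C) = ln 4
  expect_equal(term_similarity(corp, dag, "C", "A"),
               2 * log(2) / (log(4) + log(2)), tolerance = 1e-12)
  # MICA of A and B is the root: similarity 0
  expect_identical(term_similarity(corp, dag, "A", "B"), 0)
  # self-similarity 1 for informative terms
  expect_identical(term_similarity(corp, dag, "C", "C"), 1)
  # resnik normalized by corpus max IC
  expect_equal(term_similarity(corp, dag, "C", "A", method = "resnik"),
               log(2) / log(4), tolerance = 1e-12)
  # cross-namespace pairs warn and score 0
  dag2 <- go_dag(tibble::tibble(id = c("R", "M"), name = c("r", "m"),
                                namespace = c("biological_process",
                                              "molecular_function")),
                 list())
  corp2 <- suppressWarnings(information_content(dag2, list(g = c("R", "M"))))
  expect_warning(s <- term_similarity(corp2, dag2, "R", "M"), "cross-namespace")
  expect_identical(s, 0)
})

test_that("similarities agree with the brute-force oracle on random DAGs", {
  set.seed(99)
  for (rep in 1:15) {
    world <- simulate_ontology_world(n_terms = sample(8:20, 1),
                                     n_genes = sample(6:12, 1),
                                     n_namespaces = 1, seed = rep)
    corp <- information_content(world$dag, world$gene_terms)
    annotated <- names(corp$ic)
    pick <- sample(annotated, min(6, length(annotated)))
    for (t1 in pick) for (t2 in pick) {
      for (method in c("lin", "resnik")) {
        expect_equal(term_similarity(corp, world$dag, t1, t2, method),
                     brute_force_term_sim(corp, world$dag, t1, t2, method),
                     tolerance = 1e-9)
        # symmetry
        expect_equal(term_similarity(corp, world$dag, t1, t2, method),
                     term_similarity(corp, world$dag, t2, t1, method),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("best-match average matches its definition and is transpose-invariant", {
  m <- matrix(c(1.0, 0.4, 0.2, 0.6), 2, 2)  # rows: {1.0, .6} cols: {1.0, .6}
  expect_equal(bma(m), 0.8, tolerance = 1e-12)
  expect_equal(bma(diag(3)), 1.0)
  expect_equal(bma(matrix(0.37)), 0.37)
  expect_error(bma(matrix(numeric(0), 0, 0)), "empty")
  set.seed(5)
  for (rep in 1:25) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    m <- matrix(runif(nr * nc), nrow = nr)
    expect_equal(bma(m), bma(t(m)), tolerance = 1e-12)
    expect_equal(bma(m), brute_force_bma(m), tolerance = 1e-12)
  }
})

test_that("gene similarity is the BMA of the informative term matrix", {
  dag <- toy_dag(); corp <- toy_corpus()
  expect_equal(gene_similarity(corp, dag, "g1", "g1"), 1)
  # g1 (terms C, A after propagation) vs g3 (term B): manual matrix
  manual <- matrix(c(term_similarity(corp, dag, "C", "B"),
                     term_similarity(corp, dag, "A", "B")), ncol = 1)
  expect_equal(gene_similarity(corp, dag, "g1", "g3"), bma(manual),
               tolerance = 1e-12)
  expect_error(gene_similarity(corp, dag, "g1", "ghost"), "ghost")
  # genes annotated in disjoint namespaces score 0
  dag2 <- go_dag(tibble::tibble(
    id = c("R1", "B1", "R2", "M1"), name = c("r", "b", "r", "m"),
    namespace = c("biological_process", "biological_process",
                  "molecular_function", "molecular_function")),
    list(B1 = "R1", M1 = "R2"))
  corp2 <- information_content(dag2, list(ga = "B1", gb = "M1", gc = "B1",
                                          gd = "M1"))
  expect_identical(gene_similarity(corp2, dag2, "ga", "gb"), 0)
})
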
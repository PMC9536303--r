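test_that("group-unique miRNAs are those in exactly one network", {
  n1 <- network_from_pairs(cbind("a", "b"), group = "G1")
  n2 <- network_from_pairs(cbind("b", "c"), group = "G2")
  n3 <- network_from_pairs(cbind("c", "d"), group = "G3")
  uniq <- unique_mirnas(list(G1 = n1, G2 = n2, G3 = n3))
  expect_identical(uniq$G1, "a")
  expect_identical(uniq$G2, character(0))
  expect_identical(uniq$G3, "d")
  # single network: everything unique
  expect_identical(unique_mirnas(list(G1 = n1))$G1, c("a", "b"))
  # a miRNA in all networks is unique in none
  n4 <- network_from_pairs(cbind(c("x", "x"), c("a", "c")), group = "G4")
  uniq2 <- unique_mirnas(list(G1 = n1, G2 = n2, G4 = n4))
  expect_false("c" %in% unlist(uniq2))
})

test_that("candidate modules are the maximal cliques of size >= 3", {
  tri <- network_from_pairs(cbind(c("a", "a", "b"), c("b", "c", "c")),
                            pruned = TRUE)
  expect_identical(enumerate_candidate_modules(tri), list(c("a", "b", "c")))
  # K4 yields one module of size 4; triangles are non-maximal
  k4_pairs <- t(utils::combn(c("a", "b", "c", "d"), 2))
  k4 <- network_from_pairs(k4_pairs, pruned = TRUE)
  expect_identical(enumerate_candidate_modules(k4), list(c("a", "b", "c", "d")))
  # two triangles sharing one edge give two modules
  bowtie <- network_from_pairs(cbind(c("a", "a", "b", "a", "b"),
                                     c("b", "c", "c", "d", "d")),
                               pruned = TRUE)
  expect_identical(enumerate_candidate_modules(bowtie),
                   list(c("a", "b", "c"), c("a", "b", "d")))
  # only pruned networks are eligible
  expect_error(enumerate_candidate_modules(
    network_from_pairs(cbind("a", "b"))), "pruned")
})

test_that("clique enumeration matches brute force on random graphs", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    nodes <- paste0("n", seq_len(n))
    all_pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(all_pairs)) < 0.5
    if (sum(keep) == 0) next
    pairs <- all_pairs[keep, , drop = FALSE]
    net <- network_from_pairs(pairs, extra_nodes = nodes, pruned = TRUE)
    got <- enumerate_candidate_modules(net, min_size = 3)
    expected <- brute_force_max_cliques(nodes, pairs, min_size = 3)
    expect_identical(got, expected)
  }
})

test_that("the exclusivity census distinguishes membership from connectivity", {
  mod <- c("a", "b", "c")
  tri <- network_from_pairs(cbind(c("a", "a", "b"), c("b", "c", "c")),
                            group = "G1")
  # members present but one edge missing
  broken <- network_from_pairs(cbind(c("a", "b"), c("b", "c")), group = "G2")
  other <- network_from_pairs(cbind("x", "y"), group = "G3")
  expect_identical(exclusivity_census(mod, list(G1 = tri, G2 = broken,
                                                G3 = other)), 1L)
  # present as a clique in 2 of 3 networks
  tri2 <- network_from_pairs(cbind(c("a", "a", "b", "c"),
                                   c("b", "c", "c", "z")), group = "G4")
  expect_identical(exclusivity_census(mod, list(G1 = tri, G2 = broken,
                                                G4 = tri2)), 2L)
  expect_error(exclusivity_census(c("a", "b"), list(G1 = tri)), ">= 3")
})

test_that("permutation significance has the add-one floor and is seed-deterministic", {
  # module exclusive and members absent elsewhere: exact floor p
  tri <- network_from_pairs(cbind(c("a", "a", "b"), c("b", "c", "c")),
                            group = "G1", pruned = TRUE)
  other <- network_from_pairs(cbind(c("x", "x", "y"), c("y", "z", "z")),
                              group = "G2", pruned = TRUE)
  p <- permutation_significance(c("a", "b", "c"), list(G1 = tri, G2 = other),
                                n_perm = 99, seed = 5)
  expect_equal(p, 1 / 100)
  # non-exclusive module is rejected
  expect_error(permutation_significance(c("a", "b", "c"),
                                        list(G1 = tri, G2 = tri),
                                        n_perm = 9, seed = 1),
               "exclusive")
  # co-membership in a rewireable half-dense network: the module has a real
  # chance of re-forming under degree-preserving swaps, so p leaves the floor
  set.seed(30)
  nodes <- paste0("n", 1:12)
  all_pairs <- t(utils::combn(nodes, 2))
  dense1 <- network_from_pairs(all_pairs, group = "D1", pruned = TRUE)
  keep <- runif(nrow(all_pairs)) < 0.5
  # make sure the triangle is broken in D2 but its members are present
  keep[all_pairs[, 1] == "n1" & all_pairs[, 2] == "n2"] <- FALSE
  keep[all_pairs[, 1] == "n1" & all_pairs[, 2] == "n3"] <- TRUE
  keep[all_pairs[, 1] == "n2" & all_pairs[, 2] == "n3"] <- TRUE
  dense2 <- network_from_pairs(all_pairs[keep, , drop = FALSE], group = "D2",
                               extra_nodes = nodes, pruned = TRUE)
  p_dense <- permutation_significance(c("n1", "n2", "n3"),
                                      list(D1 = dense1, D2 = dense2),
                                      n_perm = 99, seed = 7)
  expect_gt(p_dense, 0.05)
  # determinism under a fixed seed
  p1 <- permutation_significance(c("n1", "n2", "n3"),
                                 list(D1 = dense1, D2 = dense2),
                                 n_perm = 49, seed = 123)
  p2 <- permutation_significance(c("n1", "n2", "n3"),
                                 list(D1 = dense1, D2 = dense2),
                                 n_perm = 49, seed = 123)
  expect_identical(p1, p2)
})

test_that("the permutation p-value estimates the rewiring reappearance
           probability", {
  # the add-one p-value is (1 + hits)/(n_perm + 1) where hits counts
  # replicates in which the module re-forms as a clique in a rewired
  # non-host network; it must agree, within binomial error, with an
  # independent Monte-Carlo estimate of that reappearance probability
  set.seed(60)
  nodes <- paste0("n", 1:12)
  all_pairs <- t(utils::combn(nodes, 2))
  host <- network_from_pairs(all_pairs, group = "H", pruned = TRUE)
  keep <- runif(nrow(all_pairs)) < 0.5
  keep[all_pairs[, 1] == "n1" & all_pairs[, 2] == "n2"] <- FALSE
  other <- network_from_pairs(all_pairs[keep, , drop = FALSE], group = "O",
                              extra_nodes = nodes, pruned = TRUE)
  module <- c("n1", "n2", "n3")
  nets <- list(H = host, O = other)
  n_perm <- 399
  p_hat <- permutation_significance(module, nets, n_perm = n_perm, seed = 1)
  # independent estimate with a different seed and direct rewiring
  set.seed(2)
  hits <- 0
  for (b in seq_len(n_perm)) {
    rn <- mirsignet:::rewire_network(other)
    keys <- mirsignet:::edge_keys(rn)
    if (mirsignet:::is_clique_in(module, rn$nodes, keys)) hits <- hits + 1
  }
  q_hat <- (1 + hits) / (n_perm + 1)
  se <- sqrt(q_hat * (1 - q_hat) / n_perm)
  expect_lt(abs(p_hat - q_hat), 4 * se + 2 / n_perm)
  # and the estimate is materially off the add-one floor for this fixture
  expect_gt(p_hat, 5 / (n_perm + 1))
})

test_that("signature-module selection recovers planted truth and honors ranking", {
  w <- simulate_association_world(n_groups = 6, group_size = 40,
                                  n_background = 24,
                                  planted_module_sizes = 3:4, seed = 42)
  res <- run_association_world(w, n_perm = 99, seed = 42)
  mods <- res$modules
  rec <- module_recovery(mods, w$truth$planted_modules)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  # every reported module is a clique in exactly one pruned network (recheck)
  for (i in seq_len(nrow(mods))) {
    members <- strsplit(mods$members[i], ";")[[1]]
    expect_identical(exclusivity_census(members, res$networks), 1L)
  }
  # reported modules for a group are mutually non-nested
  for (grp in unique(mods$group)) {
    sets <- strsplit(mods$members[mods$group == grp], ";")
    if (length(sets) < 2) next
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i != j) expect_false(all(sets[[i]] %in% sets[[j]]))
    }
  }
  # ranking: q ascending then density descending then size descending
  expect_true(!is.unsorted(mods$q_value))
  # determinism: identical seed reproduces the identical report
  res2 <- run_association_world(w, n_perm = 99, seed = 42)
  expect_identical(res2$modules, mods)
})

test_that("empty and sub-threshold collections yield empty reports", {
  # no candidates pass: all-tied weights prune to nothing
  pairs <- t(utils::combn(paste0("n", 1:5), 2))
  net <- prune_top_decile(network_from_pairs(pairs,
                                             weights = rep(0.8, nrow(pairs))))
  expect_message(mods <- select_signature_modules(list(G1 = net), n_perm = 9,
                                                  seed = 1),
                 "no candidate")
  expect_identical(nrow(mods), 0L)
})
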
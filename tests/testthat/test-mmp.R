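test_that("single-cut enumeration matches hand enumeration", {
  # benzene: no acyclic single bonds
  expect_equal(nrow(enumerate_cuts("c1ccccc1")), 0)
  # toluene: exactly one exocyclic C-c bond
  cuts <- enumerate_cuts("Cc1ccccc1", max_substituent_fraction = 1)
  expect_equal(nrow(cuts), 1)
  expect_equal(cuts$core, "*c1ccccc1")
  expect_equal(cuts$substituent, "*C")
  expect_equal(cuts$core_atoms, 6)
  expect_equal(cuts$substituent_atoms, 1)
  # n-butane: three C-C bonds; the 33% size rule removes the central cut
  # (2-atom substituent > 4/3 atoms) and keeps the two terminal methyls
  b <- enumerate_cuts("CCCC")
  expect_equal(nrow(b), 2)
  expect_true(all(b$substituent == "*C"))
  b_all <- enumerate_cuts("CCCC", max_substituent_fraction = 1)
  expect_equal(nrow(b_all), 3)
})

test_that("every cut reassembles to its parent molecule", {
  smis <- c("CCCCCC(=O)O", "COc1ccccc1C", "CCc1ccccc1", "CC(C)CC(N)=O")
  for (s in smis) {
    cuts <- enumerate_cuts(s, max_substituent_fraction = 1)
    parent <- pcmscreen:::canonicalize_smiles(s)
    for (k in seq_len(nrow(cuts))) {
      expect_equal(pcmscreen:::mmp_join(cuts$core[k], cuts$substituent[k]),
                   parent, info = paste(s, "cut", k))
    }
  }
})

test_that("the toluene / ethylbenzene pair is found exactly once", {
  cmp <- tibble::tibble(id = c("toluene", "ethylbenzene"),
                        smiles = c("Cc1ccccc1", "CCc1ccccc1"))
  pairs <- find_mmps(cmp, max_substituent_fraction = 1)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$core, "*c1ccccc1")
  expect_setequal(c(pairs$substituent_a, pairs$substituent_b), c("*C", "*CC"))
})

test_that("identical structures under different ids never pair", {
  cmp <- tibble::tibble(id = c("a", "b"),
                        smiles = c("Cc1ccccc1", "Cc1ccccc1"))
  expect_equal(nrow(find_mmps(cmp, max_substituent_fraction = 1)), 0)
})

test_that("pair discovery equals the quadratic all-pairs oracle", {
  cmp <- simulate_compounds(n_compounds = 25, seed = 99)
  got <- find_mmps(cmp)
  got_keys <- sort(paste(got$compound_a, got$compound_b, got$core,
                         sep = "|"))
  expect_identical(got_keys, mmp_oracle(cmp))
})

test_that("pair output is invariant under input permutation", {
  cmp <- simulate_compounds(n_compounds = 12, seed = 31)
  p1 <- find_mmps(cmp)
  p2 <- find_mmps(cmp[sample(nrow(cmp)), ])
  expect_identical(p1, p2)
})

test_that("the chemical-space network annotates argmax targets and components", {
  cmp <- simulate_compounds(n_compounds = 15, seed = 8)
  pairs <- find_mmps(cmp)
  screening <- tidyr::expand_grid(compound_id = cmp$id,
                                  target_id = c("NR_A", "NR_B"))
  withr::with_seed(12, screening$score <- round(stats::runif(nrow(screening)), 3))
  net <- build_network(pairs, cmp, screening)

  # argmax annotation equals per-compound brute force over the table
  for (i in seq_len(nrow(net$nodes))) {
    rows <- screening[screening$compound_id == net$nodes$id[i], ]
    expect_equal(net$nodes$best_score[i], max(rows$score))
    expect_equal(net$nodes$best_target[i],
                 rows$target_id[which.max(rows$score)])
  }
  # component count equals an independent union-find oracle
  expect_equal(max(net$nodes$component),
               components_oracle(cmp$id, pairs$compound_a, pairs$compound_b))

  # zero pairs -> all singletons
  net0 <- build_network(pairs[0, ], cmp, screening)
  expect_equal(max(net0$nodes$component), nrow(cmp))

  expect_error(build_network(pairs, cmp, screening[-1, ]), "missing")
})

test_that("network export writes GraphML with annotations", {
  cmp <- simulate_compounds(n_compounds = 10, seed = 3)
  pairs <- find_mmps(cmp)
  screening <- tidyr::expand_grid(compound_id = cmp$id, target_id = "NR_A")
  screening$score <- 0.6
  net <- build_network(pairs, cmp, screening)
  gml <- withr::local_tempfile(fileext = ".graphml")
  edges <- withr::local_tempfile(fileext = ".csv")
  write_network_graphml(net, gml, edges)
  expect_true(file.exists(gml))
  reread <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(reread), nrow(cmp))
  expect_equal(igraph::ecount(reread), nrow(pairs))
  expect_true("best_target" %in% igraph::vertex_attr_names(reread))
})
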
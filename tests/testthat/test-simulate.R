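test_that("the panel generator emits the requested family structure", {
  ps <- simulate_panel(seed = 42)
  expect_equal(nrow(ps$panel), 30)
  expect_equal(sort(unique(ps$panel$family)), 1:4)
  expect_true(all(nchar(ps$panel$sequence) == 120))
  expect_identical(ps, simulate_panel(seed = 42))

  # zero mutation rate: members identical to their ancestors
  p0 <- simulate_panel(panel_size = 8, mutation_rate = 0, seed = 1)
  anc <- p0$ancestors$sequence[p0$panel$family]
  expect_identical(p0$panel$sequence, anc)
  sim0 <- normalized_similarity(p0$panel$sequence[1], p0$panel$sequence[5])
  expect_equal(sim0, 1.0)
})

test_that("within-family similarity decreases with mutation rate", {
  p <- alignment_params()
  mean_within <- function(rate, seed) {
    ps <- simulate_panel(panel_size = 8, n_families = 2, seq_length = 60,
                         mutation_rate = rate, seed = seed)
    fam1 <- ps$panel$sequence[ps$panel$family == 1]
    mean(vapply(2:length(fam1), function(i)
      normalized_similarity(fam1[1], fam1[i], p), numeric(1)))
  }
  lo <- mean(vapply(1:5, function(s) mean_within(0.05, s), numeric(1)))
  hi <- mean(vapply(1:5, function(s) mean_within(0.5, s), numeric(1)))
  expect_gt(lo, hi)
})

test_that("the compound grammar emits valid, deterministic libraries", {
  cmp <- simulate_compounds(n_compounds = 300, seed = 42)
  expect_equal(nrow(cmp), 300)
  parsed <- vapply(cmp$smiles, function(s)
    !is.na(pcmscreen:::canonicalize_smiles(s)), logical(1))
  expect_true(all(parsed))
  expect_identical(cmp, simulate_compounds(n_compounds = 300, seed = 42))
  # grammar coverage: a long-chain carboxylic acid and an aromatic compound
  expect_true(any(cmp$chain_length >= 7 & cmp$group == "carboxyl"))
  expect_true(any(cmp$has_ring))
})

test_that("bioactivity labels follow the planted rule with consistent EC50s", {
  ps <- simulate_panel(seed = 2)
  cmp <- simulate_compounds(n_compounds = 120, seed = 3)
  bio0 <- simulate_bioactivity(ps, cmp, activity_noise = 0, seed = 4)
  # no noise: labels exactly rule-determined
  for (tg in unique(bio0$records$target_id)) {
    fam <- ps$panel$family[ps$panel$id == tg]
    expected <- ifelse(pcmscreen:::planted_rule_active(cmp, fam),
                       "active", "inactive")
    expect_identical(bio0$records$label[bio0$records$target_id == tg],
                     expected)
  }
  # EC50s reproduce the labels through the 1 uM dichotomy
  expect_identical(label_from_ec50(bio0$records$ec50), bio0$records$label)

  bio <- simulate_bioactivity(ps, cmp, activity_noise = 0.05, seed = 4)
  tab <- table(bio$records$target_id, bio$records$label)
  expect_true(all(tab > 0))
  # held-out targets come from families seen in training
  tg <- bio$targets
  expect_true(all(tg$family[tg$held_out] %in% tg$family[!tg$held_out]))
  expect_length(intersect(unique(bio$external$target_id),
                          unique(bio$records$target_id)), 0)
})

test_that("the full study wrapper is deterministic under its seed", {
  s1 <- simulate_pcm_data(n_compounds = 40, seed = 9)
  s2 <- simulate_pcm_data(n_compounds = 40, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_pcm_data(n_compounds = 40, seed = 10)
  expect_false(identical(s1$compounds$smiles, s3$compounds$smiles))
})
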
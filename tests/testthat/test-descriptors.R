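test_that("the default manifest has 187 unique, sorted names", {
  m <- default_manifest()
  expect_length(m, 187)
  expect_false(anyDuplicated(m) > 0)
  expect_identical(m, sort(m))
  # the shipped manifest file matches the registry
  shipped <- read_manifest(system.file("extdata",
                                       "descriptor_manifest_default.txt",
                                       package = "pcmscreen"))
  expect_identical(shipped, m)
})

test_that("ligand descriptors have manifest length and are finite", {
  d <- suppressMessages(ligand_descriptors(
    tibble::tibble(id = c("acid", "ring", "tiny"),
                   smiles = c("CCCCCCCC(=O)O", "COc1ccccc1", "C"))))
  expect_equal(dim(d), c(3, 188))
  expect_true(all(is.finite(as.matrix(d[, -1]))))
})

test_that("structural counts match hand-counted molecules", {
  d <- suppressMessages(ligand_descriptors(
    tibble::tibble(id = c("octanoic", "anisole", "benzene", "butanedioic"),
                   smiles = c("CCCCCCCC(=O)O", "COc1ccccc1", "c1ccccc1",
                              "OC(=O)CCC(=O)O"))))
  # octanoic acid: 8 C + 2 O heavy atoms, one carboxyl, 8-carbon chain
  expect_equal(d$L_nHeavyAtoms[1], 10)
  expect_equal(d$L_nCarboxyl[1], 1)
  expect_equal(d$L_longestCarbonChain[1], 8)
  expect_equal(d$L_nRingsSSSR[1], 0)
  # anisole: one aromatic six-ring, one methoxy
  expect_equal(d$L_nAromaticRings[2], 1)
  expect_equal(d$L_nMethoxy[2], 1)
  expect_equal(d$L_nAromaticAtoms[2], 6)
  # benzene: 6 atoms, 6 ring bonds, no rotatable bonds
  expect_equal(d$L_nHeavyAtoms[3], 6)
  expect_equal(d$L_nBondsRing[3], 6)
  expect_equal(d$L_nBondsRotatable[3], 0)
  # butanedioic (succinic) acid: two carboxyls
  expect_equal(d$L_nCarboxyl[4], 2)
})

test_that("equivalent SMILES of one molecule give identical descriptors", {
  d <- suppressMessages(ligand_descriptors(
    tibble::tibble(id = c("a", "b", "c"),
                   smiles = c("CCCCCC(=O)O", "OC(=O)CCCCC",
                              "C(CCCC)(C)C(O)=O"))))
  expect_identical(as.numeric(d[1, -1]), as.numeric(d[2, -1]))
  # the third is a different (branched) molecule
  expect_false(identical(as.numeric(d[1, -1]), as.numeric(d[3, -1])))
})

test_that("manifest subsetting and custom manifests are honored", {
  man <- c("nHeavyAtoms", "nCarboxyl", "WienerIndex")
  d <- ligand_descriptors(tibble::tibble(id = "x", smiles = "CCO"),
                          manifest = man)
  expect_equal(names(d), c("compound_id", paste0("L_", man)))
  expect_error(
    ligand_descriptors(tibble::tibble(id = "x", smiles = "CCO"),
                       manifest = "notADescriptor"),
    "registry")
})

test_that("compound reading canonicalizes and reports bad records", {
  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCCCO butanol", "C1CC broken", "c1ccccc1 benzene"), smi)
  expect_warning(cmp <- read_compounds(smi), "excluded")
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$id, c("butanol", "benzene"))
  expect_equal(attr(cmp, "problems")$id, "broken")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles", "a,CCO", "b,CCN"), csv)
  cmp2 <- read_compounds(csv)
  expect_equal(cmp2$id, c("a", "b"))
  expect_error(read_compounds(csv, smiles_col = "nope"), "missing the SMILES")

  sdf <- withr::local_tempfile(fileext = ".sdf")
  blocks <- vapply(c("CCO", "CCCN", "c1ccccc1C"), function(s)
    ChemmineOB::convertFormat("SMI", "SDF", s), character(1))
  # molecule titles live on the first molblock line
  blocks <- vapply(seq_along(blocks), function(i)
    sub("^[^\n]*", paste0("mol", i), blocks[i]), character(1))
  cat(paste0(blocks, collapse = ""), file = sdf)
  cmp3 <- read_compounds(sdf)
  expect_equal(nrow(cmp3), 3)
  expect_equal(unname(cmp3$id), c("mol1", "mol2", "mol3"))
})
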
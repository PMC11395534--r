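test_that("SMILES parsing assigns elements, aromaticity and implicit H", {
  pyr <- parse_smiles("c1ccncc1")
  expect_equal(n_atoms(pyr), 6)
  n_idx <- which(pyr$atoms$element == "N")
  expect_length(n_idx, 1)
  expect_equal(pyr$atoms$heavy_degree[n_idx], 2)
  expect_equal(pyr$atoms$implicit_h[n_idx], 0)
  expect_true(all(pyr$atoms$aromatic))
  expect_equal(sum(pyr$atoms$implicit_h), 5)

  # bracket atoms
  ur <- parse_smiles("O=c1[nH]cc(CCCI)c(=O)[nH]1")
  expect_equal(molecular_formula(ur), "C7H9IN2O2")

  # Kekule aromatic normalisation: benzene written either way is identical
  b1 <- parse_smiles("c1ccccc1")
  b2 <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(b2$atoms$aromatic))
  expect_true(molecules_isomorphic(b1, b2))
})

test_that("parse errors are raised for bad input", {
  expect_error(parse_smiles("C(C"), "unmatched")
  expect_error(parse_smiles("C1CC"), "ring")
  expect_error(parse_smiles("[Se]CC"), "unsupported element")
  expect_error(parse_smiles("C$C"), "unexpected character")
  expect_error(parse_smiles(""), "non-empty")
})

test_that("molecular weight and composition match reported analyses", {
  m41 <- parse_smiles("ClCCCc1cnc(Cl)nc1Cl")
  expect_equal(molecular_formula(m41), "C7H7Cl3N2")
  expect_equal(molecular_weight(m41), 225.50)
  expect_equal(elemental_percent(m41, "N"), 12.42)
  expect_equal(elemental_percent(m41, "C"), 37.28)
  expect_equal(elemental_percent(m41, "H"), 3.13)

  m40 <- parse_smiles("O=c1[nH]cc(CCCI)c(=O)[nH]1")
  expect_equal(molecular_weight(m40), 280.06)

  expect_equal(molecular_weight(parse_smiles("C")), 16.04)
  expect_equal(elemental_percent(parse_smiles("C"), "C"), 74.87)
  expect_equal(elemental_percent(parse_smiles("C"), "Cl"), 0)
})

test_that("elemental percents sum to 100 for every fixture molecule", {
  for (mol in fixture_molecules()) {
    els <- unique(c(mol$atoms$element, "H"))
    total <- sum(vapply(els, function(e)
      elemental_percent(mol, e, digits = NULL), numeric(1)))
    expect_equal(total, 100, tolerance = 1e-10)
  }
})

test_that("distance matrix matches shortest-path expectations and oracle", {
  prop <- parse_smiles("CCC")
  expect_equal(distance_matrix(prop)[1, 3], 2L)
  benz <- parse_smiles("c1ccccc1")
  expect_equal(max(distance_matrix(benz)), 3L)
  pyr <- parse_smiles("c1ccncc1")
  d <- distance_matrix(pyr)
  n_idx <- which(pyr$atoms$element == "N")
  expect_equal(max(d[n_idx, ]), 3L)   # para carbon

  for (mol in fixture_molecules()) {
    expect_equal(distance_matrix(mol), floyd_warshall(mol),
                 ignore_attr = TRUE)
  }
})

test_that("disconnected graphs are rejected by distance_matrix", {
  frag <- parse_smiles("CC.CC")
  expect_error(distance_matrix(frag), "disconnected")
})

test_that("parse -> write -> parse round-trips to an isomorphic graph", {
  for (mol in fixture_molecules()) {
    rt <- parse_smiles(write_smiles(mol))
    expect_true(molecules_isomorphic(mol, rt), label = mol$name)
  }
})

test_that("smi and csv readers load molecules with activities", {
  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
  mols <- read_smi(smi)
  expect_length(mols, 2)
  expect_equal(mols[[2]]$name, "benzene")

  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,name,ic50_uM", "CCO,ethanol,4.24", "CCN,amine,> 100"),
             csv)
  df <- read_molecules_csv(csv)
  expect_equal(round(df$pic50[1], 2), 5.37)
  expect_true(df$censored[2])
  expect_equal(df$pic50[2], 4)

  blind <- blind_validation_compounds()
  expect_length(blind, 4)
  expect_equal(molecular_formula(blind$compound_43), "C9H13ClN2O2")
})
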
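test_that("centered autocorrelation matches hand calculations", {
  # 3-atom path with weights (1,2,3): centered (-1,0,1)
  d3 <- distance_matrix(parse_smiles("CCC"))
  expect_equal(pyrimqsar:::.atsc_from_parts(d3, c(1, 2, 3), 1, FALSE), 0)
  expect_equal(pyrimqsar:::.atsc_from_parts(d3, c(1, 2, 3), 2, FALSE), -1)
  # 2-atom molecule, weights (1,3): -((a-b)/2)^2
  d2 <- distance_matrix(parse_smiles("CC"))
  expect_equal(pyrimqsar:::.atsc_from_parts(d2, c(1, 3), 1, FALSE), -1)
  # ordered convention doubles ATSC
  expect_equal(pyrimqsar:::.atsc_from_parts(d3, c(1, 2, 3), 2, TRUE), -2)
})

test_that("constant weights annihilate centered autocorrelations", {
  benz <- parse_smiles("c1ccccc1")
  for (k in 1:3) {
    expect_equal(atsc(benz, k, "e"), 0, tolerance = 1e-14)
    expect_equal(aatsc(benz, k, "s"), 0, tolerance = 1e-14)
    expect_equal(atsc(benz, k, "p"), 0, tolerance = 1e-14)
  }
})

test_that("AATSC equals ATSC over the pair count", {
  cfg <- descriptor_config()
  for (mol in fixture_molecules()) {
    for (k in 1:4) {
      cnt <- pair_count(mol, k, cfg)
      a <- atsc(mol, k, "e", cfg)
      aa <- aatsc(mol, k, "e", cfg)
      if (cnt == 0) expect_equal(aa, 0) else expect_equal(aa, a / cnt)
    }
  }
})

test_that("pair counts partition all atom pairs", {
  benz <- parse_smiles("c1ccccc1")
  expect_equal(pair_count(benz, 1), 6L)
  expect_equal(pair_count(benz, 3), 3L)
  for (mol in fixture_molecules()) {
    a <- n_atoms(mol)
    total <- sum(vapply(1:(a), function(k) pair_count(mol, k), integer(1)))
    expect_equal(total, a * (a - 1) / 2)
  }
  # ordered convention doubles counts
  cfg_o <- descriptor_config(ordered_pairs = TRUE)
  expect_equal(pair_count(benz, 1, cfg_o), 12L)
})

test_that("atsc agrees with the brute-force double-loop oracle", {
  for (mol in fixture_molecules()) {
    d <- distance_matrix(mol)
    for (scheme in c("s", "e", "p", "c")) {
      w <- switch(scheme,
                  s = intrinsic_state(mol)$values,
                  e = sanderson_en(mol)$values,
                  p = polarizability(mol)$values,
                  c = partial_charges(mol)$values)
      for (k in c(1, 2, 3, 5)) {
        expect_equal(atsc(mol, k, scheme), atsc_bruteforce(d, w, k),
                     tolerance = 1e-12,
                     label = paste(mol$name, scheme, k))
      }
    }
  }
})

test_that("autocorrelations are invariant under atom relabelling", {
  set.seed(7)
  mols <- generate_library(20, seed = 99)
  cfg <- published_descriptor_config()
  for (mol in mols[1:10]) {
    ref <- model_descriptors(mol, config = cfg)
    perm <- sample(nrow(mol$atoms))
    per <- model_descriptors(permute_molecule(mol, perm), config = cfg)
    for (dn in c("AATSC2s", "ATSC4c", "ATSC3e", "AATSC6p", "MDEN-23")) {
      expect_equal(per[[dn]], ref[[dn]], tolerance = 1e-10, label = dn)
    }
  }
})

test_that("scaling a weighting by c scales ATSC by c^2", {
  d <- distance_matrix(parse_smiles("CCOCC"))
  w <- c(1, 2.5, 7, 0.3, 4)
  for (k in 1:3) {
    a1 <- pyrimqsar:::.atsc_from_parts(d, w, k, FALSE)
    a3 <- pyrimqsar:::.atsc_from_parts(d, 3 * w, k, FALSE)
    expect_equal(a3, 9 * a1, tolerance = 1e-12)
  }
})

test_that("descriptor pool lays out lags, schemes and MDEN columns", {
  mols <- list(parse_smiles("CCO", name = "ethanol"),
               parse_smiles("c1ccncc1", name = "pyridine"))
  pool <- descriptor_pool(mols, lags = 1:4, schemes = c("s", "e"))
  expect_true(all(c("ATSC2s", "AATSC2s", "ATSC4e", "MDEN-23") %in%
                  names(pool)))
  expect_equal(nrow(pool), 2)
  expect_true(all(is.finite(as.matrix(pool[, -(1:2)]))))
  # consistency with the single-descriptor entry points
  expect_equal(pool$ATSC3e[2], atsc(mols[[2]], 3, "e"), tolerance = 1e-12)
  expect_equal(pool$AATSC2s[1], aatsc(mols[[1]], 2, "s"), tolerance = 1e-12)
})

test_that("model_descriptors returns the five published descriptors", {
  benzene <- parse_smiles("c1ccccc1", name = "benzene")
  d <- model_descriptors(benzene)
  expect_named(d, c("name", "smiles", "AATSC2s", "MDEN-23", "ATSC4c",
                    "ATSC3e", "AATSC6p"))
  expect_equal(d$`MDEN-23`, 0)
  # on the heavy-atom graph a homo-atomic ring has zero centered weights
  d_heavy <- model_descriptors(benzene, config = descriptor_config())
  expect_equal(d_heavy$AATSC2s, 0, tolerance = 1e-12)
  expect_equal(d_heavy$ATSC3e, 0, tolerance = 1e-12)
})
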
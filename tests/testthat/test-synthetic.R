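test_that("library generation is valid, distinct and deterministic", {
  mols <- generate_library(39, seed = 7)
  expect_length(mols, 39)
  smiles <- vapply(mols, `[[`, character(1), "smiles")
  expect_equal(anyDuplicated(smiles), 0)
  for (mol in mols) {
    # every molecule parses and carries the two-azine ring nitrogen core
    expect_gte(sum(mol$atoms$element == "N"), 2)
    expect_true(is.finite(molecular_weight(mol)))
  }
  again <- generate_library(39, seed = 7)
  expect_identical(smiles, vapply(again, `[[`, character(1), "smiles"))
  different <- generate_library(39, seed = 8)
  expect_false(identical(smiles,
                         vapply(different, `[[`, character(1), "smiles")))
})

test_that("requesting more molecules than the grammar allows errors", {
  space <- nrow(pyrimqsar:::.enumerate_library(scaffold_grammar()))
  expect_error(generate_library(space + 1), "exhausted")
})

test_that("generation does not disturb the session RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_library(5, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("every generated molecule runs through the full pipeline", {
  mols <- generate_library(15, seed = 31)
  d <- model_descriptors(mols)
  expect_true(all(is.finite(as.matrix(d[, -(1:2)]))))
  p <- predict(published_model(), d)
  expect_true(all(is.finite(p)))
})

test_that("noiseless planted activities are exactly recovered by OLS", {
  mols <- generate_library(25, seed = 17)
  planted <- planted_model(sigma = 0)
  y <- plant_activities(mols, planted, seed = 5)
  pool <- attr(y, "descriptors")
  X <- as.matrix(pool[, planted$descriptor_names])
  fit <- fit_ols(X, as.numeric(y))
  expect_equal(unname(fit$coefficients),
               unname(attr(y, "true_coefficients")), tolerance = 1e-8)
  expect_equal(fit$training_meta$R2, 1, tolerance = 1e-10)
})

test_that("planted activities span the configured range", {
  mols <- generate_library(39, seed = 7)
  y <- plant_activities(mols, planted_model(sigma = 0), seed = 2,
                        activity_range = c(4.1, 6.52))
  expect_equal(range(as.numeric(y)), c(4.1, 6.52), tolerance = 1e-10)
})

test_that("coefficient recovery degrades monotonically with noise", {
  mols <- generate_library(31, seed = 23)
  planted0 <- planted_model(sigma = 0)
  pool <- attr(plant_activities(mols, planted0, seed = 1), "descriptors")
  X <- as.matrix(pool[, planted0$descriptor_names])
  err_at <- function(sigma) {
    errs <- vapply(1:10, function(r) {
      pl <- planted_model(sigma = sigma)
      y <- plant_activities(mols, pl, seed = 100 + r)
      fit <- fit_ols(X, as.numeric(y))
      sqrt(mean((unname(fit$coefficients) -
                 unname(attr(y, "true_coefficients")))^2))
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0, 0.1, 0.3, 1.0), err_at, numeric(1))
  expect_true(all(diff(errs) > 0))
  expect_lt(errs[1], 1e-8)
})

test_that("the grouped fixture mirrors the modelled dataset layout", {
  fx <- grouped_fixture(seed = 7)
  expect_equal(nrow(fx), 39)
  expect_equal(as.integer(table(fx$group)), c(5L, 15L, 19L))
  s <- intuitive_rational_split(fx, 0.2)
  expect_equal(nrow(s$train), 31)
  expect_equal(nrow(s$test), 8)
  expect_identical(fx$pic50, grouped_fixture(seed = 7)$pic50)
})
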
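ols_oracle <- function(X, y) {
  # brute-force normal equations
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% Xi, t(Xi) %*% y)
}

test_that("fit_ols matches the normal-equations oracle and statistics", {
  set.seed(101)
  X <- matrix(rnorm(6), 6, 1, dimnames = list(NULL, "x1"))
  y <- 2 + 3 * X[, 1] + rnorm(6, sd = 0.3)
  fit <- fit_ols(X, y)
  beta <- ols_oracle(X, y)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), beta[2], tolerance = 1e-10)
  # statistics agree with lm
  lf <- lm(y ~ X)
  expect_equal(fit$training_meta$R2, summary(lf)$r.squared, tolerance = 1e-10)
  expect_equal(unname(fit$t_values["x1"]),
               summary(lf)$coefficients[2, "t value"], tolerance = 1e-8)
  expect_equal(fit$training_meta$F,
               unname(summary(lf)$fstatistic["value"]), tolerance = 1e-8)

  # perfect linear data
  yy <- 1 + 2 * X[, 1]
  pf <- fit_ols(X, yy)
  expect_equal(pf$training_meta$R2, 1, tolerance = 1e-12)
  expect_lt(pf$training_meta$rss, 1e-20)

  expect_error(fit_ols(cbind(x1 = X[, 1], x2 = X[, 1]), y), "rank")
})

test_that("q2_loo hat shortcut equals the explicit refit loop", {
  set.seed(202)
  for (rep in 1:5) {
    X <- matrix(rnorm(25 * 3), 25, 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- 1 + X %*% c(1, -0.5, 0.2) + rnorm(25, sd = 0.4)
    expect_equal(q2_loo(X, y, method = "hat"),
                 q2_loo(X, y, method = "refit"), tolerance = 1e-10)
  }
  # perfect noiseless data -> q2 = 1
  X <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- 2 + X %*% c(1, 1)
  expect_equal(q2_loo(X, drop(y)), 1, tolerance = 1e-10)
})

test_that("q2 does not exceed R2 on pure-noise responses", {
  set.seed(303)
  worse <- 0
  for (rep in 1:100) {
    X <- matrix(rnorm(30 * 3), 30, 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(30)
    r2 <- fit_ols(X, y)$training_meta$R2
    q2 <- q2_loo(X, y)
    if (q2 > r2) worse <- worse + 1
  }
  expect_lte(worse, 1)   # q2 <= R2 in >= 99/100 replicates
})

test_that("external R2 conventions behave as defined", {
  m <- qsar_model(c("a", "b"), c(1, 2), 0.5)
  X <- data.frame(a = rnorm(5), b = rnorm(5))
  y <- predict(m, X)
  expect_equal(as.numeric(r2_external(m, X, y)), 1, tolerance = 1e-12)
  # linear transform of observations still gives 1 under correlation
  expect_equal(as.numeric(r2_external(m, X, 2 * y + 3)), 1,
               tolerance = 1e-12)
  # but not under the predictive convention
  expect_lt(as.numeric(r2_external(m, X, 2 * y + 3,
                                   convention = "predictive")), 1)
  Xc <- data.frame(a = rep(1, 5), b = rep(2, 5))
  expect_error(r2_external(m, Xc, y), "constant predictions")
  expect_error(r2_external(m, X[1:2, ], y[1:2]), "at least 3")
})

test_that("prune_pool removes constant and missing-value columns", {
  X <- data.frame(good = rnorm(10), const = rep(1, 10),
                  holey = c(NA, rnorm(9)), fine = runif(10))
  out <- prune_pool(X)
  expect_named(out, c("good", "fine"))
  expect_setequal(attr(out, "removed"), c("const", "holey"))
  expect_identical(names(prune_pool(X[, c("good", "fine")])),
                   c("good", "fine"))
  expect_error(prune_pool(data.frame(const = rep(1, 5))), "empty")
})

test_that("bmlr at k = 2 equals exhaustive search over admissible pairs", {
  exhaustive_pair <- function(X, y, collinearity_r2 = 0.6, t_min = 2) {
    cn <- colnames(X)
    best <- NULL
    for (i in seq_len(ncol(X) - 1)) for (j in (i + 1):ncol(X)) {
      if (cor(X[, i], X[, j])^2 >= collinearity_r2) next
      f <- fit_ols(X[, c(i, j)], y)
      if (min(abs(f$t_values)) < t_min) next
      r2 <- f$training_meta$R2
      if (is.null(best) || r2 > best$r2 + 1e-12) {
        best <- list(r2 = r2, names = sort(cn[c(i, j)]))
      }
    }
    best
  }
  set.seed(404)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 12), 40, 12,
                dimnames = list(NULL, sprintf("x%02d", 1:12)))
    y <- 1 + 2 * X[, 3] - 1.5 * X[, 8] + rnorm(40, sd = 0.5)
    m <- bmlr_select(X, y, max_k = 2)
    oracle <- exhaustive_pair(X, y)
    expect_equal(sort(m$descriptor_names), oracle$names)
    expect_equal(m$training_meta$R2, oracle$r2, tolerance = 1e-10)
  }
})

test_that("a planted two-descriptor signal is found in nearly all draws", {
  set.seed(505)
  found <- 0
  for (rep in 1:100) {
    X <- matrix(rnorm(40 * 20), 40, 20,
                dimnames = list(NULL, sprintf("x%02d", 1:20)))
    y <- 3 * X[, 1] - 2 * X[, 5] + rnorm(40, sd = 0.1)
    m <- bmlr_select(X, y, max_k = 2)
    if (setequal(m$descriptor_names, c("x01", "x05"))) found <- found + 1
  }
  expect_gte(found, 95)
})

test_that("collinear descriptors are never co-selected", {
  set.seed(606)
  for (rep in 1:10) {
    X <- matrix(rnorm(40 * 8), 40, 8,
                dimnames = list(NULL, paste0("x", 1:8)))
    X[, 2] <- X[, 1] + rnorm(40, sd = 0.05)   # pairwise R2 far above 0.6
    y <- 2 * X[, 1] + X[, 4] + rnorm(40, sd = 0.3)
    m <- bmlr_select(X, y, max_k = 4)
    expect_false(all(c("x1", "x2") %in% m$descriptor_names))
    C2 <- cor(X[, m$descriptor_names])^2
    expect_true(all(C2[upper.tri(C2)] < 0.6))
  }
})

test_that("natural-scale report reproduces the scaled-search fit", {
  set.seed(707)
  X <- matrix(rnorm(35 * 10), 35, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- 1 + X[, 2] - 2 * X[, 7] + rnorm(35, sd = 0.2)
  m <- bmlr_select(X, y, max_k = 3)
  # refit on the scaled matrix over the same subset: fitted values must match
  Xs <- scale(X[, m$descriptor_names])
  fs <- fit_ols(Xs, y)
  nat_fitted <- predict(m, as.data.frame(X[, m$descriptor_names]))
  expect_equal(nat_fitted, fs$fitted, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("planted coefficients are recovered within two standard errors", {
  # ~95% of coefficients should sit within 2 SE of truth; check coverage
  # over 20 replicates (100 coefficients) rather than one fragile draw
  set.seed(808)
  beta <- c(1.2, -0.8, 0.5, 0.9, -0.6)
  covered <- 0
  for (rep in 1:20) {
    X <- matrix(rnorm(31 * 5), 31, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    y <- 2 + drop(X %*% beta) + rnorm(31, sd = sqrt(0.0485))
    fit <- fit_ols(X, y)
    se <- abs(unname(fit$coefficients) / unname(fit$t_values))
    covered <- covered + sum(abs(unname(fit$coefficients) - beta) <= 2 * se)
  }
  expect_gte(covered, 90)
})
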
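# Best Multi-Linear Regression: stepwise forward descriptor selection under
# pairwise-noncollinearity and coefficient-significance constraints, plus the
# internal/external validation statistics used to judge the resulting models.
#
# Search strategy: all non-collinear descriptor pairs are ranked by R2; the
# top `beam` significant two-descriptor seeds are each extended greedily,
# adding at every step the descriptor that maximises R2 subject to (i)
# pairwise squared correlation < collinearity_r2 with every descriptor
# already in the model and (ii) |t| >= t_min for every coefficient after
# refit. The search runs on centered/scaled descriptors; the reported model
# is refit in natural scale (identical fitted values).

.as_matrix_X <- function(X) {
  if (is.data.frame(X)) {
    keep <- vapply(X, is.numeric, logical(1))
    X <- X[, keep, drop = FALSE]
  }
  as.matrix(X)
}

#' Ordinary least squares fit with QSAR fit statistics
#'
#' @param X Descriptor matrix or data.frame (columns named).
#' @param y Activity vector (pIC50).
#' @param descriptor_names Optional subset of columns to fit on.
#' @param config Optional `descriptor_config` recorded on the model.
#' @return A `qsar_model` whose `training_meta` holds `N`, `k`, `R2`, `s2`
#'   (residual variance RSS/(N-k-1)), `F`, `rss`, and per-coefficient
#'   `t_values`; residuals and fitted values are attached as `residuals` and
#'   `fitted`.
#' @export
fit_ols <- function(X, y, descriptor_names = NULL,
                    config = descriptor_config()) {
  X <- .as_matrix_X(X)
  if (!is.null(descriptor_names)) X <- X[, descriptor_names, drop = FALSE]
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2) stop("need N >= k + 2 observations")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xi)
  if (qrx$rank < ncol(Xi)) stop("rank-deficient descriptor matrix")
  beta <- qr.coef(qrx, y)
  fitted <- drop(Xi %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  df <- n - k - 1
  s2 <- rss / df
  fstat <- if (k > 0 && r2 < 1) (r2 / k) / ((1 - r2) / df) else Inf
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(pmax(diag(xtx_inv), 0) * s2)
  tvals <- beta / se
  m <- qsar_model(colnames(X), unname(beta[-1]), unname(beta[1]),
                  t_values = stats::setNames(tvals[-1], colnames(X)),
                  training_meta = list(N = n, k = k, R2 = r2, s2 = s2,
                                       F = fstat, rss = rss),
                  config = config)
  m$fitted <- fitted
  m$residuals <- resid
  m$intercept_t <- unname(tvals[1])
  m
}

#' Leave-one-out cross-validated q2
#'
#' \deqn{q^2 = 1 - PRESS/TSS} where PRESS is the prediction sum of squares
#' from N refits each leaving one compound out. The default uses the exact
#' hat-matrix shortcut \eqn{e_{(i)} = e_i / (1 - h_{ii})}; `method = "refit"`
#' performs the N explicit refits (both agree to machine precision).
#'
#' @param X Descriptor matrix or data.frame.
#' @param y Activity vector.
#' @param descriptor_names Optional subset of columns.
#' @param method `"hat"` (default) or `"refit"`.
#' @return The cross-validated coefficient q2 (a.k.a. RCV2).
#' @export
q2_loo <- function(X, y, descriptor_names = NULL,
                   method = c("hat", "refit")) {
  method <- match.arg(method)
  X <- .as_matrix_X(X)
  if (!is.null(descriptor_names)) X <- X[, descriptor_names, drop = FALSE]
  n <- nrow(X)
  if (n < ncol(X) + 3) stop("need N >= k + 3 for leave-one-out validation")
  tss <- sum((y - mean(y))^2)
  if (method == "hat") {
    fit <- fit_ols(X, y)
    h <- leverages(X)
    press <- sum((fit$residuals / (1 - h))^2)
  } else {
    press <- 0
    for (i in seq_len(n)) {
      fit_i <- fit_ols(X[-i, , drop = FALSE], y[-i])
      pred_i <- fit_i$intercept +
        sum(fit_i$coefficients * X[i, colnames(X)])
      press <- press + (y[i] - pred_i)^2
    }
  }
  1 - press / tss
}

#' External validation R2 on a held-out test set
#'
#' @param model A `qsar_model`.
#' @param X_test Descriptor matrix/data.frame for the test compounds.
#' @param y_test Observed activities.
#' @param convention `"correlation"` (default): squared Pearson correlation
#'   between predictions and observations; `"predictive"`:
#'   `1 - RSS_test/TSS_test` about the observed test mean.
#' @return Rtest2 with the convention attached as attribute `"convention"`.
#' @export
r2_external <- function(model, X_test, y_test,
                        convention = c("correlation", "predictive")) {
  convention <- match.arg(convention)
  if (length(y_test) < 3) stop("need at least 3 test compounds")
  pred <- predict(model, X_test)
  val <- if (convention == "correlation") {
    if (stats::sd(pred) == 0) stop("constant predictions: Rtest2 undefined")
    stats::cor(pred, y_test)^2
  } else {
    1 - sum((y_test - pred)^2) / sum((y_test - mean(y_test))^2)
  }
  structure(val, convention = convention)
}

#' Prune a descriptor pool
#'
#' Removes descriptor columns containing missing values and columns with zero
#' variance, as required before stepwise selection.
#'
#' @param X Descriptor data.frame or matrix (numeric columns are candidates;
#'   non-numeric columns such as `name`/`smiles` are passed through).
#' @param verbose Message the removal log?
#' @return The pruned object, with attribute `"removed"` naming dropped
#'   columns.
#' @export
prune_pool <- function(X, verbose = FALSE) {
  is_df <- is.data.frame(X)
  num_cols <- if (is_df) names(X)[vapply(X, is.numeric, logical(1))]
              else colnames(X)
  removed <- character(0)
  for (cn in num_cols) {
    v <- if (is_df) X[[cn]] else X[, cn]
    if (anyNA(v) || !all(is.finite(v)) || stats::var(v) == 0) {
      removed <- c(removed, cn)
    }
  }
  out <- if (is_df) X[, setdiff(names(X), removed), drop = FALSE]
         else X[, setdiff(colnames(X), removed), drop = FALSE]
  left <- intersect(if (is_df) names(out) else colnames(out), num_cols)
  if (!length(left)) stop("empty descriptor pool after pruning")
  if (verbose && length(removed)) {
    message("pruned ", length(removed), " column(s): ",
            paste(removed, collapse = ", "))
  }
  attr(out, "removed") <- removed
  out
}

#' BMLR forward descriptor selection
#'
#' Selects up to `max_k` descriptors by beam-seeded greedy forward selection:
#' the `beam` best significant non-collinear two-descriptor models are grown
#' one descriptor at a time, each addition maximising R2 under the pairwise
#' collinearity bound and the per-coefficient significance gate. The search
#' operates on centered/scaled descriptors; the returned model is in natural
#' scale. Deterministic: ties in R2 break by larger minimum |t|, then by
#' descriptor names.
#'
#' @param X Descriptor matrix/data.frame (numeric columns only are used).
#' @param y Activity vector.
#' @param max_k Maximum number of descriptors (>= 2).
#' @param collinearity_r2 Pairwise squared-correlation bound; descriptor pairs
#'   at or above it never co-occur (default 0.6).
#' @param beam Number of two-descriptor seeds to extend (default 20).
#' @param t_min Significance gate: every coefficient must satisfy
#'   `|t| >= t_min` (default 2).
#' @return A `qsar_model` fitted in natural scale, with `q2` added to its
#'   `training_meta`.
#' @export
bmlr_select <- function(X, y, max_k = 5, collinearity_r2 = 0.6, beam = 20,
                        t_min = 2) {
  Xm <- .as_matrix_X(X)
  stopifnot(max_k >= 2)
  n <- nrow(Xm)
  if (n <= max_k + 2) stop("need N > max_k + 2")
  Xs <- scale(Xm)                      # search scale
  p <- ncol(Xs)
  cols <- colnames(Xs)
  cors <- stats::cor(Xs)
  compatible <- cors^2 < collinearity_r2
  tss <- sum((y - mean(y))^2)

  score <- function(subset) {
    Xi <- cbind(1, Xs[, subset, drop = FALSE])
    qrx <- qr(Xi)
    if (qrx$rank < ncol(Xi)) stop("rank deficient")
    beta <- qr.coef(qrx, y)
    resid <- y - drop(Xi %*% beta)
    rss <- sum(resid^2)
    s2 <- rss / (n - ncol(Xi))
    se <- sqrt(pmax(diag(chol2inv(qr.R(qrx))), 0) * s2)
    list(r2 = 1 - rss / tss, tmin = min(abs(beta[-1] / se[-1])))
  }
  passes_gate <- function(subset) {
    sc <- tryCatch(score(subset), error = function(e) NULL)
    if (is.null(sc) || sc$tmin < t_min) NULL else sc
  }

  # --- two-descriptor seeding: closed-form pair R2 from the correlations ---
  ryx <- drop(stats::cor(Xs, y))
  num <- outer(ryx^2, ryx^2, "+") - 2 * outer(ryx, ryx) * cors
  denom <- 1 - cors^2
  R2pair <- ifelse(abs(denom) > 1e-10, num / denom, -Inf)
  R2pair[!compatible] <- -Inf
  R2pair[lower.tri(R2pair, diag = TRUE)] <- -Inf
  if (!any(is.finite(R2pair) & R2pair > -Inf)) {
    stop("no admissible non-collinear descriptor pair")
  }
  ij <- which(R2pair > -Inf, arr.ind = TRUE)
  pair_names <- paste(pmin(cols[ij[, 1]], cols[ij[, 2]]),
                      pmax(cols[ij[, 1]], cols[ij[, 2]]))
  ord <- order(-R2pair[ij], pair_names)
  seeds <- lapply(utils::head(ord, beam),
                  function(k) c(ij[k, 1], ij[k, 2]))
  # diversity seeds: for every descriptor, its best admissible partner.
  # A pure top-R2 pair list tends to concentrate on one collinear cluster,
  # which leaves whole regions of the pool unexplored by the greedy phase.
  R2sym <- R2pair
  R2sym[lower.tri(R2sym)] <- t(R2pair)[lower.tri(R2pair)]
  for (j in seq_len(p)) {
    if (!any(is.finite(R2sym[j, ]))) next
    partner <- which.max(R2sym[j, ])
    seeds[[length(seeds) + 1]] <- sort(c(j, partner))
  }
  seeds <- unique(lapply(seeds, sort))

  # residual of y and candidate delta-RSS after orthogonalisation against
  # the current subset (vectorised over candidates)
  forward_deltas <- function(subset, cand) {
    Xi <- cbind(1, Xs[, subset, drop = FALSE])
    qrx <- qr(Xi)
    r <- qr.resid(qrx, y)
    Z <- qr.resid(qrx, Xs[, cand, drop = FALSE])
    d2 <- colSums(Z^2)
    delta <- ifelse(d2 > 1e-8, drop(crossprod(Z, r))^2 / d2, -Inf)
    list(delta = delta, rss = sum(r^2))
  }

  add_best <- function(subset) {
    cand <- setdiff(seq_len(p), subset)
    cand <- cand[vapply(cand, function(j) all(compatible[j, subset]),
                        logical(1))]
    if (!length(cand)) return(NULL)
    fd <- forward_deltas(subset, cand)
    ord <- order(-fd$delta, cols[cand])
    for (k in utils::head(ord, 8)) {          # best few, gate-checked in turn
      if (!is.finite(fd$delta[k])) break
      sc <- passes_gate(c(subset, cand[k]))
      if (!is.null(sc)) return(c(subset, cand[k]))
    }
    NULL
  }

  grow <- function(subset) {
    while (length(subset) < max_k) {
      nxt <- add_best(subset)
      if (is.null(nxt)) break
      subset <- nxt
    }
    subset
  }

  # frontier beam search over subset sizes. Every admissible one-descriptor
  # extension of every frontier subset is scored exactly (the orthogonalised
  # delta-RSS gives the child R2 without refitting), the best `width`
  # children by R2 form the next frontier, and the best significance-gated
  # subset is recorded per size.
  beam_search <- function(seed_list, width = 2L * beam) {
    frontier <- unique(lapply(seed_list, sort))
    best_gated <- vector("list", max_k)
    note_gated <- function(size) {
      scs <- lapply(frontier, passes_gate)
      keep <- !vapply(scs, is.null, logical(1))
      if (!any(keep)) return()
      fr <- frontier[keep]; scs <- scs[keep]
      o <- order(-vapply(scs, `[[`, numeric(1), "r2"),
                 -vapply(scs, `[[`, numeric(1), "tmin"),
                 vapply(fr, function(s) paste(cols[s], collapse = "|"),
                        character(1)))
      best_gated[[size]] <<- fr[[o[1]]]
    }
    # rank the seed frontier by R2 before the first pruning
    sr2 <- vapply(frontier, function(s)
      tryCatch(score(s)$r2, error = function(e) -Inf), numeric(1))
    frontier <- frontier[utils::head(order(-sr2), width)]
    note_gated(2L)
    size <- 2L
    while (size < max_k) {
      child_key <- character(0)
      child_sub <- list()
      child_r2 <- numeric(0)
      for (s in frontier) {
        cand <- setdiff(seq_len(p), s)
        cand <- cand[vapply(cand, function(j) all(compatible[j, s]),
                            logical(1))]
        if (!length(cand)) next
        fd <- forward_deltas(s, cand)
        ok <- is.finite(fd$delta)
        if (!any(ok)) next
        subs <- lapply(cand[ok], function(j) sort(c(s, j)))
        keys <- vapply(subs, paste, character(1), collapse = ",")
        new <- !keys %in% child_key
        child_key <- c(child_key, keys[new])
        child_sub <- c(child_sub, subs[new])
        child_r2 <- c(child_r2, (1 - (fd$rss - fd$delta[ok]) / tss)[new])
      }
      if (!length(child_sub)) break
      o <- order(-child_r2, child_key)
      frontier <- child_sub[utils::head(o, width)]
      size <- size + 1L
      note_gated(size)
    }
    Filter(Negate(is.null), best_gated)
  }

  # improvement phase: single-descriptor exchanges plus drop-two/regrow
  # moves, each accepted only when R2 strictly improves and every
  # coefficient stays significant; terminates since R2 increases.
  refine <- function(subset) {
    if (length(subset) < 2) return(subset)
    cur <- score(subset)$r2
    for (pass in seq_len(40)) {
      best <- NULL
      consider <- function(trial) {
        sc <- passes_gate(trial)
        if (is.null(sc)) return()
        key <- paste(sort(cols[trial]), collapse = "|")
        if (sc$r2 > cur + 1e-10 &&
            (is.null(best) || sc$r2 > best$r2 + 1e-12 ||
             (abs(sc$r2 - best$r2) <= 1e-12 && key < best$key))) {
          best <<- list(subset = trial, r2 = sc$r2, key = key)
        }
      }
      # single exchanges
      for (pos in seq_along(subset)) {
        rest <- subset[-pos]
        cand <- setdiff(seq_len(p), subset)
        cand <- cand[vapply(cand, function(j) all(compatible[j, rest]),
                            logical(1))]
        if (!length(cand)) next
        fd <- forward_deltas(rest, cand)
        ordc <- order(-fd$delta, cols[cand])
        for (k in utils::head(ordc, 4)) {
          if (!is.finite(fd$delta[k])) break
          consider(c(rest, cand[k]))
        }
      }
      # drop two, regrow greedily
      if (length(subset) >= 3) {
        drops <- utils::combn(seq_along(subset), 2, simplify = FALSE)
        for (dp in drops) consider(grow(subset[-dp]))
      }
      if (is.null(best)) break
      subset <- best$subset
      cur <- best$r2
    }
    subset
  }

  grown <- unique(lapply(lapply(seeds, grow), sort))
  beamed <- beam_search(seeds)
  pool_subsets <- unique(lapply(c(grown, beamed), sort))
  # refine only the most promising subsets (cost control; the improvement
  # phase dominates run time)
  g_r2 <- vapply(pool_subsets, function(s)
    tryCatch(score(s)$r2, error = function(e) -Inf), numeric(1))
  refine_set <- pool_subsets[order(-g_r2)][seq_len(min(10,
                                                       length(pool_subsets)))]
  finals <- unique(lapply(c(lapply(refine_set, refine), pool_subsets), sort))
  finals <- Filter(function(s) !is.null(passes_gate(s)), finals)
  if (!length(finals)) stop("no admissible model found")
  # prefer the largest admissible model (growth stops only when no addition
  # stays significant), then R2, minimum |t|, names
  stats_of <- lapply(finals, score)
  ord <- order(-vapply(finals, length, integer(1)),
               -vapply(stats_of, `[[`, numeric(1), "r2"),
               -vapply(stats_of, `[[`, numeric(1), "tmin"),
               vapply(finals, function(s) paste(sort(cols[s]), collapse = "|"),
                      character(1)))
  subset <- finals[[ord[1]]]

  # refit in natural scale; fitted values identical to the scaled-search fit
  final <- fit_ols(Xm[, subset, drop = FALSE], y)
  final$training_meta$q2 <- q2_loo(Xm[, subset, drop = FALSE], y)
  final
}
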
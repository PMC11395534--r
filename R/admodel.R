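# Applicability domain: leverages, critical leverage, standardized residuals
# and the Williams-plot table.

#' Leverages (hat values) of training or query compounds
#'
#' With the intercept column appended, the leverage of a row x is
#' \eqn{h = x' (X'X)^{-1} x}. For training rows this is the hat-matrix
#' diagonal; query rows measure distance from the training descriptor space.
#'
#' @param X_train Training descriptor matrix/data.frame.
#' @param X_query Optional query rows (same columns); defaults to the
#'   training rows themselves.
#' @return Numeric leverage vector, one per query row.
#' @export
leverages <- function(X_train, X_query = NULL) {
  Xt <- cbind(1, .as_matrix_X(X_train))
  Xq <- if (is.null(X_query)) Xt else {
    q <- .as_matrix_X(X_query)
    if (is.data.frame(X_query) && !is.null(colnames(Xt))) {
      cn <- colnames(Xt)[-1]
      if (all(cn %in% colnames(q))) q <- q[, cn, drop = FALSE]
    }
    cbind(1, q)
  }
  xtx <- crossprod(Xt)
  inv <- tryCatch(solve(xtx), error = function(e) {
    stop("rank-deficient training matrix: leverages undefined")
  })
  rowSums((Xq %*% inv) * Xq)
}

#' Critical leverage h*
#'
#' The conventional warning threshold \eqn{h^* = 3 (k + 1) / N} for a model
#' with k descriptors trained on N compounds, reported to 3 decimals.
#'
#' @param k Number of descriptors in the model.
#' @param N Number of training compounds; must exceed k + 1.
#' @return h*, rounded to 3 decimals.
#' @examples
#' critical_leverage(5, 31)  # 0.581
#' @export
critical_leverage <- function(k, N) {
  if (N <= k + 1) stop("need N > k + 1")
  round(3 * (k + 1) / N, 3)
}

#' Standardized residuals with outlier flags
#'
#' Residuals divided by the regression standard error s (the square root of
#' s2 = RSS/(N-k-1)); optionally internally studentized by
#' \eqn{\sqrt{1 - h_i}}. Compounds beyond 2 (3) standard errors are flagged
#' as moderate (strong) outliers.
#'
#' @param residuals Raw residual vector.
#' @param s Regression standard error; must be positive.
#' @param studentized Divide additionally by `sqrt(1 - leverage)`?
#' @param leverage Leverage vector, required when `studentized = TRUE`.
#' @return A data.frame with `std_residual`, `moderate_outlier` (|r| > 2) and
#'   `strong_outlier` (|r| > 3).
#' @export
standardized_residuals <- function(residuals, s, studentized = FALSE,
                                   leverage = NULL) {
  if (!is.finite(s) || s <= 0) stop("regression standard error must be > 0")
  r <- residuals / s
  if (studentized) {
    if (is.null(leverage)) stop("leverage required for studentized residuals")
    r <- r / sqrt(1 - leverage)
  }
  data.frame(std_residual = r,
             moderate_outlier = abs(r) > 2,
             strong_outlier = abs(r) > 3)
}

#' Applicability-domain report (Williams plot table)
#'
#' Combines leverages against the training descriptor space with
#' standardized residuals into the per-compound table a Williams plot is
#' drawn from.
#'
#' @param model A `qsar_model` (used for prediction and, if present, its
#'   training `s2`).
#' @param X_train Training descriptor data.frame (must contain the model's
#'   descriptors).
#' @param y_train Training activities.
#' @param X_query Optional query descriptor data.frame (e.g. test set).
#' @param y_query Optional query activities (residuals reported when given).
#' @param names Optional compound labels for the query rows.
#' @param studentized Use internally studentized residuals?
#' @return A data.frame of class `ad_report` with columns `name`, `leverage`,
#'   `h_critical`, `std_residual`, `in_domain`, `leverage_outlier`,
#'   `moderate_outlier`, `strong_outlier`.
#' @export
ad_report <- function(model, X_train, y_train, X_query = NULL,
                      y_query = NULL, names = NULL, studentized = FALSE) {
  Xt <- X_train[, model$descriptor_names, drop = FALSE]
  hstar <- critical_leverage(length(model$descriptor_names), nrow(Xt))
  if (is.null(X_query)) {
    Xq <- Xt; yq <- y_train
  } else {
    Xq <- X_query[, model$descriptor_names, drop = FALSE]; yq <- y_query
  }
  h <- leverages(Xt, Xq)
  pred_train <- predict(model, X_train)
  res_train <- y_train - pred_train
  k <- length(model$descriptor_names)
  s <- sqrt(sum(res_train^2) / (length(y_train) - k - 1))
  if (!is.null(yq)) {
    res <- yq - predict(model, Xq)
    sr <- standardized_residuals(res, s, studentized = studentized,
                                 leverage = if (studentized) h)
  } else {
    sr <- data.frame(std_residual = NA_real_, moderate_outlier = NA,
                     strong_outlier = NA)[rep(1, nrow(Xq)), ]
  }
  out <- data.frame(
    name = if (!is.null(names)) names else
      if (!is.null(rownames(Xq))) rownames(Xq) else seq_len(nrow(Xq)),
    leverage = h,
    h_critical = hstar,
    std_residual = sr$std_residual,
    in_domain = h <= hstar & (is.na(sr$std_residual) |
                              abs(sr$std_residual) <= 3),
    leverage_outlier = h > hstar,
    moderate_outlier = sr$moderate_outlier,
    strong_outlier = sr$strong_outlier,
    row.names = NULL
  )
  class(out) <- c("ad_report", "data.frame")
  out
}

#' Export a Williams-plot table to CSV
#' @param report An `ad_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_williams_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
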
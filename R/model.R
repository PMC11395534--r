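# Linear QSAR models: the frozen published five-descriptor equation,
# prediction, activity-unit conversion and JSON serialisation.

#' Construct a linear QSAR model
#'
#' @param descriptor_names Ordered descriptor names.
#' @param coefficients Numeric coefficients, one per descriptor.
#' @param intercept Numeric intercept.
#' @param t_values Optional per-coefficient t statistics.
#' @param training_meta Optional list of fit statistics (N, k, R2, q2, F, s2,
#'   ...).
#' @param config The `descriptor_config` the model's descriptors were
#'   computed under.
#' @return An object of class `qsar_model`.
#' @export
qsar_model <- function(descriptor_names, coefficients, intercept,
                       t_values = NULL, training_meta = list(),
                       config = descriptor_config()) {
  stopifnot(length(descriptor_names) == length(coefficients),
            is.finite(coefficients), is.finite(intercept))
  structure(list(descriptor_names = descriptor_names,
                 coefficients = stats::setNames(coefficients, descriptor_names),
                 intercept = intercept,
                 t_values = t_values,
                 training_meta = training_meta,
                 config = config),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  cat("<qsar_model> pIC50 ~", length(x$coefficients), "descriptors\n")
  terms <- sprintf("%+.4g x %s", x$coefficients, x$descriptor_names)
  cat("  ", paste(terms, collapse = " "), sprintf(" %+.4f", x$intercept),
      "\n", sep = "")
  if (length(x$training_meta)) {
    m <- x$training_meta
    cat("  ", paste(names(m), unlist(m), sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' The published five-descriptor antiproliferative activity model
#'
#' The frozen linear model for pIC50 against HeLa cells:
#' \deqn{pIC_{50} = -4.66 \, AATSC2s - 1.99 \, MDEN\mbox{-}23 + 3.45 \,
#'   ATSC4c + 0.21 \, ATSC3e - 15.28 \, AATSC6p + 4.7326}
#' with its reported training statistics (N = 31, k = 5, R2 = 0.85,
#' q2 = 0.797, F = 29.35, s2 = 0.0485, Rtest2 = 0.64) and per-coefficient t
#' statistics. The descriptor configuration is pinned to
#' [published_descriptor_config()]; coefficients are stored at their printed
#' precision and never re-fitted.
#'
#' @return A `qsar_model`.
#' @export
published_model <- function() {
  qsar_model(
    descriptor_names = c("AATSC2s", "MDEN-23", "ATSC4c", "ATSC3e", "AATSC6p"),
    coefficients = c(-4.66, -1.99, 3.45, 0.21, -15.28),
    intercept = 4.7326,
    t_values = stats::setNames(
      c(-8.23321, -5.72486, 5.41163, 4.53965, -3.62229),
      c("AATSC2s", "MDEN-23", "ATSC4c", "ATSC3e", "AATSC6p")),
    training_meta = list(N = 31, k = 5, R2 = 0.85, q2 = 0.797, F = 29.35,
                         s2 = 0.0485, Rtest2 = 0.64),
    config = published_descriptor_config()
  )
}

#' Predict pIC50 from a QSAR model
#'
#' @param object A `qsar_model`.
#' @param newdata Either a data.frame containing the model's descriptor
#'   columns (e.g. from [model_descriptors()] or [descriptor_pool()]), a named
#'   numeric vector, a `molecule`, or a list of molecules (descriptors are
#'   then computed under the model's own configuration).
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50 values.
#' @examples
#' m <- published_model()
#' predict(m, stats::setNames(numeric(5), m$descriptor_names))  # intercept
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (inherits(newdata, "molecule") ||
      (is.list(newdata) && !is.data.frame(newdata) && !is.numeric(newdata) &&
       all(vapply(newdata, inherits, logical(1), "molecule")))) {
    newdata <- model_descriptors(newdata, config = object$config)
  }
  if (is.numeric(newdata)) newdata <- as.data.frame(as.list(newdata),
                                                    check.names = FALSE)
  missing <- setdiff(object$descriptor_names, names(newdata))
  if (length(missing)) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[, object$descriptor_names, drop = FALSE])
  drop(object$intercept + X %*% object$coefficients)
}

#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 is the negative decadic logarithm of the molar IC50:
#' `-log10(ic50 * 1e-6) = 6 - log10(ic50)` for IC50 given in micromolar.
#'
#' @param ic50_uM IC50 value(s) in micromolar; must be positive.
#' @return pIC50 value(s), unrounded.
#' @examples
#' pic50_from_ic50(1)    # 6
#' pic50_from_ic50(0.3)  # 6.52...
#' @export
pic50_from_ic50 <- function(ic50_uM) {
  if (any(!is.finite(ic50_uM) | ic50_uM <= 0)) {
    stop("IC50 must be positive and finite")
  }
  6 - log10(ic50_uM)
}

#' Convert pIC50 back to IC50 in micromolar
#' @param pic50 pIC50 value(s).
#' @return IC50 in micromolar.
#' @export
ic50_from_pic50 <- function(pic50) 10^(6 - pic50)

#' Serialise a QSAR model to JSON
#'
#' @param model A `qsar_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qsar_model <- function(model, path) {
  payload <- list(
    descriptor_names = model$descriptor_names,
    coefficients = unname(model$coefficients),
    intercept = model$intercept,
    t_values = if (!is.null(model$t_values)) unname(model$t_values),
    training_meta = model$training_meta,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a QSAR model from JSON
#' @param path Path written by [write_qsar_model()].
#' @return A `qsar_model`.
#' @export
read_qsar_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(descriptor_config, p$config)
  qsar_model(p$descriptor_names, p$coefficients, p$intercept,
             t_values = if (!is.null(p$t_values))
               stats::setNames(p$t_values, p$descriptor_names),
             training_meta = p$training_meta, config = cfg)
}
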
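#' Fit the zero-intercept CGM error model
#'
#' Ordinary least squares of the CGM estimation error on the baseline-removed
#' wearable signals with the intercept forced to zero, so that the model only
#' compensates error that co-varies with the wearables and leaves the resting
#' error level untouched. The coefficients minimize `||E - Theta p||^2` and
#' equal the normal-equations solution `(Theta'Theta)^-1 Theta' E`.
#'
#' @param design Numeric matrix (or data frame), n samples x m signals, with
#'   named columns and no missing entries (rows with missing inputs must be
#'   excluded upstream).
#' @param errors Numeric vector of per-sample errors `cgm - pg`, mg/dL.
#' @return An object of class `cgm_error_model` with fields `signal_codes`
#'   (ordered column names), `coefficients` (mg/dL per signal unit) and
#'   `n_samples`.
#' @export
#' @examples
#' m <- fit_zero_intercept(cbind(FME = c(1, 2)), c(3, 6))
#' m$coefficients # 3
fit_zero_intercept <- function(design, errors) {
  X <- as.matrix(design)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (!is.numeric(X)) stop("design must be numeric")
  if (anyNA(X) || anyNA(errors))
    stop("design and errors must not contain missing values")
  n <- nrow(X); m <- ncol(X)
  if (m < 1) stop("at least one signal column is required")
  if (length(errors) != n) stop("length(errors) must equal nrow(design)")
  if (n < m)
    stop("insufficient data: ", n, " samples for ", m, " signals")
  dec <- qr(X)
  if (dec$rank < m)
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[dec$pivot[(dec$rank + 1):m]], collapse = ", "))
  fit <- stats::lm.fit(X, errors)
  structure(list(signal_codes = colnames(X),
                 coefficients = unname(fit$coefficients[colnames(X)]),
                 n_samples = n),
            class = "cgm_error_model")
}

#' @export
print.cgm_error_model <- function(x, ...) {
  cat("<cgm_error_model: E = Theta p, no intercept>\n")
  print(stats::setNames(x$coefficients, x$signal_codes))
  cat("fitted on", x$n_samples, "paired samples\n")
  invisible(x)
}

#' Predict the CGM error from wearable values
#'
#' Dot product of each row with the model coefficients. Rows in which any
#' required signal is missing yield `NA` — the prediction-unavailable marker;
#' [correct_cgm()] falls back to the uncorrected CGM there, so the correction
#' can never be worse than having no wearable data.
#'
#' @param model A `cgm_error_model`.
#' @param newdata Data frame/matrix with the model's signal columns
#'   (baseline-removed), or a named numeric vector for a single sample.
#' @return Numeric vector of predicted errors, mg/dL, `NA` where unavailable.
#' @export
predict_error <- function(model, newdata) {
  stopifnot(inherits(model, "cgm_error_model"))
  if (is.numeric(newdata) && is.null(dim(newdata)))
    newdata <- as.data.frame(as.list(newdata))
  newdata <- as.data.frame(newdata)
  X <- matrix(NA_real_, nrow(newdata), length(model$signal_codes),
              dimnames = list(NULL, model$signal_codes))
  for (code in model$signal_codes)
    if (code %in% names(newdata)) X[, code] <- newdata[[code]]
  as.numeric(X %*% model$coefficients)
}

#' Enhanced CGM values
#'
#' Subtracts the predicted error from the raw CGM trace:
#' `eCGM(k) = CGM(k) - Ehat(k)`. Where the prediction is unavailable (`NA`),
#' the raw CGM value is kept. Values are not clipped by default; a
#' physiological floor can be enabled since glucose below ~20 mg/dL is not
#' survivable, but the uncorrected trace is never clipped either.
#'
#' @param cgm Raw CGM values, mg/dL.
#' @param predicted_errors Predicted errors from [predict_error()], same
#'   length; `NA` means no prediction.
#' @param floor Optional lower clip in mg/dL (e.g. 20); `NULL` (default)
#'   disables clipping.
#' @return Enhanced CGM values, mg/dL.
#' @export
#' @examples
#' correct_cgm(c(150, 120), c(10, -8)) # 140, 128
correct_cgm <- function(cgm, predicted_errors, floor = NULL) {
  if (length(cgm) != length(predicted_errors))
    stop("cgm and predicted_errors must have equal length")
  out <- cgm - ifelse(is.na(predicted_errors), 0, predicted_errors)
  if (!is.null(floor)) out <- pmax(out, floor)
  out
}

#' Serialize / deserialize a fitted error model as JSON
#'
#' @param model A `cgm_error_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "cgm_error_model"))
  jsonlite::write_json(list(signal_codes = model$signal_codes,
                            coefficients = model$coefficients,
                            n_samples = model$n_samples),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::fromJSON(path)
  structure(list(signal_codes = as.character(x$signal_codes),
                 coefficients = as.numeric(x$coefficients),
                 n_samples = as.integer(x$n_samples)),
            class = "cgm_error_model")
}
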
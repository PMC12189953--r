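#' Fit a niche model
#'
#' The implemented learner family spans the parametric / envelope /
#' flexible classes used in ensemble niche modeling:
#'
#' * `"glmq"` — ridge-regularized logistic regression with linear and
#'   quadratic terms per variable (fixed small penalty; the quadratic terms
#'   let it express unimodal responses).
#' * `"envelope"` — rectilinear quantile envelope: predicts 1 inside the
#'   per-variable `[q, 1 - q]` presence quantile box (default q = 0.025),
#'   0 outside (a surface-range-envelope analog).
#' * `"gbt"` — gradient-boosted shallow trees (depth 3) on the binary
#'   label, via xgboost with a single thread and a fixed seed so fits are
#'   deterministic.
#'
#' Constant variables are dropped for the fit with a warning.
#'
#' @param algorithm_id One of `"glmq"`, `"envelope"`, `"gbt"`.
#' @param table data.frame with a 0/1 `label` column and the variable
#'   columns.
#' @param variables Variables to use (default: every non-metadata column).
#' @param seed Integer seed (used by the boosted learner).
#' @param quantile_q Envelope tail quantile.
#' @return An object of class `fitted_sdm` with a
#'   [predict_suitability()] method.
#' @export
fit_model <- function(algorithm_id, table, variables = NULL, seed = 1,
                      quantile_q = 0.025) {
  if (!algorithm_id %in% sdm_algorithms())
    stop("unknown algorithm_id '", algorithm_id, "'; implemented: ",
         paste(sdm_algorithms(), collapse = ", "))
  variables <- variables %||%
    setdiff(names(table), c("label", "lon", "lat", "pa_rep", "fold", "split"))
  if (!"label" %in% names(table) || !all(table$label %in% c(0, 1)))
    stop("training table needs a 0/1 'label' column")
  if (length(unique(table$label)) < 2)
    stop("training table needs both classes")
  x <- as.matrix(table[, variables, drop = FALSE])
  if (anyNA(x)) stop("training table has missing variable values")
  const <- apply(x, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning("dropping constant variable(s): ",
            paste(variables[const], collapse = ", "))
    variables <- variables[!const]
    if (!length(variables)) stop("no non-constant variables left")
    x <- x[, variables, drop = FALSE]
  }
  y <- table$label
  fit <- switch(algorithm_id,
    glmq = {
      # center before squaring: keeps the quadratic features well
      # conditioned so the light ridge penalty barely biases the band shape
      ctr <- colMeans(x)
      xc <- sweep(x, 2, ctr)
      xq <- cbind(xc, xc^2)
      colnames(xq) <- c(variables, paste0(variables, "_sq"))
      list(glmnet = glmnet::glmnet(xq, y, family = "binomial", alpha = 0,
                                   lambda = 1e-5),
           centers = ctr)
    },
    envelope = {
      pres <- x[y == 1, , drop = FALSE]
      list(lo = apply(pres, 2, stats::quantile, probs = quantile_q,
                      names = FALSE),
           hi = apply(pres, 2, stats::quantile, probs = 1 - quantile_q,
                      names = FALSE))
    },
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, nthread = 1, seed = seed),
        data = dtrain, nrounds = 60, verbose = 0)
    })
  structure(list(algorithm_id = algorithm_id, fit = fit,
                 variables = variables, seed = seed),
            class = "fitted_sdm")
}

#' Implemented SDM learner identifiers
#' @return Character vector of algorithm ids.
#' @export
sdm_algorithms <- function() c("glmq", "envelope", "gbt")

#' Predict habitat suitability from a fitted model
#'
#' @param model A `fitted_sdm` or `sdm_ensemble`.
#' @param newdata data.frame or matrix containing the model's variables.
#' @return Suitability scores in `[0, 1]`.
#' @export
predict_suitability <- function(model, newdata) {
  UseMethod("predict_suitability")
}

#' @export
predict_suitability.fitted_sdm <- function(model, newdata) {
  x <- as.matrix(as.data.frame(newdata)[, model$variables, drop = FALSE])
  p <- switch(model$algorithm_id,
    glmq = {
      xc <- sweep(x, 2, model$fit$centers)
      xq <- cbind(xc, xc^2)
      as.vector(stats::predict(model$fit$glmnet, newx = xq,
                               type = "response"))
    },
    envelope = {
      inside <- rep(TRUE, nrow(x))
      for (j in seq_along(model$variables))
        inside <- inside & x[, j] >= model$fit$lo[j] & x[, j] <= model$fit$hi[j]
      as.numeric(inside)
    },
    gbt = {
      stats::predict(model$fit, xgboost::xgb.DMatrix(x, nthread = 1))
    })
  pmin(pmax(p, 0), 1)
}

#' @exportS3Method base::print
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> %s on %d variable(s): %s\n", x$algorithm_id,
              length(x$variables), paste(x$variables, collapse = ", ")))
  invisible(x)
}
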
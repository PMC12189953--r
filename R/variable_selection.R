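#' Pearson correlation matrix over sampled cells
#'
#' Correlations between stack layers evaluated at the supplied sample
#' points (typically the presence + pseudoabsence cells, i.e. the modeling
#' domain). A layer that is constant over the samples has undefined
#' correlations; they are set to 0 with a warning.
#'
#' @param stack An `env_stack`.
#' @param sample_points data.frame with `lon`, `lat` columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(stack, sample_points) {
  vals <- sapply(stack$layers, function(l)
    extract_at(l, sample_points$lon, sample_points$lat))
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  if (nrow(vals) < 3)
    stop("need at least 3 sample points with valid values on all layers")
  sds <- apply(vals, 2, stats::sd)
  r <- suppressWarnings(stats::cor(vals))
  if (any(sds == 0)) {
    warning("constant layer(s) over samples, correlations set to 0: ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Permutation importance of one variable for a fitted model
#'
#' `1 - mean(r)` over `n_shuffles` shuffles, where `r` is the Pearson
#' correlation between the model's predictions on the original table and
#' on the table with that variable's column permuted; clipped to `[0, 1]`.
#' A variable the model ignores leaves predictions unchanged (r = 1,
#' importance 0); a variable the model copies gives r near 0 (importance
#' near 1).
#'
#' @param model A `fitted_sdm`.
#' @param table Training table containing the model's variables.
#' @param variable Variable to permute.
#' @param n_shuffles Number of shuffle repetitions.
#' @param seed Integer seed.
#' @return Importance in `[0, 1]`.
#' @export
permutation_importance <- function(model, table, variable, n_shuffles = 3,
                                   seed = 1) {
  if (!variable %in% model$variables)
    stop("configuration error: variable '", variable,
         "' is not among the model's inputs")
  p0 <- predict_suitability(model, table)
  rs <- withr::with_seed(seed, vapply(seq_len(n_shuffles), function(i) {
    tbl <- table
    tbl[[variable]] <- sample(tbl[[variable]])
    p1 <- predict_suitability(model, tbl)
    if (isTRUE(all.equal(p0, p1))) return(1)          # predictions unchanged
    if (stats::sd(p0) == 0 || stats::sd(p1) == 0) return(1)
    stats::cor(p0, p1)
  }, numeric(1)))
  min(max(1 - mean(rs), 0), 1)
}

#' Mean permutation importance across the learner family
#'
#' Fits every algorithm in `algorithms` on all candidate variables and
#' averages [permutation_importance()] over algorithms and shuffle
#' repetitions, one row per variable.
#'
#' @param table Training table (0/1 `label` + variable columns).
#' @param variables Candidate variables (default: all variable columns).
#' @param algorithms Learner ids (default [sdm_algorithms()]).
#' @param n_shuffles Shuffles per (variable, algorithm).
#' @param seed Integer seed.
#' @return data.frame with columns `variable`, `algorithm`, `importance`,
#'   plus attribute `mean_importance` (named vector averaged per variable).
#' @export
importance_table <- function(table, variables = NULL,
                             algorithms = sdm_algorithms(),
                             n_shuffles = 3, seed = 1) {
  variables <- variables %||%
    setdiff(names(table), c("label", "lon", "lat", "pa_rep", "fold", "split"))
  rows <- list()
  for (a in algorithms) {
    m <- fit_model(a, table, variables, seed = stage_seed(seed, a))
    for (v in variables) {
      imp <- permutation_importance(m, table, v, n_shuffles = n_shuffles,
                                    seed = stage_seed(seed, paste0(a, v)))
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, algorithm = a, importance = imp)
    }
  }
  out <- do.call(rbind, rows)
  mi <- tapply(out$importance, out$variable, mean)
  attr(out, "mean_importance") <- mi[variables]
  out
}

#' Greedy correlation-filtered variable selection
#'
#' Walks variables in decreasing mean importance and admits one only if its
#' absolute Pearson correlation with every already-admitted variable is
#' below `r_max`; stops after `k` admissions or exhaustion. Strong negative
#' correlation is treated as redundant, hence the absolute value.
#'
#' @param importance Named numeric vector of mean importances (or the
#'   output of [importance_table()]).
#' @param cor_matrix Correlation matrix covering the same variables.
#' @param r_max Correlation ceiling (default 0.70).
#' @param k Maximum number of variables (default 6).
#' @return Character vector of admitted variables, in admission order.
#' @export
select_variables <- function(importance, cor_matrix, r_max = 0.70, k = 6) {
  if (is.data.frame(importance))
    importance <- attr(importance, "mean_importance")
  vars <- names(importance)
  if (!all(vars %in% rownames(cor_matrix)))
    stop("correlation matrix does not cover all candidate variables")
  ord <- vars[order(-importance)]
  chosen <- character(0)
  for (v in ord) {
    if (length(chosen) >= k) break
    if (all(abs(cor_matrix[v, chosen]) < r_max)) chosen <- c(chosen, v)
  }
  if (length(chosen) < 2)
    stop("selection failed: fewer than 2 admissible variables")
  chosen
}
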
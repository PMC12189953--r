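#' Sample pseudoabsence sets
#'
#' Draws `n_reps` independent uniform samples of `n` cells, without
#' replacement within each repetition, from the eligible domain: cells
#' valid on every stack layer, at sea, and not containing any presence
#' record. Points are placed at cell centers.
#'
#' @param stack An `env_stack` defining the study domain.
#' @param occ An `occurrence_set` of presences.
#' @param n Pseudoabsences per repetition (default 5000).
#' @param n_reps Repetitions (default 3).
#' @param seed Integer seed.
#' @param land_mask Optional land [raster_layer()]; land cells are excluded.
#' @return List of `n_reps` data.frames with `rep_index`, `lon`, `lat`.
#' @export
sample_pseudoabsences <- function(stack, occ, n = 5000, n_reps = 3, seed = 1,
                                  land_mask = NULL) {
  spec <- stack$spec
  valid <- !Reduce(`|`, lapply(stack$layers, function(l) is.na(l$values)))
  if (!is.null(land_mask)) valid <- valid & !(land_mask$values > 0)
  pres <- cell_index(spec, occ$decimalLongitude, occ$decimalLatitude)
  pres <- pres[!is.na(pres$row), , drop = FALSE]
  pres_lin <- unique((pres$col - 1L) * spec$n_rows + pres$row)
  eligible <- setdiff(which(valid), pres_lin)
  if (length(eligible) < n)
    stop("insufficient domain: ", length(eligible),
         " eligible cells for ", n, " pseudoabsences")
  withr::with_seed(seed, lapply(seq_len(n_reps), function(r) {
    cells <- eligible[sample.int(length(eligible), n)]
    rc <- arrayInd(cells, c(spec$n_rows, spec$n_cols))
    ctr <- cell_center(spec, rc[, 1], rc[, 2])
    data.frame(rep_index = r, lon = ctr$lon, lat = ctr$lat)
  }))
}

#' Assemble a presence/pseudoabsence training table
#'
#' One row per presence (label 1) and pseudoabsence (label 0) with the
#' selected environmental variables extracted at each point's cell; rows
#' with any missing variable value are dropped.
#'
#' @param stack An `env_stack`.
#' @param occ Presence `occurrence_set`.
#' @param pa_points data.frame of pseudoabsences (`lon`, `lat`).
#' @param variables Layer names to extract (default: all layers).
#' @return data.frame with `lon`, `lat`, `label` and one column per
#'   variable.
#' @export
build_training_table <- function(stack, occ, pa_points, variables = NULL) {
  variables <- variables %||% names(stack$layers)
  miss <- setdiff(variables, names(stack$layers))
  if (length(miss))
    stop("configuration error: variable(s) missing from stack: ",
         paste(miss, collapse = ", "))
  pts <- rbind(
    data.frame(lon = occ$decimalLongitude, lat = occ$decimalLatitude,
               label = 1),
    data.frame(lon = pa_points$lon, lat = pa_points$lat, label = 0))
  for (v in variables)
    pts[[v]] <- extract_at(stack$layers[[v]], pts$lon, pts$lat)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Repeated stratified train/test splits
#'
#' `n_folds` independent stratified 75/25 splits (class proportions
#' preserved to within one row) plus one final `"full"` pseudo-fold whose
#' training set is every row — the split structure behind a
#' "5 + 1"-fold validation design.
#'
#' @param table Training table with a 0/1 `label` column.
#' @param train_fraction Fraction of each class used for training.
#' @param n_folds Number of evaluation folds (default 5).
#' @param seed Integer seed.
#' @return List of `n_folds + 1` folds, each `list(train=, test=)` of row
#'   indices; the last element is named `"full"`.
#' @export
split_train_test <- function(table, train_fraction = 0.75, n_folds = 5,
                             seed = 1) {
  check_two_classes(table$label)
  i1 <- which(table$label == 1); i0 <- which(table$label == 0)
  if (min(length(i1), length(i0)) < n_folds)
    stop("stratification error: a class has fewer rows than n_folds")
  folds <- withr::with_seed(seed, lapply(seq_len(n_folds), function(f) {
    tr <- c(sample(i1, round(train_fraction * length(i1))),
            sample(i0, round(train_fraction * length(i0))))
    list(train = sort(tr), test = sort(setdiff(seq_len(nrow(table)), tr)))
  }))
  names(folds) <- paste0("fold", seq_len(n_folds))
  folds$full <- list(train = seq_len(nrow(table)), test = integer(0))
  folds
}

#' Build a TSS-weighted ensemble from evaluated members
#'
#' Retains members whose held-out TSS strictly exceeds `tss_min` (default
#' 0.75) and weights them proportionally to raw TSS. The ensemble decision
#' threshold is TSS-optimized on the supplied evaluation rows scored by
#' the ensemble itself.
#'
#' @param models List of `fitted_sdm` members.
#' @param evals data.frame aligned with `models`, with columns `tss`,
#'   `roc_auc`, `threshold` (plus bookkeeping columns).
#' @param tss_min Retention gate (strict `>`).
#' @param eval_rows Optional data.frame (variables + `label`) of pooled
#'   held-out rows on which to optimize the ensemble threshold.
#' @return An object of class `sdm_ensemble`.
#' @export
build_ensemble <- function(models, evals, tss_min = 0.75, eval_rows = NULL) {
  stopifnot(length(models) == nrow(evals))
  keep <- which(evals$tss > tss_min)
  if (!length(keep)) {
    stop("ensemble empty: no member exceeds TSS ", tss_min, "; member TSS: ",
         paste(sprintf("%s=%.3f", evals$algorithm, evals$tss), collapse = ", "))
  }
  weights <- evals$tss[keep] / sum(evals$tss[keep])
  ens <- structure(
    list(members = models[keep], weights = weights,
         member_evals = evals[keep, , drop = FALSE],
         all_evals = evals, tss_min = tss_min,
         variables = models[[keep[1]]]$variables,
         threshold = NA_real_, threshold_tss = NA_real_),
    class = "sdm_ensemble")
  if (!is.null(eval_rows) && nrow(eval_rows)) {
    sc <- predict_suitability(ens, eval_rows)
    opt <- optimize_threshold(sc, eval_rows$label)
    ens$threshold <- opt$threshold
    ens$threshold_tss <- opt$tss
  }
  ens
}

#' @export
predict_suitability.sdm_ensemble <- function(model, newdata) {
  p <- 0
  for (i in seq_along(model$members))
    p <- p + model$weights[i] * predict_suitability(model$members[[i]], newdata)
  pmin(pmax(p, 0), 1)
}

#' @exportS3Method base::print
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sdm_ensemble> %d/%d members (TSS > %.2f); threshold %.3f (TSS %.3f)\n",
    length(x$members), nrow(x$all_evals), x$tss_min, x$threshold,
    x$threshold_tss))
  invisible(x)
}

#' Project a model or ensemble onto an environmental stack
#'
#' Per-cell suitability over the stack; nodata in any used layer
#' propagates to the output.
#'
#' @param model A `fitted_sdm` or `sdm_ensemble`.
#' @param stack An `env_stack` containing every model variable.
#' @return A [raster_layer()] in `[0, 1]`.
#' @export
predict_map <- function(model, stack) {
  vars <- model$variables
  miss <- setdiff(vars, names(stack$layers))
  if (length(miss))
    stop("configuration error: stack lacks layer(s): ",
         paste(miss, collapse = ", "))
  vals <- sapply(vars, function(v) as.vector(stack$layers[[v]]$values))
  vals <- matrix(vals, ncol = length(vars),
                 dimnames = list(NULL, vars))
  ok <- stats::complete.cases(vals)
  out <- rep(NA_real_, nrow(vals))
  if (any(ok))
    out[ok] <- predict_suitability(model, as.data.frame(vals[ok, , drop = FALSE]))
  raster_layer(matrix(out, stack$spec$n_rows, stack$spec$n_cols),
               stack$spec, paste0("suitability_", stack$scenario_tag))
}

#' Binarize a suitability map at a threshold
#'
#' Cell = 1 when suitability `>= threshold` (boundary convention), 0
#' otherwise; nodata preserved.
#'
#' @param map A suitability [raster_layer()] in `[0, 1]`.
#' @param threshold Threshold in the open interval (0, 1).
#' @return A 0/1 [raster_layer()].
#' @export
binarize <- function(map, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0, 1)")
  v <- map$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  raster_layer(out, map$spec, paste0(map$name, "_bin"))
}

#' Fit, evaluate and ensemble niche models for one species
#'
#' The full per-species modeling stage: pseudoabsence sampling
#' (`n_pa` points, `n_reps` repetitions), repeated stratified
#' `train_fraction` splits, fitting every learner on every
#' (repetition, fold) training set, held-out TSS/ROC evaluation, TSS-gated
#' TSS-weighted ensembling, and ensemble-threshold optimization on the
#' pooled held-out rows.
#'
#' @param stack Current-period `env_stack`.
#' @param occ Cleaned presence `occurrence_set`.
#' @param variables Selected environmental variables.
#' @param n_pa,n_reps Pseudoabsence count and repetitions.
#' @param train_fraction,n_folds Split design.
#' @param algorithms Learner ids.
#' @param tss_min Ensemble retention gate.
#' @param seed Integer seed.
#' @param land_mask Optional land mask restricting the domain.
#' @return List with the `ensemble` (`sdm_ensemble`), the full evaluation
#'   table `evals` (species, algorithm, pa_rep, fold, tss, roc_auc,
#'   threshold), and the pooled held-out rows `holdout`.
#' @export
fit_species_ensemble <- function(stack, occ, variables,
                                 n_pa = 5000, n_reps = 3,
                                 train_fraction = 0.75, n_folds = 5,
                                 algorithms = sdm_algorithms(),
                                 tss_min = 0.75, seed = 1,
                                 land_mask = NULL) {
  species <- if (nrow(occ)) occ$species[1] else "species"
  pa_sets <- sample_pseudoabsences(stack, occ, n = n_pa, n_reps = n_reps,
                                   seed = stage_seed(seed, "pa"),
                                   land_mask = land_mask)
  models <- list(); evals <- list(); holdout <- list()
  for (r in seq_len(n_reps)) {
    tbl <- build_training_table(stack, occ, pa_sets[[r]], variables)
    folds <- split_train_test(tbl, train_fraction = train_fraction,
                              n_folds = n_folds,
                              seed = stage_seed(seed, paste0("split", r)))
    for (f in seq_len(n_folds)) {
      tr <- tbl[folds[[f]]$train, , drop = FALSE]
      te <- tbl[folds[[f]]$test, , drop = FALSE]
      holdout[[paste(r, f)]] <- te
      for (a in algorithms) {
        m <- fit_model(a, tr, variables,
                       seed = stage_seed(seed, paste0(a, r, f)))
        sc <- predict_suitability(m, te)
        opt <- optimize_threshold(sc, te$label)
        models[[length(models) + 1L]] <- m
        evals[[length(evals) + 1L]] <- data.frame(
          species = species, algorithm = a, pa_rep = r, fold = f,
          tss = opt$tss, roc_auc = roc_auc(sc, te$label),
          threshold = opt$threshold)
      }
    }
  }
  evals <- do.call(rbind, evals)
  holdout <- do.call(rbind, holdout)
  ens <- build_ensemble(models, evals, tss_min = tss_min,
                        eval_rows = holdout)
  list(ensemble = ens, evals = evals, holdout = holdout)
}
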
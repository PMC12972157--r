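#' Feature-vector schema of the mortality network
#'
#' The network sees one vector per animal/timepoint combination: the five
#' numeric healthspan traits, the two strain encodings, the rank code and the
#' ordinal timepoint index. Strain, rank and timepoint are treated as one
#' "parameter" each for importance analyses, and are exempt from z-score
#' normalization.
#'
#' @return Named list mapping parameter names to feature column names.
#' @export
mlp_parameters <- function() {
  list(FI_kcal = "FI_kcal", BW_g = "BW_g", FM_g = "FM_g", FFM_g = "FFM_g",
       GLU_mgdl = "GLU_mgdl",
       strain = c("strain_b6_or_sv", "strain_cd1_or_b6"),
       rank = "rank_code", timepoint = "timepoint_idx")
}

# columns never z-normalized
mlp_exempt_columns <- function() {
  c("strain_b6_or_sv", "strain_cd1_or_b6", "rank_code", "timepoint_idx")
}

#' Build feature vectors from longitudinal records
#'
#' Converts a long table of per-timepoint measurements into the network's
#' input schema. The regression target is `D = age_at_death - current_age`
#' in weeks; a record taken at the death timepoint has `D = 0` and is
#' retained. Records with any missing parameter are dropped and counted.
#'
#' @param records data.frame with columns `animal_id`, `timepoint`,
#'   `age_weeks`, `FI_kcal`, `BW_g`, `FM_g`, `FFM_g`, `GLU_mgdl`, `strain`,
#'   `rank`.
#' @param death_age Named vector of age at death in weeks, or `NULL` for a
#'   cohort without observed deaths (target left `NA`, as when transferring
#'   the trained model to the methylation cohort).
#' @return data.frame with `animal_id`, `timepoint`, the feature columns of
#'   [mlp_parameters()], and `D`; attribute `n_dropped` counts incomplete
#'   records.
#' @export
build_feature_vectors <- function(records, death_age = NULL) {
  needed <- c("animal_id", "timepoint", "age_weeks", "FI_kcal", "BW_g",
              "FM_g", "FFM_g", "GLU_mgdl", "strain", "rank")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tp_idx <- match(records$timepoint, names(timepoint_grid()))
  if (anyNA(tp_idx)) {
    stop("unknown timepoint label(s): ",
         paste(unique(records$timepoint[is.na(tp_idx)]), collapse = ", "))
  }
  cov <- encode_covariates(records$strain, records$rank)
  fv <- data.frame(animal_id = as.character(records$animal_id),
                   timepoint = records$timepoint,
                   FI_kcal = records$FI_kcal, BW_g = records$BW_g,
                   FM_g = records$FM_g, FFM_g = records$FFM_g,
                   GLU_mgdl = records$GLU_mgdl,
                   strain_b6_or_sv = cov$strain_b6_or_sv,
                   strain_cd1_or_b6 = cov$strain_cd1_or_b6,
                   rank_code = cov$rank_code,
                   timepoint_idx = tp_idx)
  if (!is.null(death_age)) {
    da <- death_age[fv$animal_id]
    if (anyNA(da)) stop("death age missing for some animals")
    fv$D <- as.numeric(da) - records$age_weeks
    if (any(fv$D < 0, na.rm = TRUE)) {
      stop("negative time until death: record taken after death")
    }
  } else {
    fv$D <- NA_real_
  }
  feature_cols <- unlist(mlp_parameters(), use.names = FALSE)
  complete <- stats::complete.cases(fv[, feature_cols])
  out <- fv[complete, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!complete)
  out
}

# internal: feature matrix from a feature-vector frame
fv_matrix <- function(fv, drop_params = character(0)) {
  params <- mlp_parameters()
  keep <- setdiff(names(params), drop_params)
  cols <- unlist(params[keep], use.names = FALSE)
  as.matrix(fv[, cols, drop = FALSE])
}

#' Animal-grouped k-fold assignment
#'
#' Partitions animals (not records) into k folds so that all of an animal's
#' vectors share a fold, preventing leakage of within-animal structure
#' between training and validation. Fold sizes differ by at most one animal.
#'
#' @param animal_ids Character vector (possibly with repeats, one per
#'   record).
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector: fold in `1:k` per unique animal.
#' @export
grouped_kfold <- function(animal_ids, k = 5, seed = 1) {
  animals <- unique(as.character(animal_ids))
  if (length(animals) < k) stop("fewer animals than folds")
  set.seed(as.integer(seed))
  # deal shuffled animals round-robin so fold sizes differ by at most one
  shuffled <- sample(animals)
  folds <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  folds[animals]
}

#' Grouped cross-validation of the mortality network
#'
#' Runs animal-grouped k-fold cross-validation: for each fold the network is
#' trained from scratch on the other folds (normalization statistics
#' refitted per fold from training data only) and scored by mean absolute
#' error, in weeks, on the held-out animals.
#'
#' @param fv Feature vectors from [build_feature_vectors()] with observed
#'   `D`.
#' @param config An [mlp_config()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and training.
#' @param drop_params Parameter names (see [mlp_parameters()]) excluded from
#'   the inputs.
#' @return List with `fold_mae` (length k), `mean_mae`, `folds` (animal
#'   assignment).
#' @export
evaluate_cv <- function(fv, config = mlp_config(), k = 5, seed = 1,
                        drop_params = character(0)) {
  stopifnot(!anyNA(fv$D))
  folds <- grouped_kfold(fv$animal_id, k = k, seed = seed)
  x <- fv_matrix(fv, drop_params)
  fold_of_row <- folds[fv$animal_id]
  fold_mae <- vapply(seq_len(k), function(f) {
    tr <- fold_of_row != f
    model <- train_mlp(x[tr, , drop = FALSE], fv$D[tr], config,
                       seed = derive_seed(seed, paste0("fold", f)),
                       exempt = mlp_exempt_columns())
    mean(abs(predict(model, x[!tr, , drop = FALSE]) - fv$D[!tr]))
  }, numeric(1))
  list(fold_mae = fold_mae, mean_mae = mean(fold_mae), folds = folds)
}

#' Feature importance by ablation retraining
#'
#' Repeats the full grouped cross-validation once per excluded parameter and
#' compares each variant's per-fold validation losses with the control by
#' Tukey-Kramer pairwise tests, BH-adjusted across the family. With
#' `with_time = FALSE` the timepoint parameter is excluded from every
#' variant and the timepoint-removed model serves as the control.
#'
#' @param fv Feature vectors with observed `D`.
#' @param config An [mlp_config()].
#' @param k Folds (default 5).
#' @param seed Integer seed (shared fold assignment across variants).
#' @param with_time Keep the timepoint parameter available (default TRUE).
#' @return List with `losses` (named list of per-fold MAE vectors, control
#'   first), `results` (data.frame: variant, mean_loss, diff vs control, p,
#'   adjp), `control`.
#' @export
importance_by_removal <- function(fv, config = mlp_config(), k = 5, seed = 1,
                                  with_time = TRUE) {
  base_drop <- if (with_time) character(0) else "timepoint"
  control_name <- if (with_time) "none" else "timepoint"
  candidates <- setdiff(names(mlp_parameters()), base_drop)
  losses <- list()
  losses[[control_name]] <-
    evaluate_cv(fv, config, k, seed, drop_params = base_drop)$fold_mae
  for (p in candidates) {
    variant <- if (with_time) p else paste("timepoint", p, sep = "+")
    losses[[variant]] <-
      evaluate_cv(fv, config, k, seed, drop_params = c(base_drop, p))$fold_mae
  }
  res <- tukey_bh(losses, control = control_name)
  list(losses = losses, results = res, control = control_name)
}

#' Feature importance by validation-time scrambling
#'
#' Trains the network once on all data, then recomputes per-fold validation
#' losses after replacing one parameter's values with random draws:
#' standard-normal on the normalized scale for z-scored parameters,
#' N(mean, sd) of the observed column for the exempt categorical parameters.
#' A second family additionally scrambles timepoint, with the
#' timepoint-scrambled model as its control.
#'
#' @param fv Feature vectors with observed `D`.
#' @param config An [mlp_config()].
#' @param k Folds used to form the loss distributions (default 5).
#' @param seed Integer seed.
#' @param also_time Additionally produce the timepoint+parameter family
#'   (default TRUE).
#' @return List with `losses`, `results` (per family, bound together with a
#'   `family` column), `model` (the full-data fit).
#' @export
importance_by_scramble <- function(fv, config = mlp_config(), k = 5,
                                   seed = 1, also_time = TRUE) {
  stopifnot(!anyNA(fv$D))
  x <- fv_matrix(fv)
  model <- train_mlp(x, fv$D, config, seed = derive_seed(seed, "full"),
                     exempt = mlp_exempt_columns())
  folds <- grouped_kfold(fv$animal_id, k = k, seed = seed)
  fold_of_row <- folds[fv$animal_id]

  scramble <- function(params, tag) {
    set.seed(derive_seed(seed, tag))
    mat <- x
    cols <- unlist(mlp_parameters()[params], use.names = FALSE)
    for (cl in cols) {
      if (cl %in% mlp_exempt_columns()) {
        mat[, cl] <- stats::rnorm(nrow(mat), mean(x[, cl]), stats::sd(x[, cl]))
      } else {
        # standard normal on the z-scored scale, mapped back to raw units
        mat[, cl] <- model$center[cl] + model$scale[cl] * stats::rnorm(nrow(mat))
      }
    }
    mat
  }
  fold_losses <- function(mat) {
    pred <- predict(model, mat)
    vapply(seq_len(k), function(f) {
      v <- fold_of_row == f
      mean(abs(pred[v] - fv$D[v]))
    }, numeric(1))
  }

  params <- names(mlp_parameters())
  losses <- list(none = fold_losses(x))
  for (p in params) losses[[p]] <- fold_losses(scramble(p, paste0("s_", p)))
  res <- tukey_bh(losses, control = "none")
  res$family <- "single"
  all_losses <- losses

  if (also_time) {
    dual <- list(timepoint = losses[["timepoint"]])
    for (p in setdiff(params, "timepoint")) {
      nm <- paste("timepoint", p, sep = "+")
      dual[[nm]] <- fold_losses(scramble(c("timepoint", p), paste0("d_", p)))
      all_losses[[nm]] <- dual[[nm]]
    }
    res2 <- tukey_bh(dual, control = "timepoint")
    res2$family <- "dual"
    res <- rbind(res, res2)
  }
  list(losses = all_losses, results = res, model = model)
}

#' Tukey-Kramer comparisons of loss distributions against a control
#'
#' Treats each variant's per-fold validation losses as a group, pools the
#' within-group variance across all groups, and computes the studentized-
#' range (Tukey-Kramer HSD) p-value for each variant against the control;
#' the family of p-values is then BH-adjusted.
#'
#' @param losses Named list of numeric vectors (per-fold losses), including
#'   the control.
#' @param control Name of the control element.
#' @return data.frame with `variant`, `mean_loss`, `diff` (variant minus
#'   control mean), `p`, `adjp`.
#' @export
tukey_bh <- function(losses, control) {
  stopifnot(control %in% names(losses))
  groups <- names(losses)
  ni <- vapply(losses, length, integer(1))
  if (any(ni < 2)) stop("each loss distribution needs >= 2 values")
  means <- vapply(losses, mean, numeric(1))
  vars <- vapply(losses, stats::var, numeric(1))
  kgrp <- length(groups)
  df <- sum(ni) - kgrp
  mse <- sum((ni - 1) * vars) / df
  variants <- setdiff(groups, control)
  if (mse <= 0) {
    # all groups constant: no evidence of any difference
    p <- stats::setNames(rep(1, length(variants)), variants)
  } else {
    q <- abs(means[variants] - means[control]) /
      sqrt(mse / 2 * (1 / ni[variants] + 1 / ni[control]))
    p <- stats::ptukey(q, nmeans = kgrp, df = df, lower.tail = FALSE)
  }
  data.frame(variant = variants,
             mean_loss = unname(means[variants]),
             diff = unname(means[variants] - means[control]),
             p = unname(p),
             adjp = unname(bh_adjust(p)),
             row.names = NULL)
}
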
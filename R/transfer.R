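#' Timepoint weight schema for averaging mortality predictions
#'
#' Per-timepoint weights used to collapse an animal's predicted weeks until
#' death into a single value. Weights increase by 0.03 per timepoint (week
#' 12 = 0.02 up to month 16 = 0.23) so that measurements closest to the
#' post-sacrifice methylation assay dominate; the eight weights sum to 1.
#'
#' @return Named numeric vector over the standard timepoint grid.
#' @export
weight_schema <- function() {
  stats::setNames(seq(0.02, 0.23, by = 0.03), names(timepoint_grid()))
}

#' Apply a trained mortality network to the methylation cohort
#'
#' Generates one predicted weeks-until-death value per animal/timepoint
#' combination, using the training cohort's normalization statistics stored
#' in the model. A parallel model trained without the timepoint parameter
#' can be passed to produce validation predictions with the same call.
#'
#' @param model An `mlp_model` trained on the survival cohort.
#' @param fv Feature vectors from [build_feature_vectors()] (target may be
#'   `NA`).
#' @return data.frame with `animal_id`, `timepoint`, `pred` (weeks).
#' @export
predict_cohort_a <- function(model, fv) {
  x <- as.matrix(fv[, model$features, drop = FALSE])
  data.frame(animal_id = fv$animal_id, timepoint = fv$timepoint,
             pred = predict(model, x), row.names = NULL)
}

#' Weighted average of per-timepoint predictions
#'
#' Collapses predictions to one value per animal using the timepoint weight
#' schema. Only schema timepoints are considered; when an animal misses some
#' of them, the weights of the present timepoints are renormalized to sum
#' to 1.
#'
#' @param preds data.frame with `animal_id`, `timepoint`, `pred`.
#' @param schema Named weights (default [weight_schema()]).
#' @return Named numeric vector, one weighted mean per animal.
#' @export
weighted_average <- function(preds, schema = weight_schema()) {
  keep <- preds$timepoint %in% names(schema)
  preds <- preds[keep, , drop = FALSE]
  if (nrow(preds) == 0) stop("no predictions at schema timepoints")
  w <- schema[preds$timepoint]
  num <- tapply(w * preds$pred, preds$animal_id, sum)
  den <- tapply(w, preds$animal_id, sum)
  out <- stats::setNames(as.numeric(num / den), names(num))
  out[unique(preds$animal_id)]
}

#' Group trend tests on averaged mortality predictions
#'
#' Tests whether predicted time until death trends with strain (ordered
#' C57BL/6J < CD1 < Sv129Ev, i.e. increasing mortality risk), with social
#' rank (subordinate < undefined < dominant), and with rank within each
#' strain, using the Kendall rank-correlation coefficient, suited to the
#' small per-group sample sizes.
#'
#' @param avg Named vector of per-animal averaged predictions.
#' @param labels data.frame with `animal_id`, `strain`, `rank`.
#' @return data.frame with `grouping`, `tau`, `p`, `n`.
#' @export
group_trend_tests <- function(avg, labels) {
  stopifnot(all(names(avg) %in% labels$animal_id))
  lab <- labels[match(names(avg), labels$animal_id), ]
  strain_code <- match(lab$strain, c("C57BL/6J", "CD1", "Sv129Ev"))
  rank_code <- match(lab$rank, c("subordinate", "undefined", "dominant"))
  kendall <- function(code, vals) {
    if (length(unique(code)) < 2) return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(code, vals, method = "kendall"))
    c(unname(ct$estimate), ct$p.value)
  }
  rows <- list(c("strain", kendall(strain_code, avg), length(avg)),
               c("rank", kendall(rank_code, avg), length(avg)))
  for (s in unique(lab$strain)) {
    sel <- lab$strain == s
    rows[[length(rows) + 1]] <-
      c(paste0("rank|", s), kendall(rank_code[sel], avg[sel]), sum(sel))
  }
  out <- do.call(rbind.data.frame, lapply(rows, function(r) {
    data.frame(grouping = r[1], tau = as.numeric(r[2]), p = as.numeric(r[3]),
               n = as.integer(r[4]))
  }))
  rownames(out) <- NULL
  out
}

#' Elastic-net regression of mortality predictions on methylation
#'
#' Selects aging-associated CpG sites by regressing the averaged
#' weeks-until-death predictions on the beta matrix under the elastic-net
#' penalty `(1/2n)*RSS + alpha*l1*sum|b| + alpha*(1-l1)/2*sum(b^2)`, with
#' hyperparameters chosen on a (alpha, l1) grid by k-fold cross-validated
#' mean absolute error, then refit on all animals. Sites with nonzero
#' coefficients form the selected set. Methylation predictors enter
#' unstandardized by default (beta values share a scale).
#'
#' @param y Numeric response (averaged predictions, weeks), named by animal.
#' @param x Animals x sites matrix of beta values.
#' @param alpha_grid Penalty scales (default `c(0.01, 0.033, 0.1, 0.33, 1)`).
#' @param l1_grid Mixing values in `[0, 1]`
#'   (default `c(0.1, 0.3, 0.5, 0.7, 0.9, 1)`).
#' @param k CV folds (default 5).
#' @param seed Integer seed for the fold split.
#' @param standardize Standardize predictors inside the fit (default FALSE).
#' @return Object of class `enet_fit`: `alpha`, `l1`, `coef` (named,
#'   including intercept), `selected` (site ids with nonzero coefficients),
#'   `cv_mae`, and the full `cv_table`.
#' @export
fit_elastic_net <- function(y, x,
                            alpha_grid = c(0.01, 0.033, 0.1, 0.33, 1),
                            l1_grid = c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                            k = 5, seed = 1, standardize = FALSE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(x), length(alpha_grid) > 0, length(l1_grid) > 0)
  if (stats::sd(y) == 0) stop("degenerate response: zero variance")
  if (nrow(x) < k) stop("fewer animals than folds")
  lambda_path <- sort(unique(alpha_grid), decreasing = TRUE)

  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), nrow(x)))
  cv <- expand.grid(alpha = lambda_path, l1 = sort(unique(l1_grid)))
  cv$mae <- NA_real_
  for (l1 in sort(unique(l1_grid))) {
    err <- matrix(NA_real_, nrow(x), length(lambda_path))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "gaussian",
                            alpha = l1, lambda = lambda_path,
                            standardize = standardize)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE], s = lambda_path,
                             exact = FALSE)
      err[!tr, ] <- abs(pred - y[!tr])
    }
    cv$mae[cv$l1 == l1] <- colMeans(err)   # rows follow lambda_path order
  }
  best <- cv[which.min(cv$mae), ]

  full <- glmnet::glmnet(x, y, family = "gaussian", alpha = best$l1,
                         lambda = lambda_path, standardize = standardize)
  beta <- stats::coef(full, s = best$alpha)
  coefs <- stats::setNames(as.numeric(beta), rownames(beta))
  nonzero <- coefs[-1][coefs[-1] != 0]
  structure(list(alpha = best$alpha, l1 = best$l1, coef = coefs,
                 selected = names(nonzero), cv_mae = best$mae,
                 cv_table = cv),
            class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat(sprintf("enet_fit: alpha = %g, l1 = %g, %d sites selected, CV MAE = %.3f\n",
              x$alpha, x$l1, length(x$selected), x$cv_mae))
  invisible(x)
}
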
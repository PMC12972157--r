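#' Moore-Penrose pseudoinverse
#'
#' Thin-SVD pseudoinverse with the standard machine-epsilon-scaled singular
#' value cutoff: singular values below `max(dim(a)) * eps * max(d)` are
#' treated as zero.
#'
#' @param a Numeric matrix.
#' @param tol Optional explicit cutoff overriding the default.
#' @return The pseudoinverse, with dim `rev(dim(a))`.
#' @export
pinv <- function(a, tol = NULL) {
  a <- as.matrix(a)
  s <- svd(a)
  if (is.null(tol)) tol <- max(dim(a)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(a), nrow(a)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Drop animals with incomplete trait records
#'
#' Trait-to-methylation modelling is complete-case: any animal with a missing
#' trait cell is removed before fitting.
#'
#' @param traits A [trait_matrix()] or plain matrix.
#' @return The matrix restricted to complete rows, with attribute
#'   `n_dropped`.
#' @export
drop_incomplete_animals <- function(traits) {
  keep <- stats::complete.cases(unclass(traits))
  out <- traits[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Standardize traits by their standard deviation
#'
#' Each trait is divided by its sample SD (denominator n - 1) across animals.
#' Values are deliberately not mean-centered: the model carries an explicit
#' bias column instead, so only the scale is removed.
#'
#' @param traits Animals x traits numeric matrix.
#' @return Matrix of the same shape with unit-SD columns; trait metadata is
#'   preserved when present.
#' @export
standardize_traits <- function(traits) {
  vals <- unclass(traits)
  sds <- apply(vals, 2, stats::sd, na.rm = TRUE)
  bad <- which(is.na(sds) | sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance trait(s): ", paste(colnames(vals)[bad], collapse = ", "))
  }
  out <- sweep(vals, 2, sds, "/")
  meta <- attr(traits, "trait_meta")
  if (!is.null(meta)) out <- trait_matrix(out, meta)
  out
}

# internal: ordering used by the collinearity mask — timepoint descending,
# name ascending within a timepoint, no-timepoint (covariate) traits last
collinearity_order <- function(trait_names, meta) {
  tp_rank <- match(meta$timepoint, names(timepoint_grid()))
  # descending timepoint; NA (covariates) sort after all timepoints
  key <- ifelse(is.na(tp_rank), -Inf, tp_rank)
  order(-key, trait_names)
}

#' Collinearity filter over the trait set
#'
#' Prunes mutually redundant traits before the multivariate fit. The pinned
#' procedure: (1) sort traits by timepoint descending (ties by name; rank and
#' strain, which carry no timepoint, sort last); (2) form the symmetric
#' Spearman matrix; (3) mask entries on and above the diagonal except those
#' in the rank/strain columns; (4) mask the rank/strain rows entirely (they
#' are never dropped); (5) drop every trait whose row retains any unmasked
#' correlation above the threshold. Protected traits are always retained.
#'
#' @param traits Animals x traits matrix (a [trait_matrix()] or a plain
#'   matrix plus `protected`/`meta`).
#' @param threshold Correlation cutoff (default 0.7).
#' @param protected Character vector of protected trait names; defaults to
#'   the `protected` flags in the trait metadata.
#' @param use_abs Compare `abs(rho)` instead of the raw signed value
#'   (default FALSE: literal signed comparison).
#' @return List with `retained` (trait names, in original column order),
#'   `removed`, and `cor_matrix` (the sorted Spearman matrix).
#' @export
collinearity_filter <- function(traits, threshold = 0.7, protected = NULL,
                                use_abs = FALSE) {
  vals <- unclass(traits)
  meta <- attr(traits, "trait_meta")
  if (is.null(meta)) meta <- infer_trait_meta(colnames(vals))
  if (is.null(protected)) protected <- meta$trait[meta$protected]
  missing_prot <- setdiff(protected, colnames(vals))
  if (length(missing_prot) > 0) {
    stop("protected trait(s) absent: ", paste(missing_prot, collapse = ", "))
  }
  ord <- collinearity_order(colnames(vals), meta)
  nm <- colnames(vals)[ord]
  r <- stats::cor(apply(vals[, nm, drop = FALSE], 2, rank,
                        ties.method = "average"))
  dimnames(r) <- list(nm, nm)

  prot_idx <- which(nm %in% protected)
  mask <- upper.tri(r, diag = TRUE)
  if (length(prot_idx) > 0) {
    mask[, prot_idx] <- FALSE
    mask[prot_idx, ] <- TRUE
  }
  cmp <- if (use_abs) abs(r) else r
  cmp[mask] <- -Inf
  drop_row <- apply(cmp, 1, function(row) any(row > threshold))
  retained_sorted <- union(nm[!drop_row], protected)
  list(retained = intersect(colnames(vals), retained_sorted),
       removed = setdiff(colnames(vals), retained_sorted),
       cor_matrix = r)
}

#' Fit the multiple multivariate regression by pseudoinverse
#'
#' Models the beta matrix as `M = T_aug C` where `T_aug` is the standardized
#' trait matrix with a bias column of ones appended, and solves
#' `C = pinv(T_aug) M`. The coefficient matrix has one row per trait plus a
#' final bias row.
#'
#' @param traits Animals x traits standardized matrix (no bias column).
#' @param meth Animals x sites matrix, animal ids aligned by identifier.
#' @return Object of class `mmr_fit` with elements `C` ((traits + 1) x
#'   sites), `traits`, `sites`.
#' @export
fit_mmr <- function(traits, meth) {
  traits <- unclass(traits); meth <- unclass(meth)
  if (!identical(rownames(traits), rownames(meth))) {
    if (is.null(rownames(traits)) || is.null(rownames(meth)) ||
        !setequal(rownames(traits), rownames(meth))) {
      stop("animal ids of trait and methylation matrices do not match")
    }
    meth <- meth[rownames(traits), , drop = FALSE]
  }
  t_aug <- cbind(traits, bias = 1)
  cmat <- pinv(t_aug) %*% meth
  rownames(cmat) <- colnames(t_aug)
  structure(list(C = cmat, traits = colnames(traits), sites = colnames(meth)),
            class = "mmr_fit")
}

#' Predict methylation from traits under an MMR fit
#'
#' @param fit An `mmr_fit`.
#' @param traits Standardized trait matrix with the fit's trait columns.
#' @return Animals x sites predicted matrix `T_aug C`.
#' @export
predict_meth <- function(fit, traits) {
  t_aug <- cbind(unclass(traits)[, fit$traits, drop = FALSE], bias = 1)
  t_aug %*% fit$C
}

#' Invert an MMR fit to predict traits from methylation
#'
#' Computes `T_pred = M pinv(C)`. The bias row of `C` produces a constant
#' pseudo-trait prediction which is discarded.
#'
#' @param fit An `mmr_fit`.
#' @param meth Animals x sites matrix over the fit's sites.
#' @return Animals x traits predicted matrix.
#' @export
predict_traits <- function(fit, meth) {
  pred <- unclass(meth)[, fit$sites, drop = FALSE] %*% pinv(fit$C)
  colnames(pred) <- c(fit$traits, "bias")
  pred[, fit$traits, drop = FALSE]
}

#' Leave-one-out site predictability (MAE/sigma)
#'
#' For each animal, an MMR model is fitted on the remaining animals and used
#' to predict the held-out methylation row. Each site's mean absolute
#' prediction error is divided by its SD across animals; sites with
#' `MAE/sigma` below the threshold are deemed both variable and well
#' predicted. Zero-variance sites have an undefined ratio and are excluded.
#'
#' @param traits Standardized animals x traits matrix (no bias column).
#' @param meth Animals x sites matrix.
#' @param threshold Retention cutoff on MAE/sigma (default 0.5).
#' @return data.frame with columns `site`, `mae`, `sigma`, `ratio`,
#'   `retained`; attribute `n_zero_sd` counts excluded sites.
#' @export
loo_site_quality <- function(traits, meth, threshold = 0.5) {
  traits <- unclass(traits); meth <- unclass(meth)
  n <- nrow(traits)
  if (n < 3) stop("leave-one-out site quality needs at least 3 animals")
  pred <- matrix(NA_real_, n, ncol(meth), dimnames = dimnames(meth))
  for (a in seq_len(n)) {
    t_aug <- cbind(traits[-a, , drop = FALSE], bias = 1)
    cmat <- pinv(t_aug) %*% meth[-a, , drop = FALSE]
    pred[a, ] <- c(traits[a, ], 1) %*% cmat
  }
  mae <- colMeans(abs(pred - meth))
  sigma <- col_sds(meth)
  ratio <- ifelse(sigma > 0, mae / sigma, NA_real_)
  out <- data.frame(site = colnames(meth), mae = mae, sigma = sigma,
                    ratio = ratio,
                    retained = !is.na(ratio) & ratio < threshold,
                    row.names = NULL)
  attr(out, "n_zero_sd") <- sum(sigma == 0)
  out
}

#' Iterative inverse-predictability trait filter
#'
#' Repeatedly predicts every current trait from methylation through the
#' inverted MMR model (`T_pred = M pinv(C)`, leave-one-out over animals) and
#' removes, simultaneously, all non-forced traits whose Spearman correlation
#' between observed and predicted values falls below the threshold. Stops
#' when all remaining traits reach the threshold. Forced traits (rank and
#' the strain encodings, typically) are never removed and are reported with
#' their correlation.
#'
#' @param traits Standardized animals x traits matrix.
#' @param meth Animals x sites matrix restricted to the retained sites.
#' @param threshold Spearman retention cutoff (default 0.6).
#' @param forced Character vector of trait names exempt from removal.
#' @return data.frame with columns `trait`, `spearman` (the correlation at
#'   the round the trait was last evaluated), `retained`, `forced`;
#'   attribute `n_iterations`.
#' @export
iterative_trait_filter <- function(traits, meth, threshold = 0.6,
                                   forced = character(0)) {
  traits <- unclass(traits); meth <- unclass(meth)
  stopifnot(all(forced %in% colnames(traits)))
  current <- colnames(traits)
  rho_last <- stats::setNames(rep(NA_real_, ncol(traits)), colnames(traits))
  n <- nrow(traits)
  iter <- 0
  repeat {
    iter <- iter + 1
    tc <- traits[, current, drop = FALSE]
    pred <- matrix(NA_real_, n, length(current))
    for (a in seq_len(n)) {
      t_aug <- cbind(tc[-a, , drop = FALSE], bias = 1)
      cmat <- pinv(t_aug) %*% meth[-a, , drop = FALSE]
      tp <- meth[a, , drop = FALSE] %*% pinv(cmat)
      pred[a, ] <- tp[seq_along(current)]   # drop trailing bias prediction
    }
    rho <- vapply(seq_along(current),
                  function(j) spearman(tc[, j], pred[, j]), numeric(1))
    rho_last[current] <- rho
    drop <- current[rho < threshold & !(current %in% forced)]
    if (length(drop) == 0 || iter > ncol(traits)) break
    current <- setdiff(current, drop)
  }
  data.frame(trait = colnames(traits),
             spearman = unname(rho_last[colnames(traits)]),
             retained = colnames(traits) %in% current,
             forced = colnames(traits) %in% forced,
             row.names = NULL) -> out
  attr(out, "n_iterations") <- iter
  out
}
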
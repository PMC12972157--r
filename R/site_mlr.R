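#' Per-site multiple linear regression of methylation on selected traits
#'
#' For each CpG site, fits `y = b0 + b1 x1 + ... + bp xp + e` by ordinary
#' least squares, where `y` is the site's methylation level and the `x` are
#' the methylation-associated traits (standardized, as they flow from the
#' multivariate stage). Significance per (site, trait) is the two-sided
#' t-test on the slope coefficient; p-values are Benjamini-Hochberg adjusted
#' within each trait across sites.
#'
#' @param meth Animals x sites matrix (the retained sites).
#' @param traits Animals x traits matrix of the selected traits.
#' @return Object of class `mlr_result`: a list with `table` (data.frame of
#'   site, trait, beta, p, adjp), `intercept` and `sigma2` (per-site residual
#'   variance), `df` residual degrees of freedom.
#' @export
fit_site_mlr <- function(meth, traits) {
  meth <- unclass(meth); traits <- unclass(traits)
  stopifnot(identical(rownames(meth), rownames(traits)))
  n <- nrow(traits); p <- ncol(traits)
  if (n <= p + 1) stop("need n_animals > n_traits + 1 for per-site regression")
  x <- cbind(`(Intercept)` = 1, traits)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }
  xtx_inv <- chol2inv(chol(crossprod(x)))
  coefs <- xtx_inv %*% crossprod(x, meth)        # (p+1) x sites
  resid <- meth - x %*% coefs
  df <- n - p - 1
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(outer(diag(xtx_inv), sigma2))       # (p+1) x sites
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)

  slope_rows <- seq_len(p) + 1
  tab <- data.frame(
    site = rep(colnames(meth), each = p),
    trait = rep(colnames(traits), times = ncol(meth)),
    beta = as.vector(coefs[slope_rows, , drop = FALSE]),
    p = as.vector(pval[slope_rows, , drop = FALSE]),
    row.names = NULL
  )
  tab$adjp <- bh_adjust(tab$p, group = tab$trait)
  structure(list(table = tab,
                 intercept = stats::setNames(coefs[1, ], colnames(meth)),
                 sigma2 = stats::setNames(sigma2, colnames(meth)),
                 df = df),
            class = "mlr_result")
}

#' @export
print.mlr_result <- function(x, ...) {
  cat(sprintf("mlr_result: %d sites x %d traits (df = %d)\n",
              length(x$sigma2), length(unique(x$table$trait)), x$df))
  invisible(x)
}

#' Benjamini-Hochberg adjustment, optionally grouped
#'
#' Standard step-up FDR adjustment. When `group` is given, the adjustment is
#' applied independently within each group (here: within each trait, across
#' sites).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param group Optional grouping vector of the same length.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, group = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(group)) return(stats::p.adjust(p, method = "BH"))
  adj <- p
  for (g in unique(group)) {
    idx <- which(group == g)
    adj[idx] <- stats::p.adjust(p[idx], method = "BH")
  }
  adj
}

#' Select significant sites per trait and build category unions
#'
#' Thresholds the adjusted p-values to produce a significant-site set per
#' trait, then merges related sets: the blood-glucose set is the union over
#' glucose-trait sets, and the strain set is the union over the two encoded
#' strain traits.
#'
#' @param mlr An `mlr_result`.
#' @param alpha Significance cutoff on the adjusted p-value (default 0.01).
#' @param glucose_traits,strain_traits Trait names composing each union;
#'   default: traits whose name contains "GLU" / starts with "strain_".
#' @return List with `per_trait` (named list of site-id vectors), `glucose`
#'   and `strain` (union sets).
#' @export
select_sites <- function(mlr, alpha = 0.01, glucose_traits = NULL,
                         strain_traits = NULL) {
  tab <- mlr$table
  traits <- unique(tab$trait)
  if (is.null(glucose_traits)) glucose_traits <- grep("GLU", traits, value = TRUE)
  if (is.null(strain_traits)) strain_traits <- grep("^strain_", traits, value = TRUE)
  per_trait <- lapply(stats::setNames(traits, traits), function(tr) {
    sel <- tab$trait == tr & tab$adjp < alpha
    unique(tab$site[sel])
  })
  union_of <- function(nms) {
    sort(unique(unlist(per_trait[nms], use.names = FALSE)))
  }
  list(per_trait = per_trait,
       glucose = union_of(glucose_traits),
       strain = union_of(strain_traits))
}
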
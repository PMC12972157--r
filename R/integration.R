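#' Named CpG site set
#'
#' @param name Set label.
#' @param ids Character vector of site ids (single genome build);
#'   duplicates are removed.
#' @param universe_size Number of sites in the assay universe.
#' @return Object of class `site_set`.
#' @export
site_set <- function(name, ids, universe_size) {
  ids <- unique(as.character(ids))
  if (length(ids) > universe_size) stop("set larger than its universe")
  structure(list(name = name, ids = ids, universe_size = universe_size),
            class = "site_set")
}

#' Intersect the glucose, strain and aging site sets
#'
#' Exact pairwise and three-way intersections of the Model-1 trait-
#' associated sets with the Model-2 elastic-net (aging) set, plus the
#' three-way overlap expressed as a percentage of the smallest set, rounded
#' to the nearest integer.
#'
#' @param glucose,strain,aging `site_set` objects (or character vectors) on
#'   the same genome build.
#' @return List of class `overlap_result`: `sizes`, `pairwise` counts,
#'   `triple` count, `triple_sites`, `pct_of_smallest`.
#' @export
intersect_sets <- function(glucose, strain, aging) {
  get_ids <- function(s) if (inherits(s, "site_set")) s$ids else unique(as.character(s))
  g <- get_ids(glucose); s <- get_ids(strain); a <- get_ids(aging)
  triple <- intersect(intersect(g, s), a)
  sizes <- c(glucose = length(g), strain = length(s), aging = length(a))
  structure(list(
    sizes = sizes,
    pairwise = c(glucose_strain = length(intersect(g, s)),
                 glucose_aging = length(intersect(g, a)),
                 strain_aging = length(intersect(s, a))),
    triple = length(triple),
    triple_sites = sort(triple),
    pct_of_smallest = round(100 * length(triple) / min(sizes))
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result: sets %s; triple = %d (~%s%% of smallest)\n",
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = ", "),
              x$triple, format(x$pct_of_smallest)))
  invisible(x)
}

#' Monte-Carlo enrichment p-value for a multi-set overlap
#'
#' Null model: the sets are drawn independently and uniformly from the site
#' universe. The overlap of independently drawn uniform sets decomposes into
#' a chain of hypergeometric draws (the intersection of a uniform random set
#' with any fixed set of size m is hypergeometric), which is sampled
#' directly. The p-value is the add-one-smoothed exceedance probability
#' `(1 + #{overlap >= observed}) / (1 + n_mc)`. A conditional mode fixes the
#' observed overlap of the first two sets and resamples only the third.
#'
#' @param universe_size Number of sites in the universe.
#' @param sizes Integer vector of set sizes (2 or more sets).
#' @param observed Observed overlap count of all sets.
#' @param n_mc Number of Monte-Carlo replicates (>= 10,000).
#' @param seed Integer seed.
#' @param conditional Fix the first-two-set overlap at `fixed_overlap` and
#'   resample only the last set (default FALSE).
#' @param fixed_overlap Observed overlap of all but the last set; required
#'   when `conditional = TRUE`.
#' @return The smoothed p-value, with attribute `null_mean`.
#' @export
overlap_pvalue <- function(universe_size, sizes, observed, n_mc = 1e5,
                           seed = 1, conditional = FALSE,
                           fixed_overlap = NULL) {
  stopifnot(length(sizes) >= 2, all(sizes <= universe_size), n_mc >= 1e4)
  set.seed(as.integer(seed))
  if (conditional) {
    if (is.null(fixed_overlap)) stop("conditional mode needs fixed_overlap")
    ov <- stats::rhyper(n_mc, m = fixed_overlap,
                        n = universe_size - fixed_overlap,
                        k = sizes[length(sizes)])
  } else {
    ov <- rep.int(sizes[1], n_mc)
    for (i in seq_along(sizes)[-1]) {
      ov <- stats::rhyper(n_mc, m = ov, n = universe_size - ov, k = sizes[i])
    }
  }
  p <- (1 + sum(ov >= observed)) / (1 + n_mc)
  attr(p, "null_mean") <- mean(ov)
  p
}

#' Attribute the three-way intersection to glucose timepoints
#'
#' Partitions the triple-overlap set by membership in the per-timepoint
#' blood-glucose sets (month 14 only, month 16 only, both). Every triple
#' site must belong to at least one of them, since the glucose set is their
#' union.
#'
#' @param triple_sites Character vector (the three-way intersection).
#' @param m14_set,m16_set Per-timepoint glucose site sets.
#' @return Named integer vector: `m14_only`, `m16_only`, `both`.
#' @export
attribute_glucose_timepoints <- function(triple_sites, m14_set, m16_set) {
  in14 <- triple_sites %in% m14_set
  in16 <- triple_sites %in% m16_set
  if (any(!in14 & !in16)) {
    stop("inconsistent inputs: triple set contains sites outside the glucose union")
  }
  c(m14_only = sum(in14 & !in16), m16_only = sum(!in14 & in16),
    both = sum(in14 & in16))
}

#' One-way ANOVA of blood glucose by rank/strain combination
#'
#' Compares glucose variance across and within rank-by-strain groups at a
#' given timepoint; a larger F indicates stronger clustering of glucose by
#' group.
#'
#' @param values Numeric vector of glucose measurements (one per animal).
#' @param strain,rank Label vectors aligned with `values`.
#' @return List with `F`, `p`, `df` (c(between, within)), `n_groups`.
#'   Degenerate input (all values equal) reports `F = 0`, `p = 1`.
#' @export
glucose_group_anova <- function(values, strain, rank) {
  stopifnot(length(values) == length(strain), length(values) == length(rank))
  keep <- !is.na(values)
  values <- values[keep]
  group <- droplevels(interaction(rank[keep], strain[keep], drop = TRUE))
  tab <- table(group)
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop("need at least 2 groups with at least 2 observations")
  }
  if (stats::var(values) == 0) {
    return(list(F = 0, p = 1, df = c(length(tab) - 1,
                                     length(values) - length(tab)),
                n_groups = length(tab)))
  }
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
       df = s[["Df"]], n_groups = length(tab))
}

#' Run the full two-model pipeline on a synthetic study
#'
#' Convenience driver chaining every stage at a configurable scale:
#' generates both cohorts, runs the trait-to-methylation model (collinearity
#' filter, pseudoinverse fit, MAE/sigma site filter, iterative trait filter,
#' per-site regression), trains the mortality network with grouped CV,
#' transfers predictions to the methylation cohort, selects aging sites by
#' elastic net, and intersects the resulting site sets.
#'
#' @param config A [synth_config()].
#' @param mlp An [mlp_config()].
#' @param n_mc Monte-Carlo replicates for the overlap p-value.
#' @param alpha Significance cutoff for per-site regression (default 0.01).
#' @return List with the per-stage results (`site_quality`, `trait_filter`,
#'   `mlr`, `sets`, `cv`, `enet`, `overlap`, `overlap_p`).
#' @export
run_pipeline <- function(config = synth_config(), mlp = mlp_config(),
                         n_mc = 1e4, alpha = 0.01) {
  a <- generate_cohort_a(config)
  b <- generate_cohort_b(config)

  t_std <- standardize_traits(drop_incomplete_animals(a$traits))
  meta <- attr(a$traits, "trait_meta")
  protected <- meta$trait[meta$protected]
  coll <- collinearity_filter(t_std, protected = protected)
  t_sel <- t_std[, coll$retained, drop = FALSE]

  sq <- loo_site_quality(t_sel, a$meth)
  m_ret <- unclass(a$meth)[, sq$site[sq$retained], drop = FALSE]
  tf <- iterative_trait_filter(t_sel, m_ret, forced = protected)
  t_final <- t_sel[, tf$trait[tf$retained], drop = FALSE]
  mlr <- fit_site_mlr(m_ret, t_final)
  sets <- select_sites(mlr, alpha = alpha)

  fv <- build_feature_vectors(b$records, b$death_age)
  cv <- evaluate_cv(fv, mlp, seed = config$seed)
  full_model <- train_mlp(fv_matrix(fv), fv$D, mlp,
                          seed = derive_seed(config$seed, "full"),
                          exempt = mlp_exempt_columns())

  labels <- as.data.frame(a$truth$labels)
  rec_a <- cohort_a_records(a, labels)
  fv_a <- build_feature_vectors(rec_a, death_age = NULL)
  preds <- predict_cohort_a(full_model, fv_a)
  avg <- weighted_average(preds)

  enet <- fit_elastic_net(avg[rownames(a$meth)], unclass(a$meth),
                          seed = config$seed)
  ov <- intersect_sets(sets$glucose, sets$strain, enet$selected)
  ov_p <- overlap_pvalue(config$n_sites, ov$sizes, ov$triple, n_mc = n_mc,
                         seed = config$seed)
  list(site_quality = sq, trait_filter = tf, mlr = mlr, sets = sets,
       cv = cv, enet = enet, overlap = ov, overlap_p = ov_p)
}

# internal: reshape a cohort-A trait matrix into longitudinal records usable
# by the mortality network (glucose varies by timepoint; other traits are
# taken from their closest available column, constant otherwise)
cohort_a_records <- function(a, labels) {
  vals <- unclass(a$traits)
  tps <- names(timepoint_grid())
  glu_cols <- grep("GLU", colnames(vals), value = TRUE)
  glu_tp <- sub("_.*", "", glu_cols)
  pick <- function(cat) {
    cols <- grep(paste0("_aging_phase_", cat, "$"), colnames(vals), value = TRUE)
    if (length(cols) == 0) return(rep(NA_real_, nrow(vals)))
    rowMeans(vals[, cols, drop = FALSE])
  }
  base <- data.frame(animal_id = rownames(vals),
                     FI_kcal = pick("FI_kcal"), BW_g = pick("BW_g"),
                     FM_g = pick("FM_g"), FFM_g = pick("FFM_g"),
                     strain = labels$strain[match(rownames(vals), labels$animal_id)],
                     rank = labels$rank[match(rownames(vals), labels$animal_id)])
  scales <- trait_scales()
  fill_na <- function(x, mu) ifelse(is.na(x), mu, x)
  do.call(rbind, lapply(glu_tp, function(tp) {
    df <- base
    df$timepoint <- tp
    df$age_weeks <- unname(timepoint_grid()[tp])
    df$GLU_mgdl <- vals[, glu_cols[glu_tp == tp][1]]
    df$FI_kcal <- fill_na(df$FI_kcal, scales$FI_kcal[1])
    df$BW_g <- fill_na(df$BW_g, scales$BW_g[1])
    df$FM_g <- fill_na(df$FM_g, scales$FM_g[1])
    df$FFM_g <- fill_na(df$FFM_g, scales$FFM_g[1])
    df
  }))
}
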
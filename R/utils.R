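#' Standard timepoint grid
#'
#' The ordered measurement schedule shared by both cohorts: weeks 12 and 16,
#' then months 6 through 16 in two-month steps. Values are approximate ages in
#' weeks, used as the time axis for longitudinal records.
#'
#' @return Named numeric vector of ages in weeks, in chronological order.
#' @export
timepoint_grid <- function() {
  c(w12 = 12, w16 = 16, M6 = 26, M8 = 35, M10 = 43, M12 = 52, M14 = 61, M16 = 70)
}

#' Number of training passes implied by the batch convention
#'
#' The mortality network counts one "epoch" per training batch, so the number
#' of passes over the data equals the number of batches in one pass:
#' ceiling(n samples / batch size). With the full 3,390-vector cohort and
#' batches of 32 this gives 106 passes; a ~2,700-vector training split gives
#' ~86.
#'
#' @param n_samples Number of training vectors.
#' @param batch_size Minibatch size (default 32).
#' @return Integer number of passes.
#' @export
n_training_passes <- function(n_samples, batch_size = 32) {
  stopifnot(n_samples >= 1, batch_size >= 1)
  as.integer(ceiling(n_samples / batch_size))
}

# internal: sample SD (denominator n - 1) down columns of a matrix
col_sds <- function(x) {
  apply(x, 2, stats::sd)
}

# internal: Spearman correlation with average ranks for ties
spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# internal: deterministic child seed derived from a parent seed and a tag,
# kept below 2^31 so it is a valid R integer seed
derive_seed <- function(seed, tag) {
  offset <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) + offset * 1009) %% .Machine$integer.max)
}
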
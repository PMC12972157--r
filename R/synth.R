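#' Configuration for the synthetic cohort generator
#'
#' Builds seeded mouse cohorts that emulate the two arms of the study design:
#' a methylation cohort ("cohort A": 46 animals phenotyped to 16 months and
#' assayed on a methylation array at 17 months) and a survival cohort
#' ("cohort B": 345 animals followed longitudinally to death). A configurable
#' subset of CpG sites is linearly driven by glucose or strain, and age at
#' death is a linear-Gaussian function of each animal's latent trait levels,
#' so every downstream stage can be checked against planted ground truth.
#'
#' @param n_animals_A Animals in the methylation cohort (default 46).
#' @param n_sites CpG sites on the synthetic array (default 2000; the scale
#'   knob for test-size data).
#' @param n_traits Total trait columns for cohort A, including rank and the
#'   two strain encodings (default 19).
#' @param n_timepoints Number of shared timepoints, taken from the start of
#'   [timepoint_grid()] (default 8).
#' @param planted_glucose_sites,planted_strain_sites Number of CpG sites
#'   linearly driven by a glucose trait / a strain encoding.
#' @param effect_size Planted slope in beta-units per driving-trait SD
#'   (default 0.1).
#' @param noise_sd_meth Per-site Gaussian noise SD in beta-units
#'   (default 0.02).
#' @param n_animals_B Animals in the survival cohort (default 345).
#' @param lifespan_baseline Baseline age at death, weeks (default 105).
#' @param lifespan_slopes Named vector of weeks-of-life per unit of each
#'   driver: latent SD units for the five numeric traits, raw code units for
#'   covariates. Defaults give glucose, fat mass and strain the strongest
#'   effects, mirroring the traits the mortality model flags.
#' @param noise_sd_lifespan Gaussian noise on age at death, weeks (default 4).
#' @param collinear_pairs Number of traits duplicated verbatim to create
#'   Spearman ~= 1 pairs for the collinearity filter (default 0).
#' @param rank_preset "uniform" assigns ranks round-robin within strain;
#'   "observed" reproduces the deposited pattern in which no CD1 animal is
#'   subordinate.
#' @param seed Integer master seed; identical config + seed gives
#'   bit-identical cohorts.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_animals_A = 46, n_sites = 2000, n_traits = 19,
                         n_timepoints = 8,
                         planted_glucose_sites = 100,
                         planted_strain_sites = 100,
                         effect_size = 0.1, noise_sd_meth = 0.02,
                         n_animals_B = 345,
                         lifespan_baseline = 105,
                         lifespan_slopes = c(FI_kcal = 0, BW_g = -2, FM_g = -4,
                                             FFM_g = 5, GLU_mgdl = -6,
                                             strain_b6_or_sv = 2,
                                             strain_cd1_or_b6 = 6,
                                             rank_code = 2),
                         noise_sd_lifespan = 4,
                         collinear_pairs = 0,
                         rank_preset = c("uniform", "observed"),
                         seed = 1) {
  rank_preset <- match.arg(rank_preset)
  cfg <- list(n_animals_A = n_animals_A, n_sites = n_sites,
              n_traits = n_traits, n_timepoints = n_timepoints,
              planted_glucose_sites = planted_glucose_sites,
              planted_strain_sites = planted_strain_sites,
              effect_size = effect_size, noise_sd_meth = noise_sd_meth,
              n_animals_B = n_animals_B,
              lifespan_baseline = lifespan_baseline,
              lifespan_slopes = lifespan_slopes,
              noise_sd_lifespan = noise_sd_lifespan,
              collinear_pairs = collinear_pairs,
              rank_preset = rank_preset, seed = as.integer(seed))
  counts <- c(cfg$n_animals_A, cfg$n_sites, cfg$n_traits, cfg$n_timepoints,
              cfg$n_animals_B)
  if (any(counts < 1)) stop("all counts must be positive")
  if (cfg$noise_sd_meth < 0 || cfg$noise_sd_lifespan < 0) {
    stop("noise SDs must be >= 0")
  }
  if (cfg$planted_glucose_sites + cfg$planted_strain_sites > cfg$n_sites) {
    stop("planted_glucose_sites + planted_strain_sites exceeds n_sites")
  }
  if (cfg$n_timepoints > length(timepoint_grid())) {
    stop("n_timepoints exceeds the standard timepoint grid")
  }
  if (cfg$n_traits < 6) {
    stop("n_traits must be >= 6 (rank, two strain encodings, three glucose timepoints)")
  }
  class(cfg) <- "synth_config"
  cfg
}

# trait measurement scales: (mean, SD) per category, field-typical units
trait_scales <- function() {
  list(FI_kcal = c(12, 2), BW_g = c(35, 5), FM_g = c(10, 3),
       FFM_g = c(25, 3), GLU_mgdl = c(140, 25))
}

# internal: strain labels in deposited proportions, rank per preset
assign_labels <- function(n, proportions, rank_preset) {
  n_per <- round(n * proportions / sum(proportions))
  n_per[1] <- n - sum(n_per[-1])
  strain <- rep(c("C57BL/6J", "CD1", "Sv129Ev"), times = n_per)
  ranks <- c("subordinate", "undefined", "dominant")
  rank <- unlist(lapply(seq_along(n_per), function(i) {
    opts <- if (rank_preset == "observed" && i == 2) ranks[-1] else ranks
    rep_len(opts, n_per[i])
  }))
  data.frame(strain = strain, rank = rank)
}

#' Generate a synthetic methylation cohort (cohort A)
#'
#' Emits a trait matrix (glucose at three aging-phase timepoints, further
#' body-composition traits across timepoints, rank and the two strain
#' encodings) and a beta matrix in which planted sites are affine functions
#' of their driving trait plus Gaussian noise, clipped to `[0,1]`. Non-planted
#' sites fluctuate around per-site base levels independently of the traits.
#'
#' @param config A [synth_config()].
#' @return List with `traits` ([trait_matrix()]), `meth` ([meth_matrix()]),
#'   and `truth` (planted site ids, driving trait and true slope per planted
#'   site, plus the number of beta values clipped).
#' @export
generate_cohort_a <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "cohort_a"))
  n <- config$n_animals_A
  ids <- sprintf("A%03d", seq_len(n))
  labels <- assign_labels(n, c(18, 12, 16), config$rank_preset)
  cov <- encode_covariates(labels$strain, labels$rank)

  tp <- names(timepoint_grid())[seq_len(config$n_timepoints)]
  scales <- trait_scales()
  # glucose at the three latest aging-phase timepoints first, then other
  # categories cycling over timepoints until n_traits columns exist
  glu_tp <- intersect(c("M6", "M14", "M16"), tp)
  if (length(glu_tp) < 3) glu_tp <- utils::tail(tp, 3)
  numeric_names <- paste0(glu_tp, "_aging_phase_GLU_mgdl")
  other_cats <- setdiff(names(scales), "GLU_mgdl")
  fill <- as.vector(t(outer(rev(tp), other_cats, paste, sep = "_aging_phase_")))
  n_numeric <- config$n_traits - 3 - length(numeric_names)
  if (n_numeric < 0) stop("n_traits too small for the glucose timepoints")
  numeric_names <- c(numeric_names, utils::head(fill, n_numeric))

  vals <- sapply(numeric_names, function(nm) {
    cat <- sub(".*_aging_phase_", "", nm)
    sc <- scales[[cat]]
    sc[1] + sc[2] * stats::rnorm(n)
  })
  traits <- cbind(vals, rank_code = cov$rank_code,
                  strain_b6_or_sv = cov$strain_b6_or_sv,
                  strain_cd1_or_b6 = cov$strain_cd1_or_b6)
  rownames(traits) <- ids

  if (config$collinear_pairs > 0) {
    k <- min(config$collinear_pairs, length(numeric_names))
    dups <- traits[, numeric_names[seq_len(k)], drop = FALSE]
    colnames(dups) <- paste0(numeric_names[seq_len(k)], "_dup")
    traits <- cbind(traits, dups)
  }

  site_ids <- sprintf("cg%08d", seq_len(config$n_sites))
  base <- stats::runif(config$n_sites, 0.15, 0.85)
  meth <- matrix(stats::rnorm(n * config$n_sites, sd = config$noise_sd_meth),
                 nrow = n, dimnames = list(ids, site_ids))
  meth <- sweep(meth, 2, base, "+")

  n_glu <- config$planted_glucose_sites
  n_str <- config$planted_strain_sites
  glu_sites <- site_ids[seq_len(n_glu)]
  str_sites <- site_ids[n_glu + seq_len(n_str)]
  glu_traits <- paste0(glu_tp, "_aging_phase_GLU_mgdl")
  str_traits <- c("strain_b6_or_sv", "strain_cd1_or_b6")

  driver <- character(0)
  coef <- numeric(0)
  plant <- function(sites, drivers) {
    for (i in seq_along(sites)) {
      tr <- drivers[(i - 1) %% length(drivers) + 1]
      z <- traits[, tr]
      z <- (z - mean(z)) / stats::sd(z)
      meth[, sites[i]] <<- meth[, sites[i]] + config$effect_size * z
      driver[sites[i]] <<- tr
      coef[sites[i]] <<- config$effect_size
    }
  }
  if (n_glu > 0) plant(glu_sites, glu_traits)
  if (n_str > 0) plant(str_sites, str_traits)

  n_clipped <- sum(meth < 0 | meth > 1)
  meth <- pmin(pmax(meth, 0), 1)

  list(traits = trait_matrix(traits),
       meth = meth_matrix(meth, build = "mm39"),
       truth = list(glucose_sites = glu_sites, strain_sites = str_sites,
                    driver = driver, coef = coef, n_clipped = n_clipped,
                    labels = cbind(animal_id = ids, labels)))
}

#' Generate a synthetic survival cohort (cohort B)
#'
#' Longitudinal records (one row per animal x timepoint) of the five numeric
#' healthspan traits plus strain and rank labels, and an age at death that is
#' a linear-Gaussian function of each animal's latent trait levels:
#' `death = baseline + sum(slope * driver) + N(0, noise_sd_lifespan)`,
#' floored one week above the last measurement so every record has positive
#' time until death. Numeric trait records drift with age around the latent
#' level (body mass rises, glucose declines), with small measurement noise.
#'
#' @param config A [synth_config()].
#' @return List with `records` (long data.frame: `animal_id`, `timepoint`,
#'   `age_weeks`, the five traits, `strain`, `rank`), `death_age` (named
#'   vector of weeks), and `truth` (latent trait matrix and generating
#'   slopes).
#' @export
generate_cohort_b <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "cohort_b"))
  n <- config$n_animals_B
  ids <- sprintf("B%04d", seq_len(n))
  labels <- assign_labels(n, c(172, 86, 87), config$rank_preset)
  cov <- encode_covariates(labels$strain, labels$rank)

  tp <- timepoint_grid()[seq_len(config$n_timepoints)]
  scales <- trait_scales()
  cats <- names(scales)
  # per-category age trend, in latent-SD units across the measurement window
  trend <- c(FI_kcal = 0.2, BW_g = 1.0, FM_g = 0.8, FFM_g = -0.3,
             GLU_mgdl = -0.8)

  latent <- matrix(stats::rnorm(n * length(cats)), nrow = n,
                   dimnames = list(ids, cats))

  slopes <- config$lifespan_slopes
  drivers <- cbind(latent,
                   strain_b6_or_sv = cov$strain_b6_or_sv,
                   strain_cd1_or_b6 = cov$strain_cd1_or_b6,
                   rank_code = cov$rank_code)
  used <- intersect(names(slopes), colnames(drivers))
  death <- config$lifespan_baseline +
    as.vector(drivers[, used, drop = FALSE] %*% slopes[used]) +
    stats::rnorm(n, sd = config$noise_sd_lifespan)
  death <- pmax(death, max(tp) + 1)
  names(death) <- ids

  age_c <- (tp - mean(tp)) / stats::sd(tp)
  records <- do.call(rbind, lapply(seq_along(tp), function(j) {
    vals <- do.call(cbind, lapply(stats::setNames(cats, cats), function(cat) {
      sc <- scales[[cat]]
      sc[1] + sc[2] * (latent[, cat] + trend[cat] * age_c[j]) +
        stats::rnorm(n, sd = 0.1 * sc[2])
    }))
    data.frame(animal_id = ids, timepoint = names(tp)[j],
               age_weeks = unname(tp[j]), vals,
               strain = labels$strain, rank = labels$rank)
  }))
  rownames(records) <- NULL

  list(records = records, death_age = death,
       truth = list(latent = latent, slopes = slopes,
                    baseline = config$lifespan_baseline))
}

#' Generate a synthetic cross-build site mapping
#'
#' Emulates an mm39-to-mm10 probe-id lookup: each retained source site maps
#' to a renamed target-build id, and `round(drop_fraction * N)` sites are
#' absent from the table (probes with no counterpart in the target build).
#'
#' @param site_ids Character vector of source-build site ids.
#' @param drop_fraction Fraction of sites to omit, in `[0, 1)`.
#' @param seed Integer seed selecting which sites are dropped.
#' @return data.frame with columns `source` and `target`, usable with
#'   [map_sites()].
#' @export
generate_site_mapping <- function(site_ids, drop_fraction = 0, seed = 1) {
  stopifnot(drop_fraction >= 0, drop_fraction < 1)
  set.seed(derive_seed(seed, "site_mapping"))
  n_drop <- round(drop_fraction * length(site_ids))
  dropped <- if (n_drop > 0) sample(site_ids, n_drop) else character(0)
  keep <- setdiff(site_ids, dropped)
  data.frame(source = keep, target = paste0("mm10_", keep))
}
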
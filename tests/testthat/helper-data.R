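# shared builders for test fixtures (all generated in code, no files)

# hand-crafted network with all-zero weights and a fixed output bias:
# predicts `value` for any input
constant_mlp <- function(features, value) {
  sizes <- c(length(features), 4, 4, 1)
  layers <- lapply(1:3, function(i) {
    list(w = matrix(0, sizes[i], sizes[i + 1]), b = rep(0, sizes[i + 1]))
  })
  layers[[3]]$b <- value
  structure(list(layers = layers,
                 center = stats::setNames(rep(0, length(features)), features),
                 scale = stats::setNames(rep(1, length(features)), features),
                 features = features, config = mlp_config(), passes = 0L,
                 seed = 0L),
            class = "mlp_model")
}

# independent standard-normal trait matrix with the standard naming scheme
null_trait_matrix <- function(n = 46, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * 8), n,
              dimnames = list(sprintf("A%02d", seq_len(n)),
                              c(paste0(c("M16", "M14", "M12", "M10", "M8"),
                                       "_aging_phase_BW_g"),
                                "rank_code", "strain_b6_or_sv",
                                "strain_cd1_or_b6")))
  trait_matrix(m)
}

# feature matrix for a feature-vector frame (mirrors the network's schema)
fv_features <- function(fv) {
  as.matrix(fv[, unlist(mlp_parameters(), use.names = FALSE)])
}

# lifespan slopes with a single dominant driver
single_driver_slopes <- function(driver = "GLU_mgdl", slope = -10) {
  s <- c(FI_kcal = 0, BW_g = 0, FM_g = 0, FFM_g = 0, GLU_mgdl = 0,
         strain_b6_or_sv = 0, strain_cd1_or_b6 = 0, rank_code = 0)
  s[driver] <- slope
  s
}
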
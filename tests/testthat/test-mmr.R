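test_that("trait standardization divides by the sample SD without centering", {
  m <- matrix(c(2, 4, 6), 3, dimnames = list(paste0("A", 1:3),
                                             "M16_aging_phase_GLU_mgdl"))
  out <- standardize_traits(trait_matrix(m))
  expect_equal(unname(unclass(out)[, 1]), c(1, 2, 3))  # sample SD is 2

  already <- matrix(scale(rnorm(20), center = FALSE), 20,
                    dimnames = list(sprintf("A%02d", 1:20), "M14_aging_phase_BW_g"))
  # force SD exactly 1
  already <- already / sd(already)
  out2 <- standardize_traits(trait_matrix(already))
  expect_equal(unclass(out2)[, 1], already[, 1], tolerance = 1e-12)

  const <- matrix(5, 4, dimnames = list(paste0("A", 1:4), "M8_aging_phase_FM_g"))
  expect_error(standardize_traits(trait_matrix(const)), "M8_aging_phase_FM_g")
})

test_that("pseudoinverse satisfies the Moore-Penrose identity on the augmented design", {
  set.seed(1)
  t_aug <- cbind(matrix(rnorm(46 * 19), 46), 1)
  expect_lt(max(abs(t_aug %*% pinv(t_aug) %*% t_aug - t_aug)), 1e-10)
  # rank-deficient case: identity still holds
  t_def <- cbind(t_aug, t_aug[, 1])
  expect_lt(max(abs(t_def %*% pinv(t_def) %*% t_def - t_def)), 1e-10)
})

test_that("MMR recovers planted coefficients exactly at zero noise", {
  set.seed(2)
  n <- 10; p <- 4; s <- 50
  traits <- matrix(rnorm(n * p), n,
                   dimnames = list(sprintf("A%02d", 1:n), paste0("t", 1:p)))
  c_star <- matrix(rnorm((p + 1) * s), p + 1,
                   dimnames = list(c(paste0("t", 1:p), "bias"), paste0("s", 1:s)))
  meth <- cbind(traits, 1) %*% c_star
  colnames(meth) <- paste0("s", 1:s)
  fit <- fit_mmr(traits, meth)
  expect_lt(max(abs(fit$C - c_star)), 1e-8)
  # independent oracle: normal equations
  x <- cbind(traits, bias = 1)
  c_ne <- solve(crossprod(x)) %*% crossprod(x, meth)
  expect_equal(unname(fit$C), unname(c_ne), tolerance = 1e-8)
  # prediction reproduces the input in the noiseless case
  expect_lt(max(abs(predict_meth(fit, traits) - meth)), 1e-8)
})

test_that("MMR of an all-zero methylation matrix is all-zero", {
  set.seed(3)
  traits <- matrix(rnorm(20), 5, dimnames = list(paste0("A", 1:5),
                                                 paste0("t", 1:4)))
  meth <- matrix(0, 5, 7, dimnames = list(rownames(traits), paste0("s", 1:7)))
  fit <- fit_mmr(traits, meth)
  expect_true(all(fit$C == 0))
})

test_that("mmr errors on misaligned animal ids", {
  traits <- matrix(rnorm(8), 4, dimnames = list(paste0("A", 1:4), c("t1", "t2")))
  meth <- matrix(runif(8), 4, dimnames = list(paste0("B", 1:4), c("s1", "s2")))
  expect_error(fit_mmr(traits, meth), "animal ids")
})

test_that("collinearity masking drops copies and trait-covariate proxies, keeps protected", {
  set.seed(4)
  n <- 30
  a <- rnorm(n)
  b <- rnorm(n)
  rk <- rep(0:2, length.out = n)
  vals <- cbind(M16_aging_phase_GLU_mgdl = a,
                M12_aging_phase_BW_g = b,
                M6_aging_phase_FM_g = a,          # exact copy of the M16 trait
                M8_aging_phase_FFM_g = rk + 0.001 * rnorm(n),  # rank proxy
                rank_code = rk,
                strain_b6_or_sv = rep(0:1, length.out = n),
                strain_cd1_or_b6 = rep(c(1, 1, 0), length.out = n))
  rownames(vals) <- sprintf("A%02d", 1:n)
  res <- collinearity_filter(trait_matrix(vals))
  expect_true(all(c("M16_aging_phase_GLU_mgdl", "M12_aging_phase_BW_g",
                    "rank_code", "strain_b6_or_sv", "strain_cd1_or_b6") %in%
                    res$retained))
  # the later-timepoint copy sees rho = 1 below the diagonal and is dropped
  expect_true("M6_aging_phase_FM_g" %in% res$removed)
  # the rank column is exempt from masking, so its proxy is dropped too
  expect_true("M8_aging_phase_FFM_g" %in% res$removed)
  expect_error(collinearity_filter(trait_matrix(vals), protected = "absent"),
               "absent")
})

test_that("mutually independent traits survive the collinearity filter", {
  kept_all <- vapply(1:100, function(s) {
    tm <- null_trait_matrix(n = 46, seed = s)
    length(collinearity_filter(tm)$removed) == 0
  }, logical(1))
  expect_gte(mean(kept_all), 0.95)
})

test_that("LOO MAE/sigma separates planted from noise sites", {
  cfg <- synth_config(n_sites = 400, planted_glucose_sites = 100,
                      planted_strain_sites = 100, seed = 13)
  a <- generate_cohort_a(cfg)
  t_std <- standardize_traits(a$traits)
  sq <- loo_site_quality(t_std, a$meth)
  planted <- c(a$truth$glucose_sites, a$truth$strain_sites)
  noise <- setdiff(sq$site, planted)
  expect_gte(mean(planted %in% sq$site[sq$retained]), 0.9)
  expect_gte(mean(!(noise %in% sq$site[sq$retained])), 0.95)
  expect_gt(median(sq$ratio[sq$site %in% noise]), 0.5)

  # invariance to animal row order
  perm <- sample(nrow(t_std))
  sq2 <- loo_site_quality(unclass(t_std)[perm, ], unclass(a$meth)[perm, ])
  expect_equal(sq$ratio, sq2$ratio, tolerance = 1e-10)
})

test_that("pure-noise sites fail the LOO filter and zero-SD sites are excluded", {
  set.seed(5)
  traits <- matrix(rnorm(46 * 19), 46,
                   dimnames = list(sprintf("A%02d", 1:46), paste0("t", 1:19)))
  meth <- matrix(rnorm(46 * 200), 46,
                 dimnames = list(rownames(traits), paste0("s", 1:200)))
  sq <- loo_site_quality(traits, meth)
  expect_gt(median(sq$ratio), 0.5)

  meth0 <- cbind(meth, s_const = 0.4)
  sq0 <- loo_site_quality(traits, meth0)
  expect_equal(attr(sq0, "n_zero_sd"), 1L)
  expect_false(sq0$retained[sq0$site == "s_const"])
  expect_true(is.na(sq0$ratio[sq0$site == "s_const"]))
})

test_that("a noiseless linear site has MAE/sigma near zero", {
  set.seed(6)
  traits <- matrix(rnorm(20 * 3), 20,
                   dimnames = list(sprintf("A%02d", 1:20), paste0("t", 1:3)))
  meth <- cbind(lin = 0.5 + 0.1 * traits[, 1])
  rownames(meth) <- rownames(traits)
  sq <- loo_site_quality(traits, meth)
  expect_lt(sq$ratio[1], 1e-8)
  expect_true(sq$retained[1])
})

test_that("raising methylation noise never lowers the median MAE/sigma", {
  medians <- vapply(c(0.005, 0.02, 0.05, 0.1), function(nsd) {
    cfg <- synth_config(n_sites = 150, planted_glucose_sites = 150,
                        planted_strain_sites = 0, noise_sd_meth = nsd,
                        seed = 31)
    a <- generate_cohort_a(cfg)
    sq <- loo_site_quality(standardize_traits(a$traits), a$meth)
    median(sq$ratio)
  }, numeric(1))
  expect_true(all(diff(medians) > 0))
})

test_that("iterative trait filter keeps informative traits and sheds noise traits", {
  for (s in 1:10) {
    set.seed(s * 7)
    n <- 46
    inf <- matrix(rnorm(n * 2), n)
    noise <- matrix(rnorm(n * 3), n)
    vals <- cbind(M16_aging_phase_GLU_mgdl = 140 + 25 * inf[, 1],
                  M14_aging_phase_GLU_mgdl = 140 + 25 * inf[, 2],
                  M12_aging_phase_BW_g = 35 + 5 * noise[, 1],
                  M10_aging_phase_BW_g = 35 + 5 * noise[, 2],
                  M8_aging_phase_BW_g = 35 + 5 * noise[, 3],
                  rank_code = sample(0:2, n, TRUE),
                  strain_b6_or_sv = sample(0:1, n, TRUE),
                  strain_cd1_or_b6 = sample(0:1, n, TRUE))
    rownames(vals) <- sprintf("A%02d", 1:n)
    meth <- 0.5 + 0.1 * scale(inf)[, rep(1:2, 100)] +
      matrix(rnorm(n * 200, sd = 0.01), n)
    dimnames(meth) <- list(rownames(vals), paste0("s", 1:200))
    forced <- c("rank_code", "strain_b6_or_sv", "strain_cd1_or_b6")
    tf <- iterative_trait_filter(standardize_traits(trait_matrix(vals)),
                                 meth, forced = forced)
    ret <- tf$trait[tf$retained]
    expect_true(all(c("M16_aging_phase_GLU_mgdl",
                      "M14_aging_phase_GLU_mgdl") %in% ret))
    expect_false(any(grepl("BW", ret)))
    expect_true(all(forced %in% ret))
    expect_lte(attr(tf, "n_iterations"), ncol(vals))
  }
})

test_that("trait filter on uninformative data terminates with the forced set", {
  set.seed(44)
  n <- 30
  vals <- matrix(rnorm(n * 5), n,
                 dimnames = list(sprintf("A%02d", 1:n),
                                 c(paste0("M", c(16, 14, 12), "_aging_phase_BW_g"),
                                   "rank_code", "strain_b6_or_sv")))
  meth <- matrix(rnorm(n * 50), n,
                 dimnames = list(rownames(vals), paste0("s", 1:50)))
  forced <- c("rank_code", "strain_b6_or_sv")
  tf <- iterative_trait_filter(vals, meth, forced = forced)
  expect_setequal(tf$trait[tf$retained], forced)
  expect_true(all(is.finite(tf$spearman[tf$forced])))
})
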
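test_that("feature vectors count records, keep the death-timepoint boundary, drop incomplete rows", {
  cfg <- synth_config(n_animals_B = 1, seed = 1)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  expect_equal(nrow(fv), 8L)
  expect_true(all(fv$D >= 0))

  # a record taken exactly at death has D = 0 and is retained
  rec <- b$records
  death0 <- b$death_age
  death0[] <- max(rec$age_weeks)
  fv0 <- build_feature_vectors(rec, death0)
  expect_true(any(fv0$D == 0))
  expect_equal(nrow(fv0), 8L)

  # missing parameters drop the record, with a count
  rec$GLU_mgdl[3] <- NA
  fv_m <- build_feature_vectors(rec, b$death_age)
  expect_equal(nrow(fv_m), 7L)
  expect_equal(attr(fv_m, "n_dropped"), 1L)

  # records after death are inconsistent input
  late <- b$death_age - 100
  expect_error(build_feature_vectors(b$records, late), "negative time")
})

test_that("grouped folds partition animals evenly and deterministically", {
  ids <- rep(sprintf("B%02d", 1:10), each = 8)
  f <- grouped_kfold(ids, k = 5, seed = 3)
  expect_length(f, 10)
  expect_true(all(table(f) == 2))
  expect_setequal(names(f), unique(ids))
  expect_identical(f, grouped_kfold(ids, k = 5, seed = 3))
  expect_false(identical(unname(f), unname(grouped_kfold(ids, k = 5, seed = 4))))
  expect_error(grouped_kfold(sprintf("B%02d", 1:3), k = 5), "fewer animals")
})

test_that("training and validation animal sets are disjoint in CV", {
  cfg <- synth_config(n_animals_B = 20, seed = 2)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  folds <- grouped_kfold(fv$animal_id, k = 5, seed = 1)
  for (f in 1:5) {
    tr_animals <- fv$animal_id[folds[fv$animal_id] != f]
    va_animals <- fv$animal_id[folds[fv$animal_id] == f]
    expect_length(intersect(tr_animals, va_animals), 0)
  }
  expect_setequal(unique(unname(folds)), 1:5)
})

test_that("the network fits a constant target through its bias", {
  set.seed(1)
  x <- matrix(0, 64, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(5, 64)
  m <- train_mlp(x, y, mlp_config(lr = 0.05, passes = 200), seed = 1)
  expect_lt(mean(abs(predict(m, x) - y)), 0.5)
})

test_that("a leaked target feature is learned to near-zero training error", {
  set.seed(2)
  d <- runif(300, 0, 90)
  x <- cbind(D_leak = d)
  m <- train_mlp(x, d, mlp_config(lr = 0.01, passes = 150), seed = 1)
  expect_lt(mean(abs(predict(m, x) - d)), 2)
})

test_that("training is bit-reproducible under a fixed seed", {
  cfg <- synth_config(n_animals_B = 25, seed = 5)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  cv1 <- evaluate_cv(fv, mlp_config(), k = 5, seed = 9)
  cv2 <- evaluate_cv(fv, mlp_config(), k = 5, seed = 9)
  expect_identical(cv1$fold_mae, cv2$fold_mae)

  x <- fv_features(fv)
  m1 <- train_mlp(x, fv$D, mlp_config(), seed = 4,
                  exempt = c("strain_b6_or_sv", "strain_cd1_or_b6",
                             "rank_code", "timepoint_idx"))
  m2 <- train_mlp(x, fv$D, mlp_config(), seed = 4,
                  exempt = c("strain_b6_or_sv", "strain_cd1_or_b6",
                             "rank_code", "timepoint_idx"))
  expect_identical(m1$layers, m2$layers)
})

test_that("the network beats the training-median baseline under grouped CV", {
  cfg <- synth_config(n_animals_B = 120, seed = 5)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  cv <- evaluate_cv(fv, mlp_config(lr = 0.01), k = 5, seed = 2)
  folds <- cv$folds[fv$animal_id]
  median_mae <- mean(vapply(1:5, function(f) {
    mean(abs(median(fv$D[folds != f]) - fv$D[folds == f]))
  }, numeric(1)))
  expect_lt(cv$mean_mae, median_mae)
})

test_that("Tukey-Kramer comparisons match the TukeyHSD oracle to 1e-6", {
  set.seed(3)
  losses <- list(ctrl = rnorm(5, 10, 0.5), a = rnorm(5, 12, 0.5),
                 b = rnorm(5, 10.2, 0.5))
  res <- tukey_bh(losses, control = "ctrl")
  df <- data.frame(loss = unlist(losses),
                   grp = factor(rep(names(losses), each = 5)))
  hsd <- TukeyHSD(aov(loss ~ grp, data = df))$grp
  for (v in c("a", "b")) {
    key <- grep(paste0("^", v, "-ctrl$|^ctrl-", v, "$"), rownames(hsd))
    expect_equal(res$p[res$variant == v], hsd[key, "p adj"], tolerance = 1e-6)
  }
})

test_that("Tukey-Kramer handles degenerate and strongly separated groups", {
  const <- list(ctrl = rep(3, 5), a = rep(3, 5))
  expect_equal(tukey_bh(const, "ctrl")$adjp, 1)
  set.seed(4)
  sep <- list(ctrl = rnorm(5, 10, 0.3), a = rnorm(5, 13, 0.3))  # ~10 SD shift
  expect_lt(tukey_bh(sep, "ctrl")$adjp, 0.001)
})

test_that("removal importance flags an informative feature but not a noise feature", {
  cfg <- synth_config(n_animals_B = 100,
                      lifespan_slopes = single_driver_slopes("GLU_mgdl", -10),
                      seed = 1)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  imp <- importance_by_removal(fv, mlp_config(lr = 0.01), k = 5, seed = 1,
                               with_time = TRUE)
  r <- imp$results
  expect_lt(r$adjp[r$variant == "GLU_mgdl"], 0.05)
  expect_gt(r$diff[r$variant == "GLU_mgdl"], 0)
  # food intake has a zero lifespan slope: removing it changes nothing
  expect_gt(r$adjp[r$variant == "FI_kcal"], 0.05)
})

test_that("scramble importance flags timepoint and spares a zero-slope feature", {
  cfg <- synth_config(n_animals_B = 120, seed = 5)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  imp <- importance_by_scramble(fv, mlp_config(lr = 0.01), k = 5, seed = 2)
  r <- imp$results[imp$results$family == "single", ]
  expect_lt(r$adjp[r$variant == "timepoint"], 0.001)
  expect_gt(r$adjp[r$variant == "FI_kcal"], 0.05)
  # dual family: the timepoint-scrambled model is the control
  expect_true(all(grepl("^timepoint", imp$results$variant[
    imp$results$family == "dual"])))
})

test_that("a constant-output network is unaffected by scrambled inputs", {
  feats <- unlist(mlp_parameters(), use.names = FALSE)
  m <- constant_mlp(feats, 42)
  set.seed(6)
  x1 <- matrix(rnorm(10 * length(feats)), 10, dimnames = list(NULL, feats))
  x2 <- matrix(rnorm(10 * length(feats)), 10, dimnames = list(NULL, feats))
  expect_equal(predict(m, x1), rep(42, 10))
  expect_identical(predict(m, x1), predict(m, x2))
})

test_that("mean predicted time until death decreases monotonically with timepoint", {
  cfg <- synth_config(n_animals_B = 200, seed = 9)
  b <- generate_cohort_b(cfg)
  fv <- build_feature_vectors(b$records, b$death_age)
  m <- train_mlp(fv_features(fv), fv$D, mlp_config(lr = 0.01), seed = 1,
                 exempt = c("strain_b6_or_sv", "strain_cd1_or_b6",
                            "rank_code", "timepoint_idx"))
  pred <- predict(m, fv_features(fv))
  tp_means <- tapply(pred, factor(fv$timepoint, levels = names(timepoint_grid())),
                     mean)
  tau <- cor(seq_along(tp_means), as.numeric(tp_means), method = "kendall")
  expect_lt(tau, -0.9)
})
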
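test_that("the 70/30 split is stratified, extreme-anchored and seeded", {
  std65 <- generate_standards(levels = 65, noise = noise_none(),
                              grid = seq(4000, 4100, by = 2), seed = 1)
  d <- split_standards(std65, "SA", seed = 3)
  expect_length(d$train_ids, 46L)
  expect_length(d$test_ids, 19L)
  expect_length(intersect(d$train_ids, d$test_ids), 0L)

  meta <- std65$meta[std65$meta$analyte == "SA", ]
  expect_setequal(c(d$train_ids, d$test_ids), meta$sample_id)
  cmin <- meta$sample_id[which.min(meta$concentration_uM)]
  cmax <- meta$sample_id[which.max(meta$concentration_uM)]
  expect_true(all(c(cmin, cmax) %in% d$train_ids))

  expect_identical(split_standards(std65, "SA", seed = 3), d)
  expect_false(identical(split_standards(std65, "SA", seed = 4)$test_ids,
                         d$test_ids))

  d10 <- split_standards(toy_standards(n = 10), "SA", seed = 1)
  expect_length(d10$train_ids, 7L)
  expect_length(d10$test_ids, 3L)

  expect_error(split_standards(std65, "SA", fraction = 1.2), "fraction")
})

test_that("rmse and r_squared match hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(rmse(10 * c(1, 2, 3), 10 * c(1, 2, 4)),
               10 * rmse(c(1, 2, 3), c(1, 2, 4)))
  expect_error(rmse(numeric(0), numeric(0)), "length")

  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(2, 2, 2)), -1.5)
  expect_error(r_squared(rep(1, 3), c(1, 2, 3)), "degenerate")
})

test_that("leave-one-out RMSECV equals the brute-force refit oracle", {
  std <- toy_standards(n = 8, p = 25, seed = 7)
  y <- std$meta$concentration_uM
  spec <- preprocess_spec("msc", 4000, 4048)
  got <- cross_validate(std, y, spec, n_factors = 2, scheme = "loo")

  # oracle: explicitly refit everything without sample i
  ids <- std$meta$sample_id
  press <- 0
  for (i in seq_along(ids)) {
    fit_set <- subset_samples(std, ids[-i])
    out_set <- subset_samples(std, ids[i])
    ref <- msc_fit_reference(restrict_window(fit_set, 4000, 4048))
    tr <- apply_preprocess(fit_set, spec)
    m <- fit_pls(tr$set$absorbance, y[-i], 2)
    X_out <- apply_preprocess(out_set, spec,
                              msc_reference = tr$msc_fit$reference)
    press <- press + as.numeric(y[i] -
                                  pls_predict(m, X_out$set$absorbance))^2
  }
  expect_equal(got, sqrt(press / length(ids)), tolerance = 1e-10)

  # k-fold with k = n is the same partition as LOO
  expect_equal(cross_validate(std, y, spec, 2, scheme = "kfold", k = 8),
               got, tolerance = 1e-12)
  expect_error(cross_validate(std, y, spec, 2, scheme = "kfold", k = 9),
               "parameter error")
})

test_that("a noise-free linear system cross-validates to ~zero error", {
  std <- generate_standards(levels = 10, noise = noise_none(),
                            grid = seq(4000, 5400, by = 2), seed = 1)
  sa <- subset_samples(std, std$meta$sample_id[std$meta$analyte == "SA"])
  rmsecv <- cross_validate(sa, sa$meta$concentration_uM,
                           preprocess_spec("none", 4000, 5400),
                           n_factors = 2, scheme = "loo")
  expect_lt(rmsecv, 1e-6)
})

test_that("evaluate_candidate produces finite metrics and near-perfect
           validation on zero-noise standards", {
  std <- generate_standards(levels = 20, noise = noise_none(), seed = 2)
  d <- split_standards(std, "GA", seed = 2)
  rep1 <- evaluate_candidate(std, d, preprocess_spec("sg1d", 4000, 10000),
                             seed = 2)
  expect_true(all(is.finite(unlist(
    rep1[c("rmsec", "r2_cal", "rmsecv", "rmsep", "r2_pred")]))))
  expect_gte(rep1$rmsep, 0)
  expect_gte(rep1$r2_pred, 0.999)

  # a window that excludes every GA band carries no signal
  rep0 <- evaluate_candidate(std, d, preprocess_spec("none", 8000, 10000),
                             seed = 2)
  expect_lt(rep0$r2_pred, 0.5)
})

test_that("selection reproduces the reference optima for all four
           hormones, rejecting invalid low-RMSEP candidates", {
  expected <- data.frame(
    analyte = c("IAA", "GA", "SA", "kinetin"),
    method = c("sg1d", "sg1d", "none", "none"),
    rmsep = c(2.97, 1.29, 1.36, 1.45))
  for (i in seq_len(4)) {
    sel <- select_model(reference_candidate_metrics(expected$analyte[i]))
    expect_equal(sel$method, expected$method[i])
    expect_equal(sel$window_low, 4000)
    expect_equal(sel$window_high, 10000)
    expect_equal(sel$rmsep, expected$rmsep[i])
    expect_true(sel$valid)
  }
  # the SA table contains a lower-RMSEP MSC candidate that must lose on
  # the prediction-R2 validity filter
  sa <- reference_candidate_metrics("SA")
  expect_lt(min(sa$rmsep), 1.36)
  expect_lt(sa$r2_pred[which.min(sa$rmsep)], 0)
})

test_that("select_model handles degenerate candidate lists", {
  one <- reference_candidate_metrics("IAA")[3, ]
  expect_equal(select_model(one)$rmsep, one$rmsep)

  expect_error(select_model(one[0, ]), "empty")

  all_bad <- reference_candidate_metrics("SA")
  all_bad$r2_pred <- -1
  expect_warning(sel <- select_model(all_bad), "validity")
  expect_false(sel$valid)
  expect_equal(sel$rmsep, min(all_bad$rmsep))
})

test_that("external validation uses the frozen MSC reference — refitting
           it on the test set changes RMSEP", {
  std <- generate_standards(levels = 20, seed = 3)
  d <- split_standards(std, "SA", seed = 3)
  spec <- preprocess_spec("msc", 4000, 10000)
  rep1 <- evaluate_candidate(std, d, spec, seed = 3)

  train_set <- subset_samples(std, d$train_ids)
  test_set <- subset_samples(std, d$test_ids)
  y_train <- train_set$meta$concentration_uM
  y_test <- test_set$meta$concentration_uM
  tr <- apply_preprocess(train_set, spec)
  m <- fit_pls(tr$set$absorbance, y_train, rep1$n_factors)

  frozen <- apply_preprocess(test_set, spec,
                             msc_reference = tr$msc_fit$reference)$set
  leaky <- apply_preprocess(test_set, spec)$set  # refits on test: leakage
  rmsep_frozen <- rmse(y_test, pls_predict(m, frozen$absorbance))
  rmsep_leaky <- rmse(y_test, pls_predict(m, leaky$absorbance))
  expect_equal(rep1$rmsep, rmsep_frozen, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(rmsep_frozen, rmsep_leaky,
                                tolerance = 1e-10)))
})

test_that("the default candidate grid mirrors the published windows", {
  g <- default_candidate_grid("IAA")
  expect_length(g, 6L)
  tab <- t(sapply(g, function(s) c(s$method, s$window_low, s$window_high)))
  expect_true(any(tab[, 1] == "sg1d" & tab[, 2] == "4000" &
                    tab[, 3] == "5000"))
  gk <- default_candidate_grid("kinetin")
  tabk <- t(sapply(gk, function(s) c(s$method, s$window_high)))
  expect_true(any(tabk[, 1] == "sg1d" & tabk[, 2] == "7000"))
  expect_true(any(tabk[, 1] == "none" & tabk[, 2] == "6000"))
})
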
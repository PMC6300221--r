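test_that("MSC reference is the pointwise mean of the calibration set", {
  grid <- seq(4000, 4004, by = 2)
  meta <- data.frame(sample_id = c("a", "b"), role = "unknown",
                     population = "p")
  s <- spectra_set(grid, rbind(a = c(1, 2, 3), b = c(3, 4, 5)), meta)
  expect_equal(msc_fit_reference(s), c(2, 3, 4))

  # N copies of one spectrum -> that spectrum
  reps <- spectra_set(grid,
                      matrix(rep(c(1, 5, 2), each = 4), nrow = 4,
                             dimnames = list(paste0("r", 1:4), NULL),
                             byrow = FALSE),
                      data.frame(sample_id = paste0("r", 1:4),
                                 role = "unknown", population = "p"))
  expect_equal(msc_fit_reference(reps), c(1, 5, 2))

  # brute-force columnwise mean oracle on random spectra
  set.seed(9)
  A <- matrix(runif(5 * 3), nrow = 5,
              dimnames = list(paste0("q", 1:5), NULL))
  rs <- spectra_set(grid, A,
                    data.frame(sample_id = paste0("q", 1:5),
                               role = "unknown", population = "p"))
  oracle <- sapply(1:3, function(j) sum(A[, j]) / 5)
  expect_equal(msc_fit_reference(rs), oracle)

  expect_error(msc_fit_reference(subset_samples(s, "a")),
               "insufficient-data")
})

test_that("msc_correct inverts the affine scatter model", {
  r <- c(1, 2, 3, 4, 5)
  self <- msc_correct(r, r)
  expect_equal(self$a, 0, tolerance = 1e-12)
  expect_equal(self$b, 1, tolerance = 1e-12)
  expect_equal(self$corrected, r, tolerance = 1e-12)

  aff <- msc_correct(0.5 + 2 * r, r)
  expect_equal(aff$corrected, r, tolerance = 1e-12)
  expect_equal(aff$a, 0.5, tolerance = 1e-12)
  expect_equal(aff$b, 2, tolerance = 1e-12)

  # normal-equations oracle computed independently in the test
  x <- c(2.1, 4.2, 6.0, 8.1, 10.2)
  n <- length(r)
  b_or <- (n * sum(r * x) - sum(r) * sum(x)) / (n * sum(r^2) - sum(r)^2)
  a_or <- mean(x) - b_or * mean(r)
  fit <- msc_correct(x, r)
  expect_equal(fit$b, b_or, tolerance = 1e-10)
  expect_equal(fit$a, a_or, tolerance = 1e-10)
  expect_equal(fit$corrected, (x - a_or) / b_or, tolerance = 1e-10)

  expect_error(msc_correct(x, rep(1, 5)), "degenerate-fit")
})

test_that("MSC is affine-invariant and idempotent", {
  set.seed(11)
  r <- runif(40)
  for (i in 1:5) {
    x <- runif(40)
    a0 <- rnorm(1)
    b0 <- runif(1, 0.2, 3)
    expect_equal(msc_correct(b0 * x + a0, r)$corrected,
                 msc_correct(x, r)$corrected, tolerance = 1e-10)
  }

  # correcting an already-corrected set against its new mean: a~0, b~1
  # (exact on a purely affine family b_i * g + a_i of one shape g)
  grid <- seq(4000, 4078, by = 2)
  set.seed(12)
  g <- exp(-(grid - 4040)^2 / 200)
  A <- outer(runif(6, 0.5, 2), g) + matrix(rnorm(6), 6, 40)
  rownames(A) <- paste0("s", 1:6)
  s <- spectra_set(grid, A,
                   data.frame(sample_id = paste0("s", 1:6),
                              role = "unknown", population = "p"))
  first <- apply_preprocess(s, preprocess_spec("msc", 4000, 4078))
  again <- apply_preprocess(first$set, preprocess_spec("msc", 4000, 4078))
  expect_true(all(abs(again$msc_fit$a) < 1e-8))
  expect_true(all(abs(again$msc_fit$b - 1) < 1e-8))
})

test_that("SG first derivative is exact on polynomials and linear", {
  grid <- seq(4000, 4120, by = 2)

  const <- sg_first_derivative(rep(7, length(grid)), grid)
  expect_true(all(abs(const$absorbance) < 1e-12))
  expect_equal(length(const$wavenumbers), length(grid) - 12L)

  lin <- sg_first_derivative(3 * grid, grid)
  expect_equal(lin$absorbance, rep(3, length(grid) - 12),
               tolerance = 1e-10, ignore_attr = TRUE)

  quad <- 1 + 0.5 * grid + 0.01 * grid^2
  dq <- sg_first_derivative(quad, grid, sg_points = 13, sg_polyorder = 2)
  expect_equal(dq$absorbance, 0.5 + 0.02 * dq$wavenumbers,
               tolerance = 1e-8, ignore_attr = TRUE)

  # linearity: deriv(alpha x + beta y) = alpha deriv(x) + beta deriv(y)
  set.seed(4)
  x <- runif(length(grid)); y <- runif(length(grid))
  dx <- sg_first_derivative(x, grid)$absorbance
  dy <- sg_first_derivative(y, grid)$absorbance
  dxy <- sg_first_derivative(2.5 * x - 1.5 * y, grid)$absorbance
  expect_equal(dxy, 2.5 * dx - 1.5 * dy, tolerance = 1e-10)

  expect_error(sg_first_derivative(x[1:5], grid[1:5]), "length error")
})

test_that("apply_preprocess windows first, then transforms", {
  std <- generate_standards(levels = 6, noise = noise_none(),
                            grid = seq(4000, 6600, by = 2), seed = 2)
  spec <- preprocess_spec("sg1d", 4000, 6500)
  out <- apply_preprocess(std, spec)$set
  # 4000..6500 has 1251 points; 13-point SG drops 6 per edge
  expect_equal(length(out$wavenumbers), 1251L - 12L)
  expect_equal(min(out$wavenumbers), 4012)

  idn <- apply_preprocess(std, preprocess_spec("none", 4000, 6600))
  expect_equal(idn$set$absorbance, std$absorbance)
  expect_null(idn$msc_fit)

  # MSC with a stored reference is deterministic on a copied set
  fit1 <- apply_preprocess(std, preprocess_spec("msc", 4000, 6600))
  fit2 <- apply_preprocess(std, preprocess_spec("msc", 4000, 6600),
                           msc_reference = fit1$msc_fit$reference)
  expect_equal(fit2$set$absorbance, fit1$set$absorbance)
})

test_that("preprocess_spec validates its parameters", {
  expect_error(preprocess_spec("sg1d", sg_points = 12), "odd")
  expect_error(preprocess_spec("sg1d", sg_points = 3), "odd")
  expect_error(preprocess_spec("sg1d", sg_polyorder = 13), "sg_polyorder")
  expect_error(preprocess_spec("none", window_low = 5000,
                               window_high = 4000), "window")
})
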
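test_that("one-way ANOVA matches hand computation and stats::aov", {
  ident <- list(g1 = c(2, 2, 2), g2 = c(2, 2, 2))
  a0 <- anova_oneway(ident)
  expect_equal(a0$f, 0)
  expect_equal(a0$p_value, 1)

  # hand oracle: groups (1,2,3), (4,5,6): MSB = 13.5, MSW = 1 -> F = 13.5
  a1 <- anova_oneway(list(g1 = c(1, 2, 3), g2 = c(4, 5, 6)))
  expect_equal(a1$f, 13.5)
  expect_equal(a1$df_between, 1L)
  expect_equal(a1$df_within, 4L)

  set.seed(31)
  vals <- list(a = rnorm(5, 1), b = rnorm(7, 2), c = rnorm(6, 1.4))
  mine <- anova_oneway(vals)
  df <- data.frame(y = unlist(vals),
                   g = rep(names(vals), lengths(vals)))
  ref <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(mine$f, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)

  expect_error(anova_oneway(list(g1 = 1:3)), "2 groups")
})

test_that("summary-mode ANOVA is algebraically identical to raw mode", {
  set.seed(32)
  vals <- list(p1 = rnorm(4, 5), p2 = rnorm(4, 6), p3 = rnorm(4, 5.5))
  raw <- anova_oneway(vals)
  summ <- data.frame(population = names(vals),
                     mean = sapply(vals, mean),
                     se = sapply(vals, sd) / 2,
                     n = 4L)
  from_summary <- anova_oneway(summ)
  expect_equal(from_summary$f, raw$f, tolerance = 1e-10)
  expect_equal(from_summary$p_value, raw$p_value, tolerance = 1e-10)
})

test_that("two-group Tukey reduces to the pooled t-test (q = t sqrt(2))", {
  set.seed(33)
  x <- rnorm(6, 10, 1); y <- rnorm(8, 11, 1)
  tk <- tukey_hsd(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(tk$q, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-8)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-8)
})

test_that("Tukey all-pairs agrees with stats::TukeyHSD on raw data", {
  set.seed(34)
  vals <- list(a = rnorm(5, 0), b = rnorm(5, 1), c = rnorm(5, 3))
  mine <- tukey_hsd(vals)
  df <- data.frame(y = unlist(vals), g = rep(names(vals), each = 5))
  ref <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  key <- paste(mine$group_b, mine$group_a, sep = "-")
  expect_equal(mine$p_adj, ref[key, "p adj"], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(mine$diff, ref[key, "diff"], tolerance = 1e-10,
               ignore_attr = TRUE)

  none <- tukey_hsd(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_false(any(none$significant))

  # adjusted p is never below the unadjusted pooled-variance pairwise p
  # for >= 3 groups (same q statistic, t reference instead of range)
  aov_all <- anova_oneway(vals)
  for (i in seq_len(nrow(mine))) {
    praw <- 2 * stats::pt(mine$q[i] / sqrt(2), aov_all$df_within,
                          lower.tail = FALSE)
    expect_gte(mine$p_adj[i] + 1e-12, praw)
  }
})

test_that("the highest-content population separates from all others in
           the reference IAA profiles at alpha = 0.001", {
  prof <- reference_profiles()
  iaa <- prof[prof$analyte == "IAA", ]
  tk <- tukey_hsd(iaa, alpha = 0.001)
  p13 <- tk[tk$group_a == "POP13" | tk$group_b == "POP13", ]
  expect_equal(nrow(p13), 12L)
  expect_true(all(p13$significant))
})

test_that("Bray-Curtis follows its closed form", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  # frozen hand value for the first two reference populations
  expect_equal(bray_curtis(c(123.7, 112.4, 136.9, 61.5),
                           c(143.6, 164.7, 193.3, 42.6)),
               0.1507101, tolerance = 1e-6)
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "domain")
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "domain")

  # matrix path agrees with the scalar formula entrywise
  M <- profile_matrix(reference_profiles())
  D <- as.matrix(profile_dissimilarity(M))
  expect_equal(D["POP1", "POP2"], bray_curtis(M["POP1", ], M["POP2", ]),
               tolerance = 1e-10)
  expect_equal(D["POP3", "POP9"], bray_curtis(M["POP3", ], M["POP9", ]),
               tolerance = 1e-10)
})

test_that("the two most dissimilar reference populations are POP13 and
           POP2", {
  M <- profile_matrix(reference_profiles())
  D <- as.matrix(profile_dissimilarity(M))
  avg <- rowMeans(D) * nrow(D) / (nrow(D) - 1)
  expect_setequal(names(sort(avg, decreasing = TRUE))[1:2],
                  c("POP13", "POP2"))
})

test_that("nMDS embeds exactly embeddable configurations at ~zero stress", {
  d3 <- dist(matrix(c(0, 0, 1, 0, 0.3, 0.9), 3, 2, byrow = TRUE))
  r3 <- nmds(d3, k = 2, seed = 1)
  expect_lt(r3$stress, 1e-6)

  square <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  r4 <- nmds(dist(square), k = 2, seed = 1)
  expect_lt(r4$stress, 1e-3)

  # duplicated rows collapse to near-coincident points
  M <- profile_matrix(reference_profiles())
  M2 <- rbind(M, POP13b = M["POP13", ])
  r <- nmds(profile_dissimilarity(M2), k = 2, seed = 1)
  dup <- sqrt(sum((r$points["POP13", ] - r$points["POP13b", ])^2))
  spread <- max(dist(r$points))
  expect_lt(dup / spread, 1e-3)

  expect_error(nmds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("nMDS stress is invariant to rotation, translation and uniform
           scaling of the underlying configuration", {
  set.seed(35)
  X <- matrix(rnorm(14), 7, 2)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  X2 <- 2.5 * X %*% R + 3
  s1 <- nmds(dist(X), seed = 2)$stress
  s2 <- nmds(dist(X2), seed = 2)$stress
  expect_equal(s1, s2, tolerance = 1e-6)
})
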
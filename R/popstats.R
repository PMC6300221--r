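# normalize ANOVA input: either a named list of raw replicate vectors or a
# data frame of summary triples (mean, se, n). Returns per-group stats.
group_summaries <- function(groups) {
  if (is.data.frame(groups)) {
    need <- c("mean", "se", "n")
    if (!all(need %in% names(groups))) {
      stop("parameter error: summary input needs columns mean, se, n",
           call. = FALSE)
    }
    labs <- if ("population" %in% names(groups)) groups$population else
      rownames(groups)
    if (any(groups$n < 2 & groups$se > 0)) {
      stop("parameter error: summary groups with se > 0 need n >= 2",
           call. = FALSE)
    }
    data.frame(group = as.character(labs), mean = groups$mean,
               var = groups$n * groups$se^2,  # se = sd/sqrt(n)
               n = as.integer(groups$n))
  } else if (is.list(groups)) {
    labs <- names(groups)
    if (is.null(labs)) labs <- paste0("g", seq_along(groups))
    data.frame(group = labs,
               mean = vapply(groups, mean, numeric(1)),
               var = vapply(groups, function(v)
                 if (length(v) > 1L) stats::var(v) else 0, numeric(1)),
               n = vapply(groups, length, integer(1)))
  } else {
    stop("parameter error: groups must be a list or summary data frame",
         call. = FALSE)
  }
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA, accepting either raw replicate
#' values (a named list of numeric vectors) or summary triples
#' (a data frame with `mean`, `se`, `n` per group, as in a published
#' profile table). Summary mode reconstructs the within-group sum of
#' squares from the standard errors (`var = n * se^2`), which is an exact
#' algebraic identity with raw mode.
#'
#' @param groups Named list of numeric vectors, or a summary data frame
#'   with columns `mean`, `se`, `n` (and optionally `population` labels).
#' @return List with `f`, `df_between`, `df_within`, `p_value`,
#'   `ms_between`, `ms_within`, and the per-group `summaries`.
#' @export
anova_oneway <- function(groups) {
  g <- group_summaries(groups)
  if (nrow(g) < 2L) {
    stop("parameter error: need >= 2 groups", call. = FALSE)
  }
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ss_between <- sum(g$n * (g$mean - grand)^2)
  ss_within <- sum((g$n - 1) * g$var)
  df_b <- nrow(g) - 1L
  df_w <- N - nrow(g)
  if (df_w < 1L) {
    stop("parameter error: no within-group degrees of freedom",
         call. = FALSE)
  }
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) {
    if (ms_b == 0) 0 else Inf
  } else ms_b / ms_w
  p <- if (ms_w == 0 && ms_b == 0) 1 else
    stats::pf(f, df_b, df_w, lower.tail = FALSE)
  list(f = f, df_between = df_b, df_within = df_w, p_value = p,
       ms_between = ms_b, ms_within = ms_w, summaries = g)
}

#' Tukey HSD all-pairs comparisons
#'
#' Studentized-range multiple comparisons on the one-way layout (the
#' Tukey-Kramer form for unequal group sizes), in raw or summary mode as
#' in [anova_oneway()].
#'
#' @param groups As in [anova_oneway()].
#' @param alpha Familywise significance level; default 0.05.
#' @return Data frame with one row per pair: `group_a`, `group_b`, `diff`
#'   (mean difference), `q` (studentized-range statistic), `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  a <- anova_oneway(groups)
  g <- a$summaries
  k <- nrow(g)
  pairs <- utils::combn(k, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- g$mean[i2] - g$mean[i1]
    se_q <- sqrt(a$ms_within / 2 * (1 / g$n[i1] + 1 / g$n[i2]))
    q <- if (se_q == 0) {
      if (d == 0) 0 else Inf
    } else abs(d) / se_q
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
    data.frame(group_a = g$group[i1], group_b = g$group[i2], diff = d,
               q = q, p_adj = p, significant = p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity of two nonnegative profiles
#'
#' `sum(|u - v|) / sum(u + v)`, in `[0, 1]`: 0 for identical profiles,
#' 1 for disjoint support.
#'
#' @param u,v Equal-length nonnegative numeric vectors, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) {
    stop("length error: vectors differ in length", call. = FALSE)
  }
  if (any(u < 0) || any(v < 0)) {
    stop("domain error: Bray-Curtis needs nonnegative entries",
         call. = FALSE)
  }
  tot <- sum(u + v)
  if (tot == 0) {
    stop("domain error: both profiles are all-zero", call. = FALSE)
  }
  sum(abs(u - v)) / tot
}

#' Bray-Curtis dissimilarity matrix of population profiles
#'
#' @param profiles Numeric matrix (populations x hormones), nonnegative,
#'   e.g. from [profile_matrix()]. Profiles are used raw — no
#'   standardization — matching the use of Bray-Curtis on abundance-like
#'   data; set `range_scale = TRUE` to range-scale columns to `[0, 1]`
#'   first.
#' @param range_scale Range-scale columns before computing? Default
#'   `FALSE`.
#' @return A `dist` object.
#' @export
profile_dissimilarity <- function(profiles, range_scale = FALSE) {
  M <- as.matrix(profiles)
  if (any(M < 0)) {
    stop("domain error: profiles must be nonnegative", call. = FALSE)
  }
  if (range_scale) {
    M <- apply(M, 2, function(col) {
      r <- range(col)
      if (diff(r) == 0) rep(0, length(col)) else (col - r[1]) / diff(r)
    })
  }
  vegan::vegdist(M, method = "bray")
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Kruskal stress-1 nMDS: the embedding is optimized by iterative
#' majorization with isotonic regression on the dissimilarity ranks
#' (vegan's engine, primary/averaging tie treatment), initialized from
#' classical scaling and from seeded random configurations; the lowest-
#' stress solution over all restarts is returned.
#'
#' @param D Symmetric dissimilarity matrix or `dist` object with zero
#'   diagonal.
#' @param k Embedding dimension; default 2.
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of starts (first is classical scaling);
#'   default 8.
#' @return An object of class `nmds_result`: `points` (n x k coordinate
#'   matrix), `stress` (Kruskal stress-1, in `[0, 1]`), `seed`,
#'   `n_restarts`.
#' @export
nmds <- function(D, k = 2L, seed = 1L, n_restarts = 8L) {
  if (inherits(D, "dist")) {
    Dm <- as.matrix(D)
  } else {
    Dm <- as.matrix(D)
    if (nrow(Dm) != ncol(Dm) || any(abs(Dm - t(Dm)) > 1e-10)) {
      stop("domain error: D must be symmetric", call. = FALSE)
    }
    if (any(abs(diag(Dm)) > 1e-12)) {
      stop("domain error: D must have a zero diagonal", call. = FALSE)
    }
  }
  d <- stats::as.dist(Dm)
  n <- attr(d, "Size")
  starts <- with_local_seed(seed, {
    inits <- vector("list", n_restarts)
    inits[[1]] <- stats::cmdscale(d, k = k)
    if (ncol(inits[[1]]) < k) {  # degenerate classical scaling
      inits[[1]] <- cbind(inits[[1]],
                          matrix(stats::rnorm(n * (k - ncol(inits[[1]]))),
                                 nrow = n) * 1e-4)
    }
    for (i in seq_len(n_restarts - 1L)) {
      inits[[i + 1L]] <- matrix(stats::rnorm(n * k), n, k)
    }
    inits
  })
  best <- NULL
  for (init in starts) {
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = 300, smin = 1e-8, sratmax = 1 - 1e-8)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  structure(list(points = best$points, stress = best$stress,
                 seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("nmds_result: %d points in %d dims, stress-1 = %.4g\n",
              nrow(x$points), ncol(x$points), x$stress))
  invisible(x)
}
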
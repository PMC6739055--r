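random_profiles <- function(n, seed, labels = STUDY_LABELS[1:10]) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * length(labels)), n)
  colnames(m) <- labels
  df <- tibble::as_tibble(as.data.frame(100 * m / rowSums(m), check.names = FALSE))
  df <- tibble::add_column(df, sample_id = paste0("s", seq_len(n)),
                           species = "sp", tissue = "host", .before = 1)
  fa_profiles(df, renormalize = TRUE)
}

test_that("Bray-Curtis distances match the hand-computed formula", {
  x <- random_profiles(6, seed = 31)
  d <- as.matrix(fa_dist(x, "bray"))
  m <- fa_matrix(x)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j],
                 sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ]),
                 tolerance = 1e-12)
  }
  # identity and maximal dissimilarity
  a <- fa_profile(c("16:0" = 100), sample_id = "a")
  b <- fa_profile(c("18:0" = 100), sample_id = "b")
  a2 <- fa_profile(c("16:0" = 100), sample_id = "a2")
  d2 <- as.matrix(fa_dist(bind_profiles(a, b, a2), "bray"))
  expect_equal(d2["a", "a2"], 0)
  expect_equal(d2["a", "b"], 1)
})

test_that("PERMANOVA partition agrees with vegan::adonis2 on a crossed design", {
  x <- simulate_study(seed = 41)
  d <- fa_dist(x, "bray")
  mine <- permanova(d, fa_meta(x), c("species", "tissue", "species:tissue"),
                    n_perm = 99, seed = 1)
  ref <- vegan::adonis2(d ~ species * tissue, data = fa_meta(x),
                        permutations = 99, by = "terms")
  expect_equal(mine$tab$SS, ref$SumOfSqs[1:3], tolerance = 1e-10)
  expect_equal(mine$tab$pseudo_F, ref$F[1:3], tolerance = 1e-10)
  expect_equal(mine$tab$df, ref$Df[1:3])
  expect_equal(mine$residual$SS, ref$SumOfSqs[4], tolerance = 1e-10)
  expect_equal(mine$residual$df, ref$Df[4])
  # df accounting: term dfs plus residual df equal n - 1
  expect_equal(sum(mine$tab$df) + mine$residual$df, nrow(x) - 1L)
})

test_that("small designs are tested by exhaustive enumeration, matching brute force", {
  x <- random_profiles(6, seed = 43)
  g <- rep(c("a", "b"), each = 3)
  d <- fa_dist(x, "bray")
  expect_message(
    res <- permanova(d, data.frame(g = g), "g", n_perm = 9999),
    "enumerating")
  expect_true(res$exhaustive)
  expect_equal(res$tab$p_perm, oracle_exact_p(d, g), tolerance = 1e-12)
  expect_equal(res$tab$pseudo_F, oracle_pseudo_f(d, g), tolerance = 1e-10)
})

test_that("Euclidean two-group pseudo-F equals the pooled classical ANOVA F", {
  set.seed(45)
  for (rep in 1:5) {
    m <- matrix(rnorm(16 * 4), 16)
    g <- factor(rep(c("a", "b"), each = 8))
    d <- stats::dist(m)
    res <- permanova(as.matrix(d), data.frame(g = g), "g", n_perm = 99)
    # classical multivariate trace statistic, per-coordinate SS pooled
    ssb <- sum(vapply(seq_len(ncol(m)), function(j) {
      sum(tapply(m[, j], g, function(v) length(v) * (mean(v) - mean(m[, j]))^2))
    }, numeric(1)))
    ssw <- sum(vapply(seq_len(ncol(m)), function(j) {
      sum(tapply(m[, j], g, function(v) sum((v - mean(v))^2)))
    }, numeric(1)))
    f_classical <- (ssb / 1) / (ssw / (16 - 2))
    expect_equal(res$tab$pseudo_F, f_classical, tolerance = 1e-10)
  }
})

test_that("PERMANOVA statistics are invariant to sample order; p depends on seed only", {
  x <- simulate_study(seed = 47)
  d <- as.matrix(fa_dist(x))
  meta <- fa_meta(x)
  perm <- sample(nrow(d))
  r1 <- permanova(d, meta, c("species", "tissue"), n_perm = 199, seed = 5)
  r2 <- permanova(d[perm, perm], meta[perm, ], c("species", "tissue"),
                  n_perm = 199, seed = 5)
  expect_equal(r1$tab$SS, r2$tab$SS, tolerance = 1e-9)
  expect_equal(r1$tab$pseudo_F, r2$tab$pseudo_F, tolerance = 1e-9)
  r3 <- permanova(d, meta, c("species", "tissue"), n_perm = 199, seed = 5)
  expect_identical(r1$tab$p_perm, r3$tab$p_perm)
})

test_that("degenerate and erroneous PERMANOVA inputs are handled", {
  one <- fa_profile(c("16:0" = 60, "18:0" = 40))
  x <- bind_profiles(
    fa_profile(c("16:0" = 60, "18:0" = 40), sample_id = "a"),
    fa_profile(c("16:0" = 60, "18:0" = 40), sample_id = "b"),
    fa_profile(c("16:0" = 60, "18:0" = 40), sample_id = "c"),
    fa_profile(c("16:0" = 60, "18:0" = 40), sample_id = "d"))
  d <- fa_dist(x, "euclidean")
  suppressMessages(
    res <- permanova(as.matrix(d), data.frame(g = c("a", "a", "b", "b")), "g",
                     n_perm = 9999))
  expect_equal(res$tab$SS, 0, tolerance = 1e-12)
  expect_equal(res$tab$pseudo_F, 0)

  expect_error(permanova(as.matrix(d), data.frame(g = c("a", "a", "b", "b")),
                         "unknown_factor", n_perm = 99), "unknown factor")
})

test_that("pairwise comparisons equal fresh two-level tests on each subset", {
  x <- simulate_study(seed = 49)
  hosts <- x[x$tissue == "host", ]
  attr(hosts, "fa_labels") <- fa_labels(x)
  class(hosts) <- c("fa_profiles", class(hosts))
  d <- fa_dist(hosts)
  pw <- pairwise_permanova(d, hosts$species, n_perm = 199, seed = 3)
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$t, sqrt(pw$pseudo_F))
  # consistency: statistic equals a fresh permanova on the restricted matrix
  lv <- c(pw$level_1[1], pw$level_2[1])
  idx <- hosts$species %in% lv
  ref <- permanova(as.matrix(d)[idx, idx],
                   data.frame(g = hosts$species[idx]), "g", n_perm = 99)
  expect_equal(pw$pseudo_F[1], ref$tab$pseudo_F, tolerance = 1e-10)

  # a level with < 2 samples is skipped with a warning
  g2 <- c(rep("a", 5), rep("b", 5), "c")
  dsub <- as.matrix(d)[1:11, 1:11]
  # level "c" appears in two pairs, so two skip warnings are raised
  expect_warning(expect_warning(
    pw2 <- pairwise_permanova(dsub, g2, n_perm = 99), "skipping"), "skipping")
  expect_equal(nrow(pw2), 1L)
})

test_that("PERMDISP detects dispersion differences and matches the Euclidean oracle", {
  set.seed(51)
  base <- matrix(rnorm(20 * 3), 20)
  same <- rbind(base, base + 5)  # identical internal geometry, shifted
  g <- rep(c("a", "b"), each = 20)
  res <- permdisp(stats::dist(same), g, n_perm = 199, seed = 1)
  expect_lt(res$F, 1e-10)
  expect_gt(res$p_perm, 0.5)

  scaled <- rbind(base, 3 * base)
  res2 <- permdisp(stats::dist(scaled), g, n_perm = 199, seed = 1)
  expect_lt(res2$p_perm, 0.05)
  expect_gt(res2$dispersions[["b"]], res2$dispersions[["a"]])

  # Euclidean case: distances to centroid equal direct distances to group mean
  manual <- unlist(lapply(split(seq_len(40), g), function(idx) {
    ctr <- colMeans(scaled[idx, ])
    sqrt(rowSums(sweep(scaled[idx, ], 2, ctr)^2))
  }), use.names = FALSE)
  expect_equal(unname(res2$distances[order(g, seq_along(g))]), manual,
               tolerance = 1e-8)
})

test_that("PCA satisfies its definitional identities", {
  x <- random_profiles(20, seed = 53)
  pc <- fa_pca(x, standardize = TRUE)
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-9)
  expect_equal(unname(colSums(pc$contributions)),
               rep(100, ncol(pc$contributions)), tolerance = 1e-9)
  # scores' covariance is diagonal with the eigenvalues
  cv <- stats::cov(pc$scores)
  expect_equal(unname(diag(cv)), unname(pc$eigenvalues), tolerance = 1e-9)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-9)
  # reconstruction of the standardized data
  m <- scale(fa_matrix(x))
  expect_equal(unname(pc$scores %*% t(pc$loadings)), unname(m[, ]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading on each axis is positive
  for (k in seq_len(ncol(pc$loadings))) {
    expect_gte(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  }
})

test_that("collinear points load entirely on the first axis", {
  t_seq <- seq(0, 1, length.out = 10)
  m <- cbind(a = 2 * t_seq, b = -1 * t_seq, c = 0.5 * t_seq)
  pc <- fa_pca(m, standardize = FALSE)
  expect_equal(pc$percent_variance[1], 100, tolerance = 1e-9)

  m2 <- cbind(m, d = 1)
  expect_error(fa_pca(m2, standardize = TRUE), "constant")
})

test_that("confidence ellipses enclose most of a normal score cloud", {
  set.seed(55)
  sco <- cbind(rnorm(500), rnorm(500, sd = 2))
  ell <- score_ellipse(sco, level = 0.95)
  expect_equal(dim(ell), c(100L, 2L))
  # center of the ellipse approximates the score centroid
  expect_equal(colMeans(ell), colMeans(sco), tolerance = 0.2)
})
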
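# Shared fixtures, built in code.

# The 30 fatty-acid labels used across the coral study tables.
STUDY_LABELS <- c(
  "14:0", "15:0", "16:0", "17:0", "18:0", "20:0", "22:0",
  "14:1n-5", "16:1n-7", "16:1n-9", "18:1n-7", "18:1n-9",
  "20:1n-11", "20:1n-9", "20:1n-7", "22:1n-11", "22:1n-9", "22:1n-7",
  "18:2n-6", "18:3n-3", "18:3n-6", "18:4n-3", "20:2n-6", "20:3n-6",
  "20:4n-3", "20:4n-6", "20:5n-3", "22:4n-6", "22:5n-3", "22:6n-3")

toy_profile <- function(props, id = "s1", tissue = "host", species = "sp",
                        ...) {
  fa_profile(props, sample_id = id, species = species, tissue = tissue,
             renormalize = TRUE, ...)
}

# Three well-separated PUFA sources used throughout the attribution tests.
separated_specs <- function(concentration = 150) {
  sp <- example_source_specs(concentration)
  list(sp$diatom, sp$copepod,
       example_symbiont_spec("symbiont", concentration))
}

simulate_separated_library <- function(seed, n = 15, concentration = 150) {
  source_library(simulate_sources(separated_specs(concentration),
                                  n_per_source = n, seed = seed))
}

# Independent pseudo-F from a distance matrix for a one-way grouping, via
# within-group sums of squared dissimilarities (no Gower matrix, no hat
# matrices) -- the brute-force oracle for the PERMANOVA implementation.
oracle_pseudo_f <- function(dm, grouping) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  grouping <- factor(grouping)
  a <- nlevels(grouping)
  ss_total <- sum(dm[upper.tri(dm)]^2) / n
  ss_within <- sum(vapply(levels(grouping), function(g) {
    idx <- which(grouping == g)
    sub <- dm[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# Exact permutation p for a one-way design: enumerate every assignment of
# samples to groups with the observed sizes.
oracle_exact_p <- function(dm, grouping) {
  grouping <- factor(grouping)
  n <- length(grouping)
  sizes <- table(grouping)
  stopifnot(nlevels(grouping) == 2L)
  f_obs <- oracle_pseudo_f(dm, grouping)
  combs <- utils::combn(n, sizes[1])
  f_all <- apply(combs, 2L, function(idx) {
    g <- rep(levels(grouping)[2], n)
    g[idx] <- levels(grouping)[1]
    oracle_pseudo_f(dm, g)
  })
  mean(f_all >= f_obs - 1e-12)
}

# Independent Gaussian pooled-covariance Bayes rule (Mahalanobis distance
# plus log prior), used as the classification oracle.
oracle_bayes_labels <- function(train_x, train_g, test_x, ridge = NULL) {
  train_g <- factor(train_g)
  classes <- sort(levels(train_g))
  d <- ncol(train_x)
  mus <- lapply(classes, function(g) colMeans(train_x[train_g == g, , drop = FALSE]))
  pooled <- Reduce(`+`, lapply(classes, function(g) {
    xg <- train_x[train_g == g, , drop = FALSE]
    crossprod(sweep(xg, 2, colMeans(xg)))
  })) / (nrow(train_x) - length(classes))
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(pooled)) / d
  sinv <- solve(pooled + diag(ridge, d))
  delta <- vapply(seq_along(classes), function(k) {
    apply(test_x, 1L, function(x) {
      v <- x - mus[[k]]
      -0.5 * drop(t(v) %*% sinv %*% v) + log(1 / length(classes))
    })
  }, numeric(nrow(test_x)))
  classes[max.col(matrix(delta, nrow = nrow(test_x)), ties.method = "first")]
}
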
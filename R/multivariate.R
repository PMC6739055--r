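# Distance-based permutation statistics. The sums-of-squares partition
# follows the direct distance-matrix formulation: Gower-centre the matrix of
# squared dissimilarities and take traces against projection (hat) matrices
# of the design, term by term in sequential order. Significance is by
# unrestricted permutation of sample identities, recomputing every term's
# pseudo-F against the permuted Gower matrix.

#' Pairwise dissimilarity matrix of fatty-acid profiles
#'
#' Bray-Curtis (the conventional resemblance for percent-composition data)
#' or Euclidean distances on the untransformed percent proportions.
#'
#' @param x An `fa_profiles` object or a numeric samples-x-variables matrix.
#' @param method `"bray"` or `"euclidean"`.
#' @return A [stats::dist] object with a `"method"` attribute.
#' @export
fa_dist <- function(x, method = c("bray", "euclidean")) {
  method <- match.arg(method)
  m <- if (inherits(x, "fa_profiles")) fa_matrix(x) else as.matrix(x)
  if (nrow(m) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (method == "bray" && any(rowSums(m) == 0)) {
    stop("Bray-Curtis undefined for all-zero profile(s)", call. = FALSE)
  }
  vegan::vegdist(m, method = method)
}

gower_centre <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

# Hat matrix of a model matrix (including intercept), via QR.
hat_of <- function(mm) {
  q <- qr.Q(qr(mm))
  tcrossprod(q)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared dissimilarities among crossed fixed
#' factors (and their interactions) and tests each term's pseudo-F by
#' unrestricted permutation of the samples. Terms are fitted sequentially in
#' the order given; for balanced designs the partition is order-invariant.
#' The p-value uses the add-one estimator
#' \eqn{(1 + \#\{F^* \ge F\}) / (1 + n_{perm})}, so it is never 0. When the
#' number of distinct sample permutations is at most `n_perm`, all of them
#' are enumerated instead and the p-value is the exact proportion.
#'
#' @param d A [stats::dist] or square matrix of dissimilarities.
#' @param data Data frame of factor columns, rows aligned with `d`.
#' @param terms Character vector of model terms, e.g.
#'   `c("species", "tissue", "species:tissue")`.
#' @param n_perm Number of permutations (default 9999; minimum 99).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `"permanova"`: list with `tab` (tibble of
#'   term, df, SS, MS, pseudo_F, p_perm), `residual` and `total` rows,
#'   `n_perm` (permutations actually used), `exhaustive` flag and `seed`.
#' @export
permanova <- function(d, data, terms, n_perm = 9999, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(nrow(data) == n)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("term(s) reference unknown factor(s): ",
         paste(sQuote(missing_vars), collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(lapply(as.data.frame(data)[vars], factor))

  g <- gower_centre(dm)
  ss_total <- sum(diag(g))

  # sequential hat matrices: intercept, then cumulative terms
  hats <- vector("list", length(terms) + 1L)
  hats[[1]] <- matrix(1 / n, n, n)
  dfs <- integer(length(terms))
  for (k in seq_along(terms)) {
    f <- stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    mm <- stats::model.matrix(f, data)
    hats[[k + 1L]] <- hat_of(mm)
    dfs[k] <- qr(mm)$rank - qr(stats::model.matrix(
      if (k == 1L) ~1 else stats::as.formula(
        paste("~", paste(terms[seq_len(k - 1L)], collapse = " + "))), data))$rank
  }
  h_full <- hats[[length(hats)]]
  df_res <- n - qr(stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))), data))$rank
  if (df_res < 1L) stop("no residual degrees of freedom", call. = FALSE)

  diffs <- lapply(seq_along(terms), function(k) hats[[k + 1L]] - hats[[k]])
  resid_proj <- diag(n) - h_full

  stat <- function(gp) {
    ss <- vapply(diffs, function(h) sum(h * gp), numeric(1))
    ss_res <- sum(resid_proj * gp)
    f <- (ss / dfs) / (ss_res / df_res)
    f[!is.finite(f)] <- 0  # degenerate case: no variation at all
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat(g)

  n_distinct <- factorial(n)
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_perm
  if (exhaustive) {
    message("enumerating all ", n_distinct, " sample permutations (exact test)")
    perms <- all_permutations(n)
    fmat <- apply(perms, 1L, function(p) stat(g[p, p])$f)
    fmat <- matrix(fmat, nrow = length(terms))
    p_perm <- rowMeans(fmat >= obs$f - 1e-12)
    n_used <- n_distinct
  } else {
    if (!is.null(seed)) set.seed(seed)
    count <- numeric(length(terms))
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      count <- count + (stat(g[p, p])$f >= obs$f - 1e-12)
    }
    p_perm <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }

  tab <- tibble::tibble(
    term = terms, df = dfs, SS = obs$ss, MS = obs$ss / dfs,
    pseudo_F = obs$f, p_perm = p_perm)
  structure(list(
    tab = tab,
    residual = list(df = df_res, SS = obs$ss_res, MS = obs$ss_res / df_res),
    total = list(df = n - 1L, SS = ss_total),
    n_perm = n_used, exhaustive = exhaustive, seed = seed),
    class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", if (x$exhaustive) "exact, " else "", x$n_perm,
      " permutations)\n", sep = "")
  print(as.data.frame(x$tab), digits = 4)
  cat(sprintf("Residual: df = %d, SS = %.4f\nTotal:    df = %d, SS = %.4f\n",
              x$residual$df, x$residual$SS, x$total$df, x$total$SS))
  invisible(x)
}

#' Pairwise PERMANOVA comparisons
#'
#' Tests each pair of levels of one factor on the dissimilarity sub-matrix
#' restricted to those samples; equivalent to a fresh two-level PERMANOVA on
#' each subset. The statistic `t` is the square root of the pseudo-F.
#'
#' @param d A [stats::dist] or square matrix of dissimilarities.
#' @param grouping Factor (or vector) of group labels aligned with `d`.
#' @param n_perm Permutations per pair.
#' @param seed Integer seed.
#' @return Tibble with one row per level pair: `level_1`, `level_2`, `t`,
#'   `pseudo_F`, `p_perm`, `n_perm`. Pairs with a level of fewer than 2
#'   samples are skipped with a warning.
#' @export
pairwise_permanova <- function(d, grouping, n_perm = 9999, seed = NULL) {
  dm <- as.matrix(d)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("need at least 2 levels", call. = FALSE)
  pairs <- utils::combn(levels(grouping), 2L)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    lv <- pairs[, j]
    idx <- which(grouping %in% lv)
    if (min(table(droplevels(grouping[idx]))) < 2L) {
      warning("skipping pair ", lv[1], " vs ", lv[2],
              ": level with < 2 samples", call. = FALSE)
      return(NULL)
    }
    res <- permanova(dm[idx, idx], data.frame(g = droplevels(grouping[idx])),
                     terms = "g", n_perm = n_perm)
    tibble::tibble(level_1 = lv[1], level_2 = lv[2],
                   t = sqrt(res$tab$pseudo_F), pseudo_F = res$tab$pseudo_F,
                   p_perm = res$tab$p_perm, n_perm = res$n_perm)
  })
  do.call(rbind, rows)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Tests whether groups differ in their multivariate dispersion: samples are
#' embedded by principal coordinates (with the standard correction for
#' negative eigenvalues of non-Euclidean dissimilarities, via
#' [vegan::betadisper()]), each sample's distance to its group centroid is
#' computed, and the one-way F on these distances is tested by permuting
#' group labels.
#'
#' @param d A [stats::dist] object.
#' @param grouping Group labels aligned with `d`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `"permdisp"`: `dispersions` (mean distance to
#'   centroid per group), `F`, `df`, `p_perm`, `n_perm`, `distances`
#'   (per-sample distances to centroid), `seed`.
#' @export
permdisp <- function(d, grouping, n_perm = 999, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (min(table(grouping)) < 2L) stop("every group needs at least 2 samples", call. = FALSE)
  bd <- vegan::betadisper(d, grouping, type = "centroid")
  z <- bd$distances
  f_of <- function(g) {
    fit <- stats::lm(z ~ g)
    stats::anova(fit)[1, "F value"]
  }
  f_obs <- f_of(grouping)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    if (f_of(sample(grouping)) >= f_obs - 1e-12) count <- count + 1L
  }
  structure(list(
    dispersions = tapply(z, grouping, mean),
    F = f_obs,
    df = c(nlevels(grouping) - 1L, length(z) - nlevels(grouping)),
    p_perm = (1 + count) / (1 + n_perm),
    n_perm = n_perm, distances = z, seed = seed),
    class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat(sprintf("PERMDISP: F(%d, %d) = %.4f, P(perm) = %.4g [%d permutations]\n",
              x$df[1], x$df[2], x$F, x$p_perm, x$n_perm))
  cat("Mean distance to centroid:\n"); print(round(x$dispersions, 4))
  invisible(x)
}

#' Principal component analysis of fatty-acid profiles
#'
#' Eigendecomposition of the covariance (or, with `standardize = TRUE`, the
#' correlation) matrix of the centred data. Reports percent variance per
#' axis and the percent contribution of each variable to each axis
#' (\eqn{100 \, \ell_{jk}^2 / \sum_j \ell_{jk}^2} for loading
#' \eqn{\ell_{jk}}). The sign of each axis is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x An `fa_profiles` object or numeric matrix (samples x variables).
#' @param standardize Use the correlation matrix (default `TRUE`); with
#'   `FALSE` the covariance matrix of the raw percent data is used.
#' @return Object of class `"fa_pca"`: `eigenvalues`, `percent_variance`,
#'   `scores` (samples x axes), `loadings` (variables x axes),
#'   `contributions` (percent, columns summing to 100), `center`, `scale`.
#' @export
fa_pca <- function(x, standardize = TRUE) {
  m <- if (inherits(x, "fa_profiles")) fa_matrix(x) else as.matrix(x)
  if (nrow(m) < 3L || ncol(m) < 2L) {
    stop("need at least 3 samples and 2 variables", call. = FALSE)
  }
  if (standardize) {
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("constant variable(s) cannot be standardized: ",
           paste(sQuote(colnames(m)[sds == 0]), collapse = ", "), call. = FALSE)
    }
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = standardize)
  eig <- pc$sdev^2
  rot <- pc$rotation
  sco <- pc$x
  for (k in seq_len(ncol(rot))) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) {
      rot[, k] <- -rot[, k]
      sco[, k] <- -sco[, k]
    }
  }
  structure(list(
    eigenvalues = eig,
    percent_variance = 100 * eig / sum(eig),
    scores = sco, loadings = rot,
    contributions = 100 * rot^2 / rep(colSums(rot^2), each = nrow(rot)),
    center = pc$center,
    scale = if (standardize) pc$scale else NULL),
    class = "fa_pca")
}

#' @export
print.fa_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat("PCA: percent variance of first axes:\n")
  print(round(stats::setNames(x$percent_variance[1:k],
                              paste0("Dim", 1:k)), 2))
  invisible(x)
}

#' Normal-theory 95% confidence ellipse for ordination scores
#'
#' Returns the outline of the 2-D normal confidence ellipse of a group's
#' scores on two ordination axes, for plotting.
#'
#' @param scores Two-column matrix of a group's scores.
#' @param level Coverage (default 0.95).
#' @param n_points Number of polygon vertices.
#' @return Two-column matrix of ellipse coordinates.
#' @export
score_ellipse <- function(scores, level = 0.95, n_points = 100) {
  stopifnot(ncol(scores) == 2L, nrow(scores) >= 3L)
  ctr <- colMeans(scores)
  cv <- stats::cov(scores)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points)
  circle <- cbind(cos(theta), sin(theta))
  e <- eigen(cv, symmetric = TRUE)
  t(ctr + t(circle %*% diag(sqrt(pmax(e$values, 0))) %*% t(e$vectors)) * r)
}
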
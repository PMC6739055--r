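# Bootstrap-LDA source attribution. The classifier is a Gaussian rule with
# per-class means and one pooled within-class covariance (optionally ridge-
# regularised, since compositional profiles are collinear by construction).
# All classification happens on a fixed, shared set of PUFA labels, with
# profiles renormalized to sum 100 over that set.

#' Build a library of candidate PUFA source groups
#'
#' Collects labelled groups of profiles (plankton groups, symbionts, ...)
#' into the training library for the discriminant model. Profiles are
#' restricted to `pufa_labels` and, by default, renormalized to sum 100 over
#' them, so that sources reported on different denominators are comparable.
#'
#' @param x An `fa_profiles` object whose `source_group` column names each
#'   sample's group.
#' @param pufa_labels Labels defining the model space; defaults to the
#'   PUFA-class labels present in `x`.
#' @param renormalize Renormalize each profile over `pufa_labels`
#'   (default `TRUE`).
#' @return Object of class `"source_library"`: `x` (matrix), `group`
#'   (factor), `labels`.
#' @export
source_library <- function(x, pufa_labels = NULL, renormalize = TRUE) {
  stopifnot(inherits(x, "fa_profiles"))
  if (all(is.na(x$source_group))) stop("source_group metadata required", call. = FALSE)
  if (is.null(pufa_labels)) pufa_labels <- fa_labels_of_class(x, "PUFA")
  sub <- subset_fas(x, pufa_labels, renormalize = renormalize)
  lib <- structure(list(x = fa_matrix(sub),
                        group = factor(x$source_group),
                        labels = canonicalize_fa_label(pufa_labels)),
                   class = "source_library")
  if (nlevels(lib$group) < 2L) stop("need at least 2 source groups", call. = FALSE)
  if (min(table(lib$group)) < 3L) {
    stop("every source group needs at least 3 samples", call. = FALSE)
  }
  lib
}

#' @export
print.source_library <- function(x, ...) {
  cat("<source_library> ", nlevels(x$group), " groups over ",
      length(x$labels), " PUFA\n", sep = "")
  print(table(x$group))
  invisible(x)
}

# Core fit: class means, pooled within-class covariance (+ ridge), and the
# linear discriminant weights. Classes sorted so argmax ties resolve
# lexicographically.
fit_lda_core <- function(x, group, priors = "uniform", ridge = NULL) {
  group <- factor(group, levels = sort(unique(as.character(group))))
  classes <- levels(group)
  k <- length(classes)
  d <- ncol(x)
  n <- nrow(x)
  means <- do.call(rbind, lapply(classes, function(g) colMeans(x[group == g, , drop = FALSE])))
  rownames(means) <- classes
  sw <- matrix(0, d, d)
  for (g in classes) {
    xg <- x[group == g, , drop = FALSE]
    if (nrow(xg) > 1L) {
      xc <- sweep(xg, 2L, colMeans(xg))
      sw <- sw + crossprod(xc)
    }
  }
  cov <- sw / (n - k)
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(cov)) / d
  cov_r <- cov + diag(ridge, d)
  ch <- tryCatch(chol(cov_r), error = function(e) NULL)
  if (is.null(ch)) {
    stop("pooled covariance is singular; supply a positive ridge", call. = FALSE)
  }
  w <- backsolve(ch, forwardsolve(t(ch), t(means)))  # S^-1 M', d x k
  prior <- if (identical(priors, "proportional")) {
    as.numeric(table(group)) / n
  } else rep(1 / k, k)
  b <- -0.5 * colSums(t(means) * w) + log(prior)
  list(classes = classes, means = means, cov = cov_r, ridge = ridge,
       prior = stats::setNames(prior, classes), w = w, b = b)
}

#' Fit the pooled-covariance linear discriminant model
#'
#' @param lib A [source_library()].
#' @param priors `"uniform"` (default: prey availability is unknown, so
#'   group sizes reflect literature coverage, not diet) or `"proportional"`
#'   to group sizes.
#' @param ridge Ridge added to the pooled covariance diagonal; default
#'   `1e-6 * trace / dimension`, guaranteeing invertibility on compositional
#'   data. Use 0 to forbid regularisation (errors if singular).
#' @return Object of class `"lda_model"` with class means, regularised
#'   pooled covariance, priors and discriminant weights.
#' @export
fit_lda <- function(lib, priors = c("uniform", "proportional"), ridge = NULL) {
  stopifnot(inherits(lib, "source_library"))
  priors <- match.arg(priors)
  core <- fit_lda_core(lib$x, lib$group, priors, ridge)
  core$labels <- lib$labels
  core$priors_mode <- priors
  structure(core, class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat("<lda_model> ", length(x$classes), " classes, ", ncol(x$means),
      " variables, ridge = ", format(x$ridge, digits = 3), "\n", sep = "")
  invisible(x)
}

classify_core <- function(core, newx) {
  scores <- newx %*% core$w + rep(core$b, each = nrow(newx))
  idx <- max.col(scores, ties.method = "first")
  post <- exp(scores - apply(scores, 1L, max))
  post <- post / rowSums(post)
  colnames(post) <- core$classes
  list(class = core$classes[idx], posterior = post, scores = scores)
}

#' Classify profiles with a fitted discriminant model
#'
#' Assigns each profile to the class maximising the Gaussian posterior under
#' the shared covariance; ties are broken lexicographically by class name
#' (and reported via [message()]).
#'
#' @param model An `"lda_model"`.
#' @param newdata An `fa_profiles` object or numeric matrix over the model's
#'   labels. Profiles are subset to the model's labels and renormalized.
#' @return List with `class` (character vector) and `posterior` (matrix,
#'   rows summing to 1).
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "lda_model"))
  newx <- prepare_hosts(newdata, model$labels)
  if (ncol(newx) != ncol(model$means)) {
    stop("dimension mismatch: model has ", ncol(model$means),
         " variables, data has ", ncol(newx), call. = FALSE)
  }
  res <- classify_core(model, newx)
  s <- apply(res$scores, 1L, function(v) sort(v, decreasing = TRUE)[1:2])
  n_tie <- sum(abs(s[1, ] - s[2, ]) < 1e-12)
  if (n_tie > 0) message(n_tie, " tied classification(s) broken lexicographically")
  res[c("class", "posterior")]
}

prepare_hosts <- function(newdata, labels, renormalize = TRUE) {
  if (inherits(newdata, "fa_profiles")) {
    fa_matrix(subset_fas(newdata, labels, renormalize = renormalize))
  } else {
    m <- as.matrix(newdata)
    if (is.null(colnames(m))) {
      stopifnot(ncol(m) == length(labels))
      colnames(m) <- labels
    }
    absent <- setdiff(labels, colnames(m))
    if (length(absent)) {
      stop("dimension mismatch: data lacks label(s) ",
           paste(sQuote(absent), collapse = ", "), call. = FALSE)
    }
    m[, labels, drop = FALSE]
  }
}

#' Leave-one-out cross-validated source classification
#'
#' Each library sample is classified by a model fitted on all other samples;
#' per-group classification rates and the confusion matrix are reported.
#' This is the evidence on which [prune_sources()] decides which candidate
#' sources are distinguishable enough to keep.
#'
#' @param lib A [source_library()] (every group >= 3 samples).
#' @param priors,ridge Passed to the per-fold fits.
#' @return Object of class `"loocv_report"`: `rates` (named, correct/n per
#'   group), `confusion` (true x assigned counts), `n` (group sizes).
#' @export
loocv <- function(lib, priors = "uniform", ridge = NULL) {
  stopifnot(inherits(lib, "source_library"))
  n <- nrow(lib$x)
  pred <- character(n)
  for (i in seq_len(n)) {
    core <- fit_lda_core(lib$x[-i, , drop = FALSE], lib$group[-i], priors, ridge)
    pred[i] <- classify_core(core, lib$x[i, , drop = FALSE])$class
  }
  truth <- as.character(lib$group)
  classes <- levels(lib$group)
  confusion <- table(true = factor(truth, classes), assigned = factor(pred, classes))
  rates <- diag(confusion) / rowSums(confusion)
  structure(list(rates = rates, confusion = confusion,
                 n = rowSums(confusion)), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat("LOOCV classification rates:\n")
  print(round(x$rates, 3))
  invisible(x)
}

#' Remove candidate sources with poor cross-validated classification
#'
#' Groups whose leave-one-out classification rate falls below `threshold`
#' (default 0.85) are dropped from the library: a source the discriminant
#' model cannot reliably recognise among the candidates cannot be attributed
#' meaningfully. By default this is a single pass on the full library;
#' `iterate = TRUE` refits and re-evaluates until the retained set is stable.
#'
#' @param lib A [source_library()].
#' @param threshold Minimum LOOCV rate to retain (default 0.85).
#' @param report Optional precomputed [loocv()] report for `lib` (computed
#'   if missing).
#' @param iterate Re-run LOOCV on the pruned library until stable.
#' @param priors,ridge Passed to [loocv()].
#' @return A pruned `"source_library"` with attribute `"dropped"` naming the
#'   removed groups.
#' @export
prune_sources <- function(lib, threshold = 0.85, report = NULL,
                          iterate = FALSE, priors = "uniform", ridge = NULL) {
  stopifnot(inherits(lib, "source_library"))
  dropped <- character(0)
  repeat {
    if (is.null(report)) report <- loocv(lib, priors, ridge)
    bad <- names(report$rates)[report$rates < threshold]
    if (length(bad) == 0L) break
    message("removing source group(s) below LOOCV rate ", threshold, ": ",
            paste(bad, collapse = ", "))
    dropped <- c(dropped, bad)
    keep <- !(lib$group %in% bad)
    lib$x <- lib$x[keep, , drop = FALSE]
    lib$group <- droplevels(lib$group[keep])
    if (nlevels(lib$group) < 2L) {
      stop("fewer than 2 source groups survive pruning", call. = FALSE)
    }
    report <- NULL
    if (!iterate) break
  }
  attr(lib, "dropped") <- dropped
  lib
}

#' Drop PUFA absent from every retained source
#'
#' A fatty acid that no candidate source carries (all-zero across the
#' library) cannot inform attribution and is removed from both the library
#' and the host profiles; host profiles are re-restricted to the shared
#' label set. In the coral study this removes 18:5n-3, which occurs in some
#' hosts but in none of the retained sources.
#'
#' @param lib A [source_library()].
#' @param hosts An `fa_profiles` object of host samples (optional).
#' @return List with `library`, `hosts` (subset to the shared labels, or
#'   `NULL`), and `dropped` (removed labels).
#' @export
drop_unshared_pufa <- function(lib, hosts = NULL) {
  stopifnot(inherits(lib, "source_library"))
  all_zero <- colSums(lib$x) == 0
  dropped <- lib$labels[all_zero]
  if (length(dropped)) {
    message("dropping PUFA absent from all sources: ", paste(dropped, collapse = ", "))
    lib$x <- lib$x[, !all_zero, drop = FALSE]
    lib$labels <- lib$labels[!all_zero]
  }
  if (!is.null(hosts)) hosts <- subset_fas(hosts, lib$labels, renormalize = FALSE)
  list(library = lib, hosts = hosts, dropped = dropped)
}

#' Bootstrap estimation of per-source contributions to host PUFA
#'
#' The attribution engine. Per iteration: each source group is resampled
#' with replacement to its own size, the discriminant model is refitted on
#' the resampled library, and every host sample of each species is
#' hard-classified to a source; the iteration's "diet combination" for a
#' species is the fraction of its host samples assigned to each source
#' (exact multiples of 1/n hosts, summing to 1). Across iterations this
#' yields a distribution of possible diet combinations per species,
#' summarised by mean, SD and percentile 95% interval. Host samples are
#' never resampled and never enter fitting. A resample in which any group
#' collapses to a single distinct point is redrawn (counted and reported).
#'
#' @param lib A pruned, label-aligned [source_library()].
#' @param hosts An `fa_profiles` object of host samples with a `species`
#'   column; profiles are restricted to the library labels and renormalized.
#' @param n_iter Bootstrap iterations (default 10000; below 100 a warning is
#'   issued).
#' @param priors,ridge Passed to each iteration's fit.
#' @param seed Integer seed; with it fixed, the result is bit-reproducible.
#' @param mode `"hard"` (default, fraction of hosts assigned per source) or
#'   `"posterior"` (mean posterior probability per source).
#' @return Object of class `"contribution_distribution"`: `draws` (named
#'   list per species of n_iter x n_sources fraction matrices), `summary`
#'   (tibble: species, source, mean, sd, ci_lower, ci_upper), `n_iter`,
#'   `ridge`, `seed`, `redraws`.
#' @export
bootstrap_attribution <- function(lib, hosts, n_iter = 10000,
                                  priors = "uniform", ridge = NULL,
                                  seed = NULL, mode = c("hard", "posterior")) {
  stopifnot(inherits(lib, "source_library"), inherits(hosts, "fa_profiles"))
  mode <- match.arg(mode)
  if (n_iter < 100) warning("n_iter < 100 gives unstable intervals", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  classes <- levels(lib$group)
  group_idx <- split(seq_len(nrow(lib$x)), lib$group)
  hx <- prepare_hosts(hosts, lib$labels)
  species <- sort(unique(hosts$species))
  sp_idx <- lapply(stats::setNames(species, species), function(s) which(hosts$species == s))
  draws <- lapply(sp_idx, function(i) {
    matrix(NA_real_, n_iter, length(classes), dimnames = list(NULL, classes))
  })
  redraws <- 0L
  for (it in seq_len(n_iter)) {
    repeat {
      idx <- unlist(lapply(group_idx, function(ii) sample(ii, length(ii), replace = TRUE)),
                    use.names = FALSE)
      xb <- lib$x[idx, , drop = FALSE]
      gb <- lib$group[idx]
      collapsed <- vapply(split(seq_along(gb), gb), function(ii) {
        nrow(unique(xb[ii, , drop = FALSE])) < 2L
      }, logical(1))
      if (!any(collapsed)) break
      redraws <- redraws + 1L
    }
    core <- fit_lda_core(xb, gb, priors, ridge)
    res <- classify_core(core, hx)
    for (s in species) {
      i <- sp_idx[[s]]
      draws[[s]][it, ] <- if (mode == "hard") {
        tabulate(factor(res$class[i], classes), nbins = length(classes)) / length(i)
      } else {
        colMeans(res$posterior[i, , drop = FALSE])
      }
    }
  }
  if (redraws > 0) message(redraws, " degenerate bootstrap resample(s) redrawn")
  summary <- do.call(rbind, lapply(species, function(s) {
    m <- draws[[s]]
    tibble::tibble(
      species = s, source = classes,
      mean = unname(colMeans(m)), sd = unname(apply(m, 2L, stats::sd)),
      ci_lower = unname(apply(m, 2L, stats::quantile, 0.025)),
      ci_upper = unname(apply(m, 2L, stats::quantile, 0.975)))
  }))
  structure(list(draws = draws, summary = summary, n_iter = n_iter,
                 mode = mode, ridge = if (is.null(ridge)) NA_real_ else ridge,
                 seed = seed, redraws = redraws),
            class = "contribution_distribution")
}

#' @export
print.contribution_distribution <- function(x, ...) {
  cat("Bootstrap source contributions (", x$n_iter, " iterations, ",
      x$mode, " assignment)\n", sep = "")
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Aggregate source contributions into categories
#'
#' Sums per-iteration diet fractions over a source-to-category mapping
#' (typically particulate food vs endosymbionts) and summarises the
#' resulting category distributions per host species. Within every
#' iteration the category fractions still sum to 1.
#'
#' @param cd A `"contribution_distribution"`.
#' @param mapping Named character vector, `source name -> category`; must
#'   cover every source in `cd`.
#' @return Tibble with `species`, `category`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper` (percentile 95% interval).
#' @export
aggregate_contributions <- function(cd, mapping) {
  stopifnot(inherits(cd, "contribution_distribution"))
  sources <- colnames(cd$draws[[1]])
  unmapped <- setdiff(sources, names(mapping))
  if (length(unmapped)) {
    stop("unmapped source(s): ", paste(sQuote(unmapped), collapse = ", "), call. = FALSE)
  }
  cats <- sort(unique(unname(mapping[sources])))
  do.call(rbind, lapply(names(cd$draws), function(s) {
    m <- cd$draws[[s]]
    agg <- vapply(cats, function(cat) {
      rowSums(m[, mapping[sources] == cat, drop = FALSE])
    }, numeric(nrow(m)))
    tibble::tibble(
      species = s, category = cats,
      mean = unname(colMeans(agg)), sd = unname(apply(agg, 2L, stats::sd)),
      ci_lower = unname(apply(agg, 2L, stats::quantile, 0.025)),
      ci_upper = unname(apply(agg, 2L, stats::quantile, 0.975)))
  }))
}
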
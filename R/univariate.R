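# Classical fixed-effects ANOVA, TukeyHSD and OLS regression, wrapped into
# the table shapes the rest of the pipeline consumes. Undefined index values
# (NA from zero denominators) are dropped pairwise before fitting, with a
# message reporting the count.

#' One- or two-way fixed-effects analysis of variance
#'
#' @param response Numeric response vector; `NA` values are dropped (with a
#'   message) together with their factor labels.
#' @param factors A factor/vector, or a named list of one or two of them.
#' @param interaction Include the interaction term in two-way models
#'   (default `TRUE`). Interaction models require every cell to contain at
#'   least 2 observations.
#' @return Object of class `"fa_anova"`: `tab` (tibble of term, df, SS, MS,
#'   F, p), `residual`, and the fitted [stats::aov] object in `$fit` (for
#'   [tukey_hsd()]).
#' @examples
#' fa_anova(c(1, 2, 3, 4, 5, 6), factors = rep(c("a", "b"), each = 3))
#' @export
fa_anova <- function(response, factors, interaction = TRUE) {
  if (!is.list(factors)) factors <- list(f1 = factors)
  if (is.null(names(factors)) || any(names(factors) == "")) {
    names(factors) <- paste0("f", seq_along(factors))
  }
  stopifnot(length(factors) %in% 1:2)
  df <- data.frame(.y = response, lapply(factors, factor))
  keep <- !is.na(df$.y)
  if (any(!keep)) {
    message(sum(!keep), " observation(s) with undefined response dropped")
    df <- df[keep, , drop = FALSE]
    df[-1] <- lapply(df[-1], droplevels)
  }
  for (f in df[-1]) {
    if (nlevels(f) < 2L) stop("each factor needs at least 2 levels", call. = FALSE)
  }
  rhs <- paste(names(factors), collapse = if (interaction && length(factors) == 2L) " * " else " + ")
  if (interaction && length(factors) == 2L) {
    cells <- table(df[[2]], df[[3]])
    if (any(cells == 0L)) stop("empty cell(s) in interaction model", call. = FALSE)
    if (any(cells < 2L)) stop("interaction model needs >= 2 observations per cell", call. = FALSE)
  }
  fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = df)
  a <- stats::anova(fit)
  if (stats::var(df$.y) < .Machine$double.eps * mean(df$.y)^2 ||
      stats::var(df$.y) == 0) {
    # no variation at all: the decomposition is degenerate, not significant
    a$`F value`[] <- 0
    a$`Pr(>F)`[] <- 1
  }
  terms <- rownames(a)
  res_i <- terms == "Residuals"
  structure(list(
    tab = tibble::tibble(
      term = terms[!res_i], df = a$Df[!res_i], SS = a$`Sum Sq`[!res_i],
      MS = a$`Mean Sq`[!res_i], F = a$`F value`[!res_i], p = a$`Pr(>F)`[!res_i]),
    residual = list(df = a$Df[res_i], SS = a$`Sum Sq`[res_i],
                    MS = a$`Mean Sq`[res_i]),
    fit = fit), class = "fa_anova")
}

#' @export
print.fa_anova <- function(x, ...) {
  print(as.data.frame(x$tab), digits = 4)
  cat(sprintf("Residual: df = %d, SS = %.4f\n", x$residual$df, x$residual$SS))
  invisible(x)
}

#' Tukey honest-significant-difference post-hoc comparisons
#'
#' Studentized-range-adjusted pairwise comparisons following a significant
#' ANOVA. For two-way models with interaction, `which = "cells"` compares
#' the interaction cell means; otherwise each main-effect factor's levels
#' are compared marginally.
#'
#' @param a An `"fa_anova"` object.
#' @param which `"factors"` (marginal level comparisons per factor, default)
#'   or `"cells"` (interaction cell means; two-way models only).
#' @return Tibble with `term`, `comparison`, `diff` (difference of means),
#'   `lwr`, `upr` (95% family-wise interval) and `p_adj`.
#' @export
tukey_hsd <- function(a, which = c("factors", "cells")) {
  stopifnot(inherits(a, "fa_anova"))
  which <- match.arg(which)
  tk <- if (which == "cells") {
    nm <- setdiff(a$tab$term, grep(":", a$tab$term, value = TRUE))
    if (length(nm) < 2L) stop("cell comparisons need a two-way model", call. = FALSE)
    stats::TukeyHSD(a$fit, which = paste(nm, collapse = ":"))
  } else {
    stats::TukeyHSD(a$fit, which = setdiff(a$tab$term, grep(":", a$tab$term, value = TRUE)))
  }
  rows <- lapply(names(tk), function(term) {
    m <- tk[[term]]
    tibble::tibble(term = term, comparison = rownames(m),
                   diff = m[, "diff"], lwr = m[, "lwr"], upr = m[, "upr"],
                   p_adj = m[, "p adj"])
  })
  do.call(rbind, rows)
}

#' Ordinary least-squares fit of y on x
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; pairs with `NA` in
#'   either are dropped.
#' @return List with `slope`, `intercept`, `r_squared`, `adj_r_squared`
#'   (\eqn{1 - (1 - R^2)(n - 1)/(n - 2)}), `p` (slope t-test), `n`, and the
#'   [stats::lm] fit.
#' @export
linear_fit <- function(x, y) {
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       adj_r_squared = s$adj.r.squared,
       p = unname(s$coefficients[2, 4]),
       n = length(x), fit = fit)
}

colony_of <- function(x) {
  if ("colony" %in% names(x) && !all(is.na(x$colony))) return(x$colony)
  sub("[_-](host|symbiont)$", "", x$sample_id)
}

#' Per-fatty-acid regressions of host on symbiont proportions
#'
#' For every fatty acid present in both tissue fractions, regresses the host
#' proportion on the symbiont proportion across colonies, pairing host and
#' symbiont samples by colony (an explicit `colony` column, or the
#' `sample_id` stripped of a `_host`/`_symbiont` suffix). A row for the
#' summed long-chain MUFA index is appended. No multiple-testing correction
#' is applied across fatty acids; raw p-values are reported and flagged at
#' alpha = 0.05.
#'
#' @param x An `fa_profiles` object containing host and symbiont samples.
#' @param by_species Fit within each species separately (default `TRUE`).
#' @return Tibble with `species` (or `"all"`), `fa`, `slope`, `intercept`,
#'   `adj_r_squared`, `p`, `n`, `significant`.
#' @export
host_symbiont_regressions <- function(x, by_species = TRUE) {
  stopifnot(inherits(x, "fa_profiles"))
  host <- x[x$tissue == "host", ]
  symb <- x[x$tissue == "symbiont", ]
  hc <- colony_of(host); sc <- colony_of(symb)
  orphans <- c(setdiff(hc, sc), setdiff(sc, hc))
  if (length(orphans)) {
    stop("unpaired colony id(s): ", paste(sQuote(unique(orphans)), collapse = ", "),
         call. = FALSE)
  }
  symb <- symb[match(hc, sc), ]
  hm <- fa_matrix(restore_profiles(host, x))
  sm <- fa_matrix(restore_profiles(symb, x))
  groups <- if (by_species) split(seq_len(nrow(hm)), host$species) else list(all = seq_len(nrow(hm)))
  vars <- c(fa_labels(x), "lc_mufa_sum")
  hv <- cbind(hm, lc_mufa_sum = sum_lc_mufa(restore_profiles(host, x)))
  sv <- cbind(sm, lc_mufa_sum = sum_lc_mufa(restore_profiles(symb, x)))
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    per_fa <- lapply(vars, function(v) {
      xs <- sv[idx, v]; ys <- hv[idx, v]
      if (sum(!(is.na(xs) | is.na(ys))) < 3L || stats::sd(xs, na.rm = TRUE) == 0) {
        return(NULL)
      }
      f <- linear_fit(xs, ys)
      tibble::tibble(species = gname, fa = v, slope = f$slope,
                     intercept = f$intercept, adj_r_squared = f$adj_r_squared,
                     p = f$p, n = f$n, significant = f$p < 0.05)
    })
    do.call(rbind, per_fa)
  })
  do.call(rbind, rows)
}

# Re-attach fa_profiles class/attrs after a tibble subset operation.
restore_profiles <- function(sub, orig) {
  attr(sub, "fa_labels") <- fa_labels(orig)
  if (!inherits(sub, "fa_profiles")) class(sub) <- c("fa_profiles", class(sub))
  sub
}
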
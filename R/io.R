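# Readers/writers for the tabular profile layout (one row per sample:
# metadata columns, then one column per fatty-acid label) and the pipeline
# orchestrator.

#' Read fatty-acid profiles from a delimited file or spreadsheet
#'
#' Expects a header row with the metadata columns (`sample_id`, `species`,
#' `tissue`, optionally `depth_m`, `source_group`, `colony`) followed by one
#' column per fatty-acid label. Labels are canonicalized (whitespace
#' stripped, typographic minus normalized), so spreadsheet exports using
#' "n−7" parse as "n-7". Columns that parse neither as metadata nor as
#' fatty-acid shorthand raise an error naming them.
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"` or `"xlsx"` (guessed from the extension by
#'   default; xlsx requires the readxl package).
#' @param renormalize,tol Passed to [fa_profiles()].
#' @return An `fa_profiles` object.
#' @export
read_fa_profiles <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                             renormalize = FALSE, tol = 1.0) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", xlsx = "xlsx", xls = "xlsx", "csv")
  }
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    tsv = utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("reading xlsx requires the readxl package", call. = FALSE)
      }
      as.data.frame(readxl::read_excel(path), check.names = FALSE)
    })
  unknown <- setdiff(names(df), META_COLS)
  ok <- vapply(unknown, function(nm) {
    !inherits(tryCatch(parse_fatty_acid(nm), error = function(e) e), "error")
  }, logical(1))
  if (any(!ok)) {
    stop("column(s) neither metadata nor fatty-acid labels: ",
         paste(sQuote(unknown[!ok]), collapse = ", "), call. = FALSE)
  }
  fa_profiles(df, renormalize = renormalize, tol = tol)
}

#' Write fatty-acid profiles to CSV or TSV
#'
#' Inverse of [read_fa_profiles()]: `read_fa_profiles(write_fa_profiles(x, p))`
#' round-trips the profile set.
#'
#' @param x An `fa_profiles` object.
#' @param path Output path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_fa_profiles <- function(x, path, format = c("csv", "tsv")) {
  stopifnot(inherits(x, "fa_profiles"))
  format <- match.arg(format)
  utils::write.table(as.data.frame(x), path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Run the full trophic analysis pipeline
#'
#' Orchestrates the analysis stages in order on a host/symbiont profile set:
#' (1) test the depth factor by PERMANOVA and pool depths when it is
#' non-significant at `alpha`; (2) PERMANOVA of species x tissue with
#' pairwise comparisons and PERMDISP on the interaction grouping; (3) PCA on
#' all fatty acids and on the PUFA subset; (4) the three trophic indices
#' with one-way ANOVA and Tukey comparisons per tissue; (5) host-symbiont
#' per-fatty-acid regressions; (6) optionally, bootstrap-LDA source
#' attribution when a source library is supplied.
#'
#' @param x An `fa_profiles` object with host and symbiont samples.
#' @param sources Optional `fa_profiles` of candidate PUFA sources (with
#'   `source_group` set) for the attribution stage.
#' @param metric Dissimilarity for the multivariate stage (`"bray"` or
#'   `"euclidean"`).
#' @param n_perm Permutations for PERMANOVA/PERMDISP (default 9999).
#' @param n_iter Bootstrap iterations for attribution (default 10000).
#' @param loocv_threshold Pruning threshold for source LOOCV rates.
#' @param category_mapping Named vector mapping each retained source to
#'   `"particulate"` or `"symbiont"` for [aggregate_contributions()];
#'   by default every group named like a symbiont maps to `"symbiont"`
#'   and the rest to `"particulate"`.
#' @param pool_depths `"auto"` (pool when depth is non-significant),
#'   `"always"`, or `"never"`.
#' @param alpha Significance level for the depth pooling decision.
#' @param ridge Ridge for the discriminant fits.
#' @param seed Integer seed governing every stochastic stage.
#' @return List of class `"trophic_report"` with elements `config`,
#'   `depth_test`, `pooled_depths`, `permanova`, `pairwise`, `permdisp`,
#'   `pca_all`, `pca_pufa`, `indices`, `index_anova`, `regressions`, and
#'   (when sources are given) `loocv`, `pruned`, `attribution`,
#'   `aggregated`.
#' @export
run_trophic_pipeline <- function(x, sources = NULL, metric = "bray",
                                 n_perm = 9999, n_iter = 10000,
                                 loocv_threshold = 0.85,
                                 category_mapping = NULL,
                                 pool_depths = c("auto", "always", "never"),
                                 alpha = 0.05, ridge = NULL, seed = 1L) {
  stopifnot(inherits(x, "fa_profiles"))
  pool_depths <- match.arg(pool_depths)
  set.seed(seed)
  report <- list(config = list(metric = metric, n_perm = n_perm, n_iter = n_iter,
                               loocv_threshold = loocv_threshold, alpha = alpha,
                               seed = seed))

  d <- fa_dist(x, metric)
  has_depth <- !all(is.na(x$depth_m))
  if (has_depth && pool_depths != "always") {
    report$depth_test <- permanova(
      d, fa_meta(x), terms = c("depth_m", "species", "tissue", "species:tissue"),
      n_perm = n_perm)
    depth_p <- report$depth_test$tab$p_perm[report$depth_test$tab$term == "depth_m"]
  } else depth_p <- 1
  report$pooled_depths <- pool_depths == "always" ||
    (pool_depths == "auto" && depth_p >= alpha)
  if (!report$pooled_depths) {
    message("depth significant at alpha = ", alpha, "; retained as a factor")
  }

  terms <- if (report$pooled_depths) c("species", "tissue", "species:tissue") else
    c("depth_m", "species", "tissue", "species:tissue")
  report$permanova <- permanova(d, fa_meta(x), terms = terms, n_perm = n_perm)
  report$pairwise <- list(
    tissue = pairwise_permanova(d, x$tissue, n_perm = n_perm),
    species_host = with_subset_pairwise(x, "host", metric, n_perm),
    species_symbiont = with_subset_pairwise(x, "symbiont", metric, n_perm))
  report$permdisp <- permdisp(d, interaction(x$species, x$tissue), n_perm = min(n_perm, 999))

  report$pca_all <- fa_pca(x)
  pufa <- intersect(fa_labels(x), fa_labels_of_class(x, "PUFA"))
  if (length(pufa) >= 2L) report$pca_pufa <- fa_pca(subset_fas(x, pufa))

  report$indices <- index_table(x)
  report$index_anova <- lapply(
    stats::setNames(c("ratio_18_1", "photo_animal", "lc_mufa_sum"),
                    c("ratio_18_1", "photo_animal", "lc_mufa_sum")),
    function(v) {
      lapply(stats::setNames(c("host", "symbiont"), c("host", "symbiont")), function(tis) {
        idx <- report$indices[report$indices$tissue == tis, ]
        if (nrow(idx) < 4L || length(unique(idx$species)) < 2L) return(NULL)
        a <- fa_anova(idx[[v]], list(species = idx$species))
        list(anova = a, tukey = tukey_hsd(a))
      })
    })

  if (all(c("host", "symbiont") %in% x$tissue)) {
    report$regressions <- host_symbiont_regressions(x)
  }

  if (!is.null(sources)) {
    lib <- source_library(sources)
    report$loocv <- loocv(lib, ridge = ridge)
    pruned <- prune_sources(lib, threshold = loocv_threshold,
                            report = report$loocv, ridge = ridge)
    hosts <- restore_profiles(x[x$tissue == "host", ], x)
    shared <- drop_unshared_pufa(pruned, hosts)
    report$pruned <- shared$library
    report$attribution <- bootstrap_attribution(
      shared$library, shared$hosts, n_iter = n_iter, ridge = ridge)
    if (is.null(category_mapping)) {
      src <- levels(shared$library$group)
      category_mapping <- stats::setNames(
        ifelse(grepl("symbiont", src, ignore.case = TRUE), "symbiont", "particulate"),
        src)
    }
    report$aggregated <- aggregate_contributions(report$attribution, category_mapping)
  }
  class(report) <- "trophic_report"
  report
}

with_subset_pairwise <- function(x, tissue, metric, n_perm) {
  sub <- restore_profiles(x[x$tissue == tissue, ], x)
  if (nrow(sub) < 4L || length(unique(sub$species)) < 2L) return(NULL)
  pairwise_permanova(fa_dist(sub, metric), sub$species, n_perm = n_perm)
}

#' @export
print.trophic_report <- function(x, ...) {
  cat("Trophic analysis report (seed ", x$config$seed, ")\n", sep = "")
  cat("Depths pooled: ", x$pooled_depths, "\n\nPERMANOVA:\n", sep = "")
  print(x$permanova)
  if (!is.null(x$attribution)) {
    cat("\nSource attribution:\n")
    print(x$attribution)
  }
  invisible(x)
}
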
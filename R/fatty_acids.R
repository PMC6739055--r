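#' @keywords internal
"_PACKAGE"

# Metadata columns recognised in profile tables, in canonical order.
META_COLS <- c("sample_id", "species", "tissue", "depth_m", "source_group", "colony")
TISSUE_LEVELS <- c("host", "symbiont", "source")

#' Canonicalize fatty-acid shorthand labels
#'
#' Strips whitespace and normalizes typographic minus/dash variants in the
#' omega part ("n−7" becomes "n-7") so labels read from heterogeneous
#' spreadsheets compare equal.
#'
#' @param label Character vector of shorthand labels such as `"18:1n-7"`.
#' @return Character vector of canonical labels.
#' @export
canonicalize_fa_label <- function(label) {
  x <- gsub("[[:space:]]", "", as.character(label))
  # unicode minus, en-dash, em-dash -> ASCII hyphen
  x <- gsub("[−–—]", "-", x)
  x
}

#' Parse fatty-acid shorthand notation
#'
#' Parses `"C:Dn-x"` shorthand (carbons:double bonds, first double bond `x`
#' carbons from the methyl end) into its components and assigns the
#' saturation class: SFA for 0 double bonds, MUFA for 1, PUFA for 2 or more.
#'
#' @param label Character vector of labels, e.g. `c("16:0", "20:5n-3")`.
#' @return A [tibble::tibble] with one row per label and columns `label`
#'   (canonical form), `carbons`, `double_bonds`, `omega` (`NA` for
#'   saturated fatty acids), and `class` (`"SFA"`, `"MUFA"` or `"PUFA"`).
#' @examples
#' parse_fatty_acid(c("18:1n-7", "16:0", "22:6n-3"))
#' @export
parse_fatty_acid <- function(label) {
  lab <- canonicalize_fa_label(label)
  m <- regmatches(lab, regexec("^([0-9]+):([0-9]+)(n-([0-9]+))?$", lab))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed fatty-acid label(s): ",
         paste(sQuote(label[bad]), collapse = ", "), call. = FALSE)
  }
  carbons <- vapply(m, function(g) as.integer(g[2]), integer(1))
  dbl     <- vapply(m, function(g) as.integer(g[3]), integer(1))
  omega   <- vapply(m, function(g) if (g[4] == "") NA_integer_ else as.integer(g[5]),
                    integer(1))
  if (any(carbons <= 0L)) {
    stop("fatty-acid label with non-positive carbon count: ",
         paste(sQuote(lab[carbons <= 0L]), collapse = ", "), call. = FALSE)
  }
  if (any(dbl == 0L & !is.na(omega))) {
    stop("omega series given for saturated fatty acid(s): ",
         paste(sQuote(lab[dbl == 0L & !is.na(omega)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(dbl > 0L & is.na(omega))) {
    stop("unsaturated fatty acid(s) missing the omega series: ",
         paste(sQuote(lab[dbl > 0L & is.na(omega)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    label = lab,
    carbons = carbons,
    double_bonds = dbl,
    omega = omega,
    class = fa_class_from_db(dbl)
  )
}

fa_class_from_db <- function(double_bonds) {
  c("SFA", "MUFA", "PUFA")[pmin(double_bonds, 2L) + 1L]
}

#' Format a fatty acid back to shorthand
#'
#' Inverse of [parse_fatty_acid()]: `format_fatty_acid(parse_fatty_acid(x))`
#' returns the canonical form of `x`.
#'
#' @param fa A data frame with columns `carbons`, `double_bonds`, `omega`
#'   (as returned by [parse_fatty_acid()]).
#' @return Character vector of canonical labels.
#' @export
format_fatty_acid <- function(fa) {
  ifelse(fa$double_bonds == 0L,
         sprintf("%d:%d", fa$carbons, fa$double_bonds),
         sprintf("%d:%dn-%d", fa$carbons, fa$double_bonds, fa$omega))
}

#' Saturation class of fatty-acid labels
#'
#' @param label Character vector of shorthand labels.
#' @return Character vector: `"SFA"`, `"MUFA"` or `"PUFA"`.
#' @export
fa_class <- function(label) parse_fatty_acid(label)$class

#' Construct and validate a set of fatty-acid profiles
#'
#' Builds the package's central container: a tibble with one row per sample,
#' metadata columns (`sample_id`, `species`, `tissue`, and optionally
#' `depth_m`, `source_group`, `colony`), and one numeric column per
#' fatty-acid label holding percent of total fatty acids. Missing values are
#' treated as 0% (a fatty acid not detected in a sample is semantically
#' absent). Each row must sum to 100 within `tol` percentage points unless
#' `renormalize = TRUE`, in which case rows are rescaled to sum exactly 100.
#'
#' @param data Data frame with the metadata columns above followed by one
#'   column per fatty-acid label (any order; columns are recognised by
#'   parsing their names as fatty-acid shorthand).
#' @param renormalize Rescale each row to sum exactly 100 (default `FALSE`).
#' @param tol Allowed deviation of row sums from 100, in percentage points
#'   (default 1.0, absorbing rounding in published tables). Use a small
#'   value for strict checking.
#' @return A tibble of class `"fa_profiles"` with canonical metadata columns
#'   first, fatty-acid columns in their given order, and the fatty-acid
#'   labels stored in `attr(, "fa_labels")`.
#' @examples
#' fa_profiles(data.frame(sample_id = "s1", species = "sp", tissue = "host",
#'                        `16:0` = 60, `18:0` = 40, check.names = FALSE))
#' @export
fa_profiles <- function(data, renormalize = FALSE, tol = 1.0) {
  data <- tibble::as_tibble(data)
  names(data)[!(names(data) %in% META_COLS)] <-
    canonicalize_fa_label(names(data)[!(names(data) %in% META_COLS)])
  fa_cols <- setdiff(names(data), META_COLS)
  if (length(fa_cols) == 0L) stop("no fatty-acid columns found", call. = FALSE)
  parse_fatty_acid(fa_cols)  # errors on malformed labels

  for (col in c("sample_id", "species", "tissue")) {
    if (!col %in% names(data)) stop("missing metadata column ", sQuote(col), call. = FALSE)
  }
  if (anyDuplicated(data$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(sQuote(unique(data$sample_id[duplicated(data$sample_id)])), collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$tissue %in% TISSUE_LEVELS)) {
    stop("tissue must be one of ", paste(TISSUE_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (!"depth_m" %in% names(data)) data$depth_m <- NA_real_
  if (!"source_group" %in% names(data)) data$source_group <- NA_character_
  data$sample_id <- as.character(data$sample_id)
  data$species <- as.character(data$species)
  data$tissue <- as.character(data$tissue)
  data$depth_m <- as.numeric(data$depth_m)
  data$source_group <- as.character(data$source_group)
  if ("colony" %in% names(data)) data$colony <- as.character(data$colony)
  if (any(!is.na(data$depth_m) & data$depth_m < 0)) {
    stop("depth_m must be non-negative", call. = FALSE)
  }

  x <- as.matrix(data[fa_cols])
  storage.mode(x) <- "double"
  x[is.na(x)] <- 0
  if (any(x < 0)) {
    bad <- unique(data$sample_id[rowSums(x < 0) > 0])
    stop("negative proportions in sample(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  rs <- rowSums(x)
  if (any(rs == 0)) {
    stop("all-zero profile(s): ",
         paste(sQuote(data$sample_id[rs == 0]), collapse = ", "), call. = FALSE)
  }
  if (renormalize) {
    x <- 100 * x / rs
  } else if (any(abs(rs - 100) > tol)) {
    bad <- data$sample_id[abs(rs - 100) > tol]
    stop("profile sum outside 100 ± ", tol, " for sample(s): ",
         paste(sQuote(bad), collapse = ", "),
         " (use renormalize = TRUE to rescale)", call. = FALSE)
  }
  data[fa_cols] <- as.data.frame(x)

  meta_present <- intersect(META_COLS, names(data))
  out <- data[c(meta_present, fa_cols)]
  attr(out, "fa_labels") <- fa_cols
  class(out) <- c("fa_profiles", class(out))
  out
}

#' Build a single-sample profile
#'
#' Convenience wrapper around [fa_profiles()] for one sample given as a
#' named vector of proportions.
#'
#' @param proportions Named numeric vector, percent of total fatty acids.
#' @param sample_id,species,tissue,depth_m,source_group Sample metadata.
#' @inheritParams fa_profiles
#' @return A one-row `fa_profiles` tibble.
#' @export
fa_profile <- function(proportions, sample_id = "sample", species = "unknown",
                       tissue = "host", depth_m = NA_real_,
                       source_group = NA_character_,
                       renormalize = FALSE, tol = 1.0) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)))
  df <- tibble::as_tibble(as.list(proportions))
  names(df) <- names(proportions)
  df <- tibble::add_column(df,
    sample_id = sample_id, species = species, tissue = tissue,
    depth_m = depth_m, source_group = source_group, .before = 1)
  fa_profiles(df, renormalize = renormalize, tol = tol)
}

#' Fatty-acid labels of a profile set
#' @param x An `fa_profiles` object.
#' @return Character vector of labels in column order.
#' @export
fa_labels <- function(x) {
  stopifnot(inherits(x, "fa_profiles"))
  attr(x, "fa_labels")
}

#' Numeric matrix view of a profile set
#'
#' @param x An `fa_profiles` object.
#' @return Numeric matrix (samples x fatty acids) with `sample_id` rownames.
#' @export
fa_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, fa_labels(x), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' Metadata view of a profile set
#' @param x An `fa_profiles` object.
#' @return Tibble of the metadata columns only.
#' @export
fa_meta <- function(x) {
  tibble::as_tibble(as.data.frame(x)[, intersect(META_COLS, names(x)), drop = FALSE])
}

#' Subset profiles to selected fatty acids
#'
#' Restricts every profile to the requested labels. Labels absent from the
#' set are included as 0% columns (absent fatty acid = not detected). With
#' `renormalize = TRUE` each row is rescaled to sum exactly 100 over the
#' retained labels, e.g. to re-express a profile as percent of total PUFA.
#'
#' @param x An `fa_profiles` object.
#' @param labels Character vector of fatty-acid labels to keep.
#' @param renormalize Rescale retained proportions to sum 100 per sample.
#' @return An `fa_profiles` object over exactly `labels`.
#' @export
subset_fas <- function(x, labels, renormalize = FALSE) {
  stopifnot(inherits(x, "fa_profiles"), length(labels) > 0)
  labels <- canonicalize_fa_label(labels)
  parse_fatty_acid(labels)
  df <- tibble::as_tibble(as.data.frame(x))
  for (lab in setdiff(labels, fa_labels(x))) df[[lab]] <- 0
  meta <- intersect(META_COLS, names(df))
  out <- df[c(meta, labels)]
  m <- as.matrix(out[labels])
  if (renormalize) {
    rs <- rowSums(m)
    if (any(rs == 0)) {
      stop("cannot renormalize: sample(s) with no mass on the retained labels: ",
           paste(sQuote(out$sample_id[rs == 0]), collapse = ", "), call. = FALSE)
    }
    out[labels] <- as.data.frame(100 * m / rs)
  }
  attr(out, "fa_labels") <- labels
  class(out) <- c("fa_profiles", class(out))
  out
}

#' Labels of a given saturation class within a profile set
#'
#' @param x An `fa_profiles` object or a character vector of labels.
#' @param class One of `"SFA"`, `"MUFA"`, `"PUFA"`.
#' @return Character vector of matching labels.
#' @export
fa_labels_of_class <- function(x, class = c("PUFA", "MUFA", "SFA")) {
  class <- match.arg(class)
  labs <- if (inherits(x, "fa_profiles")) fa_labels(x) else canonicalize_fa_label(x)
  labs[parse_fatty_acid(labs)$class == class]
}

#' @export
print.fa_profiles <- function(x, ...) {
  cat("<fa_profiles> ", nrow(x), " sample(s), ", length(fa_labels(x)),
      " fatty acid(s)\n", sep = "")
  NextMethod()
}

#' Combine profile sets
#'
#' Row-binds several `fa_profiles` objects over the union of their
#' fatty-acid labels (absent fatty acids filled with 0) and metadata
#' columns (filled with `NA`).
#'
#' @param ... `fa_profiles` objects.
#' @return An `fa_profiles` object.
#' @export
bind_profiles <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, logical(1), "fa_profiles")))
  labels <- Reduce(union, lapply(xs, fa_labels))
  meta <- Reduce(union, lapply(xs, function(x) intersect(META_COLS, names(x))))
  dfs <- lapply(xs, function(x) {
    df <- tibble::as_tibble(as.data.frame(subset_fas(x, labels)))
    for (col in setdiff(meta, names(df))) {
      df[[col]] <- if (col == "depth_m") NA_real_ else NA_character_
    }
    df[c(meta, labels)]
  })
  fa_profiles(do.call(rbind, dfs))
}

#' Convert GC-FID peak areas to fatty-acid mass per dry tissue
#'
#' Applies the standard-curve conversion: each fatty acid's mass is its peak
#' area divided by the calibration slope (area per microgram), scaled by the
#' hexane volume the methyl esters were dissolved in and normalised by the
#' dry tissue mass. Masses are in micrograms per milligram dry tissue.
#'
#' @param peak_areas Named numeric vector of peak areas (detector units),
#'   names being fatty-acid labels.
#' @param slope Calibration slope (peak area per microgram), from the
#'   fatty-acid standard curve; must be positive.
#' @param hexane_volume_ml Volume of hexane the sample was dissolved in (mL).
#' @param tissue_mass_mg Dry tissue mass (mg).
#' @return List with `mass` (named vector, ug per mg dry tissue) and
#'   `total_mass` (their sum).
#' @examples
#' mass_from_peaks(c("16:0" = 5000, "18:0" = 2500),
#'                 slope = 100, hexane_volume_ml = 1, tissue_mass_mg = 5)
#' @export
mass_from_peaks <- function(peak_areas, slope, hexane_volume_ml, tissue_mass_mg) {
  stopifnot(is.numeric(peak_areas), !is.null(names(peak_areas)))
  if (!is.numeric(slope) || length(slope) != 1L || slope <= 0) {
    stop("slope must be a single positive number", call. = FALSE)
  }
  if (hexane_volume_ml <= 0) stop("hexane_volume_ml must be positive", call. = FALSE)
  if (tissue_mass_mg <= 0) stop("tissue_mass_mg must be positive", call. = FALSE)
  if (any(peak_areas < 0)) stop("peak areas must be non-negative", call. = FALSE)
  names(peak_areas) <- canonicalize_fa_label(names(peak_areas))
  mass <- (peak_areas / slope) * hexane_volume_ml / tissue_mass_mg
  list(mass = mass, total_mass = sum(mass))
}
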
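# Compositional simulation: every generated profile satisfies the
# fa_profiles contract (non-negative, rows summing to 100).

# Dirichlet draws parameterised by mean (proportions summing to 1) and a
# concentration (larger = tighter around the mean). Components with zero
# mean stay exactly zero.
rdirichlet_mean <- function(n, mean, concentration) {
  stopifnot(concentration > 0, all(mean >= 0))
  mean <- mean / sum(mean)
  k <- length(mean)
  x <- matrix(0, n, k, dimnames = list(NULL, names(mean)))
  pos <- mean > 0
  if (is.infinite(concentration)) {
    x[, pos] <- matrix(mean[pos], n, sum(pos), byrow = TRUE)
    return(x)
  }
  g <- matrix(stats::rgamma(n * sum(pos), shape = mean[pos] * concentration),
              n, sum(pos), byrow = TRUE)
  x[, pos] <- g / rowSums(g)
  x
}

#' Specify a PUFA (or total fatty-acid) source group
#'
#' A source group is defined by its mean composition and a within-group
#' dispersion: samples are drawn from a Dirichlet distribution with that
#' mean, scaled by `concentration` (larger values give tighter groups;
#' `Inf` collapses the group onto its mean).
#'
#' @param name Group name, e.g. `"diatom"` or `"copepod"`.
#' @param mean_composition Named numeric vector of percent proportions
#'   (renormalized to sum 100).
#' @param concentration Positive Dirichlet concentration.
#' @return A `source_spec` list.
#' @export
source_spec <- function(name, mean_composition, concentration = 200) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(mean_composition), !is.null(names(mean_composition)))
  if (any(mean_composition < 0)) stop("mean_composition must be non-negative", call. = FALSE)
  if (sum(mean_composition) <= 0) stop("mean_composition must have positive total", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be positive", call. = FALSE)
  }
  names(mean_composition) <- canonicalize_fa_label(names(mean_composition))
  structure(list(name = name,
                 mean_composition = 100 * mean_composition / sum(mean_composition),
                 concentration = concentration),
            class = "source_spec")
}

spec_label_union <- function(specs) {
  Reduce(union, lapply(specs, function(s) names(s$mean_composition)))
}

spec_mean_vector <- function(spec, labels) {
  m <- stats::setNames(numeric(length(labels)), labels)
  m[names(spec$mean_composition)] <- spec$mean_composition
  m
}

#' Simulate samples from source groups
#'
#' Draws `n_per_source` compositional samples from each group's Dirichlet
#' distribution. Used to emulate literature libraries of plankton and
#' symbiont fatty-acid profiles.
#'
#' @param specs List of [source_spec()] objects.
#' @param n_per_source Integer, or named integer vector (one entry per
#'   group); at least 2 per group.
#' @param seed Integer seed for reproducibility.
#' @param tissue Tissue label attached to the samples (default `"source"`).
#' @return An `fa_profiles` object with `source_group` set per sample.
#' @export
simulate_sources <- function(specs, n_per_source, seed = NULL, tissue = "source") {
  stopifnot(length(specs) >= 1L)
  if (inherits(specs, "source_spec")) specs <- list(specs)
  nms <- vapply(specs, `[[`, character(1), "name")
  if (length(n_per_source) == 1L && is.null(names(n_per_source))) {
    n_per_source <- stats::setNames(rep(as.integer(n_per_source), length(nms)), nms)
  }
  if (any(n_per_source[nms] < 2L)) stop("need n >= 2 per source group", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- spec_label_union(specs)
  rows <- lapply(specs, function(s) {
    n <- n_per_source[[s$name]]
    x <- 100 * rdirichlet_mean(n, spec_mean_vector(s, labels) / 100, s$concentration)
    df <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
    tibble::add_column(df,
      sample_id = sprintf("%s_%02d", s$name, seq_len(n)),
      species = s$name, tissue = tissue, depth_m = NA_real_,
      source_group = s$name, .before = 1)
  })
  fa_profiles(do.call(rbind, rows), renormalize = TRUE)
}

#' Simulate host samples as noisy convex mixtures of source compositions
#'
#' Each host profile is drawn around the convex combination of the source
#' mean compositions with the given weights. With
#' `noise_concentration = Inf` every host equals the mixed mean exactly.
#'
#' @param specs List of [source_spec()] objects.
#' @param weights Named numeric vector of mixture weights over the source
#'   names; non-negative, summing to 1.
#' @param n_samples Number of host samples.
#' @param noise_concentration Dirichlet concentration of the compositional
#'   noise around the mixed mean.
#' @param seed Integer seed.
#' @param species Species label for the generated hosts.
#' @return List with `profiles` (an `fa_profiles` of hosts) and
#'   `true_weights` (the estimand, for recovery tests).
#' @export
simulate_host_mixture <- function(specs, weights, n_samples = 10,
                                  noise_concentration = 500, seed = NULL,
                                  species = "host_mix") {
  nms <- vapply(specs, `[[`, character(1), "name")
  if (!setequal(names(weights), nms)) {
    stop("weights must be named by the source names", call. = FALSE)
  }
  weights <- weights[nms]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  labels <- spec_label_union(specs)
  means <- vapply(specs, spec_mean_vector, numeric(length(labels)), labels = labels)
  mixed <- drop(means %*% weights)  # percent scale
  x <- 100 * rdirichlet_mean(n_samples, mixed / 100, noise_concentration)
  df <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
  df <- tibble::add_column(df,
    sample_id = sprintf("%s_%02d", species, seq_len(n_samples)),
    species = species, tissue = "host", depth_m = NA_real_,
    source_group = NA_character_, .before = 1)
  list(profiles = fa_profiles(df, renormalize = TRUE), true_weights = weights)
}

#' Simulate host samples with known source membership
#'
#' Each host sample is drawn from one source group's distribution, with a
#' fixed number of hosts per source. The estimand recovered by
#' [bootstrap_attribution()] is the membership fraction `counts / sum(counts)`.
#'
#' @param specs List of [source_spec()] objects.
#' @param counts Named integer vector: hosts drawn from each source.
#' @param seed Integer seed.
#' @param species Species label for the hosts.
#' @return List with `profiles` (hosts, in source order then index order)
#'   and `true_fractions` (named, summing to 1).
#' @export
simulate_host_membership <- function(specs, counts, seed = NULL,
                                     species = "host_mem") {
  nms <- vapply(specs, `[[`, character(1), "name")
  if (!setequal(names(counts), nms)) stop("counts must be named by the source names", call. = FALSE)
  counts <- counts[nms]
  if (!is.null(seed)) set.seed(seed)
  labels <- spec_label_union(specs)
  rows <- mapply(function(s, n) {
    if (n == 0L) return(NULL)
    100 * rdirichlet_mean(n, spec_mean_vector(s, labels) / 100, s$concentration)
  }, specs, counts, SIMPLIFY = FALSE)
  x <- do.call(rbind, rows)
  df <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
  df <- tibble::add_column(df,
    sample_id = sprintf("%s_%02d", species, seq_len(nrow(x))),
    species = species, tissue = "host", depth_m = NA_real_,
    source_group = NA_character_, .before = 1)
  list(profiles = fa_profiles(df, renormalize = TRUE),
       true_fractions = counts / sum(counts))
}

#' Build a crossed species x tissue x depth cell table
#'
#' Helper for [simulate_factorial()]: one row per factor-level combination,
#' all cells sharing `mean` (a null design). Modify the `mean` list-column
#' afterwards (e.g. with [shift_composition()]) to introduce effects.
#'
#' @param mean Named numeric vector, the shared cell mean composition.
#' @param species,tissues,depths Factor levels to cross.
#' @return Tibble with columns `species`, `tissue`, `depth_m`, `mean`.
#' @export
crossed_cells <- function(mean, species = c("sp1", "sp2"),
                          tissues = c("host", "symbiont"), depths = c(10, 30)) {
  g <- expand.grid(species = species, tissue = tissues, depth_m = depths,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- tibble::as_tibble(g)
  g$mean <- rep(list(mean), nrow(g))
  g
}

#' Shift a composition toward selected fatty acids
#'
#' Adds `amount` percentage points to each of the named labels and
#' renormalizes to 100, producing a controlled effect for power tests.
#'
#' @param mean Named numeric composition (percent).
#' @param toward Labels to enrich.
#' @param amount Percentage points added to each.
#' @return Named numeric composition summing to 100.
#' @export
shift_composition <- function(mean, toward, amount) {
  stopifnot(all(toward %in% names(mean)))
  mean[toward] <- mean[toward] + amount
  100 * mean / sum(mean)
}

#' Simulate a crossed factorial fatty-acid dataset
#'
#' Draws `n_per_cell` samples per cell from a Dirichlet distribution around
#' each cell's mean composition, labelling samples with the crossed factors.
#' With identical cell means the design is null: downstream permutation
#' p-values are uniform.
#'
#' @param cells Tibble as produced by [crossed_cells()]: columns `species`,
#'   `tissue`, `depth_m` and a list-column `mean` of named compositions.
#' @param n_per_cell Samples per cell (>= 2).
#' @param concentration Dirichlet concentration shared by all cells.
#' @param seed Integer seed.
#' @return An `fa_profiles` object with `sum(n_per_cell)` rows.
#' @export
simulate_factorial <- function(cells, n_per_cell = 10, concentration = 200,
                               seed = NULL) {
  stopifnot(nrow(cells) >= 2L, all(c("species", "tissue", "mean") %in% names(cells)))
  if (n_per_cell < 2L) stop("need n_per_cell >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- Reduce(union, lapply(cells$mean, names))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    m <- stats::setNames(numeric(length(labels)), labels)
    m[names(cells$mean[[i]])] <- cells$mean[[i]]
    x <- 100 * rdirichlet_mean(n_per_cell, m / sum(m), concentration)
    df <- tibble::as_tibble(as.data.frame(x, check.names = FALSE))
    depth <- if ("depth_m" %in% names(cells)) cells$depth_m[i] else NA_real_
    tibble::add_column(df,
      sample_id = sprintf("%s_%s_%sm_%02d", cells$species[i], cells$tissue[i],
                          ifelse(is.na(depth), "na", depth), seq_len(n_per_cell)),
      species = cells$species[i], tissue = cells$tissue[i],
      depth_m = depth, source_group = NA_character_, .before = 1)
  })
  fa_profiles(do.call(rbind, rows), renormalize = TRUE)
}

# ---- study-shaped defaults -------------------------------------------------

# The 12 PUFA measured in coral tissue, plus 18:5n-3 which occurs in some
# phytoplankton and symbionts but not in coral hosts.
PUFA_12 <- c("18:2n-6", "18:3n-3", "18:3n-6", "18:4n-3", "20:2n-6", "20:3n-6",
             "20:4n-3", "20:4n-6", "20:5n-3", "22:4n-6", "22:5n-3", "22:6n-3")
LC_MUFA <- c("20:1n-11", "20:1n-9", "20:1n-7", "22:1n-11", "22:1n-9", "22:1n-7")

#' Example PUFA source library specifications
#'
#' Five candidate diet source groups with mean PUFA compositions loosely
#' patterned on published group signatures: diatoms rich in 20:5n-3 (EPA),
#' dinoflagellates in 22:6n-3 (DHA) and 18:4n-3 with some 18:5n-3,
#' cryptophytes in 18:3n-3 and 18:4n-3, cyanobacteria in 18:2n-6 and
#' 18:3n-6, copepods in 22:6n-3 and 20:5n-3. Plus a per-species symbiont
#' group rich in 18:3n-6 and 18:4n-3. These are synthetic fixtures for
#' exercising the attribution machinery, not literature data.
#'
#' @param concentration Dirichlet concentration for all groups.
#' @return Named list of [source_spec()] objects.
#' @export
example_source_specs <- function(concentration = 150) {
  mk <- function(name, v) source_spec(name, v, concentration)
  pufa8 <- c("18:2n-6", "18:3n-3", "18:3n-6", "18:4n-3", "18:5n-3",
             "20:4n-6", "20:5n-3", "22:6n-3")
  comp <- function(...) stats::setNames(c(...), pufa8)
  list(
    diatom         = mk("diatom",         comp( 3,  1,  2,  6,  0,  4, 60, 24)),
    dinoflagellate = mk("dinoflagellate", comp( 4,  2,  3, 18,  8,  3, 17, 45)),
    cryptophyte    = mk("cryptophyte",    comp( 8, 30,  3, 26,  0,  2, 19, 12)),
    cyanobacteria  = mk("cyanobacteria",  comp(42, 18, 22,  6,  0,  4,  6,  2)),
    copepod        = mk("copepod",        comp( 4,  2,  1,  5,  0,  5, 33, 50))
  )
}

#' Example symbiont source specification
#'
#' Host-associated Symbiodiniaceae PUFA signature used alongside
#' [example_source_specs()]: rich in 18:3n-6 and 18:4n-3 with substantial
#' 22:6n-3, and carrying some 18:5n-3. Synthetic fixture.
#'
#' @param species Host species the symbionts are associated with.
#' @param concentration Dirichlet concentration.
#' @return A [source_spec()].
#' @export
example_symbiont_spec <- function(species = "symbiont", concentration = 150) {
  pufa8 <- c("18:2n-6", "18:3n-3", "18:3n-6", "18:4n-3", "18:5n-3",
             "20:4n-6", "20:5n-3", "22:6n-3")
  source_spec(species, stats::setNames(c(9, 1, 24, 22, 5, 6, 8, 25), pufa8),
              concentration)
}

#' Baseline host and symbiont mean compositions
#'
#' The 24-fatty-acid mean compositions (percent of total) from which
#' [study_cells()] derives its cell means: a coral host fraction
#' (SFA-dominated, moderate PUFA) and a symbiont fraction (enriched in
#' 16:1n-7, 18:3n-6, 18:4n-3 and 22:6n-3, depleted in long-chain MUFA).
#' Useful as starting points for custom designs via [shift_composition()]
#' and [crossed_cells()]. Purely synthetic fixtures.
#'
#' @return Named numeric vector of mean percent proportions.
#' @export
study_base_host <- function() {
  c("14:0" = 2, "16:0" = 33, "18:0" = 25,
    "16:1n-7" = 2, "18:1n-7" = 2, "18:1n-9" = 4,
    "20:1n-11" = 0.3, "20:1n-9" = 1, "20:1n-7" = 0.3,
    "22:1n-11" = 0.5, "22:1n-9" = 0.2, "22:1n-7" = 0.2,
    "18:2n-6" = 1.5, "18:3n-3" = 0, "18:3n-6" = 1, "18:4n-3" = 1.5,
    "20:2n-6" = 0.5, "20:3n-6" = 0.5, "20:4n-3" = 1, "20:4n-6" = 5,
    "20:5n-3" = 6, "22:4n-6" = 6, "22:5n-3" = 2, "22:6n-3" = 5)
}

#' @rdname study_base_host
#' @export
study_base_symbiont <- function() {
  c("14:0" = 3, "16:0" = 38, "18:0" = 8,
    "16:1n-7" = 5, "18:1n-7" = 3, "18:1n-9" = 3,
    "20:1n-11" = 0.05, "20:1n-9" = 0.2, "20:1n-7" = 0.05,
    "22:1n-11" = 0.1, "22:1n-9" = 0.05, "22:1n-7" = 0.05,
    "18:2n-6" = 3, "18:3n-3" = 0.1, "18:3n-6" = 6, "18:4n-3" = 6,
    "20:2n-6" = 0.3, "20:3n-6" = 0.5, "20:4n-3" = 1, "20:4n-6" = 3,
    "20:5n-3" = 7, "22:4n-6" = 2, "22:5n-3" = 1, "22:6n-3" = 10)
}

#' Cell means for a study-shaped coral dataset
#'
#' A 3 species x 2 tissues x 2 depths crossed design whose cell means
#' reproduce the qualitative host/symbiont and between-species contrasts the
#' analysis is designed to detect: one species ("heterotroph") enriched in
#' long-chain MUFA and 22:5n-3 with a low 18:1n-7/18:1n-9 ratio, one
#' ("autotroph") with the opposite pattern, one ("mixotroph") intermediate;
#' depth has no effect on the means. Purely synthetic.
#'
#' @return Tibble accepted by [simulate_factorial()].
#' @export
study_cells <- function() {
  host <- study_base_host(); symb <- study_base_symbiont()
  mean_for <- function(species, tissue) {
    m <- if (tissue == "host") host else symb
    if (species == "heterotroph") {
      m <- shift_composition(m, c("20:1n-9", "22:1n-11", "20:1n-11"),
                             if (tissue == "host") 1.2 else 0.3)
      m <- shift_composition(m, "18:1n-9", 1.5)
      m <- shift_composition(m, "22:5n-3", if (tissue == "host") 1 else 0.2)
    } else if (species == "autotroph") {
      m <- shift_composition(m, c("18:1n-7", "16:1n-7"), 1.5)
      m <- shift_composition(m, "18:3n-6", if (tissue == "host") 0.8 else 2)
    }
    m
  }
  cells <- crossed_cells(host, species = c("mixotroph", "autotroph", "heterotroph"))
  cells$mean <- mapply(mean_for, cells$species, cells$tissue, SIMPLIFY = FALSE)
  cells
}

#' Simulate a full study-shaped dataset
#'
#' Convenience wrapper: [simulate_factorial()] over [study_cells()] with
#' n = 10 per species/tissue/depth cell, giving 60 host and 60 symbiont
#' samples across the two depths. Host and symbiont samples from the same
#' cell index share a colony identifier.
#'
#' @param seed Integer seed.
#' @param n_per_cell Samples per species/tissue/depth cell (default 10).
#' @param concentration Dirichlet concentration (within-cell dispersion).
#' @return An `fa_profiles` object with a `colony` column.
#' @export
simulate_study <- function(seed = NULL, n_per_cell = 10, concentration = 400) {
  x <- simulate_factorial(study_cells(), n_per_cell = n_per_cell,
                          concentration = concentration, seed = seed)
  df <- tibble::as_tibble(as.data.frame(x))
  df$colony <- sprintf("%s_%sm_%02d", df$species,
                       df$depth_m, as.integer(sub(".*_", "", df$sample_id)))
  df$sample_id <- paste0(df$colony, "_", df$tissue)
  fa_profiles(df, renormalize = TRUE)
}
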
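test_that("two symmetric 1-D classes put the decision boundary at the midpoint", {
  x <- matrix(c(-1, 0, 1, 1, 2, 3), ncol = 1)
  core <- fatrophic:::fit_lda_core(x, rep(c("lo", "hi"), each = 3), ridge = 0)
  cls <- fatrophic:::classify_core(core, matrix(c(0.9, 1.1), ncol = 1))$class
  expect_equal(cls, c("lo", "hi"))
  # exactly at the boundary: lexicographic tie-break
  post <- fatrophic:::classify_core(core, matrix(1, ncol = 1))$posterior
  expect_equal(unname(post[1, ]), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("classification equals the brute-force pooled-covariance Bayes rule", {
  set.seed(81)
  for (rep in 1:20) {
    k <- 3; d <- 5; n <- 12
    mus <- matrix(rnorm(k * d, sd = 2), k)
    train <- do.call(rbind, lapply(1:k, function(g) {
      sweep(matrix(rnorm(n * d), n), 2, mus[g, ], `+`)
    }))
    g <- rep(paste0("g", 1:k), each = n)
    test <- matrix(rnorm(10 * d), 10)
    colnames(train) <- colnames(test) <- paste0("v", 1:d)
    core <- fatrophic:::fit_lda_core(train, g)
    mine <- fatrophic:::classify_core(core, test)$class
    expect_identical(mine, oracle_bayes_labels(train, g, test))
  }
})

test_that("hard labels agree with an independent reference LDA implementation", {
  skip_if_not_installed("MASS")
  set.seed(83)
  for (rep in 1:20) {
    k <- 3; d <- 4; n <- 15
    mus <- matrix(rnorm(k * d, sd = 1.5), k)
    train <- do.call(rbind, lapply(1:k, function(g) {
      sweep(matrix(rnorm(n * d), n), 2, mus[g, ], `+`)
    }))
    g <- rep(paste0("g", 1:k), each = n)
    probe <- matrix(rnorm(20 * d), 20)
    core <- fatrophic:::fit_lda_core(train, g, ridge = 0)
    mine <- fatrophic:::classify_core(core, probe)$class
    ref <- MASS::lda(train, grouping = g, prior = rep(1 / k, k))
    theirs <- as.character(stats::predict(ref, probe)$class)
    expect_identical(mine, theirs)
  }
})

test_that("classifying at a class mean returns that class with posterior near 1", {
  lib <- simulate_separated_library(seed = 85, concentration = 500)
  model <- fit_lda(lib)
  means <- model$means
  res <- classify(model, means)
  expect_identical(res$class, rownames(means))
  expect_true(all(diag(res$posterior[, rownames(means)]) > 0.99))
  expect_equal(unname(rowSums(res$posterior)), rep(1, nrow(means)),
               tolerance = 1e-12)
  expect_error(classify(model, means[, 1:3]), "dimension mismatch")
})

test_that("LOOCV rates and confusion matrix satisfy the accounting identities", {
  lib <- simulate_separated_library(seed = 87)
  rep <- loocv(lib)
  expect_true(all(rep$rates >= 0 & rep$rates <= 1))
  expect_equal(unname(rowSums(rep$confusion)), unname(rep$n))
  expect_equal(unname(diag(rep$confusion) / rowSums(rep$confusion)),
               unname(rep$rates))
  # widely separated tight clusters classify perfectly
  expect_true(all(rep$rates == 1))
})

test_that("two groups drawn from one distribution cross-validate near chance", {
  set.seed(89)
  rates <- replicate(10, {
    sp <- example_source_specs()$diatom
    x <- simulate_sources(list(source_spec("a", sp$mean_composition, 100),
                               source_spec("b", sp$mean_composition, 100)),
                          n_per_source = 12)
    mean(loocv(source_library(x))$rates)
  })
  expect_gt(mean(rates), 0.25)
  expect_lt(mean(rates), 0.75)
})

test_that("pruning removes inseparable sources and keeps separable ones", {
  sp <- example_source_specs()
  # "shadow" is drawn from the diatom distribution: inseparable by design
  specs <- list(sp$diatom, sp$copepod, example_symbiont_spec("symbiont"),
                source_spec("shadow", sp$diatom$mean_composition, 150))
  for (seed in 1:3) {
    lib <- source_library(simulate_sources(specs, n_per_source = 12, seed = seed))
    rep <- loocv(lib)
    expect_lt(min(rep$rates[c("diatom", "shadow")]), 0.85)
    pruned <- suppressMessages(prune_sources(lib, report = rep))
    expect_false("shadow" %in% levels(pruned$group) &&
                   "diatom" %in% levels(pruned$group))
    expect_true(all(c("copepod", "symbiont") %in% levels(pruned$group)))
  }

  # all rates above threshold: library unchanged
  lib2 <- simulate_separated_library(seed = 91)
  pruned2 <- prune_sources(lib2)
  expect_identical(levels(pruned2$group), levels(lib2$group))
  expect_identical(attr(pruned2, "dropped"), character(0))
})

test_that("PUFA absent from all sources are dropped from sources and hosts", {
  specs <- separated_specs()
  # none of these three sources carries 18:5n-3? diatom/copepod lack it, the
  # symbiont spec has it -- so build a library from the two that lack it
  lib <- source_library(simulate_sources(specs[1:2], n_per_source = 8, seed = 93))
  hosts <- simulate_host_membership(specs[1:2], c(diatom = 3, copepod = 3),
                                    seed = 94)$profiles
  expect_true("18:5n-3" %in% lib$labels)
  expect_true(all(lib$x[, "18:5n-3"] == 0))
  expect_message(out <- drop_unshared_pufa(lib, hosts), "18:5n-3")
  expect_false("18:5n-3" %in% out$library$labels)
  expect_false("18:5n-3" %in% fa_labels(out$hosts))
  expect_identical(out$dropped, "18:5n-3")

  # no all-zero PUFA: identity
  lib2 <- out$library
  out2 <- drop_unshared_pufa(lib2)
  expect_identical(out2$library$labels, lib2$labels)
  expect_identical(out2$dropped, character(0))
})

test_that("bootstrap attribution is reproducible, closed, and order-invariant", {
  specs <- separated_specs()
  lib <- simulate_separated_library(seed = 95)
  hosts <- simulate_host_membership(
    specs, c(diatom = 6, copepod = 3, symbiont = 1), seed = 96)$profiles
  cd1 <- bootstrap_attribution(lib, hosts, n_iter = 200, seed = 7)
  cd2 <- bootstrap_attribution(lib, hosts, n_iter = 200, seed = 7)
  expect_identical(cd1$draws, cd2$draws)

  # per-iteration fractions are multiples of 1/n_hosts and sum to 1
  m <- cd1$draws[[1]]
  expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-12)
  expect_true(all(abs(m * 10 - round(m * 10)) < 1e-9))

  # shuffling host order leaves the distribution untouched
  perm <- sample(nrow(hosts))
  hosts_shuffled <- fa_profiles(as.data.frame(hosts)[perm, ])
  cd3 <- bootstrap_attribution(lib, hosts_shuffled, n_iter = 200, seed = 7)
  expect_equal(cd1$summary, cd3$summary, tolerance = 1e-12)

  # summaries lie inside [0, 1]
  expect_true(all(cd1$summary$ci_lower >= 0 & cd1$summary$ci_upper <= 1))
  expect_warning(bootstrap_attribution(lib, hosts, n_iter = 50, seed = 1),
                 "unstable")
})

test_that("hosts at a tight source mean are attributed entirely to that source", {
  specs <- separated_specs(concentration = 2000)
  lib <- simulate_separated_library(seed = 97, concentration = 2000)
  hosts <- simulate_host_mixture(
    specs, c(diatom = 1, copepod = 0, symbiont = 0),
    n_samples = 8, noise_concentration = Inf, seed = 98)$profiles
  cd <- bootstrap_attribution(lib, hosts, n_iter = 300, seed = 9)
  s <- cd$summary[cd$summary$source == "diatom", ]
  expect_gt(s$mean, 0.99)
  expect_gt(s$ci_lower, 0.5)
})

test_that("category aggregation preserves closure and totals", {
  specs <- separated_specs()
  lib <- simulate_separated_library(seed = 99)
  hosts <- simulate_host_membership(
    specs, c(diatom = 5, copepod = 3, symbiont = 2), seed = 100)$profiles
  cd <- bootstrap_attribution(lib, hosts, n_iter = 200, seed = 11)

  agg <- aggregate_contributions(
    cd, c(diatom = "particulate", copepod = "particulate", symbiont = "symbiont"))
  by_sp <- split(agg, agg$species)
  for (s in by_sp) expect_equal(sum(s$mean), 1, tolerance = 1e-12)

  # single-category mapping: the interval collapses to [1, 1]
  agg1 <- aggregate_contributions(
    cd, c(diatom = "all", copepod = "all", symbiont = "all"))
  expect_equal(agg1$ci_lower, 1, tolerance = 1e-12)
  expect_equal(agg1$ci_upper, 1, tolerance = 1e-12)

  expect_error(aggregate_contributions(cd, c(diatom = "particulate")),
               "unmapped")
})
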
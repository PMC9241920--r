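test_that("simulated phylogenies are ultrametric with the requested tips", {
  tree <- simulate_phylogeny(20, seed = 1)
  expect_s3_class(tree, "phylo")
  expect_length(tree$tip.label, 20)
  expect_true(ape::is.ultrametric(tree, tol = 1e-8))
  expect_true(all(tree$edge.length >= 0))
  expect_identical(ape::write.tree(simulate_phylogeny(50, seed = 3)),
                   ape::write.tree(simulate_phylogeny(50, seed = 3)))
  # two tips: forced cherry, patristic distance = twice the root height
  two <- simulate_phylogeny(2, seed = 5)
  d <- ape::cophenetic.phylo(two)
  expect_equal(d[1, 2], 2 * max(ape::node.depth.edgelength(two)))
  expect_error(simulate_phylogeny(1), ">= 2")
  expect_error(simulate_phylogeny(5, birth_rate = 1, death_rate = 2))
})

test_that("Brownian optima have the expected moments", {
  tree <- driftnet:::scale_tree_height(simulate_phylogeny(10, seed = 2))
  expect_equal(unname(evolve_optima(tree, 0, root_value = 1.5)),
               rep(1.5, 10))
  # marginal variance of a tip optimum ~ rate * root-to-tip depth (= 1)
  reps <- vapply(1:300, function(s)
    evolve_optima(tree, brownian_rate = 4, seed = s)[1], numeric(1))
  expect_lt(abs(var(reps) - 4), 0.8)
  # sibling covariance ~ rate * shared path length
  cherry <- tree_from_text("((A:0.1,B:0.1):0.9,C:1);")
  pairs <- vapply(1:300, function(s) {
    o <- evolve_optima(cherry, brownian_rate = 1, seed = 1000 + s)
    c(o["A"], o["B"])
  }, numeric(2))
  expect_lt(abs(cov(pairs[1, ], pairs[2, ]) - 0.9), 0.25)
  # early-burst variant stays zero-mean with reduced late variance
  eb <- vapply(1:300, function(s)
    evolve_optima(tree, brownian_rate = 4, eb_decay = 6, seed = s)[1],
    numeric(1))
  expect_lt(var(eb), var(reps))
})

test_that("environment tables honour spreads and seeds", {
  e0 <- generate_environments(8, n_seasons = 2, season_spreads = 0, seed = 1)
  expect_equal(nrow(e0), 16)
  expect_equal(max(tapply(e0$temperature, e0$season, sd)), 0)

  e1 <- generate_environments(10, 1, season_means = 0, season_spreads = 1,
                              seed = 4)
  e2 <- generate_environments(10, 1, season_means = 0, season_spreads = 2,
                              seed = 4)
  d1 <- mean(dist(e1$temperature))
  d2 <- mean(dist(e2$temperature))
  expect_equal(d2, 2 * d1)   # same seed: distances scale exactly

  expect_identical(generate_environments(5, 4, seed = 9),
                   generate_environments(5, 4, seed = 9))
  expect_error(generate_environments(5, 2, season_spreads = -1))
})

test_that("metacommunity assembly conserves community size", {
  tree <- driftnet:::scale_tree_height(simulate_phylogeny(30, seed = 3))
  optima <- evolve_optima(tree, 4, seed = 4)
  env <- generate_environments(6, 1, 0, 1, seed = 5)
  sim <- assemble_metacommunity(tree, optima, env, community_size = 200,
                                filter_width = 1, drift_generations = 3,
                                seed = 6)
  expect_equal(unname(rowSums(sim$otu)), rep(200, 6))
  expect_identical(colnames(sim$otu), tree$tip.label)

  # lottery sampling also conserves J
  lot <- assemble_metacommunity(tree, optima, env, community_size = 200,
                                lottery_concentration = 10, seed = 6)
  expect_equal(unname(rowSums(lot$otu)), rep(200, 6))
})

test_that("no filtering approximates multinomial sampling from the pool", {
  tree <- driftnet:::scale_tree_height(simulate_phylogeny(20, seed = 7))
  optima <- evolve_optima(tree, 4, seed = 8)
  env <- generate_environments(30, 1, 0, 5, seed = 9)  # divergent E, ignored
  pool <- rep(1 / 20, 20)
  sim <- assemble_metacommunity(tree, optima, env, community_size = 500,
                                filter_width = Inf, pool_abundance = pool,
                                seed = 10)
  freq <- colMeans(sim$otu) / 500
  expect_lt(max(abs(freq - 1 / 20)), 0.015)
})

test_that("strong filtering across divergent environments separates communities", {
  tree <- driftnet:::scale_tree_height(simulate_phylogeny(40, seed = 11))
  optima <- evolve_optima(tree, 9, seed = 12)
  env <- data.frame(temperature = c(min(optima), max(optima)),
                    row.names = c("cold", "hot"))
  sim <- assemble_metacommunity(tree, optima, env, community_size = 500,
                                filter_width = 0.2, seed = 13)
  bc <- bray_curtis(sim$otu)
  expect_gt(bc["cold", "hot"], 0.95)
})

test_that("prolonged drift fixates local communities", {
  tree <- tree_from_text("((A:1,B:1):1,(C:1,D:1):1);")
  optima <- setNames(rep(0, 4), c("A", "B", "C", "D"))
  env <- data.frame(temperature = 0, row.names = "x1")
  sim <- assemble_metacommunity(tree, optima, env, community_size = 50,
                                drift_generations = 200, seed = 3)
  expect_equal(sum(sim$otu > 0), 1L)   # one taxon left standing
  expect_equal(sum(sim$otu), 50L)
})

test_that("regime presets are reproducible and labelled", {
  a <- simulate_regime("drift", n_taxa = 40, n_sites = 4, seed = 2)
  b <- simulate_regime("drift", n_taxa = 40, n_sites = 4, seed = 2)
  expect_identical(a$otu, b$otu)
  expect_identical(a$true_regime, "drift")
  expect_equal(nrow(a$otu), 4)
})

test_that("compositional generator imposes the requested basis correlation", {
  sim <- simulate_compositional(20, 300, depth = 5000,
                                cor_pairs = data.frame(a = 1, b = 2,
                                                       rho = 0.8),
                                seed = 21)
  expect_lt(abs(cor(sim$basis[, 1], sim$basis[, 2]) - 0.8), 0.08)
  expect_equal(unname(rowSums(sim$counts)), rep(5000, 300))
  expect_equal(dim(sim$counts), c(300, 20))
})
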
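test_that("simulated geometry respects the separation rule and type coverage", {
  geo <- simulate_coordinates(523, seed = 12)
  expect_equal(nrow(geo$coordinates), 523)
  expect_equal(sort(unique(as.character(geo$labels))), LETTERS[1:4])
  expect_gte(min_pairwise_distance(geo$coordinates), 0.4 / sqrt(523))

  geo2 <- simulate_coordinates(523, seed = 12)
  expect_identical(geo, geo2)
  geo3 <- simulate_coordinates(523, seed = 13)
  expect_false(identical(geo$coordinates, geo3$coordinates))
})

test_that("the noiseless limit reproduces the planted linear model exactly", {
  sim <- simulate_spatial_dataset(n_cells = 120, genes_per_cluster = 25,
                                  alpha = 0, seed = 5)
  resid <- sim$dataset$expression - sim$truth$X_scored %*% sim$truth$W_true
  expect_lt(max(abs(resid)), 1e-12)
  expect_equal(sim$truth$vp, 1)
})

test_that("the default design plants four 500-gene clusters over four types", {
  sim <- simulate_spatial_dataset(seed = 2)
  expect_equal(dim(sim$dataset$expression), c(523, 2000))
  expect_equal(unname(table(sim$truth$cluster)), rep(500L, 4),
               ignore_attr = TRUE)
  expect_equal(rownames(sim$truth$W_true), LETTERS[1:4])
  # planted pattern: cluster 1 multi-input (A, C), 2 -> B, 3 -> C, 4 none
  tab <- default_coefficient_table(1)
  expect_equal(unname(tab[, 1]), c(1, 0, 1, 0))
  expect_equal(unname(tab[, 2]), c(0, 1, 0, 0))
  expect_equal(unname(tab[, 3]), c(0, 0, 1, 0))
  expect_equal(unname(tab[, 4]), c(0, 0, 0, 0))
  # no-effect genes have exactly zero model-term variance
  c4 <- names(sim$truth$cluster)[sim$truth$cluster == 4]
  expect_true(all(sim$truth$W_true[, c4] == 0))
})

test_that("realized noise matches the per-gene scale model", {
  sim <- simulate_spatial_dataset(n_cells = 600, genes_per_cluster = 50,
                                  alpha = 2, seed = 8)
  ratio <- apply(sim$truth$noise, 2, var) / sim$truth$sigma^2
  expect_lt(abs(mean(ratio) - 1), 0.1)

  simg <- simulate_spatial_dataset(n_cells = 200, genes_per_cluster = 30,
                                   noise = "gamma", seed = 8)
  expect_lt(max(abs(colMeans(simg$truth$noise))), 1e-10)
  expect_equal(unname(apply(simg$truth$noise, 2, sd)), rep(1, 120),
               tolerance = 1e-10)
  # log-gamma noise is left-skewed, unlike the symmetric Gaussian draw
  skew <- mean(apply(simg$truth$noise, 2, function(x) mean((x - mean(x))^3)))
  expect_lt(skew, -0.2)
})

test_that("VP agrees with the closed-form variance decomposition", {
  sim <- simulate_spatial_dataset(n_cells = 600, genes_per_cluster = 75,
                                  alpha = 1, seed = 21)
  affected <- colSums(sim$truth$W_true != 0) > 0
  v <- apply(sim$truth$X_scored %*% sim$truth$W_true[, affected], 2, var)
  closed <- mean(v / (v + sim$truth$alpha^2 * sim$truth$sigma[affected]^2))
  expect_lt(abs(sim$truth$vp - closed) / closed, 0.05)
})

test_that("VP rises with effect size and falls with noise", {
  vp_w <- vapply(c(0.5, 1, 2), function(w) {
    simulate_spatial_dataset(n_cells = 200, genes_per_cluster = 30,
                             w_max = w, alpha = 1, seed = 33)$truth$vp
  }, 0)
  expect_true(all(diff(vp_w) > 0))
  vp_a <- vapply(c(1, 2, 4), function(a) {
    simulate_spatial_dataset(n_cells = 200, genes_per_cluster = 30,
                             w_max = 1, alpha = a, seed = 33)$truth$vp
  }, 0)
  expect_true(all(diff(vp_a) < 0))
})

test_that("user-provided geometry is passed through unchanged", {
  geo <- simulate_coordinates(60, seed = 9)
  sim <- simulate_spatial_dataset(genes_per_cluster = 10, coords = geo$coordinates,
                                  labels = geo$labels, seed = 1)
  expect_equal(sim$dataset$coordinates, geo$coordinates,
               ignore_attr = TRUE)
  expect_equal(as.character(sim$dataset$labels), as.character(geo$labels))
})

test_that("the condition grid and simulation writer round-trip", {
  g <- simulation_grid()
  expect_equal(nrow(g), 9)
  expect_setequal(unique(g$w_max), c(1, 0.5, 0.1))
  expect_setequal(unique(g$alpha), c(1, 2, 4))

  sim <- simulate_spatial_dataset(n_cells = 40, genes_per_cluster = 5, seed = 4)
  dir <- withr::local_tempdir()
  save_simulation(sim, dir)
  truth <- read.delim(file.path(dir, "truth.tsv"), check.names = FALSE)
  expect_equal(truth$cluster, unname(sim$truth$cluster))
  expect_equal(as.matrix(truth[, LETTERS[1:4]]),
               t(sim$truth$W_true), ignore_attr = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "sim_meta.json"))
  expect_equal(meta$vp, sim$truth$vp)
  ds <- read_spatial_dataset(file.path(dir, "expression.csv"),
                             file.path(dir, "coordinates.csv"),
                             file.path(dir, "labels.csv"), scale = "processed")
  expect_equal(ds$expression, sim$dataset$expression)
})
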
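# one-trajectory table with supplied per-(replicate, generation) frequencies
traj_table <- function(freqs, gens, n_rep, coverage = 90, group = "A2C") {
  # freqs: L x (n_rep * length(gens)) matrix of true frequencies
  L <- nrow(freqs)
  grid <- expand.grid(replicate = seq_len(n_rep), generation = gens)
  samples <- data.frame(
    sample_id = paste0(group, "_r", grid$replicate, "_G", grid$generation),
    group = group, replicate = grid$replicate,
    generation = grid$generation,
    timepoint = paste0("G", grid$generation))
  minor <- matrix(0L, L, nrow(grid)); cov <- matrix(0L, L, nrow(grid))
  for (j in seq_len(nrow(grid))) {
    d <- pool_seq_sample(freqs[, j], 200, coverage)
    minor[, j] <- d$minor; cov[, j] <- d$coverage
  }
  toy_table(minor, cov, samples = samples)
}

test_that("delta_p pools counts within generations before differencing", {
  gens <- c(0, 65)
  samples <- data.frame(
    sample_id = paste0("A2C_r", rep(1:3, 2), "_G", rep(gens, each = 3)),
    group = "A2C", replicate = rep(1:3, 2),
    generation = rep(gens, each = 3), timepoint = rep(c("G0", "G65"), each = 3))
  minor <- matrix(c(5L, 10L, 15L, 20L, 20L, 20L), 1, 6)
  cov <- matrix(50L, 1, 6)
  tab <- toy_table(minor, cov, samples = samples)
  expect_equal(delta_p(tab), 60 / 150 - 30 / 150)
  expect_equal(delta_p(tab, replicates = 1), 20 / 50 - 5 / 50)
  # identical counts at both generations
  tab2 <- toy_table(matrix(10L, 1, 6), cov, samples = samples)
  expect_equal(delta_p(tab2), 0)
  expect_error(delta_p(tab, gen_last = 99), "generation 99 absent")
})

test_that("qb_generation_scan flags true slopes and stays quiet on
          constant loci", {
  set.seed(27)
  gens <- c(0, 30, 65); n_rep <- 10
  # 200 loci with logit slope 0.05/generation, 800 neutral
  L <- 1000
  slope <- c(rep(0.05, 200), rep(0, 800))
  f0 <- runif(L, 0.15, 0.35)
  grid <- expand.grid(replicate = seq_len(n_rep), generation = gens)
  freqs <- vapply(seq_len(nrow(grid)), function(j)
    plogis(qlogis(f0) + slope * grid$generation[j]), numeric(L))
  tab <- traj_table(freqs, gens, n_rep)
  scan <- qb_generation_scan(tab)
  expect_gte(mean(scan$padj[1:200] < 0.05, na.rm = TRUE), 0.95)
  # constant-frequency locus: estimate near zero, p near one
  const <- toy_table(matrix(30L, 1, nrow(grid)),
                     matrix(90L, 1, nrow(grid)),
                     samples = tab$samples)
  sc <- qb_generation_scan(const)
  expect_lt(abs(sc$estimate), 1e-8)
  expect_gt(sc$p, 0.99)
})

test_that("loo_parallelism is deterministic and symmetric for duplicated
          replicates", {
  set.seed(28)
  gens <- c(0, 65); n_rep <- 4
  L <- 120
  grid <- expand.grid(replicate = seq_len(n_rep), generation = gens)
  f0 <- runif(L, 0.2, 0.5)
  slope <- c(rep(0.04, 20), rep(0, 100))
  freqs <- vapply(seq_len(nrow(grid)), function(j)
    plogis(qlogis(f0) + slope * grid$generation[j]), numeric(L))
  tab <- traj_table(freqs, gens, n_rep)
  # duplicate replicate 1's counts into replicate 2
  for (g in gens) {
    j1 <- which(tab$samples$replicate == 1 & tab$samples$generation == g)
    j2 <- which(tab$samples$replicate == 2 & tab$samples$generation == g)
    tab$minor[, j2] <- tab$minor[, j1]
    tab$coverage[, j2] <- tab$coverage[, j1]
  }
  a <- suppressWarnings(loo_parallelism(tab, "A2C", seed = 5))
  b <- suppressWarnings(loo_parallelism(tab, "A2C", seed = 5))
  expect_identical(a$iterations, b$iterations)
  expect_identical(a$tests, b$tests)
  # identical training sets (others of 1 vs others of 2 coincide) give
  # identical target counts for the two held-out twins
  gw <- a$iterations[a$iterations$region == "genome", ]
  expect_equal(gw$n_targets[gw$replicate == 1], gw$n_targets[gw$replicate == 2])
  expect_equal(gw$target_median[gw$replicate == 1],
               gw$target_median[gw$replicate == 2])
})

test_that("target counts shrink as thresholds tighten", {
  set.seed(30)
  gens <- c(0, 30, 65); n_rep <- 6
  L <- 400
  slope <- c(rep(0.03, 60), rep(0, 340))
  f0 <- runif(L, 0.2, 0.5)
  grid <- expand.grid(replicate = seq_len(n_rep), generation = gens)
  freqs <- vapply(seq_len(nrow(grid)), function(j)
    plogis(qlogis(f0) + slope * grid$generation[j] +
             rnorm(L, 0, 0.02)), numeric(L))
  tab <- traj_table(freqs, gens, n_rep)
  n_targets <- function(res) sum(res$iterations$n_targets[
    res$iterations$region == "genome"])
  loose <- loo_parallelism(tab, "A2C", fdr = 0.05, min_abs_dp = 0, seed = 1)
  strict_fdr <- suppressWarnings(
    loo_parallelism(tab, "A2C", fdr = 0.01, min_abs_dp = 0, seed = 1))
  with_dp <- suppressWarnings(
    loo_parallelism(tab, "A2C", fdr = 0.05, min_abs_dp = 0.02, seed = 1))
  expect_lte(n_targets(strict_fdr), n_targets(loose))
  expect_lte(n_targets(with_dp), n_targets(loose))
})

test_that("targets outpace controls when a parallel signal exists", {
  set.seed(31)
  gens <- c(0, 30, 65); n_rep <- 8
  L <- 500
  slope <- c(rep(0.04, 50), rep(0, 450))
  f0 <- runif(L, 0.2, 0.4)
  grid <- expand.grid(replicate = seq_len(n_rep), generation = gens)
  freqs <- vapply(seq_len(nrow(grid)), function(j)
    plogis(qlogis(f0) + slope * grid$generation[j]), numeric(L))
  tab <- traj_table(freqs, gens, n_rep)
  res <- loo_parallelism(tab, "A2C", seed = 4)
  gw <- res$iterations[res$iterations$region == "genome", ]
  expect_gte(sum(gw$target_median > gw$control_median), n_rep - 1)
  expect_lt(res$tests$p[res$tests$region == "genome"], 0.01)
})

test_that("loo_parallelism validates its preconditions", {
  set.seed(32)
  gens <- c(0, 65)
  grid <- expand.grid(replicate = 1:2, generation = gens)
  freqs <- matrix(0.3, 50, nrow(grid))
  tab <- traj_table(freqs, gens, 2)
  expect_error(loo_parallelism(tab, "A2C"), ">= 3 replicates")
})
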
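test_that("design construction does the record/species bookkeeping", {
  tr <- ape::read.tree(text = "((sp1:1,sp2:1):1,sp3:2);")
  dat <- data.frame(species_id = rep(c("sp1", "sp2", "sp3"), each = 2),
                    y = rnorm(6), x = rnorm(6))
  spec <- model_spec("y", "x")
  des <- build_design(dat, spec, tr)
  expect_equal(dim(des$Z), c(6, 3))
  expect_equal(unname(Matrix::colSums(des$Z)), rep(2, 3))
  expect_equal(unname(diag(des$A)), rep(1, 3))
  expect_equal(colnames(des$X), c("(Intercept)", "x"))

  # standardization is idempotent
  dat$x <- (dat$x - mean(dat$x)) / sd(dat$x)
  des2 <- build_design(dat, spec, tr)
  expect_equal(unname(des2$X[, "x"]), dat$x, tolerance = 1e-12)

  # two-point log standardization: {e, e^2} -> +/- 0.707
  dat2 <- data.frame(species_id = c("sp1", "sp2"), y = c(1, 2),
                     v = c(exp(1), exp(2)))
  sp2 <- model_spec("y", "v", transform_map = c(v = "log"))
  tr2 <- ape::read.tree(text = "(sp1:1,sp2:1);")
  des3 <- build_design(dat2, sp2, tr2)
  expect_equal(unname(des3$X[, "v"]), c(-1, 1) / sqrt(2), tolerance = 1e-9)

  expect_error(build_design(data.frame(species_id = "nope", y = 1, x = 1),
                            spec, tr), "absent from tree")
  dat$x <- 1
  expect_error(build_design(dat, spec, tr), "constant predictor")
})

test_that("the Gibbs sampler is deterministic under a fixed seed", {
  sc <- nest_scenario(n_species = 20, records_per_species = 2, seed = 3)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  spec <- model_spec("response", names(sc$beta_true),
                     fixed_types = c(insular = "binary"),
                     standardize = FALSE)
  des <- build_design(sim$records, spec, tr)
  st <- mcmc_settings(n_iterations = 200, burn_in = 50, thin = 5, seed = 7)
  f1 <- gibbs_run(des, prior_spec(), st)
  f2 <- gibbs_run(des, prior_spec(), st)
  expect_identical(f1$beta_draws, f2$beta_draws)
  expect_identical(f1$var_phylo_draws, f2$var_phylo_draws)
  expect_true(all(f1$var_phylo_draws > 0))
  expect_true(all(f1$var_residual_draws > 0))
})

test_that("with no phylogenetic or species signal the posterior mean tracks OLS", {
  sc <- nest_scenario(n_species = 80, records_per_species = 1,
                      lambda_true = 0,
                      beta_true = c(x1 = 0.8, x2 = -0.3),
                      binary_predictors = character(0),
                      sigma2_phylo = 0, sigma2_species = 0,
                      sigma2_residual = 0.4, source_offset = 0, seed = 11)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  spec <- model_spec("response", c("x1", "x2"),
                     random_terms = "phylogeny", standardize = FALSE)
  des <- build_design(sim$records, spec, tr)
  fit <- gibbs_run(des, prior_spec(),
                   mcmc_settings(n_iterations = 2000, burn_in = 500,
                                 thin = 3, seed = 2))
  ols <- lm(response ~ x1 + x2, data = sim$records)
  se <- summary(ols)$coefficients[, "Std. Error"]
  post <- colMeans(fit$beta_draws)
  expect_true(all(abs(post - coef(ols)) < 2 * se))
})

test_that("multi-tree pooling arithmetic and identity hold", {
  sc <- nest_scenario(n_species = 15, records_per_species = 2, seed = 5)
  trees <- lapply(1:5, function(i) simulate_tree(sc, seed = i))
  sim <- simulate_traits(trees[[1]], sc)
  spec <- model_spec("response", names(sc$beta_true),
                     fixed_types = c(insular = "binary"),
                     standardize = FALSE)
  st <- mcmc_settings(n_iterations = 120, burn_in = 20, thin = 50, seed = 1,
                      trees_per_run = 5)
  pooled <- multi_tree_run(sim$records, spec, prior_spec(), st, trees)
  # floor((120 - 20) / 50) = 2 retained draws per tree, 5 trees
  expect_equal(nrow(pooled$beta_draws), 10)
  expect_equal(pooled$tree_index, rep(1:5, each = 2))

  one <- multi_tree_run(sim$records, spec, prior_spec(), st, trees[1])
  expect_equal(nrow(one$beta_draws), 2)

  bad <- mcmc_settings(n_iterations = 120, burn_in = 100, thin = 50, seed = 1)
  expect_error(multi_tree_run(sim$records, spec, prior_spec(), bad, trees),
               "zero")
})

test_that("pMCMC counts signs with a 2/N floor", {
  expect_equal(pmcmc(c(-1, 2, 3, 4)), 0.5)
  expect_equal(pmcmc(rep(1, 1000)), 0.002)
  expect_equal(pmcmc(c(-2, -1, 1, 2)), 1.0)
  expect_error(pmcmc(1), "at least 2")
})

test_that("conditional R2 follows its closed forms", {
  fake <- function(vf, vs, ve, X, beta) {
    structure(list(beta_draws = matrix(beta, nrow = 4, ncol = length(beta),
                                       byrow = TRUE,
                                       dimnames = list(NULL, colnames(X))),
                   var_phylo_draws = rep(vf, 4),
                   var_species_draws = rep(vs, 4),
                   var_residual_draws = rep(ve, 4),
                   design = list(X = X)), class = "posterior_sample")
  }
  X <- cbind(`(Intercept)` = rep(1, 10))
  # intercept-only, equal components: (0 + v + v) / (0 + v + v + v) = 2/3
  expect_equal(conditional_r2(fake(1, 1, 1, X, 0)), 2 / 3)
  # vanishing residual variance drives R2 to 1
  expect_equal(conditional_r2(fake(1, 1, 1e-12, X, 0)), 1, tolerance = 1e-9)
  # with fixed-effect variance: Vfix = population variance of X beta
  X2 <- cbind(`(Intercept)` = 1, x = c(-1, 1))
  vfix <- 1  # beta_x = 1 on x = +/-1
  expect_equal(conditional_r2(fake(0.5, 0.25, 0.75, X2, c(0, 1))),
               (vfix + 0.75) / (vfix + 0.75 + 0.75))
})

test_that("repeatability hits its degenerate limits and errors", {
  df <- data.frame(species_id = rep(paste0("s", 1:6), each = 3),
                   y = rep(c(1, 3, 5, 7, 9, 11), each = 3))
  expect_equal(suppressWarnings(repeatability(df, "y"))$repeatability, 1,
               tolerance = 1e-6)

  set.seed(8)
  df$y <- rnorm(18)  # no between-species structure
  expect_lt(repeatability(df, "y")$repeatability, 0.35)

  solo <- data.frame(species_id = paste0("s", 1:6), y = rnorm(6))
  expect_error(repeatability(solo, "y"), "replication")
})

test_that("variance inflation factors match their closed forms", {
  # orthogonal predictors
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(X)), c(1, 1))
  # exact correlation 0.6 -> VIF = 1 / (1 - 0.36) = 1.5625
  z1 <- c(1, 1, -1, -1) / 2
  z2 <- c(1, -1, 1, -1) / 2
  X2 <- cbind(p = z1, q = 0.6 * z1 + sqrt(1 - 0.36) * z2)
  expect_equal(unname(vif(X2)), c(1.5625, 1.5625), tolerance = 1e-10)
  expect_error(vif(cbind(x = z1, dup = z1)), "collinearity")
  expect_error(vif(cbind(x = z1)), "at least 2")
})

test_that("summaries report effects, HPDs and convergence flags", {
  sc <- nest_scenario(n_species = 25, records_per_species = 2, seed = 13)
  tr <- simulate_tree(sc)
  sim <- simulate_traits(tr, sc)
  spec <- model_spec("response", names(sc$beta_true),
                     fixed_types = c(insular = "binary"),
                     standardize = FALSE)
  des <- build_design(sim$records, spec, tr)
  fit <- gibbs_run(des, prior_spec(),
                   mcmc_settings(n_iterations = 600, burn_in = 100,
                                 thin = 2, n_chains = 2, seed = 4))
  s <- summarize_posterior(fit, ess_floor = 5)
  expect_setequal(s$fixed$term, c("(Intercept)", names(sc$beta_true)))
  expect_true(all(s$fixed$hpd_lower <= s$fixed$post_mean &
                    s$fixed$post_mean <= s$fixed$hpd_upper))
  expect_true(all(s$fixed$pMCMC >= 2 / s$n_draws & s$fixed$pMCMC <= 1))
  expect_true(s$conditional_r2 >= 0 && s$conditional_r2 <= 1)
  # variance components positive, denominator >= numerator by construction
  expect_true(all(s$variances$post_mean > 0))
  expect_output(print(s), "Fixed effects")
})

test_that("an empirical HPD interval brackets the right mass", {
  set.seed(9)
  d <- rnorm(4000)
  hp <- hpd_interval(d)
  expect_equal(mean(d >= hp[1] & d <= hp[2]), 0.95, tolerance = 0.01)
  expect_lt(hp[2] - hp[1], quantile(d, 0.975) - quantile(d, 0.025) + 0.05)
})
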
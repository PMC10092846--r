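# Shared fixtures and independent oracles, all built in code.

# Brute-force GLS/conditional-expectation oracle for ancestral states:
# builds the joint covariance of tips and internal nodes from node depths
# and pairwise path distances, estimates the root by GLS on the tips and
# predicts each internal node by conditional expectation. Independent of
# the package's Laplacian solver.
oracle_ancestral <- function(tree, trait) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  D <- ape::dist.nodes(tree)
  depth <- D[n + 1, ]
  Call <- (outer(depth, depth, "+") - D) / 2
  Ct <- Call[1:n, 1:n]
  Cnt <- Call[(n + 1):(n + m), 1:n, drop = FALSE]
  y <- trait[tree$tip.label]
  Ci <- solve(Ct)
  mu <- sum(Ci %*% y) / sum(Ci)
  est <- drop(mu + Cnt %*% Ci %*% (y - mu))
  names(est) <- as.character((n + 1):(n + m))
  est
}

# Simulate a trait under Pagel's lambda on a tree (unit rate).
sim_lambda_trait <- function(tree, lambda, sigma2 = 1) {
  C <- ape::vcv.phylo(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  x <- drop(crossprod(chol(sigma2 * Cl), stats::rnorm(ape::Ntip(tree))))
  stats::setNames(x, tree$tip.label)
}

# Axis-aligned rectangle polygon.
rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# Small complete synthetic study for pipeline tests: measurement table
# with raw dimensions realising known volumes, a life-history table and
# a geographic summary table, plus a small tree sample.
make_study <- function(n_species = 40, n_trees = 2, seed = 99) {
  set.seed(seed)
  sc <- nest_scenario(n_species = n_species, seed = seed)
  trees <- lapply(seq_len(n_trees), function(i) simulate_tree(sc, seed + i))
  species <- trees[[1]]$tip.label

  lh <- data.frame(
    species_id = species,
    body_mass = exp(rnorm(n_species, 3, 0.8)),
    clutch_size = pmax(1, round(rnorm(n_species, 4, 1.2))),
    nest_ground = rbinom(n_species, 1, 0.2),
    nest_vegetation = rbinom(n_species, 1, 0.6),
    nest_cliff = rbinom(n_species, 1, 0.1),
    cavity_nester = rbinom(n_species, 1, 0.1),
    nest_height = exp(rnorm(n_species, 0.5, 0.6)),
    migratory = rbinom(n_species, 1, 0.4),
    nest_builder = sample(c("female", "mainly_female", "both", "male"),
                          n_species, replace = TRUE,
                          prob = c(0.3, 0.2, 0.45, 0.05)),
    care_system = sample(c("biparental", "female_only", "helpers"),
                         n_species, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    nestling_period = exp(rnorm(n_species, 2.6, 0.3)))

  geo <- data.frame(
    species_id = species,
    midpoint_lat = runif(n_species, -60, 60),
    midpoint_lon = runif(n_species, -30, 30),
    mean_temperature = runif(n_species, -5, 28),
    mean_precipitation = runif(n_species, 20, 300),
    insular_large_threshold = rbinom(n_species, 1, 0.2) == 1,
    insular_small_threshold = FALSE,
    insular_proportion = 0)
  geo$hemisphere <- ifelse(geo$midpoint_lat >= 0, "north", "south")

  # one or two records per species; dimensions chosen so the
  # half-spheroid volumes land on lognormal targets (H = 0.6 D)
  n_rec <- 1L + rbinom(n_species, 1L, 0.3)
  ri <- rep(seq_len(n_species), n_rec)
  N <- length(ri)
  inner_v <- exp(rnorm(N, 4.2, 0.7))
  outer_v <- inner_v * exp(rnorm(N, 0.9, 0.3))
  full_v <- inner_v + outer_v
  dia <- function(v) (v / (0.1 * pi))^(1 / 3)
  D <- dia(full_v); d <- dia(inner_v)
  meas <- data.frame(
    species_id = species[ri],
    source = sample(c("museum", "literature"), N, replace = TRUE),
    site_label = paste0("site", stats::ave(ri, ri, FUN = seq_along)),
    D1 = D, D2 = D, D3 = D, D4 = D, H1 = 0.6 * D, H2 = 0.6 * D,
    d1 = d, d2 = d, d3 = d, d4 = d, h1 = 0.6 * d, h2 = 0.6 * d)
  list(measurements = meas, life_history = lh, geo = geo, trees = trees,
       scenario = sc)
}
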
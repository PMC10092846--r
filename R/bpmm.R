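#' Specify a phylogenetic mixed model
#'
#' @param response Response column name (record-level table).
#' @param fixed_terms Character vector of predictor column names.
#' @param fixed_types Named character vector mapping each fixed term to
#'   \code{"continuous"} or \code{"binary"}; defaults to continuous.
#' @param random_terms \code{c("phylogeny", "species")} (record-level
#'   data) or \code{"phylogeny"} (one row per species).
#' @param transform_map Named character vector per variable:
#'   \code{"log"}, \code{"sqrt"}, \code{"signed_sqrt"} or \code{"none"}.
#'   Transforms are applied before standardisation.
#' @param standardize Mean-centre and scale continuous predictors (and
#'   leave binary predictors as 0/1 dummies)?
#' @param sd_divisor \code{"n-1"} (sample SD, the default and the usual
#'   reporting convention) or \code{"n"} (population SD).
#' @return Object of class \code{"model_spec"}.
#' @export
model_spec <- function(response, fixed_terms,
                       fixed_types = NULL,
                       random_terms = c("phylogeny", "species"),
                       transform_map = NULL,
                       standardize = TRUE,
                       sd_divisor = c("n-1", "n")) {
  sd_divisor <- match.arg(sd_divisor)
  if (response %in% fixed_terms)
    stop("response cannot appear among fixed terms")
  stopifnot(all(random_terms %in% c("phylogeny", "species")),
            "phylogeny" %in% random_terms)
  types <- stats::setNames(rep("continuous", length(fixed_terms)), fixed_terms)
  if (!is.null(fixed_types)) types[names(fixed_types)] <- fixed_types
  stopifnot(all(types %in% c("continuous", "binary")))
  tm <- stats::setNames(rep("none", length(c(response, fixed_terms))),
                        c(response, fixed_terms))
  if (!is.null(transform_map)) tm[names(transform_map)] <- transform_map
  stopifnot(all(tm %in% c("log", "sqrt", "signed_sqrt", "none")))
  structure(list(response = response, fixed_terms = fixed_terms,
                 fixed_types = types, random_terms = random_terms,
                 transform_map = tm, standardize = standardize,
                 sd_divisor = sd_divisor), class = "model_spec")
}

#' Variance and fixed-effect priors
#'
#' Univariate inverse-Wishart(V, nu) priors for the phylogenetic,
#' between-species and residual variances — implemented as
#' inverse-gamma(shape nu/2, scale nu V/2) — and diffuse normal priors
#' for fixed effects.
#'
#' @param variance_prior_V Scale, default 1.
#' @param variance_prior_nu Degree of belief, default 0.02.
#' @param fixed_effect_mean Default 0.
#' @param fixed_effect_variance Default 1e10.
#' @return Object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(variance_prior_V = 1, variance_prior_nu = 0.02,
                       fixed_effect_mean = 0, fixed_effect_variance = 1e10) {
  stopifnot(variance_prior_V > 0, variance_prior_nu > 0,
            fixed_effect_variance > 0)
  structure(list(variance_prior_V = variance_prior_V,
                 variance_prior_nu = variance_prior_nu,
                 fixed_effect_mean = fixed_effect_mean,
                 fixed_effect_variance = fixed_effect_variance),
            class = "prior_spec")
}

#' MCMC schedule
#'
#' The default is a desk-scale schedule (5000 iterations, 1000 burn-in,
#' thin 20, one retained chain per tree over 100 trees). The published
#' protocol (2400 iterations, 400 burn-in, thin 1000, three chains on
#' each of 1000 trees, retaining 2 draws per tree) is available via
#' \code{paper_schedule()}.
#'
#' @param n_iterations,burn_in,thin,n_chains,seed,trees_per_run Integers.
#' @return Object of class \code{"mcmc_settings"}.
#' @export
mcmc_settings <- function(n_iterations = 5000, burn_in = 1000, thin = 20,
                          n_chains = 1, seed = 1, trees_per_run = 100) {
  stopifnot(burn_in < n_iterations, thin >= 1, n_chains >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 trees_per_run = as.integer(trees_per_run)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
paper_schedule <- function(seed = 1) {
  mcmc_settings(n_iterations = 2400, burn_in = 400, thin = 1000,
                n_chains = 3, seed = seed, trees_per_run = 1000)
}

.apply_transform <- function(x, how, what = "variable") {
  switch(how,
    none = x,
    log = {
      if (any(x <= 0, na.rm = TRUE))
        stop("log transform of non-positive values in ", what, " (records ",
             paste(utils::head(which(x <= 0), 5), collapse = ", "), ")")
      log(x)
    },
    sqrt = {
      if (any(x < 0, na.rm = TRUE))
        stop("sqrt transform of negative values in ", what)
      sqrt(x)
    },
    signed_sqrt = sign(x) * sqrt(abs(x)))
}

.standardize <- function(x, divisor = "n-1") {
  n <- length(x)
  s <- stats::sd(x) * if (divisor == "n") sqrt((n - 1) / n) else 1
  if (!is.finite(s) || s == 0) stop("constant predictor: undefined SD")
  (x - mean(x)) / s
}

#' Build the model design from a record-level table
#'
#' Applies transforms and standardisation, builds the fixed design
#' matrix (intercept first), the record-to-species incidence map and the
#' phylogenetic relatedness matrix A — the BM covariance of the pruned
#' tree scaled to unit diagonal (a correlation matrix).
#'
#' @param data Record-level \code{data.frame} with a \code{species_id}
#'   column, the response and all predictors.
#' @param spec A \code{\link{model_spec}}.
#' @param tree A \code{phylo} object whose tips cover the data species.
#' @return Object of class \code{"bpmm_design"}: \code{y}, \code{X},
#'   \code{Z} (record x species incidence), \code{A} (species
#'   correlation), \code{species}, \code{spec}.
#' @export
build_design <- function(data, spec, tree) {
  stopifnot(inherits(spec, "model_spec"), inherits(tree, "phylo"))
  need <- c("species_id", spec$response, spec$fixed_terms)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, need])
  data <- data[cc, , drop = FALSE]
  absent <- setdiff(unique(data$species_id), tree$tip.label)
  if (length(absent))
    stop("species absent from tree: ", paste(absent, collapse = ", "))
  if (length(setdiff(tree$tip.label, data$species_id)))
    tree <- ape::keep.tip(tree, unique(data$species_id))

  y <- .apply_transform(data[[spec$response]],
                        spec$transform_map[[spec$response]], spec$response)
  cols <- lapply(spec$fixed_terms, function(v) {
    x <- .apply_transform(data[[v]], spec$transform_map[[v]], v)
    if (spec$fixed_types[[v]] == "continuous" && spec$standardize)
      x <- .standardize(x, spec$sd_divisor)
    if (spec$fixed_types[[v]] == "binary" &&
        !all(x %in% c(0, 1))) x <- as.numeric(as.factor(x)) - 1
    x
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X) <- c("(Intercept)", spec$fixed_terms)
  for (v in spec$fixed_terms)
    if (stats::sd(X[, v]) == 0) stop("constant predictor: ", v)

  species <- tree$tip.label
  si <- match(data$species_id, species)
  Z <- Matrix::sparseMatrix(i = seq_len(nrow(data)), j = si,
                            x = 1, dims = c(nrow(data), length(species)),
                            dimnames = list(NULL, species))
  A <- stats::cov2cor(bm_covariance(tree))
  structure(list(y = y, X = X, Z = Z, A = A, species = species,
                 species_index = si, spec = spec, tree = tree,
                 data = data), class = "bpmm_design")
}

# Conjugate Gibbs sampler core. Location effects (fixed + phylogenetic +
# optional species) are drawn jointly from their multivariate-normal full
# conditional via the mixed-model equations; each variance component from
# its inverse-gamma full conditional. Uses R's RNG, so set.seed() gives
# bitwise reproducibility.
.gibbs_core <- function(y, X, Zs, Ainv, with_species, priors, n_iter,
                        burn_in, thin) {
  n <- length(y); p <- ncol(X); q <- nrow(Ainv)
  W <- cbind(X, as.matrix(Zs))
  if (with_species) W <- cbind(W, as.matrix(Zs))
  k <- ncol(W)
  WtW <- crossprod(W); Wty <- drop(crossprod(W, y))
  ia <- p + seq_len(q)
  is_ <- if (with_species) p + q + seq_len(q) else integer(0)
  nu <- priors$variance_prior_nu; V <- priors$variance_prior_V
  bprec <- 1 / priors$fixed_effect_variance
  bmean_term <- priors$fixed_effect_mean * bprec

  sa <- ss <- se <- stats::var(y) / if (with_species) 3 else 2
  theta <- numeric(k)
  nk <- max(0L, (n_iter - burn_in) %/% thin)
  if (nk == 0L) stop("settings retain zero draws per chain")
  beta_draws <- matrix(NA_real_, nk, p, dimnames = list(NULL, colnames(X)))
  va <- vs <- ve <- numeric(nk)
  kk <- 0L
  for (it in seq_len(n_iter)) {
    Cmat <- WtW / se
    Cmat[ia, ia] <- Cmat[ia, ia] + Ainv / sa
    if (with_species) {
      d <- seq.int(p + q + 1L, k)
      Cmat[cbind(d, d)] <- Cmat[cbind(d, d)] + 1 / ss
    }
    dd <- seq_len(p)
    Cmat[cbind(dd, dd)] <- Cmat[cbind(dd, dd)] + bprec
    rhs <- Wty / se
    rhs[dd] <- rhs[dd] + bmean_term
    L <- tryCatch(chol(Cmat), error = function(e)
      stop("non-positive-definite mixed-model equations (location update)"))
    mu <- backsolve(L, forwardsolve(L, rhs, upper.tri = TRUE, transpose = TRUE))
    theta <- mu + backsolve(L, stats::rnorm(k))
    a <- theta[ia]
    e <- y - drop(W %*% theta)
    se <- 1 / stats::rgamma(1, shape = (nu + n) / 2,
                            rate = (nu * V + sum(e * e)) / 2)
    sa <- 1 / stats::rgamma(1, shape = (nu + q) / 2,
                            rate = (nu * V + drop(crossprod(a, Ainv %*% a))) / 2)
    if (with_species) {
      s <- theta[is_]
      ss <- 1 / stats::rgamma(1, shape = (nu + q) / 2,
                              rate = (nu * V + sum(s * s)) / 2)
    }
    if (it >= burn_in + thin && (it - burn_in) %% thin == 0L) {
      kk <- kk + 1L
      beta_draws[kk, ] <- theta[dd]
      va[kk] <- sa; vs[kk] <- ss; ve[kk] <- se
    }
  }
  list(beta = beta_draws, var_phylo = va,
       var_species = if (with_species) vs else rep(NA_real_, nk),
       var_residual = ve)
}

#' Run the Gibbs sampler on one tree
#'
#' @param design A \code{\link{build_design}} result.
#' @param priors A \code{\link{prior_spec}}.
#' @param settings An \code{\link{mcmc_settings}}. Chains beyond the
#'   first are run (with seeds \code{seed + chain - 1}) solely for
#'   convergence diagnostics; pooled inference uses chain 1.
#' @return Object of class \code{"posterior_sample"}: \code{beta_draws},
#'   \code{var_phylo_draws}, \code{var_species_draws},
#'   \code{var_residual_draws}, \code{tree_index}, and \code{chains}
#'   (per-chain draw lists for diagnostics).
#' @export
gibbs_run <- function(design, priors = prior_spec(),
                      settings = mcmc_settings()) {
  stopifnot(inherits(design, "bpmm_design"))
  with_species <- "species" %in% design$spec$random_terms
  Ainv <- tryCatch(chol2inv(chol(design$A)), error = function(e)
    stop("non-positive-definite phylogenetic relatedness matrix A"))
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(settings$seed + ch - 1L)
    chains[[ch]] <- .gibbs_core(design$y, design$X, design$Z, Ainv,
                                with_species, priors,
                                settings$n_iterations, settings$burn_in,
                                settings$thin)
  }
  main <- chains[[1L]]
  structure(list(beta_draws = main$beta,
                 var_phylo_draws = main$var_phylo,
                 var_species_draws = main$var_species,
                 var_residual_draws = main$var_residual,
                 tree_index = rep(1L, nrow(main$beta)),
                 chains = chains,
                 design = design, settings = settings),
            class = "posterior_sample")
}

#' Pool the sampler over a sample of trees
#'
#' One chain is run per tree; each contributes
#' \code{floor((n_iterations - burn_in) / thin)} retained draws to the
#' pooled posterior (the published schedule retains 2 per tree for 2000
#' pooled solutions over 1000 trees). Additional chains, if requested,
#' are run on each tree for the Gelman-Rubin diagnostic only.
#'
#' @param data Record-level table.
#' @param spec A \code{\link{model_spec}}.
#' @param priors A \code{\link{prior_spec}}.
#' @param settings An \code{\link{mcmc_settings}}; \code{trees_per_run}
#'   trees are used (a seeded subsample if more are supplied).
#' @param trees List of \code{phylo} objects.
#' @return A pooled \code{"posterior_sample"} with \code{tree_index} per
#'   draw and a \code{diagnostics} data.frame (per-tree max PSRF when
#'   multiple chains were run).
#' @export
multi_tree_run <- function(data, spec, priors, settings, trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  if (length(trees) > settings$trees_per_run) {
    set.seed(settings$seed)
    trees <- trees[sort(sample.int(length(trees), settings$trees_per_run))]
  }
  beta <- NULL; va <- vs <- ve <- ti <- numeric(0)
  psrf_max <- rep(NA_real_, length(trees))
  for (i in seq_along(trees)) {
    des <- build_design(data, spec, trees[[i]])
    st <- settings; st$seed <- settings$seed + 1000L * (i - 1L)
    fit <- gibbs_run(des, priors, st)
    beta <- rbind(beta, fit$beta_draws)
    va <- c(va, fit$var_phylo_draws); vs <- c(vs, fit$var_species_draws)
    ve <- c(ve, fit$var_residual_draws)
    ti <- c(ti, rep(i, nrow(fit$beta_draws)))
    if (settings$n_chains > 1L) {
      mats <- lapply(fit$chains, function(ch)
        cbind(ch$beta, ch$var_phylo, ch$var_residual))
      psrf_max[i] <- max(vapply(seq_len(ncol(mats[[1]])), function(j)
        psrf(lapply(mats, function(m) m[, j])), numeric(1)))
    }
  }
  last_design <- build_design(data, spec, trees[[length(trees)]])
  structure(list(beta_draws = beta, var_phylo_draws = va,
                 var_species_draws = vs, var_residual_draws = ve,
                 tree_index = ti, design = last_design, settings = settings,
                 diagnostics = data.frame(tree = seq_along(trees),
                                          psrf_max = psrf_max)),
            class = "posterior_sample")
}

#' Summarise a posterior sample
#'
#' Reports, per fixed effect, the posterior mean of the standardized
#' coefficient (the headline effect size), the 95\% HPD interval and
#' pMCMC; per variance component the posterior mean and HPD; the
#' conditional R-squared; and effective sample size with the lag-1 (at
#' the thinned scale) autocorrelation per parameter.
#'
#' @param sample A \code{"posterior_sample"}.
#' @param ess_floor Runs with any parameter ESS below this (or any
#'   per-tree PSRF at or above 1.1) are flagged non-converged.
#' @return Object of class \code{"model_summary"} with elements
#'   \code{fixed} (data.frame), \code{variances} (data.frame),
#'   \code{conditional_r2}, \code{converged}, \code{n_draws}.
#' @export
summarize_posterior <- function(sample, ess_floor = 100) {
  stopifnot(inherits(sample, "posterior_sample"))
  B <- sample$beta_draws
  fixed <- do.call(rbind, lapply(colnames(B), function(nm) {
    d <- B[, nm]
    hp <- hpd_interval(d)
    data.frame(term = nm, post_mean = mean(d), hpd_lower = hp[1],
               hpd_upper = hp[2], pMCMC = pmcmc(d))
  }))
  vlist <- list(phylogenetic = sample$var_phylo_draws,
                species = sample$var_species_draws,
                residual = sample$var_residual_draws)
  vlist <- vlist[!vapply(vlist, function(v) all(is.na(v)), logical(1))]
  variances <- do.call(rbind, lapply(names(vlist), function(nm) {
    d <- vlist[[nm]]
    hp <- hpd_interval(d)
    data.frame(component = nm, post_mean = mean(d), hpd_lower = hp[1],
               hpd_upper = hp[2])
  }))
  r2 <- conditional_r2(sample)
  pars <- c(as.list(as.data.frame(B)), vlist)
  ess <- vapply(pars, function(d) ess_and_autocorr(d)$ess, numeric(1))
  ac1 <- vapply(pars, function(d) ess_and_autocorr(d)$autocorr[1], numeric(1))
  psrf_ok <- all(is.na(sample$diagnostics$psrf_max)) ||
    max(sample$diagnostics$psrf_max, na.rm = TRUE) < 1.1
  structure(list(fixed = fixed, variances = variances,
                 conditional_r2 = r2,
                 ess = ess, autocorr_lag1 = ac1,
                 converged = psrf_ok && all(ess >= ess_floor),
                 n_draws = nrow(B)), class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Bayesian phylogenetic mixed model (", x$n_draws, " pooled draws",
      if (!x$converged) ", NON-CONVERGED", ")\n\nFixed effects:\n", sep = "")
  print(x$fixed, row.names = FALSE, digits = 3)
  cat("\nVariance components:\n")
  print(x$variances, row.names = FALSE, digits = 3)
  cat("\nConditional R2: ", format(x$conditional_r2, digits = 3), "\n", sep = "")
  invisible(x)
}
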
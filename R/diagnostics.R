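#' MCMC sign probability (pMCMC)
#'
#' Two-sided significance measure for a posterior sample:
#' \eqn{2 \min(\#\{d > 0\}, \#\{d < 0\}) / N}, floored at \eqn{2/N} so a
#' finite sample never reports exactly zero.
#'
#' @param draws Numeric vector of posterior draws (N >= 2).
#' @return Probability in [2/N, 1].
#' @export
pmcmc <- function(draws) {
  N <- length(draws)
  if (N < 2L) stop("need at least 2 draws")
  p <- 2 * min(sum(draws > 0), sum(draws < 0)) / N
  max(p, 2 / N)
}

#' 95\% highest posterior density interval
#'
#' Empirical HPD: the shortest window containing the requested mass of
#' the sorted draws.
#'
#' @param draws Numeric vector.
#' @param prob Interval mass, default 0.95.
#' @return Length-2 vector (lower, upper).
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- max(1L, min(n - 1L, floor(n * prob)))
  widths <- x[(m + 1L):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with W the mean
#' within-chain variance and B = n times the between-chain variance of
#' chain means. Values below 1.1 are the conventional convergence bar.
#'
#' @param chains List of >= 2 equal-length numeric vectors.
#' @return The PSRF.
#' @export
psrf <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 10L) stop("chains too short (need n >= 10)")
  W <- mean(vapply(chains, stats::var, numeric(1)))
  B <- n * stats::var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size and autocorrelation
#'
#' \eqn{ESS = N / (1 + 2\sum_k \rho_k)} with the sum truncated at the
#' first non-positive autocorrelation. The lag-1 autocorrelation (at the
#' thinned scale) is reported against the conventional 0.1 threshold.
#'
#' @param draws Numeric vector (N >= 10).
#' @param max_lag Largest lag considered; defaults to N - 1 capped at
#'   10 sqrt(N).
#' @return List: \code{ess}, \code{autocorr} (vector from lag 1),
#'   \code{below_threshold} (is |lag-1 autocorrelation| < 0.1?).
#' @export
ess_and_autocorr <- function(draws, max_lag = NULL) {
  N <- length(draws)
  if (N < 10L) stop("need at least 10 draws")
  if (stats::var(draws) == 0) stop("zero-variance draws: ESS undefined")
  if (is.null(max_lag)) max_lag <- min(N - 1L, ceiling(10 * sqrt(N)))
  rho <- drop(stats::acf(draws, lag.max = max_lag, plot = FALSE,
                         demean = TRUE)$acf)[-1]
  first_np <- which(rho <= 0)
  s <- if (length(first_np)) sum(rho[seq_len(first_np[1] - 1L)]) else sum(rho)
  ess <- N / (1 + 2 * s)
  list(ess = ess, autocorr = rho,
       below_threshold = abs(rho[1]) < 0.1)
}

#' Conditional R-squared of a fitted model
#'
#' Per draw, \eqn{R^2 = (V_{fix} + \sigma^2_{phylo} + \sigma^2_{species})
#' / (V_{fix} + \sigma^2_{phylo} + \sigma^2_{species} + \sigma^2_{res})}
#' where \eqn{V_{fix}} is the variance of the fixed-effect linear
#' predictor over records; the reported value is the posterior mean.
#'
#' @param sample A \code{"posterior_sample"}.
#' @param X Fixed design matrix; defaults to the one stored in the
#'   sample.
#' @return Posterior-mean conditional R-squared in [0, 1].
#' @export
conditional_r2 <- function(sample, X = NULL) {
  stopifnot(inherits(sample, "posterior_sample"))
  if (is.null(X)) X <- sample$design$X
  B <- sample$beta_draws
  n <- nrow(X)
  eta <- X %*% t(B)                       # record x draw linear predictors
  vfix <- apply(eta, 2, function(v) sum((v - mean(v))^2) / n)
  vs <- sample$var_species_draws
  vs[is.na(vs)] <- 0
  num <- vfix + sample$var_phylo_draws + vs
  mean(num / (num + sample$var_residual_draws))
}

#' Repeatability of a trait across replicated records
#'
#' Proportion of total phenotypic variance attributable to
#' between-species differences, from an intercept-only
#' variance-components model with species grouping:
#' \eqn{R = \sigma^2_{species} / (\sigma^2_{species} + \sigma^2_{res})}.
#'
#' @param records \code{data.frame} with a \code{species_id} column.
#' @param trait Trait column name.
#' @return Object of class \code{"repeatability_result"}:
#'   \code{repeatability}, \code{trait}, \code{n_records},
#'   \code{n_species}.
#' @export
repeatability <- function(records, trait) {
  stopifnot(trait %in% names(records), "species_id" %in% names(records))
  df <- records[stats::complete.cases(records[, c("species_id", trait)]), ]
  counts <- table(df$species_id)
  if (sum(counts >= 2) < 2L)
    stop("no within-species replication: need >= 2 species with >= 2 records")
  df$..y <- df[[trait]]
  fit <- lme4::lmer(..y ~ 1 + (1 | species_id), data = df,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_sp <- vc$vcov[vc$grp == "species_id"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  structure(list(repeatability = v_sp / (v_sp + v_res), trait = trait,
                 n_records = nrow(df), n_species = length(counts)),
            class = "repeatability_result")
}

#' Variance inflation factors
#'
#' \eqn{VIF_j = 1 / (1 - R^2_j)} with \eqn{R^2_j} from regressing
#' predictor j on all other predictors (with intercept). Values below 6
#' were the multicollinearity bar applied to every non-interaction
#' predictor.
#'
#' @param X Numeric matrix of predictors (no intercept column), >= 2
#'   columns, none constant.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (ncol(X) < 2L) stop("need at least 2 predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant predictor: ", paste(colnames(X)[sds == 0], collapse = ", "))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10)
      stop("perfect collinearity: predictor ", colnames(X)[j],
           " is a linear combination of the others")
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  out
}
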
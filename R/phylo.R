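#' Brownian-motion covariance matrix of a tree
#'
#' Expected trait covariance among tips under Brownian motion with unit
#' rate: entry (i, j) is the shared root-to-MRCA path length of tips i
#' and j, the diagonal the root-to-tip depth. Polytomies and zero-length
#' internal branches are handled through the tree structure directly.
#'
#' @param tree An \code{ape} \code{phylo} object (rooted, branch lengths).
#' @return A symmetric positive semidefinite matrix with tip-name
#'   dimnames.
#' @export
bm_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip names: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  ape::vcv.phylo(tree)
}

# lambda transform: scale off-diagonal (shared-path) entries
.lambda_vcv <- function(C, lambda) {
  D <- diag(C)
  C <- C * lambda
  diag(C) <- D
  C
}

# GLS profile log-likelihood of a trait under covariance C (unit-rate
# shape); sigma2 and root state profiled out analytically (ML).
.bm_profile <- function(C, y) {
  n <- length(y)
  L <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance: ", conditionMessage(e)))
  logdet <- 2 * sum(log(diag(L)))
  # solve via cholesky: Ci1 = C^-1 1, Ciy = C^-1 y
  sol <- backsolve(L, forwardsolve(L, cbind(1, y), upper.tri = TRUE,
                                   transpose = TRUE))
  Ci1 <- sol[, 1]; Ciy <- sol[, 2]
  mu <- sum(Ciy) / sum(Ci1)
  r <- y - mu
  Cir <- Ciy - mu * Ci1
  sigma2 <- sum(r * Cir) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  list(mu = mu, sigma2 = sigma2, loglik = ll)
}

#' Fit Pagel's lambda to a continuous trait
#'
#' Pagel's lambda scales the off-diagonal entries of the Brownian-motion
#' covariance: 0 erases phylogenetic signal, 1 is pure Brownian motion.
#' The Brownian rate and root state are profiled out by GLS and lambda is
#' maximised over [0, 1] by bounded one-dimensional search.
#'
#' @param tree A \code{phylo} object.
#' @param trait Named numeric vector covering every tip.
#' @return Object of class \code{"lambda_fit"}: \code{lambda_hat},
#'   \code{sigma2_hat}, \code{root_state_hat}, \code{log_likelihood},
#'   \code{flat_likelihood}. On a star tree the likelihood is constant in
#'   lambda; \code{flat_likelihood} is set and lambda 0 returned by
#'   convention.
#' @export
fit_lambda <- function(tree, trait) {
  y <- .match_trait(tree, trait)
  if (length(y) < 3L) stop("need at least 3 tips to estimate lambda")
  C <- bm_covariance(tree)
  ll_at <- function(lam) .bm_profile(.lambda_vcv(C, lam), y)$loglik
  l0 <- ll_at(0); l1 <- ll_at(1)
  if (isTRUE(all.equal(l0, l1, tolerance = 1e-10)) &&
      isTRUE(all.equal(l0, ll_at(0.5), tolerance = 1e-10))) {
    fit <- .bm_profile(.lambda_vcv(C, 0), y)
    return(structure(list(lambda_hat = 0, sigma2_hat = fit$sigma2,
                          root_state_hat = fit$mu, log_likelihood = fit$loglik,
                          flat_likelihood = TRUE), class = "lambda_fit"))
  }
  opt <- stats::optimize(ll_at, interval = c(0, 1), maximum = TRUE,
                         tol = 1e-8)
  # the optimum can sit at a boundary the golden search never touches
  cand <- rbind(c(0, l0), c(opt$maximum, opt$objective), c(1, l1))
  best <- cand[which.max(cand[, 2]), ]
  fit <- .bm_profile(.lambda_vcv(C, best[1]), y)
  structure(list(lambda_hat = best[1], sigma2_hat = fit$sigma2,
                 root_state_hat = fit$mu, log_likelihood = best[2],
                 flat_likelihood = FALSE), class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat("Pagel's lambda fit\n",
      "  lambda = ", format(x$lambda_hat, digits = 4),
      if (x$flat_likelihood) " (flat likelihood)" else "", "\n",
      "  sigma2 = ", format(x$sigma2_hat, digits = 4),
      ", root = ", format(x$root_state_hat, digits = 4),
      ", logLik = ", format(x$log_likelihood, digits = 6), "\n", sep = "")
  invisible(x)
}

.match_trait <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label))
      stop("unnamed trait vector of wrong length")
    names(trait) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for tips: ", paste(miss, collapse = ", "))
  trait[tree$tip.label]
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML reconstruction of internal-node states: under Brownian
#' motion the negative log-likelihood is a sum of squared state changes
#' weighted by inverse branch lengths, so the ML states solve the
#' weighted graph-Laplacian system of the tree with tip states fixed.
#' This equals the GLS estimator computed from the full BM covariance
#' (root estimated with a flat prior). Variances come from the inverse
#' of the internal-node block of the Laplacian scaled by the ML
#' Brownian rate; 95\% intervals are estimate +/- 1.96 sd.
#'
#' @param tree A \code{phylo} object.
#' @param trait Named numeric vector covering every tip.
#' @return Object of class \code{"ancestral_reconstruction"}:
#'   \code{node_states} (named by ape node number), \code{node_ci95}
#'   (matrix, lower/upper), \code{root_state}, \code{root_ci95},
#'   \code{sigma2_hat}.
#' @export
ancestral_states <- function(tree, trait) {
  y <- .match_trait(tree, trait)
  n <- length(tree$tip.label); m <- tree$Nnode
  edge <- tree$edge; len <- tree$edge.length
  # zero-length terminal pendant pairs make the tip covariance singular
  zt <- edge[, 2] <= n & len <= 0
  if (any(zt)) {
    par <- edge[zt, 1]
    dup <- par[duplicated(par) | rev(duplicated(rev(par)))]
    if (length(dup))
      stop("zero-length terminal pendant pair at node ", dup[1],
           ": covariance singular")
  }
  # floor zero-length internal edges (polytomy-equivalent; states forced equal)
  eps <- 1e-10 * max(len)
  len <- pmax(len, eps)
  w <- 1 / len
  # weighted Laplacian over all nodes, partitioned tips | internals
  idx <- c(seq_len(n), n + seq_len(m))
  Laa <- matrix(0, m, m)          # internal block
  rhs <- numeric(m)               # -Lat %*% y
  dg <- numeric(n + m)
  for (e in seq_along(w)) {
    i <- edge[e, 1]; j <- edge[e, 2]; we <- w[e]
    dg[i] <- dg[i] + we; dg[j] <- dg[j] + we
    ii <- i - n                   # parents are always internal
    if (j > n) {
      jj <- j - n
      Laa[ii, jj] <- Laa[ii, jj] - we
      Laa[jj, ii] <- Laa[jj, ii] - we
    } else {
      rhs[ii] <- rhs[ii] + we * y[j]
    }
  }
  diag(Laa) <- dg[n + seq_len(m)]
  Linv <- tryCatch(solve(Laa), error = function(e)
    stop("singular reconstruction system: ", conditionMessage(e)))
  states <- drop(Linv %*% rhs)
  names(states) <- as.character(n + seq_len(m))
  # Brownian rate from the GLS fit on tips; the unbiased (n-1) divisor
  # is used for interval construction
  C <- bm_covariance(tree)
  fit <- .bm_profile(C, y)
  sigma2 <- fit$sigma2 * length(y) / (length(y) - 1)
  vars <- sigma2 * diag(Linv)
  ci <- cbind(lower = states - 1.96 * sqrt(vars),
              upper = states + 1.96 * sqrt(vars))
  rownames(ci) <- names(states)
  root_lab <- as.character(n + 1L)
  structure(list(node_states = states, node_ci95 = ci,
                 root_state = states[[root_lab]],
                 root_ci95 = ci[root_lab, ],
                 sigma2_hat = sigma2), class = "ancestral_reconstruction")
}

#' Evolutionary correlation between two traits
#'
#' Estimates the evolutionary variance-covariance of two traits by GLS
#' under the tree's Brownian-motion covariance C:
#' \eqn{R = (X - 1\hat a)' C^{-1} (X - 1\hat a) / (n - 1)} with
#' \eqn{\hat a} the GLS phylogenetic means, and reports the implied
#' Pearson-type correlation. The p-value uses
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n-2 df applied to the
#' phylogenetically corrected r.
#'
#' @param tree A \code{phylo} object.
#' @param trait_x,trait_y Named numeric vectors on the same tips.
#' @return Object of class \code{"evolutionary_correlation"}: \code{r},
#'   \code{p_value}, \code{n_species}, \code{R} (2x2 evolutionary
#'   covariance).
#' @export
phylo_correlation <- function(tree, trait_x, trait_y) {
  x <- .match_trait(tree, trait_x); y <- .match_trait(tree, trait_y)
  n <- length(x)
  if (n < 3L) stop("need at least 3 species")
  C <- bm_covariance(tree)
  L <- chol(C)
  X <- cbind(x, y)
  sol <- backsolve(L, forwardsolve(L, cbind(1, X), upper.tri = TRUE,
                                   transpose = TRUE))
  Ci1 <- sol[, 1]; CiX <- sol[, 2:3]
  a <- colSums(CiX) / sum(Ci1)     # GLS phylogenetic means
  Xc <- sweep(X, 2, a)
  CiXc <- CiX - outer(Ci1, a)
  R <- crossprod(Xc, CiXc) / (n - 1)
  if (R[1, 1] <= 0 || R[2, 2] <= 0)
    stop("undefined correlation: zero evolutionary variance")
  r <- R[1, 2] / sqrt(R[1, 1] * R[2, 2])
  r <- max(-1, min(1, r))
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, p_value = p, n_species = n, R = R),
            class = "evolutionary_correlation")
}

#' Apply a per-tree estimator over a sample of trees
#'
#' Comparative estimates are reported as the average over a posterior
#' sample of topologies. Trees are pruned to their common tip set (or to
#' \code{species} if given) before the estimator runs.
#'
#' @param trees A \code{multiPhylo} object or list of \code{phylo} trees.
#' @param op Function taking a tree as first argument and returning a
#'   numeric scalar or vector.
#' @param ... Further arguments passed to \code{op}.
#' @param species Optional tip set to prune each tree to.
#' @return Object of class \code{"tree_summary"}: \code{per_tree}
#'   (matrix, tree x component), \code{mean}, \code{min}, \code{max},
#'   \code{n_trees}.
#' @export
over_trees <- function(trees, op, ..., species = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) == 0L) stop("empty tree collection")
  trees <- prune_to_common(trees, species = species)
  vals <- lapply(trees, function(tr) {
    v <- op(tr, ...)
    if (!is.numeric(v)) stop("estimator must return numeric values")
    v
  })
  per_tree <- do.call(rbind, vals)
  structure(list(per_tree = per_tree,
                 mean = colMeans(per_tree),
                 min = apply(per_tree, 2, min),
                 max = apply(per_tree, 2, max),
                 n_trees = length(trees)), class = "tree_summary")
}

#' Prune a collection of trees to a common tip set
#'
#' @param trees List of \code{phylo} objects or a \code{multiPhylo}.
#' @param species Optional character vector; defaults to the
#'   intersection of all trees' tips.
#' @return List of pruned trees.
#' @export
prune_to_common <- function(trees, species = NULL) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  common <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (!is.null(species)) common <- intersect(common, species)
  if (length(common) < 3L)
    stop("fewer than 3 tips shared across trees")
  lapply(trees, function(tr) {
    if (length(setdiff(tr$tip.label, common)) == 0L) return(tr)
    ape::keep.tip(tr, common)
  })
}

#' Read trees from a Newick or Nexus file
#'
#' Multi-tree files are supported; tip names can be normalised by
#' replacing underscores with spaces or vice versa to match species IDs.
#'
#' @param path File path; Nexus detected from a \code{#NEXUS} header,
#'   Newick otherwise.
#' @param normalize \code{"none"}, \code{"underscore_to_space"} or
#'   \code{"space_to_underscore"}.
#' @return A list of \code{phylo} objects.
#' @export
read_trees <- function(path, normalize = c("none", "underscore_to_space",
                                           "space_to_underscore")) {
  normalize <- match.arg(normalize)
  first <- toupper(trimws(readLines(path, n = 1L)))
  trees <- if (startsWith(first, "#NEXUS")) ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  fix <- switch(normalize,
    none = identity,
    underscore_to_space = function(x) gsub("_", " ", x, fixed = TRUE),
    space_to_underscore = function(x) gsub(" ", "_", x, fixed = TRUE))
  lapply(trees, function(tr) { tr$tip.label <- fix(tr$tip.label); tr })
}
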
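#' Evaluate context-dependent factor loadings
#'
#' The loading of species \eqn{j} on latent factor \eqn{h} is modelled
#' as a linear function of a context vector \eqn{x^*} (leading 1 for the
#' intercept): \eqn{\lambda_{jh}(x^*) = \sum_k x^*_k \lambda_{jhk}}.
#' This evaluates the species-by-factor loading matrix
#' \eqn{\Lambda(x^*) = \sum_k x^*_k \Lambda_k} at a given context.
#'
#' @param lambda_coeffs numeric array of dimension
#'   `c(nc_star, n_species, nf)`: `lambda_coeffs[k, j, h]` is the
#'   coefficient of context covariate `k` for species `j`, factor `h`.
#'   A list of `nc_star` species-by-factor matrices is also accepted.
#' @param x_star numeric context vector of length `nc_star`; its first
#'   element is the intercept and must be 1.
#' @return a species-by-factor numeric matrix \eqn{\Lambda(x^*)}.
#' @seealso [association_matrix()]
#' @export
loadings_at <- function(lambda_coeffs, x_star) {
  lambda_coeffs <- as_lambda_array(lambda_coeffs)
  nc_star <- dim(lambda_coeffs)[1L]
  if (length(x_star) != nc_star) {
    stop("`x_star` has length ", length(x_star),
         " but `lambda_coeffs` expects ", nc_star, " context covariates")
  }
  if (abs(x_star[1L] - 1) > 1e-12) {
    stop("the first element of `x_star` is the intercept and must be 1")
  }
  S <- dim(lambda_coeffs)[2L]
  nf <- dim(lambda_coeffs)[3L]
  out <- matrix(0, S, nf)
  for (k in seq_len(nc_star)) {
    out <- out + x_star[k] * matrix(lambda_coeffs[k, , ], S, nf)
  }
  dimnames(out) <- dimnames(lambda_coeffs)[c(2L, 3L)]
  out
}

as_lambda_array <- function(lambda_coeffs) {
  if (is.list(lambda_coeffs)) {
    dims <- dim(lambda_coeffs[[1L]])
    arr <- array(0, c(length(lambda_coeffs), dims[1L], dims[2L]),
                 dimnames = c(list(NULL), dimnames(lambda_coeffs[[1L]])))
    for (k in seq_along(lambda_coeffs)) {
      if (!identical(dim(lambda_coeffs[[k]]), dims)) {
        stop("all loading coefficient matrices must share dimensions")
      }
      arr[k, , ] <- lambda_coeffs[[k]]
    }
    return(arr)
  }
  if (!is.array(lambda_coeffs) || length(dim(lambda_coeffs)) != 3L) {
    stop("`lambda_coeffs` must be a 3-d array or a list of matrices")
  }
  lambda_coeffs
}

#' Residual correlation matrix implied by a loading matrix
#'
#' Forms the residual covariance \eqn{\Omega = \Lambda \Lambda^T} and
#' scales it to a correlation matrix
#' \eqn{R_{j_1 j_2} = \Omega_{j_1 j_2} / \sqrt{\Omega_{j_1 j_1}
#' \Omega_{j_2 j_2}}}.  \eqn{R} captures co-occurrence between species
#' that the fixed covariate effects do not explain; entries lie in
#' \eqn{[-1, 1]} and the diagonal is exactly 1.
#'
#' @param loadings species-by-factor matrix \eqn{\Lambda}, e.g. from
#'   [loadings_at()].
#' @return symmetric species-by-species correlation matrix.
#' @examples
#' association_matrix(rbind(c(1, 1), c(1, -1)))  # orthogonal: R12 = 0
#' @export
association_matrix <- function(loadings) {
  loadings <- as.matrix(loadings)
  omega <- tcrossprod(loadings)
  d <- diag(omega)
  if (any(d <= 0)) {
    bad <- rownames(loadings)[d <= 0]
    if (is.null(bad)) bad <- which(d <= 0)
    stop("correlation undefined: species with all-zero loadings: ",
         paste(bad, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  r <- omega * tcrossprod(s)
  diag(r) <- 1
  # guard against rounding pushing |r| marginally past 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Bernoulli-probit log likelihood of the latent-factor model
#'
#' Computes \eqn{\sum_{ij} y_{ij} \log \Phi(\eta_{ij}) + (1 - y_{ij})
#' \log(1 - \Phi(\eta_{ij}))} with linear predictor
#' \eqn{\eta_{ij} = \sum_k x_{ik} \beta_{jk} + \sum_h z_{ih}
#' \lambda_{jh}(x^*_i)}.  The predictor is clamped at \eqn{|\eta| = 37}
#' so the log probabilities stay finite.
#'
#' @param beta species-by-covariate fixed-effect matrix.
#' @param lambda_coeffs loading coefficient array, see [loadings_at()].
#' @param z station-by-factor latent score matrix.
#' @param x station-by-covariate design matrix (leading intercept column).
#' @param x_star station-by-context design matrix (leading intercept
#'   column).
#' @param y binary station-by-species matrix.
#' @return the log likelihood (a single number).
#' @export
jsdm_loglik <- function(beta, lambda_coeffs, z, x, x_star, y) {
  lambda_coeffs <- as_lambda_array(lambda_coeffs)
  n <- nrow(y); S <- ncol(y)
  stopifnot(nrow(x) == n, nrow(x_star) == n, nrow(z) == n)
  if (nrow(beta) != S || ncol(beta) != ncol(x)) {
    stop("`beta` must be species x covariate, matching `x`")
  }
  if (dim(lambda_coeffs)[1L] != ncol(x_star) ||
      dim(lambda_coeffs)[2L] != S ||
      dim(lambda_coeffs)[3L] != ncol(z)) {
    stop("`lambda_coeffs` dimensions inconsistent with x_star/z")
  }
  eta <- linear_predictor(beta, lambda_coeffs, z, x, x_star)
  eta <- pmin(pmax(eta, -37), 37)
  sum(ifelse(y == 1,
             stats::pnorm(eta, log.p = TRUE),
             stats::pnorm(-eta, log.p = TRUE)))
}

# eta = X B' + sum_h z_h * lambda_h(x*), computed as W Theta with
# W = [X, z_ih x*_ik] -- shared by the sampler and the likelihood.
linear_predictor <- function(beta, lambda_coeffs, z, x, x_star) {
  eta <- x %*% t(beta)
  nc_star <- dim(lambda_coeffs)[1L]
  nf <- dim(lambda_coeffs)[3L]
  for (k in seq_len(nc_star)) {
    for (h in seq_len(nf)) {
      eta <- eta + (x_star[, k] * z[, h]) %o% lambda_coeffs[k, , h]
    }
  }
  eta
}

#' Tally association signs and significance over species pairs
#'
#' Counts, over the \eqn{S(S-1)/2} unordered species pairs of an
#' association estimate, how many posterior-mean correlations are
#' positive or negative and how many are significant in the sense that
#' the 95\% credible interval excludes zero.  Percentages are rounded to
#' the nearest integer.
#'
#' @param estimate a `cdjsdm_assoc` object from [predict.cdjsdm()], or
#'   any list with elements `R_mean`, `R_lower`, `R_upper`.
#' @return a list with counts `n_pairs`, `positive`, `negative`,
#'   `significant_positive`, `significant_negative` and matching
#'   integer percentages `pct_*` of `n_pairs`.
#' @export
classify_pairs <- function(estimate) {
  R <- estimate$R_mean
  lo <- estimate$R_lower
  hi <- estimate$R_upper
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  ut <- upper.tri(R)
  n_pairs <- sum(ut)
  pos <- sum(R[ut] > 0)
  neg <- sum(R[ut] < 0)
  sig <- !(lo[ut] <= 0 & hi[ut] >= 0)
  sig_pos <- sum(sig & R[ut] > 0)
  sig_neg <- sum(sig & R[ut] < 0)
  pct <- function(k) as.integer(round(100 * k / n_pairs))
  list(n_pairs = n_pairs,
       positive = pos, negative = neg,
       significant_positive = sig_pos, significant_negative = sig_neg,
       pct_positive = pct(pos), pct_negative = pct(neg),
       pct_significant_positive = pct(sig_pos),
       pct_significant_negative = pct(sig_neg))
}

#' Deviance information criterion of a fitted model
#'
#' DIC \eqn{= \bar D + p_D} with deviance \eqn{D = -2 \log L},
#' \eqn{\bar D} the posterior mean deviance and effective parameter
#' count \eqn{p_D = \bar D - D(\hat\theta)} evaluated at the posterior
#' means of \eqn{\beta}, \eqn{\lambda} and \eqn{z}.  Used to compare
#' latent factor counts `nf`; lower is better.  \eqn{p_D} can go
#' slightly negative in pathological multimodal posteriors; a warning is
#' raised if it does.
#'
#' @param object a fitted [cdjsdm()] model.
#' @param thin evaluate the posterior deviance on every `thin`-th draw
#'   (the mean deviance is a Monte-Carlo average; thinning trades a
#'   little precision for speed).
#' @return a list with `dic`, `mean_deviance`, `p_d`.
#' @export
dic <- function(object, thin = 10L) {
  stopifnot(inherits(object, "cdjsdm"))
  idx <- seq(1L, n_draws(object), by = as.integer(thin))
  db <- dim(object$draws$beta); dl <- dim(object$draws$lambda)
  dz <- dim(object$draws$z)
  dev <- vapply(idx, function(d) {
    -2 * jsdm_loglik(matrix(object$draws$beta[d, , ], db[2L], db[3L]),
                     array(object$draws$lambda[d, , , ], dl[-1L]),
                     matrix(object$draws$z[d, , ], dz[2L], dz[3L]),
                     object$x, object$x_star, object$y)
  }, numeric(1))
  mean_dev <- mean(dev)
  beta_hat <- apply(object$draws$beta, c(2L, 3L), mean)
  lambda_hat <- apply(object$draws$lambda, c(2L, 3L, 4L), mean)
  z_hat <- apply(object$draws$z, c(2L, 3L), mean)
  dev_hat <- -2 * jsdm_loglik(beta_hat, lambda_hat, z_hat,
                              object$x, object$x_star, object$y)
  p_d <- mean_dev - dev_hat
  if (p_d < 0) warning("effective parameter count p_D is negative")
  list(dic = mean_dev + p_d, mean_deviance = mean_dev, p_d = p_d)
}
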
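#' Fit a context-dependent joint species distribution model
#'
#' Fits a latent-factor multivariate probit model to a station-by-species
#' presence-absence matrix.  Species \eqn{j} occurs at station \eqn{i}
#' with probability \eqn{\Psi_{ij} = \Phi(\eta_{ij})} where
#' \deqn{\eta_{ij} = \sum_{k=1}^{nc} x_{ik} \beta_{jk} +
#'       \sum_{h=1}^{nf} z_{ih} \lambda_{jh}(x^*_i),}
#' \eqn{z_{ih}} are station-level latent factor scores and the factor
#' loadings are themselves linear in a context vector \eqn{x^*_i}
#' (intercept plus disturbance covariates):
#' \eqn{\lambda_{jh}(x^*_i) = \sum_k x^*_{ik} \lambda_{jhk}}.  Residual
#' associations between species therefore vary along the disturbance
#' gradient; they are recovered at any context with
#' [predict.cdjsdm()].
#'
#' Priors are independent normals: \eqn{\beta \sim N(0,
#' \code{prior_sd_beta}^2)}, \eqn{\lambda \sim N(0,
#' \code{prior_sd_lambda}^2)}, \eqn{z \sim N(0, 1)}.  Posterior draws
#' come from a fully conjugate Gibbs sampler using probit data
#' augmentation: the latent continuous response \eqn{y^*_{ij} \sim
#' N(\eta_{ij}, 1)} truncated by the observed presence/absence is
#' sampled, after which the \eqn{(\beta, \lambda)} block and the
#' \eqn{z} block each have closed-form multivariate-normal conditional
#' distributions.  With a fixed `seed` the draws are exactly
#' reproducible.
#'
#' The loadings are not rotation-identified (no triangular constraint
#' is imposed); every reported quantity -- \eqn{R}, occurrence
#' probabilities, DIC -- is invariant to rotation of the factors, and
#' association matrices are always computed per draw before averaging.
#'
#' @param y binary station-by-species matrix (column names = species).
#' @param covariates covariate table from [transform_covariates()], or
#'   any data frame whose first column may be `station_id` and that
#'   contains an `intercept` column of ones plus standardized
#'   covariate columns.
#' @param context names of the covariate columns whose gradient the
#'   associations may follow (the context vector \eqn{x^*} is the
#'   intercept plus these columns).  Raw names without the `_z`/`_logz`
#'   suffix are matched to their standardized columns.
#' @param nf number of latent factors.
#' @param n_chains,n_burn,n_samples MCMC chains, burn-in iterations
#'   discarded per chain, and retained draws per chain.
#' @param prior_sd_beta,prior_sd_lambda prior standard deviations of
#'   the fixed effects and loading coefficients.
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param verbose print progress per chain.
#' @return an object of class `"cdjsdm"`: a list with posterior draw
#'   arrays (`draws$beta`, `draws$lambda`, `draws$z`), the design
#'   matrices, species/covariate names, split R-hat per fixed-effect
#'   parameter (`convergence`), and the call.
#' @references The model partitions co-occurrence into shared
#'   environmental responses (the \eqn{\beta} terms) and residual
#'   correlation (the latent-factor term), with the residual part free
#'   to change along the disturbance gradient.
#' @examples
#' \donttest{
#' sim <- sim_community(sim_config(n_stations = 150, n_species = 4,
#'                                 n_factors = 2, seed = 1),
#'                      sim_covariates(150, seed = 1))
#' fit <- cdjsdm(sim$occupancy, sim$covariates, nf = 2,
#'               n_chains = 2, n_burn = 200, n_samples = 300, seed = 1)
#' summary(fit)
#' }
#' @export
cdjsdm <- function(y, covariates,
                   context = c("human_modification", "human_presence"),
                   nf = 3L,
                   n_chains = 3L, n_burn = 2000L, n_samples = 3000L,
                   prior_sd_beta = 2.5, prior_sd_lambda = 1.0,
                   seed = 1L, verbose = FALSE) {
  y <- as.matrix(y)
  if (!all(y %in% c(0, 1))) stop("`y` must be a binary 0/1 matrix")
  if (ncol(y) < 2L) stop("at least two species are required")
  if (nf < 1L) stop("`nf` must be at least 1")
  if (prior_sd_beta <= 0 || prior_sd_lambda <= 0) {
    stop("prior standard deviations must be positive")
  }
  dm <- design_matrices(covariates, context)
  if (nrow(dm$x) != nrow(y)) {
    stop("`y` and `covariates` must describe the same stations ",
         "(", nrow(y), " vs ", nrow(dm$x), " rows)")
  }
  n <- nrow(y); S <- ncol(y)
  nc <- ncol(dm$x); nc_star <- ncol(dm$x_star)

  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    if (verbose) message("chain ", ch, "/", n_chains)
    chains[[ch]] <- gibbs_chain(y, dm$x, dm$x_star, nf,
                                n_burn, n_samples,
                                prior_sd_beta, prior_sd_lambda,
                                seed = as.integer(seed) + ch - 1L)
  }

  draws <- list(
    beta = abind_first(lapply(chains, `[[`, "beta")),
    lambda = abind_first(lapply(chains, `[[`, "lambda")),
    z = abind_first(lapply(chains, `[[`, "z"))
  )
  dimnames(draws$beta) <- list(NULL, colnames(y), colnames(dm$x))
  dimnames(draws$lambda) <- list(NULL, colnames(dm$x_star), colnames(y), NULL)

  rhat <- beta_rhat(lapply(chains, `[[`, "beta"))
  dimnames(rhat) <- list(colnames(y), colnames(dm$x))
  conv <- list(rhat_beta = rhat, max_rhat = max(rhat),
               converged = max(rhat) < 1.1)
  if (!conv$converged) {
    warning("split R-hat exceeds 1.1 for some fixed effects (max ",
            format(conv$max_rhat, digits = 4), ")")
  }

  structure(list(
    call = match.call(),
    y = y, x = dm$x, x_star = dm$x_star,
    species = colnames(y),
    covariate_names = colnames(dm$x),
    context_names = colnames(dm$x_star),
    nf = as.integer(nf),
    n_chains = as.integer(n_chains),
    n_burn = as.integer(n_burn),
    n_samples = as.integer(n_samples),
    prior_sd_beta = prior_sd_beta, prior_sd_lambda = prior_sd_lambda,
    seed = as.integer(seed),
    draws = draws,
    convergence = conv
  ), class = "cdjsdm")
}

# Resolve the fixed-effect design matrix (intercept + all standardized
# covariates) and the context design matrix (intercept + the named
# context columns) from a covariate table.
design_matrices <- function(covariates, context) {
  cv <- as.data.frame(covariates)
  if ("station_id" %in% names(cv)) {
    rownames(cv) <- cv$station_id
    cv$station_id <- NULL
  }
  if (!"intercept" %in% names(cv)) {
    stop("covariate table must contain an `intercept` column")
  }
  num <- vapply(cv, is.numeric, logical(1))
  cv <- cv[num]
  x <- as.matrix(cv)
  ctx_cols <- vapply(context, function(nm) {
    hit <- which(names(cv) == nm |
                 names(cv) == paste0(nm, "_z") |
                 names(cv) == paste0(nm, "_logz"))
    if (length(hit) != 1L) {
      stop("context covariate `", nm, "` not found in the covariate table")
    }
    hit
  }, integer(1))
  x_star <- cbind(intercept = 1, x[, ctx_cols, drop = FALSE])
  list(x = x, x_star = x_star)
}

# One chain of the Albert-Chib Gibbs sampler.  Parameterisation:
# Theta (p x S) stacks beta (nc rows) over lambda coefficients
# (nf * nc_star rows, row index m = (k - 1) * nf + h for lambda_jhk),
# so that eta = W Theta with W = [X, z_ih * xstar_ik].
gibbs_chain <- function(y, x, x_star, nf, n_burn, n_samples,
                        prior_sd_beta, prior_sd_lambda, seed) {
  set.seed(seed)
  n <- nrow(y); S <- ncol(y)
  nc <- ncol(x); nc_star <- ncol(x_star)
  p <- nc + nf * nc_star
  prior_prec <- diag(c(rep(1 / prior_sd_beta^2, nc),
                       rep(1 / prior_sd_lambda^2, nf * nc_star)), p)

  theta <- matrix(0, p, S)
  z <- matrix(0, n, nf)
  y1 <- y == 1

  beta_out <- array(NA_real_, c(n_samples, S, nc))
  lambda_out <- array(NA_real_, c(n_samples, nc_star, S, nf))
  z_out <- array(NA_real_, c(n_samples, n, nf))

  total <- n_burn + n_samples
  for (it in seq_len(total)) {
    W <- make_w(x, x_star, z, nf)
    eta <- W %*% theta

    ## 1. latent continuous response, truncated by y
    plo <- stats::pnorm(-eta)                      # P(y* - eta < -eta)
    u <- matrix(stats::runif(n * S), n, S)
    q <- ifelse(y1, plo + u * (1 - plo), u * plo)
    q <- pmin(pmax(q, 1e-300), 1 - 1e-16)
    ystar <- eta + stats::qnorm(q)

    ## 2. joint (beta, lambda) update, conjugate across all species
    A <- crossprod(W) + prior_prec
    U <- chol(A)
    mu <- backsolve(U, forwardsolve(t(U), crossprod(W, ystar)))
    theta <- mu + backsolve(U, matrix(stats::rnorm(p * S), p, S))

    ## 3. latent factor scores, station by station (batched)
    lam <- theta_lambda(theta, nc, nc_star, nf)    # [k, j, h]
    z <- draw_z(ystar - x %*% theta[seq_len(nc), , drop = FALSE],
                x_star, lam, nf)

    if (it > n_burn) {
      d <- it - n_burn
      beta_out[d, , ] <- t(theta[seq_len(nc), , drop = FALSE])
      lambda_out[d, , , ] <- lam
      z_out[d, , ] <- z
    }
  }
  list(beta = beta_out, lambda = lambda_out, z = z_out)
}

# W = [X | z_ih * xstar_ik], lambda-block column m = (k - 1) * nf + h.
make_w <- function(x, x_star, z, nf) {
  n <- nrow(x); nc_star <- ncol(x_star)
  zw <- matrix(0, n, nf * nc_star)
  for (k in seq_len(nc_star)) {
    for (h in seq_len(nf)) {
      zw[, (k - 1L) * nf + h] <- x_star[, k] * z[, h]
    }
  }
  cbind(x, zw)
}

# Reshape the lambda block of Theta into the [k, j, h] coefficient array.
theta_lambda <- function(theta, nc, nc_star, nf) {
  S <- ncol(theta)
  lam <- array(0, c(nc_star, S, nf))
  for (k in seq_len(nc_star)) {
    for (h in seq_len(nf)) {
      lam[k, , h] <- theta[nc + (k - 1L) * nf + h, ]
    }
  }
  lam
}

# Conditional draw of the latent scores: z_i ~ N(M_i^-1 b_i, M_i^-1)
# with M_i = I + Lambda_i' Lambda_i, b_i = Lambda_i' r_i, and
# Lambda_i = sum_k xstar_ik Lambda_k.  All stations are processed at
# once: M is an n x nf x nf stack assembled from the nc_star^2 Gram
# blocks Lambda_k' Lambda_l, followed by a vectorised Cholesky sweep
# over the nf x nf stack.
draw_z <- function(resid, x_star, lam, nf) {
  n <- nrow(resid); nc_star <- ncol(x_star)
  M <- array(0, c(n, nf, nf))
  for (h in seq_len(nf)) M[, h, h] <- 1
  for (k in seq_len(nc_star)) {
    Lk <- matrix(lam[k, , ], ncol = nf)
    for (l in seq_len(nc_star)) {
      G <- crossprod(Lk, matrix(lam[l, , ], ncol = nf))  # nf x nf
      w <- x_star[, k] * x_star[, l]
      for (a in seq_len(nf)) for (b in seq_len(nf)) {
        M[, a, b] <- M[, a, b] + w * G[a, b]
      }
    }
  }
  b <- matrix(0, n, nf)
  for (k in seq_len(nc_star)) {
    b <- b + x_star[, k] * (resid %*% matrix(lam[k, , ], ncol = nf))
  }

  ## batched Cholesky M = L L'
  L <- array(0, c(n, nf, nf))
  for (j in seq_len(nf)) {
    s <- M[, j, j]
    if (j > 1L) for (k in seq_len(j - 1L)) s <- s - L[, j, k]^2
    L[, j, j] <- sqrt(s)
    if (j < nf) for (i in (j + 1L):nf) {
      s <- M[, i, j]
      if (j > 1L) for (k in seq_len(j - 1L)) s <- s - L[, i, k] * L[, j, k]
      L[, i, j] <- s / L[, j, j]
    }
  }
  ## solve L v = b (forward), then L' m = v (backward) for the mean
  v <- matrix(0, n, nf)
  for (i in seq_len(nf)) {
    s <- b[, i]
    if (i > 1L) for (k in seq_len(i - 1L)) s <- s - L[, i, k] * v[, k]
    v[, i] <- s / L[, i, i]
  }
  m <- matrix(0, n, nf)
  for (i in rev(seq_len(nf))) {
    s <- v[, i]
    if (i < nf) for (k in (i + 1L):nf) s <- s - L[, k, i] * m[, k]
    m[, i] <- s / L[, i, i]
  }
  ## draw: z = m + solve(L', eps), eps ~ N(0, I)
  eps <- matrix(stats::rnorm(n * nf), n, nf)
  w <- matrix(0, n, nf)
  for (i in rev(seq_len(nf))) {
    s <- eps[, i]
    if (i < nf) for (k in (i + 1L):nf) s <- s - L[, k, i] * w[, k]
    w[, i] <- s / L[, i, i]
  }
  m + w
}

# Concatenate arrays along their first (draw) dimension.  Column-major
# storage makes each array a draws x rest matrix, so rbind + re-dim.
abind_first <- function(arrs) {
  rest <- dim(arrs[[1L]])[-1L]
  stacked <- do.call(rbind, lapply(arrs, function(a) {
    matrix(a, nrow = dim(a)[1L])
  }))
  array(stacked, c(nrow(stacked), rest))
}

# Split R-hat per scalar beta parameter, computed across chains.
beta_rhat <- function(beta_chains) {
  d <- dim(beta_chains[[1L]])          # draws x S x nc
  S <- d[2L]; nc <- d[3L]
  out <- matrix(NA_real_, S, nc)
  for (j in seq_len(S)) for (k in seq_len(nc)) {
    halves <- unlist(lapply(beta_chains, function(ch) {
      v <- ch[, j, k]
      half <- length(v) %/% 2L
      list(v[seq_len(half)], v[half + seq_len(half)])
    }), recursive = FALSE)
    out[j, k] <- rhat_from_chains(halves)
  }
  out
}

rhat_from_chains <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1L]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  B <- n * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((n - 1) / n * Wv + B / n) / Wv)
}

n_draws <- function(object) dim(object$draws$beta)[1L]
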
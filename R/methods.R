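#' @export
print.cdjsdm <- function(x, ...) {
  cat("Context-dependent joint species distribution model\n")
  cat(sprintf("  %d stations, %d species, %d latent factors\n",
              nrow(x$y), length(x$species), x$nf))
  cat(sprintf("  fixed effects: %s\n",
              paste(x$covariate_names, collapse = ", ")))
  cat(sprintf("  context (loadings): %s\n",
              paste(x$context_names, collapse = ", ")))
  cat(sprintf("  posterior: %d chains x %d draws (burn-in %d); max R-hat %.3f\n",
              x$n_chains, x$n_samples, x$n_burn, x$convergence$max_rhat))
  invisible(x)
}

#' Posterior summary of the fixed effects
#'
#' Posterior mean, 95\% equal-tailed credible interval and split R-hat
#' for every species-by-covariate fixed effect (probit linear scale).
#'
#' @param object a fitted [cdjsdm()] model.
#' @param ... unused.
#' @return a data frame with one row per species x covariate, columns
#'   `species`, `covariate`, `mean`, `lower`, `upper`, `rhat`,
#'   `significant` (95\% CI excludes zero).
#' @export
summary.cdjsdm <- function(object, ...) {
  b <- object$draws$beta
  S <- length(object$species); nc <- length(object$covariate_names)
  rows <- expand.grid(species = object$species,
                      covariate = object$covariate_names,
                      stringsAsFactors = FALSE)
  rows$mean <- NA_real_; rows$lower <- NA_real_; rows$upper <- NA_real_
  rows$rhat <- NA_real_
  for (r in seq_len(nrow(rows))) {
    j <- match(rows$species[r], object$species)
    k <- match(rows$covariate[r], object$covariate_names)
    dr <- b[, j, k]
    rows$mean[r] <- mean(dr)
    qs <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    rows$lower[r] <- qs[1L]; rows$upper[r] <- qs[2L]
    rows$rhat[r] <- object$convergence$rhat_beta[j, k]
  }
  rows$significant <- rows$lower > 0 | rows$upper < 0
  class(rows) <- c("summary.cdjsdm", "data.frame")
  rows
}

#' @export
print.summary.cdjsdm <- function(x, digits = 3, ...) {
  cat("Fixed effects (posterior mean and 95% CI, probit scale)\n")
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits); y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits); y$rhat <- round(y$rhat, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.cdjsdm <- function(object, ...) {
  apply(object$draws$beta, c(2L, 3L), mean)
}

#' Posterior association matrices at a disturbance context
#'
#' Builds the context vector \eqn{x^*} with the named disturbance
#' covariate set to the minimum, mean or maximum observed in the fitted
#' data (on the standardized scale) and any other context covariate
#' held at its mean (0 after standardization), evaluates the loading
#' matrix and the residual correlation matrix \eqn{R} for every
#' posterior draw, and summarises elementwise by the posterior mean and
#' the 2.5/97.5 percentiles.
#'
#' @param object a fitted [cdjsdm()] model.
#' @param context name of the context covariate to vary (one of the
#'   model's context columns; raw names match their standardized
#'   columns).
#' @param level `"min"`, `"mean"` or `"max"` of the observed gradient.
#' @param ... unused.
#' @return an object of class `"cdjsdm_assoc"`: list with `context`
#'   (the named x* vector used), `R_mean`, `R_lower`, `R_upper`
#'   (species-by-species matrices) and `significant` (logical matrix,
#'   95\% CI excludes zero).
#' @export
predict.cdjsdm <- function(object, context = "human_modification",
                           level = c("mean", "min", "max"), ...) {
  level <- match.arg(level)
  ctx <- resolve_context(object$context_names, context)
  x_star <- stats::setNames(numeric(length(object$context_names)),
                            object$context_names)
  x_star["intercept"] <- 1
  other <- setdiff(object$context_names, c("intercept", ctx))
  for (nm in other) x_star[nm] <- mean(object$x_star[, nm])
  obs <- object$x_star[, ctx]
  x_star[ctx] <- switch(level, min = min(obs), mean = mean(obs),
                        max = max(obs))
  association_summary(object, x_star)
}

resolve_context <- function(context_names, context) {
  hit <- which(context_names == context |
               context_names == paste0(context, "_z") |
               context_names == paste0(context, "_logz"))
  if (length(hit) != 1L) {
    stop("unknown context covariate `", context, "`; model contexts: ",
         paste(setdiff(context_names, "intercept"), collapse = ", "))
  }
  context_names[hit]
}

# Per-draw R summarised elementwise; R is computed for every draw and
# only then averaged (loadings are never averaged across draws).
association_summary <- function(object, x_star) {
  S <- length(object$species)
  nd <- n_draws(object)
  dl <- dim(object$draws$lambda)
  acc <- matrix(0, S, S)
  ut <- upper.tri(acc)
  draws_ut <- matrix(NA_real_, nd, sum(ut))
  for (d in seq_len(nd)) {
    lam <- array(object$draws$lambda[d, , , ], dl[-1L])
    R <- association_matrix(loadings_at(lam, x_star))
    acc <- acc + R
    draws_ut[d, ] <- R[ut]
  }
  R_mean <- acc / nd
  qs <- apply(draws_ut, 2L, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  R_lower <- R_upper <- diag(1, S)
  R_lower[ut] <- qs[1L, ]; R_upper[ut] <- qs[2L, ]
  R_lower <- sym_from_upper(R_lower)
  R_upper <- sym_from_upper(R_upper)
  dimnames(R_mean) <- dimnames(R_lower) <- dimnames(R_upper) <-
    list(object$species, object$species)
  sig <- !(R_lower <= 0 & R_upper >= 0)
  diag(sig) <- FALSE
  structure(list(context = x_star, R_mean = R_mean,
                 R_lower = R_lower, R_upper = R_upper,
                 significant = sig),
            class = "cdjsdm_assoc")
}

sym_from_upper <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' @export
print.cdjsdm_assoc <- function(x, ...) {
  cat("Residual species associations at context:\n")
  print(round(x$context, 3))
  counts <- classify_pairs(x)
  cat(sprintf("  %d pairs: %d positive (%d%%), %d negative (%d%%)\n",
              counts$n_pairs, counts$positive, counts$pct_positive,
              counts$negative, counts$pct_negative))
  cat(sprintf("  significant (95%% CI excludes 0): %d positive, %d negative\n",
              counts$significant_positive, counts$significant_negative))
  invisible(x)
}

#' Heat-map of an association matrix
#'
#' @param x a `cdjsdm_assoc` object.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot.cdjsdm_assoc <- function(x, main = "residual associations", ...) {
  R <- x$R_mean
  S <- ncol(R)
  pal <- grDevices::hcl.colors(101, "Blue-Red 3")
  graphics::image(seq_len(S), seq_len(S), t(R[S:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main, ...)
  graphics::axis(1, at = seq_len(S), labels = colnames(R), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(S), labels = rev(rownames(R)), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' @export
plot.cdjsdm <- function(x, context = "human_modification",
                        level = "mean", ...) {
  plot(predict(x, context = context, level = level),
       main = paste0("R at ", level, " ", context), ...)
}

#' Posterior-mean occurrence probabilities and residuals
#'
#' `fitted()` returns the posterior mean of \eqn{\Psi_{ij} =
#' \Phi(\eta_{ij})} (averaged over draws, including the latent scores);
#' `residuals()` returns the raw residuals \eqn{y - \hat\Psi}.
#'
#' @param object a fitted [cdjsdm()] model.
#' @param thin use every `thin`-th draw.
#' @param ... unused.
#' @export
fitted.cdjsdm <- function(object, thin = 10L, ...) {
  idx <- seq(1L, n_draws(object), by = as.integer(thin))
  db <- dim(object$draws$beta); dl <- dim(object$draws$lambda)
  dz <- dim(object$draws$z)
  acc <- matrix(0, nrow(object$y), ncol(object$y))
  for (d in idx) {
    eta <- linear_predictor(
      matrix(object$draws$beta[d, , ], db[2L], db[3L]),
      array(object$draws$lambda[d, , , ], dl[-1L]),
      matrix(object$draws$z[d, , ], dz[2L], dz[3L]),
      object$x, object$x_star)
    acc <- acc + stats::pnorm(eta)
  }
  psi <- acc / length(idx)
  dimnames(psi) <- dimnames(object$y)
  psi
}

#' @rdname fitted.cdjsdm
#' @export
residuals.cdjsdm <- function(object, thin = 10L, ...) {
  object$y - fitted(object, thin = thin)
}

#' @export
logLik.cdjsdm <- function(object, thin = 10L, ...) {
  idx <- seq(1L, n_draws(object), by = as.integer(thin))
  db <- dim(object$draws$beta); dl <- dim(object$draws$lambda)
  dz <- dim(object$draws$z)
  ll <- mean(vapply(idx, function(d) {
    jsdm_loglik(matrix(object$draws$beta[d, , ], db[2L], db[3L]),
                array(object$draws$lambda[d, , , ], dl[-1L]),
                matrix(object$draws$z[d, , ], dz[2L], dz[3L]),
                object$x, object$x_star, object$y)
  }, numeric(1)))
  structure(ll, df = NA, class = "logLik")
}

#' Posterior-predictive presence-absence matrices
#'
#' Draws replicate presence-absence matrices from randomly selected
#' posterior draws (conditional on the fitted latent scores).
#'
#' @param object a fitted [cdjsdm()] model.
#' @param nsim number of replicate matrices.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` binary matrices.
#' @export
simulate.cdjsdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  db <- dim(object$draws$beta); dl <- dim(object$draws$lambda)
  dz <- dim(object$draws$z)
  picks <- sample.int(n_draws(object), nsim, replace = TRUE)
  lapply(picks, function(d) {
    eta <- linear_predictor(
      matrix(object$draws$beta[d, , ], db[2L], db[3L]),
      array(object$draws$lambda[d, , , ], dl[-1L]),
      matrix(object$draws$z[d, , ], dz[2L], dz[3L]),
      object$x, object$x_star)
    y <- matrix(stats::rbinom(length(eta), 1L, stats::pnorm(eta)),
                nrow(eta), ncol(eta))
    dimnames(y) <- dimnames(object$y)
    y
  })
}
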
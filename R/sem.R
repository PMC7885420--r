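#' Structural equation model for transcription rate and half-life
#'
#' A linear-Gaussian path model on the natural-log scale. For a TU with
#' feature row x (first entry the intercept X0 = 1):
#' \deqn{b = x \lambda + \epsilon_b, \quad t_{1/2} = x \mu + \epsilon_t,
#'       \quad m = b + t_{1/2} + C}
#' with C fixed at 0 (an arbitrary constant absorbed into the half-life
#' intercept). Replicate observations are log PRO-seq and log RNA-seq TPMs,
#' \eqn{p_j = b + \epsilon_p} and \eqn{r_j = m + \epsilon_r}, with all four
#' epsilon terms independent zero-mean Gaussians. The TU-level terms
#' \eqn{\epsilon_b, \epsilon_t} induce the correlation structure between
#' replicates and between assays; \eqn{\epsilon_p, \epsilon_r} are
#' assay-specific measurement noise.
#'
#' @param lambda numeric vector of transcription coefficients (intercept
#'   first).
#' @param mu numeric vector of half-life coefficients, same length.
#' @param sigma_b,sigma_t,sigma_p,sigma_r non-negative standard deviations of the
#'   TU-level transcription and half-life effects and the PRO-seq / RNA-seq
#'   observation noise.
#' @return list of class `"sem_model"`.
#' @export
sem_model <- function(lambda, mu, sigma_b, sigma_t, sigma_p, sigma_r) {
  stopifnot(length(lambda) == length(mu),
            sigma_b >= 0, sigma_t >= 0, sigma_p >= 0, sigma_r >= 0)
  structure(list(lambda = as.numeric(lambda), mu = as.numeric(mu),
                 sigma_b = sigma_b, sigma_t = sigma_t,
                 sigma_p = sigma_p, sigma_r = sigma_r),
            class = "sem_model")
}

sem_cov <- function(sigma_b, sigma_t, sigma_p, sigma_r, J_p, J_r) {
  J <- J_p + J_r
  k <- c(rep(0, J_p), rep(1, J_r))
  S <- matrix(sigma_b^2, J, J) + sigma_t^2 * tcrossprod(k) +
    diag(c(rep(sigma_p^2, J_p), rep(sigma_r^2, J_r)), nrow = J)
  S
}

#' Marginal distribution of replicate observations under the SEM
#'
#' Integrating out the TU-level effects gives a multivariate normal for the
#' stacked vector (p_1..p_Jp, r_1..r_Jr): means `x lambda` for PRO-seq and
#' `x (lambda + mu)` for RNA-seq; covariance with `var(p) = sb^2 + sp^2`,
#' `cov(p, p') = cov(p, r) = sb^2`, `var(r) = sb^2 + st^2 + sr^2`,
#' `cov(r, r') = sb^2 + st^2`.
#'
#' @param model a [sem_model()].
#' @param x feature row (length matching `model$lambda`).
#' @param J_p,J_r replicate counts.
#' @return list with `mean` (length `J_p + J_r`) and `cov` (symmetric
#'   positive-definite matrix).
#' @export
sem_marginal <- function(model, x, J_p, J_r) {
  stopifnot(length(x) == length(model$lambda), J_p >= 0, J_r >= 0)
  mp <- sum(x * model$lambda)
  mr <- mp + sum(x * model$mu)
  S <- sem_cov(model$sigma_b, model$sigma_t, model$sigma_p, model$sigma_r,
               J_p, J_r)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  stopifnot(all(ev > 0))
  list(mean = c(rep(mp, J_p), rep(mr, J_r)), cov = S)
}

#' Bundle aligned SEM observations
#'
#' @param X feature matrix (TUs x features) whose first column is the
#'   intercept (all 1).
#' @param p,r matrices of log PRO-seq / log RNA-seq TPMs (TUs x replicates).
#'   `NA` entries mark missing replicates; a TU must have at least one finite
#'   observation.
#' @return list of class `"sem_observations"`.
#' @export
sem_observations <- function(X, p, r) {
  X <- as.matrix(X); p <- as.matrix(p); r <- as.matrix(r)
  stopifnot(nrow(X) == nrow(p), nrow(X) == nrow(r))
  if (!all(X[, 1L] == 1)) stop("first feature column must be the intercept")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (any(is.nan(p)) || any(is.infinite(p)) ||
      any(is.nan(r)) || any(is.infinite(r)))
    stop("non-finite observations; exclude zero-TPM TUs upstream")
  if (any(rowSums(is.finite(p)) + rowSums(is.finite(r)) == 0))
    stop("TU with no finite observations")
  structure(list(X = X, p = p, r = r), class = "sem_observations")
}

# Split TUs by missing-replicate pattern; each group shares one covariance.
sem_groups <- function(obs) {
  Y <- cbind(obs$p, obs$r)
  J_p <- ncol(obs$p)
  fin <- is.finite(Y)
  pat <- apply(fin, 1L, paste, collapse = "")
  lapply(split(seq_len(nrow(Y)), pat), function(idx) {
    cols <- which(fin[idx[1L], ])
    list(rows = idx, cols = cols,
         J_p = sum(cols <= J_p), J_r = sum(cols > J_p),
         Y = Y[idx, cols, drop = FALSE],
         X = obs$X[idx, , drop = FALSE])
  })
}

sem_loglik_groups <- function(lambda, mu, sigmas, groups) {
  ll <- 0
  for (g in groups) {
    S <- sem_cov(sigmas[1], sigmas[2], sigmas[3], sigmas[4], g$J_p, g$J_r)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    W <- chol2inv(ch)
    logdet <- 2 * sum(log(diag(ch)))
    kcol <- c(rep(0, g$J_p), rep(1, g$J_r))
    M <- outer(as.vector(g$X %*% lambda), rep(1, length(kcol))) +
      outer(as.vector(g$X %*% mu), kcol)
    Rm <- g$Y - M
    quad <- sum((Rm %*% W) * Rm)
    n_g <- nrow(g$Y); J_g <- ncol(g$Y)
    ll <- ll - 0.5 * (n_g * (J_g * log(2 * pi) + logdet) + quad)
  }
  ll
}

# GLS estimate of (lambda, mu) given the variance components.
sem_gls <- function(sigmas, groups, q) {
  A <- matrix(0, 2 * q, 2 * q)
  rhs <- numeric(2 * q)
  for (g in groups) {
    S <- sem_cov(sigmas[1], sigmas[2], sigmas[3], sigmas[4], g$J_p, g$J_r)
    W <- chol2inv(chol(S))
    K <- cbind(1, c(rep(0, g$J_p), rep(1, g$J_r)))
    G <- crossprod(K, W %*% K)
    XtX <- crossprod(g$X)
    A <- A + kronecker(G, XtX)
    B <- crossprod(g$X, g$Y %*% (W %*% K))  # q x 2
    rhs <- rhs + as.vector(B)
  }
  theta <- solve(A, rhs)
  list(lambda = theta[seq_len(q)], mu = theta[q + seq_len(q)])
}

#' Log-likelihood of SEM observations
#'
#' Sum over TUs of the multivariate-normal log-density implied by
#' [sem_marginal()]; TUs are independent, so the result is invariant to row
#' permutation and additive over duplicated rows.
#'
#' @param model a [sem_model()].
#' @param obs a [sem_observations()].
#' @return scalar log-likelihood.
#' @export
sem_loglik <- function(model, obs) {
  groups <- sem_groups(obs)
  sem_loglik_groups(model$lambda, model$mu,
                    c(model$sigma_b, model$sigma_t, model$sigma_p,
                      model$sigma_r), groups)
}

#' Fit the SEM by maximum likelihood
#'
#' The coefficients (lambda, mu) are profiled out analytically: for fixed
#' variance components their ML estimate is a generalized-least-squares
#' solve, so the optimizer works over the four log standard deviations only
#' (quasi-Newton with box constraints, three deterministic starts).
#' Standard errors come from the inverse observed information (numerical
#' Hessian of the full likelihood at the optimum); Z-scores and two-sided
#' normal p-values follow, with significance stars at p < 0.05 (*),
#' p < 0.005 (**) and p < 0.0005 (***).
#'
#' Continuous features are z-score standardized by default so coefficient
#' magnitudes are comparable across heterogeneous features; the centers and
#' scales used are returned. Coefficients are on the natural-log scale unless
#' `log2_report = TRUE` (division by ln 2).
#'
#' @param obs a [sem_observations()].
#' @param standardize standardize non-intercept feature columns (default
#'   `TRUE`).
#' @param log2_report report coefficients per log2 unit (default `FALSE`).
#' @param gtol gradient-norm convergence tolerance.
#' @return list of class `"sem_fit"`: `model` (a [sem_model()] at the ML
#'   estimate), `se_lambda`, `se_mu`, `z_lambda`, `z_mu`, `p_lambda`, `p_mu`,
#'   `stars_lambda`, `stars_mu`, `loglik`, `n_tus`, `converged`,
#'   `standardize`, `centers`, `scales`.
#' @export
sem_fit <- function(obs, standardize = TRUE, log2_report = FALSE,
                    gtol = 1e-8) {
  X <- obs$X
  q <- ncol(X)
  qr_X <- qr(X)
  if (qr_X$rank < q) {
    bad <- setdiff(seq_len(q), qr_X$pivot[seq_len(qr_X$rank)])
    stop("singular feature matrix; collinear column(s): ",
         paste(colnames(X)[bad] %||% bad, collapse = ", "))
  }
  centers <- rep(0, q); scales <- rep(1, q)
  if (standardize && q > 1L) {
    for (j in 2:q) {
      sdj <- stats::sd(X[, j])
      if (sdj > 0) {
        centers[j] <- mean(X[, j]); scales[j] <- sdj
        X[, j] <- (X[, j] - centers[j]) / sdj
      }
    }
  }
  obs2 <- obs; obs2$X <- X
  groups <- sem_groups(obs2)

  # moment-based initialization
  pbar <- rowMeans(obs$p, na.rm = TRUE)
  rbar <- rowMeans(obs$r, na.rm = TRUE)
  lam0 <- qr.coef(qr(X), pbar)
  del0 <- qr.coef(qr(X), rbar)
  wvar <- function(m) {
    v <- apply(m, 1L, stats::var, na.rm = TRUE)
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else 0.01
  }
  sp0 <- sqrt(max(wvar(obs$p), 1e-4))
  sr0 <- sqrt(max(wvar(obs$r), 1e-4))
  sb0 <- sqrt(max(stats::var(pbar - X %*% lam0) - sp0^2 / ncol(obs$p), 1e-4))
  st0 <- sqrt(max(stats::var(rbar - pbar - X %*% (del0 - lam0)) -
                    sp0^2 / ncol(obs$p) - sr0^2 / ncol(obs$r), 1e-4))
  init <- log(c(sb0, st0, sp0, sr0))

  negloglik_sig <- function(ls) {
    sig <- exp(ls)
    th <- tryCatch(sem_gls(sig, groups, q), error = function(e) NULL)
    if (is.null(th)) return(1e10)
    -sem_loglik_groups(th$lambda, th$mu, sig, groups)
  }
  starts <- list(init, init + 0.7, init - 0.7)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negloglik_sig, method = "L-BFGS-B",
                   lower = rep(-12, 4), upper = rep(6, 4),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("SEM optimization failed from all starts")
  sig_hat <- exp(best$par)
  th_hat <- sem_gls(sig_hat, groups, q)

  # observed information over the full parameter vector
  full_neg <- function(par) {
    lam <- par[seq_len(q)]; mu <- par[q + seq_len(q)]
    sig <- exp(par[2 * q + 1:4])
    -sem_loglik_groups(lam, mu, sig, groups)
  }
  par_hat <- c(th_hat$lambda, th_hat$mu, log(sig_hat))
  H <- stats::optimHess(par_hat, full_neg)
  Vall <- tryCatch(solve(H), error = function(e) matrix(NA_real_,
                                                        length(par_hat),
                                                        length(par_hat)))
  se <- sqrt(pmax(diag(Vall), 0))
  grad_ok <- {
    eps <- 1e-5
    g <- vapply(seq_len(4), function(i) {
      e <- numeric(4); e[i] <- eps
      (negloglik_sig(best$par + e) - negloglik_sig(best$par - e)) / (2 * eps)
    }, numeric(1))
    sqrt(sum(g^2)) < max(gtol * abs(best$value), 1e-3)
  }

  scl <- if (log2_report) log(2) else 1
  lam <- th_hat$lambda / scl; mu <- th_hat$mu / scl
  se_lam <- se[seq_len(q)] / scl
  se_mu <- se[q + seq_len(q)] / scl
  z_lam <- lam / se_lam; z_mu <- mu / se_mu
  p_lam <- 2 * stats::pnorm(-abs(z_lam))
  p_mu <- 2 * stats::pnorm(-abs(z_mu))
  stars <- function(p) ifelse(p < 5e-4, "***",
                       ifelse(p < 5e-3, "**",
                       ifelse(p < 5e-2, "*", "")))
  structure(list(
    model = sem_model(th_hat$lambda, th_hat$mu, sig_hat[1], sig_hat[2],
                      sig_hat[3], sig_hat[4]),
    lambda = lam, mu = mu,
    se_lambda = se_lam, se_mu = se_mu,
    z_lambda = z_lam, z_mu = z_mu,
    p_lambda = p_lam, p_mu = p_mu,
    stars_lambda = stars(p_lam), stars_mu = stars(p_mu),
    loglik = -best$value, n_tus = nrow(X),
    converged = best$convergence == 0 && grad_ok,
    standardize = standardize, centers = centers, scales = scales,
    feature_names = colnames(obs$X) %||%
      c("(intercept)", paste0("X", seq_len(q - 1L))),
    log2_report = log2_report),
    class = "sem_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate a SEM fit
#' @param fit a `"sem_fit"`.
#' @return data.frame with one row per feature: estimate, SE, Z, p and stars
#'   for both the transcription (lambda) and half-life (mu) paths.
#' @export
sem_fit_table <- function(fit) {
  q <- length(fit$lambda)
  nms <- fit$feature_names
  data.frame(feature = nms,
             lambda = fit$lambda, se_lambda = fit$se_lambda,
             z_lambda = fit$z_lambda, p_lambda = fit$p_lambda,
             stars_lambda = fit$stars_lambda,
             mu = fit$mu, se_mu = fit$se_mu, z_mu = fit$z_mu,
             p_mu = fit$p_mu, stars_mu = fit$stars_mu,
             stringsAsFactors = FALSE)
}

#' Draw replicate observations from the SEM generative equations
#'
#' @param model a [sem_model()].
#' @param X feature matrix (intercept first column).
#' @param J_p,J_r replicate counts.
#' @return list with matrices `p`, `r` and the latent vectors `b`, `t`, `m`.
#' @export
sem_simulate <- function(model, X, J_p = 2L, J_r = 2L) {
  X <- as.matrix(X)
  n <- nrow(X)
  b <- as.vector(X %*% model$lambda) + stats::rnorm(n, 0, model$sigma_b)
  t <- as.vector(X %*% model$mu) + stats::rnorm(n, 0, model$sigma_t)
  m <- b + t
  p <- b + matrix(stats::rnorm(n * J_p, 0, model$sigma_p), n, J_p)
  r <- m + matrix(stats::rnorm(n * J_r, 0, model$sigma_r), n, J_r)
  list(p = p, r = r, b = b, t = t, m = m)
}
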
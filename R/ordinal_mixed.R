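# Random-intercept proportional-odds (cumulative logit) model, fitted by
# maximum likelihood with Gauss-Hermite quadrature over the network-level
# intercept. Parameterization: P(Y <= k | x, u) = logistic(zeta_k - x'beta
# - u), u ~ N(0, sigma^2), so positive beta means higher categories and
# exp(beta) is the odds ratio for a higher outcome. Thresholds are kept
# ordered through a log-difference parameterization.

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) by Golub-Welsch.
gauss_hermite <- function(k) {
  if (k == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(k - 1) / 2)
  J <- diag(0, k)
  J[cbind(seq_len(k - 1), 2:k)] <- off
  J[cbind(2:k, seq_len(k - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

zeta_from_par <- function(par, K) {
  # K categories -> K-1 ordered thresholds
  z <- numeric(K - 1)
  z[1] <- par[1]
  if (K > 2) z[2:(K - 1)] <- z[1] + cumsum(exp(par[2:(K - 1)]))
  z
}

par_from_zeta <- function(zeta) {
  c(zeta[1], if (length(zeta) > 1) log(diff(zeta)))
}

# Negative log-likelihood. par = (threshold par, beta, log sigma); when
# fixed_sigma0 = TRUE sigma is dropped from par and the model is a plain
# proportional-odds fit (the quadrature collapses exactly).
polr_mixed_nll <- function(par, y, X, cluster, gh, K, fixed_sigma0 = FALSE) {
  p_thr <- K - 1L
  p_x <- ncol(X)
  zeta <- zeta_from_par(par[seq_len(p_thr)], K)
  beta <- par[p_thr + seq_len(p_x)]
  sigma <- if (fixed_sigma0) 0 else exp(par[p_thr + p_x + 1L])
  eta <- drop(X %*% beta)
  zl <- c(-Inf, zeta)[y]        # lower threshold per obs (y in 1..K)
  zu <- c(zeta, Inf)[y]
  nodes <- if (fixed_sigma0) 0 else sqrt(2) * sigma * gh$nodes
  logw <- if (fixed_sigma0) 0 else log(gh$weights / sqrt(pi))
  nq <- length(nodes)
  ncl <- length(unique(cluster))
  S <- matrix(0, ncl, nq)        # cluster log-likelihood per node
  for (q in seq_len(nq)) {
    pr <- stats::plogis(zu - eta - nodes[q]) -
      stats::plogis(zl - eta - nodes[q])
    pr <- pmax(pr, 1e-300)
    S[, q] <- rowsum(log(pr), cluster)[, 1]
  }
  M <- apply(S, 1, max)
  ll <- sum(M + log(rowSums(exp(sweep(S, 1, M) +
                                  rep(logw, each = ncl)))))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Analytic gradient of the negative log-likelihood (same parameterization).
polr_mixed_grad <- function(par, y, X, cluster, gh, K, fixed_sigma0 = FALSE) {
  p_thr <- K - 1L
  p_x <- ncol(X)
  zeta <- zeta_from_par(par[seq_len(p_thr)], K)
  beta <- par[p_thr + seq_len(p_x)]
  sigma <- if (fixed_sigma0) 0 else exp(par[p_thr + p_x + 1L])
  eta <- drop(X %*% beta)
  zl <- c(-Inf, zeta)[y]
  zu <- c(zeta, Inf)[y]
  nodes <- if (fixed_sigma0) 0 else sqrt(2) * sigma * gh$nodes
  logw <- if (fixed_sigma0) 0 else log(gh$weights / sqrt(pi))
  nq <- length(nodes)
  n <- length(y)
  cl <- as.integer(cluster)
  ncl <- max(cl)

  P <- FU <- FL <- matrix(0, n, nq)
  S <- matrix(0, ncl, nq)
  for (q in seq_len(nq)) {
    au <- zu - eta - nodes[q]
    al <- zl - eta - nodes[q]
    pq <- pmax(stats::plogis(au) - stats::plogis(al), 1e-300)
    P[, q] <- pq
    FU[, q] <- stats::dlogis(au)
    FL[, q] <- ifelse(is.finite(al), stats::dlogis(al), 0)
    S[, q] <- rowsum(log(pq), cl)[, 1]
  }
  M <- apply(S, 1, max)
  W <- exp(sweep(S, 1, M) + rep(logw, each = ncl))
  PI <- W / rowSums(W)          # posterior node weight per cluster
  PIo <- PI[cl, , drop = FALSE] # per observation

  G_eta <- -(FU - FL) / P
  w_obs <- rowSums(PIo * G_eta)
  g_beta <- drop(crossprod(X, w_obs))

  up <- rowSums(PIo * FU / P)   # d/d zeta_{y_i}
  lo <- -rowSums(PIo * FL / P)  # d/d zeta_{y_i - 1}
  g_zeta <- numeric(p_thr)
  for (k in seq_len(p_thr))
    g_zeta[k] <- sum(up[y == k]) + sum(lo[y == (k + 1L)])
  g_par_thr <- numeric(p_thr)
  g_par_thr[1] <- sum(g_zeta)
  if (p_thr > 1)
    for (j in 2:p_thr)
      g_par_thr[j] <- exp(par[j]) * sum(g_zeta[j:p_thr])

  g <- c(g_par_thr, g_beta)
  if (!fixed_sigma0) {
    g_logsig <- sum(vapply(seq_len(nq), function(q)
      nodes[q] * sum(PIo[, q] * G_eta[, q]), numeric(1)))
    g <- c(g, g_logsig)
  }
  -g
}

#' Proportional-odds model with a cluster random intercept
#'
#' Fits \eqn{P(Y \le k) = logit^{-1}(\zeta_k - x'\beta - u)},
#' \eqn{u \sim N(0, \sigma^2)} per cluster, by maximum likelihood with
#' Gauss-Hermite quadrature (default 15 nodes). \code{exp(beta)} is the
#' odds ratio for a higher outcome category. Starting values come from a
#' \code{MASS::polr} fit without the random intercept.
#'
#' @param y Ordered outcome (integer or factor; at least 2 observed levels).
#' @param X Numeric model matrix (no intercept column).
#' @param cluster Cluster (network) identifier per observation.
#' @param nq Number of quadrature nodes.
#' @param fixed_sigma0 Fit with \eqn{\sigma = 0} (plain proportional odds);
#'   used for the variance-component likelihood-ratio test.
#' @return List with \code{beta}, \code{se}, \code{p} (Wald, two-sided),
#'   \code{zeta}, \code{sigma}, \code{logLik}, \code{aic}, \code{npar},
#'   \code{convergence}, \code{levels}.
#' @export
polr_mixed <- function(y, X, cluster, nq = 15L, fixed_sigma0 = FALSE) {
  yf <- factor(y)
  if (nlevels(yf) < 2L) stop("outcome is constant", call. = FALSE)
  yi <- as.integer(yf)
  K <- nlevels(yf)
  X <- as.matrix(X)
  cluster <- as.integer(factor(cluster))
  gh <- gauss_hermite(nq)

  start_fit <- tryCatch(
    MASS::polr(yf ~ X, Hess = FALSE, method = "logistic"),
    error = function(e) NULL)
  if (!is.null(start_fit)) {
    beta0 <- unname(stats::coef(start_fit))
    zeta0 <- unname(start_fit$zeta)
    if (anyNA(beta0) || anyNA(zeta0) || any(diff(zeta0) <= 0))
      start_fit <- NULL
  }
  if (is.null(start_fit)) {
    beta0 <- rep(0, ncol(X))
    zeta0 <- stats::qlogis(cumsum(prop.table(table(yi)))[-K])
  }
  par0 <- c(par_from_zeta(zeta0), beta0,
            if (!fixed_sigma0) log(0.5))

  opt <- stats::nlminb(par0, polr_mixed_nll, gradient = polr_mixed_grad,
                       y = yi, X = X, cluster = cluster, gh = gh, K = K,
                       fixed_sigma0 = fixed_sigma0,
                       control = list(iter.max = 500, eval.max = 1000))
  if (opt$convergence != 0 && opt$objective >= 1e10)
    stop("proportional-odds fit did not converge: ", opt$message,
         call. = FALSE)
  p_thr <- K - 1L
  p_x <- ncol(X)
  H <- stats::optimHess(opt$par, polr_mixed_nll, polr_mixed_grad,
                        y = yi, X = X, cluster = cluster, gh = gh, K = K,
                        fixed_sigma0 = fixed_sigma0)
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  beta <- opt$par[p_thr + seq_len(p_x)]
  se <- sqrt(pmax(diag(V)[p_thr + seq_len(p_x)], 0))
  names(beta) <- names(se) <- colnames(X)
  zv <- beta / se
  npar <- length(opt$par)
  list(beta = beta, se = se, p = 2 * stats::pnorm(-abs(zv)),
       zeta = zeta_from_par(opt$par[seq_len(p_thr)], K),
       sigma = if (fixed_sigma0) 0 else exp(opt$par[npar]),
       logLik = -opt$objective, aic = 2 * opt$objective + 2 * npar,
       npar = npar, convergence = opt$convergence,
       levels = levels(yf))
}
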
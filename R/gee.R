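#' Logistic generalized estimating equation with exchangeable correlation
#'
#' Marginal logistic regression for correlated binary outcomes (here, the
#' two reading arms of the same woman), solved by Fisher scoring on the
#' generalized estimating equations with an exchangeable (or independence)
#' working correlation and a cluster-robust sandwich variance. Under the
#' independence working structure with one observation per cluster the
#' estimating equation is the ordinary logistic score, so coefficients
#' coincide with [stats::glm()].
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Design matrix (include an intercept column explicitly).
#' @param id Cluster identifier (one cluster per woman).
#' @param corstr Working correlation: `"exchangeable"` or `"independence"`.
#' @param tol Convergence tolerance on the coefficient change.
#' @param maxit Maximum Fisher-scoring iterations.
#' @return Object of class `gee_logit`: list with `coefficients`, `vcov`
#'   (robust sandwich), `vcov_naive`, `alpha` (working correlation), `phi`
#'   (dispersion), `n_clusters`, `iterations`, `converged`.
#' @examples
#' set.seed(1)
#' x <- cbind(1, rbinom(200, 1, 0.5))
#' y <- rbinom(200, 1, plogis(-1 + 0.5 * x[, 2]))
#' gee_logit(y, x, id = seq_along(y), corstr = "independence")$coefficients
#' @export
gee_logit <- function(y, x, id, corstr = c("exchangeable", "independence"),
                      tol = 1e-10, maxit = 50) {
  corstr <- match.arg(corstr)
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), length(id) == nrow(x),
            all(y %in% c(0, 1)))
  id <- as.integer(factor(id))
  ord <- order(id)
  y <- y[ord]; x <- x[ord, , drop = FALSE]; id <- id[ord]
  n <- length(y); p <- ncol(x)
  sizes <- as.vector(table(id))
  if (max(sizes) > 2 && corstr == "exchangeable") {
    return(gee_logit_general(y, x, id, corstr, tol, maxit))
  }
  first <- cumsum(c(1, sizes[-length(sizes)]))
  is_pair <- sizes == 2
  i1 <- first[is_pair]; i2 <- i1 + 1L          # paired rows
  i0 <- first[!is_pair]                        # singleton rows
  n_pairs <- sum(is_pair)

  beta <- stats::glm.fit(x, y, family = stats::binomial())$coefficients
  alpha <- 0; phi <- 1; converged <- FALSE; it <- 0
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    a_var <- mu * (1 - mu)
    s <- sqrt(pmax(a_var, .Machine$double.eps))
    r <- y - mu
    e <- r / s
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable" && n_pairs > 0) {
      denom <- n_pairs - p
      if (denom <= 0) denom <- n_pairs
      alpha <- sum(e[i1] * e[i2]) / (phi * denom)
      alpha <- min(max(alpha, -0.99), 0.99)
    } else {
      alpha <- 0
    }
    f <- 1 / (phi * (1 - alpha^2))
    # information: sum over clusters of D' V^{-1} D
    m_diag <- crossprod(x, (a_var / phi) * x)    # independence part, all rows
    info <- m_diag
    u <- crossprod(x, r / phi)
    if (alpha != 0) {
      x1 <- x[i1, , drop = FALSE]; x2 <- x[i2, , drop = FALSE]
      # replace the independence contribution of paired rows by the
      # exchangeable-correlation contribution
      m_pair_ind <- crossprod(x1, (a_var[i1] / phi) * x1) +
                    crossprod(x2, (a_var[i2] / phi) * x2)
      cross_ <- crossprod(x1, (alpha * s[i1] * s[i2] * f) * x2)
      m_pair <- f * phi * m_pair_ind - (cross_ + t(cross_))
      info <- m_diag - m_pair_ind + m_pair
      c1 <- f * s[i1] * (e[i1] - alpha * e[i2])
      c2 <- f * s[i2] * (e[i2] - alpha * e[i1])
      u_pair_ind <- crossprod(x1, r[i1] / phi) + crossprod(x2, r[i2] / phi)
      u <- u - u_pair_ind + crossprod(x1, c1) + crossprod(x2, c2)
    }
    step <- solve(info, u)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  # sandwich variance: B = sum_i g_i g_i' with g_i the cluster score
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  a_var <- mu * (1 - mu)
  s <- sqrt(pmax(a_var, .Machine$double.eps))
  r <- y - mu
  e <- r / s
  f <- 1 / (phi * (1 - alpha^2))
  g_mat <- matrix(0, nrow = length(sizes), ncol = p)
  if (n_pairs > 0) {
    x1 <- x[i1, , drop = FALSE]; x2 <- x[i2, , drop = FALSE]
    c1 <- f * s[i1] * (e[i1] - alpha * e[i2])
    c2 <- f * s[i2] * (e[i2] - alpha * e[i1])
    g_mat[is_pair, ] <- c1 * x1 + c2 * x2
  }
  if (length(i0)) {
    g_mat[!is_pair, ] <- (r[i0] / phi) * x[i0, , drop = FALSE]
  }
  info <- info_at(x, a_var, s, e, phi, alpha, i1, i2)
  bread <- solve(info)
  meat <- crossprod(g_mat)
  vcov_r <- bread %*% meat %*% bread
  dimnames(vcov_r) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, vcov = vcov_r, vcov_naive = bread,
                 alpha = alpha, phi = phi, n_clusters = length(sizes),
                 iterations = it, converged = converged, corstr = corstr),
            class = "gee_logit")
}

# model information Sum D'V^{-1}D at given state (clusters of size <= 2)
info_at <- function(x, a_var, s, e, phi, alpha, i1, i2) {
  m_diag <- crossprod(x, (a_var / phi) * x)
  if (alpha == 0 || length(i1) == 0) return(m_diag)
  f <- 1 / (phi * (1 - alpha^2))
  x1 <- x[i1, , drop = FALSE]; x2 <- x[i2, , drop = FALSE]
  m_pair_ind <- crossprod(x1, (a_var[i1] / phi) * x1) +
                crossprod(x2, (a_var[i2] / phi) * x2)
  cross_ <- crossprod(x1, (alpha * s[i1] * s[i2] * f) * x2)
  m_diag - m_pair_ind + (f * phi * m_pair_ind - (cross_ + t(cross_)))
}

# general cluster sizes: per-cluster loop with the analytic inverse of the
# exchangeable correlation matrix
gee_logit_general <- function(y, x, id, corstr, tol, maxit) {
  p <- ncol(x); n <- length(y)
  idx <- split(seq_len(n), id)
  beta <- stats::glm.fit(x, y, family = stats::binomial())$coefficients
  alpha <- 0; phi <- 1; converged <- FALSE; it <- 0
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(drop(x %*% beta))
    a_var <- mu * (1 - mu)
    s <- sqrt(pmax(a_var, .Machine$double.eps))
    e <- (y - mu) / s
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ii in idx) {
        if (length(ii) > 1) {
          es <- e[ii]
          num <- num + (sum(es)^2 - sum(es^2)) / 2
          npairs <- npairs + length(ii) * (length(ii) - 1) / 2
        }
      }
      denom <- npairs - p
      if (denom <= 0) denom <- npairs
      alpha <- min(max(num / (phi * denom), -0.99), 0.99)
    }
    info <- matrix(0, p, p); u <- numeric(p)
    for (ii in idx) {
      ni <- length(ii)
      xi <- x[ii, , drop = FALSE]; si <- s[ii]; ei <- e[ii]
      # R^{-1} = (I - alpha/(1 + (ni-1) alpha) J) / (1 - alpha)
      aa <- alpha / (1 + (ni - 1) * alpha)
      z <- (ei - aa * sum(ei)) / (1 - alpha)          # R^{-1} e
      xs <- si * xi                                    # A^{1/2} X
      u <- u + crossprod(xs, z) / phi
      info <- info + (crossprod(xs) - aa * tcrossprod(colSums(xs))) /
        (phi * (1 - alpha))
    }
    step <- solve(info, u)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  mu <- stats::plogis(drop(x %*% beta))
  a_var <- mu * (1 - mu)
  s <- sqrt(pmax(a_var, .Machine$double.eps))
  e <- (y - mu) / s
  info <- matrix(0, p, p); meat <- matrix(0, p, p)
  for (ii in idx) {
    ni <- length(ii)
    xi <- x[ii, , drop = FALSE]; si <- s[ii]; ei <- e[ii]
    aa <- alpha / (1 + (ni - 1) * alpha)
    z <- (ei - aa * sum(ei)) / (1 - alpha)
    xs <- si * xi
    g <- crossprod(xs, z) / phi
    meat <- meat + tcrossprod(g)
    info <- info + (crossprod(xs) - aa * tcrossprod(colSums(xs))) /
      (phi * (1 - alpha))
  }
  bread <- solve(info)
  vcov_r <- bread %*% meat %*% bread
  dimnames(vcov_r) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, vcov = vcov_r, vcov_naive = bread,
                 alpha = alpha, phi = phi, n_clusters = length(idx),
                 iterations = it, converged = converged, corstr = corstr),
            class = "gee_logit")
}

#' @export
print.gee_logit <- function(x, ...) {
  cat(sprintf("GEE logistic (%s working correlation, alpha = %.3f, %d clusters)\n",
              x$corstr, x$alpha, x$n_clusters))
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, robust_se = se,
              z = x$coefficients / se))
  invisible(x)
}
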
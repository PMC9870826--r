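# Dense, brute-force reference implementations used to validate the sparse
# paths.  Everything here works on explicit n-by-n covariance matrices and
# base-R solves; nothing is shared with the package's sparse code.

# -2 * restricted log-likelihood, computed directly from V
dense_reml_m2ll <- function(y, X, Zlist, sigma2, s2e) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(s2e, n)
  for (i in seq_along(Zlist)) {
    Zi <- Zlist[[i]]
    V <- V + sigma2[i] * tcrossprod(Zi)
  }
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  as.numeric(determinant(V, logarithm = TRUE)$modulus +
             determinant(XtViX, logarithm = TRUE)$modulus +
             crossprod(r, Vi %*% r) + (n - p) * log(2 * pi))
}

# brute-force restricted-likelihood maximizer: multistart box-constrained
# quasi-Newton on log variances, polished by Nelder-Mead
dense_reml_fit <- function(y, X, Zlist, starts = NULL) {
  k <- length(Zlist)
  obj <- function(lpar) {
    dense_reml_m2ll(y, X, Zlist, exp(lpar[seq_len(k)]), exp(lpar[k + 1]))
  }
  vy <- stats::var(y)
  if (is.null(starts)) {
    starts <- list(rep(log(vy / (k + 1)), k + 1),
                   c(rep(log(vy / 10), k), log(vy)),
                   rep(0, k + 1))
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "L-BFGS-B",
                      lower = rep(-25, k + 1), upper = rep(25, k + 1),
                      control = list(maxit = 500, factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
  }
  pol <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
  if (pol$value < best$value) best <- pol
  list(sigma2 = exp(best$par[seq_len(k)]), s2e = exp(best$par[k + 1]),
       loglik = -best$value / 2)
}

# dense Henderson mixed-model equations with known variance components
dense_mme_blup <- function(y, Zlist, vars, ve) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Zs <- lapply(Zlist, function(f) {
    f <- as.factor(f)
    Z <- matrix(0, n, nlevels(f), dimnames = list(NULL, levels(f)))
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Z
  })
  W <- do.call(cbind, c(list(X), Zs))
  q <- vapply(Zs, ncol, integer(1))
  D <- diag(c(0, rep(ve / vars, times = q)))
  sol <- solve(crossprod(W) + D, crossprod(W, y))
  out <- list(mu = sol[1])
  at <- 1L
  for (i in seq_along(Zs)) {
    v <- sol[at + seq_len(q[i])]
    names(v) <- colnames(Zs[[i]])
    out[[names(Zlist)[i]]] <- v
    at <- at + q[i]
  }
  out
}

# random small crossed dataset for oracle comparisons
random_tiny_instance <- function(seed) {
  set.seed(seed)
  n <- sample(35:50, 1)
  g1 <- sample(letters[1:7], n, replace = TRUE)
  g2 <- sample(LETTERS[1:5], n, replace = TRUE)
  s <- c(g1 = runif(1, 0.5, 3), g2 = runif(1, 0.5, 3))
  se <- runif(1, 0.5, 2)
  y <- 5 +
    rnorm(7, 0, sqrt(s["g1"]))[match(g1, letters[1:7])] +
    rnorm(5, 0, sqrt(s["g2"]))[match(g2, LETTERS[1:5])] +
    rnorm(n, 0, sqrt(se))
  data.frame(y = y, g1 = g1, g2 = g2)
}

indicator_dense <- function(f) {
  f <- as.factor(f)
  Z <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}
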
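#' Fit a crossed random-effects model by REML
#'
#' Maximizes the restricted log-likelihood
#' \deqn{\ell_R(\sigma^2) = -\tfrac12\left[\log|V| + \log|X^\top V^{-1}X| +
#'   y^\top P y + (n-p)\log 2\pi\right]}
#' over the non-negative variance components of a model with an intercept,
#' optional fixed regressions on the year of testing (`t`) and the year of
#' first testing (`r`), and independent homoscedastic crossed random
#' factors.  The residual variance is profiled out and the remaining
#' variance ratios are optimized on the log scale with a quasi-Newton
#' method, so estimates respect the non-negativity boundary by
#' construction; a ratio pushed to the lower box bound is reported as a
#' zero variance.  Each likelihood evaluation costs one sparse Cholesky
#' refactorization of the mixed-model equations (the symbolic analysis is
#' reused across iterations), which keeps fits of datasets with tens of
#' thousands of cells and many thousands of interaction levels cheap.
#'
#' @param data dataset with columns `y`, `year`, `location`, `genotype`,
#'   `trial`, `first_year`.
#' @param spec a [model_spec()]; defaults to the reduced trend model.
#' @param start optional starting values: a [variance_components()] object
#'   or a named vector of variances (including `residual`).  The default
#'   splits the phenotypic variance equally across all factors.
#' @param max_iter iteration cap of the optimizer.
#' @param verbose print optimizer progress.
#' @return An object of class `vcu_fit` with elements `vc` (named variance
#'   component estimates, residual last), `fixed` (estimates and standard
#'   errors of the fixed effects; asymptotic SEs from
#'   \eqn{(X^\top \hat V^{-1} X)^{-1}}), `blup` (named BLUP vector per
#'   random factor), `loglik` (the restricted log-likelihood at the
#'   optimum), `convergence` diagnostics, and bookkeeping used by the
#'   evaluation helpers.
#' @export
reml_fit <- function(data, spec = trend_model_spec(), start = NULL,
                     max_iter = 200L, verbose = FALSE) {
  spec <- validate_model_spec(spec, data)
  des <- build_design(data, spec)
  n <- length(des$y)
  p <- ncol(des$X)
  if (n <= p) stop_config("need more observations than fixed effects")
  if (qr(des$X)$rank < p) {
    stop(errorCondition(
      paste("fixed-effect design is rank deficient; the first-year and",
            "year-of-testing covariates are confounded in these data"),
      class = c("vcu_estimability_error", "error")))
  }

  W <- do.call(cbind, c(list(Matrix::Matrix(des$X, sparse = TRUE)), des$Z))
  M0 <- as(Matrix::forceSymmetric(Matrix::crossprod(W)), "CsparseMatrix")
  Wty <- as.numeric(Matrix::crossprod(W, des$y))
  yty <- sum(des$y^2)
  q <- des$q
  k <- length(q)
  idx_rand <- rep(seq_len(k), times = q)

  # the optimizer only moves the diagonal of the mixed-model equations:
  # patch the stored entries in place instead of re-allocating the matrix
  cols <- rep.int(seq_len(ncol(M0)), diff(M0@p))
  diag_pos <- which(M0@i + 1L == cols)
  stopifnot(length(diag_pos) == ncol(M0))  # all data columns are occupied
  diag_rand <- diag_pos[-seq_len(p)]
  x0 <- M0@x

  gamma0 <- start_gammas(spec, start, des, data)
  lower <- rep(-18, k); upper <- rep(18, k)

  env <- new.env()
  env$chol <- NULL
  m2ll <- function(par) {
    gam <- exp(par)
    xx <- x0
    xx[diag_rand] <- xx[diag_rand] + (1 / gam)[idx_rand]
    M <- M0; M@x <- xx
    ok <- TRUE
    ch <- tryCatch({
      if (is.null(env$chol)) {
        env$chol <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
      } else {
        env$chol <- Matrix::update(env$chol, M)
      }
      env$chol
    }, error = function(e) { ok <<- FALSE; NULL })
    if (!ok) return(1e10)
    logdetM <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    sol <- as.numeric(Matrix::solve(ch, Wty, system = "A"))
    quad <- yty - sum(Wty * sol)
    if (quad <= 0) return(1e10)
    s2e <- quad / (n - p)
    val <- logdetM + sum(q * par) + (n - p) * log(s2e) +
      (n - p) * (1 + log(2 * pi))
    if (verbose) cat(sprintf("-2l_R = %.6f\n", val))
    val
  }

  opt <- stats::nlminb(log(gamma0), m2ll, lower = lower, upper = upper,
                       control = list(iter.max = max_iter, eval.max = 2000,
                                      rel.tol = 1e-11, x.tol = 1e-9))
  par <- opt$par
  gam <- exp(par)
  at_bound <- par <= lower + 1e-6
  obj <- m2ll(par)  # refresh factor at the optimum
  ch <- env$chol

  sol <- as.numeric(Matrix::solve(ch, Wty, system = "A"))
  quad <- yty - sum(Wty * sol)
  s2e <- quad / (n - p)
  beta_hat <- sol[seq_len(p)]
  Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                             dims = c(p + sum(q), p))
  covb <- s2e * as.matrix(Matrix::solve(ch, Ep, system = "A"))[seq_len(p), ,
                                                               drop = FALSE]
  se <- sqrt(pmax(diag(covb), 0))
  fixed <- data.frame(term = colnames(des$X), estimate = beta_hat, se = se,
                      row.names = NULL)

  u <- sol[-seq_len(p)]
  blup <- vector("list", k)
  names(blup) <- des$terms
  at <- 0L
  for (i in seq_len(k)) {
    vals <- u[at + seq_len(q[i])]
    names(vals) <- colnames(des$Z[[i]])
    blup[[i]] <- vals
    at <- at + q[i]
  }

  vc <- stats::setNames(ifelse(at_bound, 0, gam * s2e),
                        term_vc_name(des$terms))
  vc <- c(vc, residual = s2e)

  # per-genotype bookkeeping for the evaluation module
  geno_info <- NULL
  if (all(c("genotype", "year") %in% names(data))) {
    gyears <- tapply(data$year, data$genotype,
                     function(x) length(unique(x)))
    geno_info <- data.frame(genotype = names(gyears),
                            n_years = as.integer(gyears), row.names = NULL)
  }

  structure(list(
    vc = vc, fixed = fixed, blup = blup, loglik = -obj / 2,
    convergence = list(
      code = opt$convergence, message = opt$message,
      # nlminb labels flat-optimum stops "singular convergence"; for a
      # profiled REML surface that is a converged fit, not a failure
      converged = opt$convergence == 0 ||
        grepl("relative convergence|X-convergence|singular convergence",
              opt$message),
      iterations = opt$iterations, evaluations = opt$evaluations,
      boundary = des$terms[at_bound]),
    spec = spec, n = n, p = p, geno_info = geno_info
  ), class = "vcu_fit")
}

start_gammas <- function(spec, start, des, data) {
  k <- length(des$terms)
  if (is.null(start)) return(rep(1, k))
  if (inherits(start, "vcu_vc")) {
    s <- start$sigma2
    resid <- unname(s["residual"])
    if (!"genotype:year:location" %in% spec$random) {
      resid <- resid + unname(s["genotype_year_location"])
    }
    g <- s[term_vc_name(des$terms)] / resid
  } else {
    resid <- unname(start["residual"])
    g <- start[term_vc_name(des$terms)] / resid
  }
  g[!is.finite(g)] <- 1
  pmin(pmax(unname(g), 1e-6), 1e6)
}

#' @export
print.vcu_fit <- function(x, ...) {
  cat("REML fit (", x$n, " observations)\n", sep = "")
  cat("Variance components:\n")
  print(round(x$vc, 4))
  cat("Fixed effects:\n")
  print(transform(x$fixed, estimate = signif(estimate, 5),
                  se = signif(se, 4)), row.names = FALSE)
  cat(sprintf("logLik (REML): %.4f; convergence code %d\n",
              x$loglik, x$convergence$code))
  invisible(x)
}

#' Genotype deviation BLUPs of a fit
#'
#' Returns the predicted genotype deviations \eqn{H_i} from the fitted
#' genetic trend line -- the genotype-factor BLUPs of the fit, since the
#' genetic trend is carried by the fixed regression on the year of first
#' testing.
#'
#' @param fit a [reml_fit()] result whose spec includes a `genotype` factor.
#' @return Named numeric vector of BLUPs (one per genotype).
#' @export
blup_H <- function(fit) {
  if (!"genotype" %in% names(fit$blup)) {
    stop_config("fit has no genotype factor")
  }
  fit$blup$genotype
}

#' Trend slopes of a fit
#'
#' @param fit a [reml_fit()] result.
#' @return Named vector with the genetic slope (`beta`, coefficient of the
#'   first-year covariate) and non-genetic slope (`gamma`, coefficient of
#'   the testing-year covariate); `NA` for covariates not in the model.
#' @export
trend_slopes <- function(fit) {
  est <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  c(beta = unname(est["r"]), gamma = unname(est["t"]))
}
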
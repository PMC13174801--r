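# Firth-penalized logistic regression.
#
# The penalized log-likelihood is l(b) + 0.5*log|I(b)| (Jeffreys prior),
# which guarantees finite estimates under complete separation and reduces
# small-count bias -- the regime of rare-variant burden tests. Newton
# iterations use the modified score U*(b) = X'(y - mu + h*(0.5 - mu)) with
# h the hat-diagonal, plus step-halving on the penalized likelihood.

# `free`: columns whose coefficients are estimated; the others are fixed
# at 0 but stay in the Jeffreys penalty (the logistf convention for the
# penalized likelihood-ratio test: the restricted model keeps the full
# design's information determinant).
.firth_fit <- function(X, y, offset = NULL, max_iter = 50, tol = 1e-8,
                       free = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(offset)) offset <- numeric(n)
  if (is.null(free)) free <- seq_len(p)
  beta <- numeric(p)
  pll <- function(beta) {
    eta <- offset + drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(w))
    ld <- determinant(XtWX, logarithm = TRUE)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    list(value = ll + 0.5 * as.numeric(ld$modulus),
         mu = mu, w = w, XtWX = XtWX)
  }
  cur <- pll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    inv <- tryCatch(solve(cur$XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * X) * cur$w
    adj <- y - cur$mu + h * (0.5 - cur$mu)
    score <- drop(crossprod(X[, free, drop = FALSE], adj))
    info_free <- cur$XtWX[free, free, drop = FALSE]
    step_free <- drop(solve(info_free, score))
    step <- numeric(p); step[free] <- step_free
    # step-halving on the penalized likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      new <- pll(cand)
      if (is.finite(new$value) && new$value >= cur$value - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { new <- cur; cand <- beta; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand; cur <- new
    if (moved < tol && max(abs(score)) < sqrt(tol)) { converged <- TRUE; break }
    if (max(abs(score)) < tol) { converged <- TRUE; break }
  }
  inv <- tryCatch(solve(cur$XtWX), error = function(e)
    matrix(NA_real_, p, p))
  list(beta = beta, pll = cur$value, vcov = inv, converged = converged,
       iterations = it)
}

#' Firth-corrected logistic burden test
#'
#' Tests association between a burden genotype and a binary phenotype with
#' Firth's Jeffreys-prior penalization. In `exact` mode the penalized
#' likelihood is maximized jointly over intercept, burden and covariates.
#' In `approximate` mode (the large-scale default) the covariate-only null
#' model is first fit by ordinary maximum likelihood, its linear predictor
#' is fixed as an offset, and Firth is applied to intercept and burden
#' only; this is the standard fast approximation for exome-wide scans. The
#' p-value is the two-sided penalized likelihood-ratio test, and the
#' standard error is back-corrected from it as |beta|/z with
#' z = qnorm(1 - p/2), so the Wald interval reproduces the LRT inference.
#'
#' @param burden Numeric per-sample burden genotype (carrier indicator or
#'   allele count).
#' @param phenotype Binary 0/1 vector; both classes must be present.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (no intercept column).
#' @param mode `"exact"` or `"approximate"`.
#' @param max_iter,tol Newton iteration controls.
#' @return A one-row data frame: `beta`, `se`, `p`, `or`, `ci_lo`, `ci_hi`,
#'   `cmac`, `n_carriers`, `n_cases`, `n_referents`, `converged`.
#' @export
#' @examples
#' set.seed(1)
#' y <- rbinom(200, 1, 0.3)
#' x <- rbinom(200, 1, 0.05)
#' firth_logistic(x, y, mode = "exact")
firth_logistic <- function(burden, phenotype, covariates = NULL,
                           mode = c("exact", "approximate"),
                           max_iter = 50, tol = 1e-8) {
  mode <- match.arg(mode)
  y <- as.numeric(phenotype)
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2) stop("phenotype has a single class")
  x <- as.numeric(burden)
  if (stats::var(x) == 0)
    stop("degenerate predictor: burden genotype has no variation")
  n <- length(y)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    storage.mode(C) <- "double"
  } else C <- NULL

  if (mode == "approximate" && !is.null(C)) {
    null_ml <- stats::glm.fit(cbind(1, C), y,
                              family = stats::binomial())
    offset <- drop(cbind(1, C) %*% null_ml$coefficients)
    Xf <- cbind(`(Intercept)` = 1, burden = x)
  } else {
    offset <- NULL
    Xf <- cbind(`(Intercept)` = 1, if (!is.null(C)) C, burden = x)
    colnames(Xf)[ncol(Xf)] <- "burden"
  }
  full <- .firth_fit(Xf, y, offset, max_iter, tol)
  null <- .firth_fit(Xf, y, offset, max_iter, tol,
                     free = seq_len(ncol(Xf) - 1L))
  b <- full$beta[ncol(Xf)]
  lrt <- max(0, 2 * (full$pll - null$pll))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  z <- stats::qnorm(1 - p / 2)
  se <- if (is.finite(z) && z > 0 && abs(b) > 0) abs(b) / z
        else sqrt(full$vcov[ncol(Xf), ncol(Xf)])
  data.frame(beta = b, se = se, p = p,
             or = exp(b),
             ci_lo = exp(b - 1.959963984540054 * se),
             ci_hi = exp(b + 1.959963984540054 * se),
             cmac = sum(x),
             n_carriers = sum(x > 0),
             n_cases = sum(y == 1),
             n_referents = sum(y == 0),
             converged = full$converged && null$converged)
}
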
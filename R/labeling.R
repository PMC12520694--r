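#' @title Gaussian-mixture consensus labeling
#' @description Each gene set's per-cell activity scores are modelled as a
#'   two-component univariate Gaussian mixture fitted by EM; a cell is HIGH
#'   for a set when its posterior for the larger-mean component exceeds the
#'   cut. Cells HIGH for every set are high-confidence hypoxic, LOW for
#'   every set high-confidence normoxic, anything mixed is low-confidence.
#' @name labeling
NULL

.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fn()
}

.emRun <- function(v, mu, s2, w, tol, maxIter, varFloor) {
  n <- length(v)
  trace <- numeric(0)
  ll <- -Inf
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * dnorm(v, mu[1], sqrt(s2[1]))
    d2 <- w[2] * dnorm(v, mu[2], sqrt(s2[2]))
    tot <- pmax(d1 + d2, 1e-300)
    newll <- sum(log(tot))
    trace <- c(trace, newll)
    if (is.finite(ll) && abs(newll - ll) < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
    ll <- newll
    r <- d1 / tot
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) break
    mu <- c(sum(r * v) / n1, sum((1 - r) * v) / n2)
    s2 <- pmax(c(sum(r * (v - mu[1])^2) / n1,
                 sum((1 - r) * (v - mu[2])^2) / n2), varFloor)
    w <- c(n1 / n, n2 / n)
  }
  list(mu = mu, s2 = s2, w = w, ll = trace[length(trace)], trace = trace,
       nIter = it, converged = converged)
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Initialization takes the 30th/70th percentiles as starting means plus
#' `nInit - 1` seeded random restarts (means drawn from the data); the run
#' with the best log-likelihood is kept. Component variances are floored at
#' `1e-6` times the sample variance. The per-iteration log-likelihood trace
#' is retained so monotonicity can be asserted.
#'
#' @param values numeric vector, length >= 10, finite, non-constant.
#' @param seed integer seed for the random restarts.
#' @param nInit number of EM starts (default 5).
#' @param tol absolute log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter iteration cap per start (default 500).
#' @return a [MixtureFit-class].
#' @export
fitGmm1d <- function(values, seed = 0L, nInit = 5L, tol = 1e-6,
                     maxIter = 500L) {
  if (length(values) < 10L) stop("need at least 10 values")
  if (any(!is.finite(values))) stop("values must be finite")
  sv <- stats::var(values)
  if (!is.finite(sv) || sv <= 0) stop("degenerate score distribution")
  varFloor <- 1e-6 * sv

  inits <- list(list(mu = unname(quantile(values, c(0.3, 0.7))),
                     s2 = c(sv, sv), w = c(0.5, 0.5)))
  if (nInit > 1L) {
    extra <- .withSeed(seed, function() {
      lapply(seq_len(nInit - 1L), function(i) {
        mu <- sample(values, 2L)
        tries <- 0L
        while (mu[1] == mu[2] && tries < 20L) {
          mu <- sample(values, 2L); tries <- tries + 1L
        }
        list(mu = mu, s2 = c(sv, sv) / 2, w = c(0.5, 0.5))
      })
    })
    inits <- c(inits, extra)
  }
  best <- NULL
  for (ini in inits) {
    if (ini$mu[1] == ini$mu[2]) ini$mu[2] <- ini$mu[2] + sqrt(sv) / 10
    fit <- .emRun(values, ini$mu, ini$s2, ini$w, tol, maxIter, varFloor)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  high <- if (best$mu[1] == best$mu[2])
    which.max(best$w) else which.max(best$mu)
  new("MixtureFit", means = best$mu, variances = best$s2,
      weights = best$w, logLik = best$ll, logLikTrace = best$trace,
      nIter = best$nIter, converged = best$converged,
      highComponent = as.integer(high))
}

#' Posterior probability of the high (larger-mean) component
#'
#' @param fit a [MixtureFit-class].
#' @param values numeric vector to score.
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
gmmPosteriorHigh <- function(fit, values) {
  stopifnot(is(fit, "MixtureFit"))
  h <- fit@highComponent
  l <- 3L - h
  dh <- fit@weights[h] * dnorm(values, fit@means[h], sqrt(fit@variances[h]))
  dl <- fit@weights[l] * dnorm(values, fit@means[l], sqrt(fit@variances[l]))
  dh / pmax(dh + dl, 1e-300)
}

#' Consensus labels from per-set mixture fits
#'
#' A cell is HIGH for a gene set when its posterior for the larger-mean
#' component exceeds `posteriorCut`. Cells HIGH in every set become
#' `HC_HYPOXIC`, LOW in every set `HC_NORMOXIC`, and the rest `LOW_CONF`.
#'
#' @param scoreMat a [ScoreMatrix-class].
#' @param fits list of [MixtureFit-class], one per score column, in column
#'   order.
#' @param posteriorCut posterior threshold for a HIGH call (default 0.5,
#'   i.e. maximum-responsibility assignment).
#' @return a [HypoxiaLabels-class].
#' @export
consensusLabel <- function(scoreMat, fits, posteriorCut = 0.5) {
  stopifnot(is(scoreMat, "ScoreMatrix"),
            length(fits) == ncol(scoreMat@scores))
  s <- scoreMat@scores
  post <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  for (k in seq_len(ncol(s)))
    post[, k] <- gmmPosteriorHigh(fits[[k]], s[, k])
  grp <- ifelse(post > posteriorCut, "HIGH", "LOW")
  allHigh <- rowSums(grp == "HIGH") == ncol(grp)
  allLow <- rowSums(grp == "LOW") == ncol(grp)
  statusVec <- ifelse(allHigh, "HC_HYPOXIC",
                      ifelse(allLow, "HC_NORMOXIC", "LOW_CONF"))
  names(fits) <- colnames(s)
  new("HypoxiaLabels", cellId = rownames(s), status = unname(statusVec),
      perSetGroup = grp, posteriorHigh = post, fits = fits)
}

#' Score-to-label convenience wrapper
#'
#' Fits one mixture per gene set (per-set seeds expanded deterministically
#' from the master seed by set index) and applies the consensus rule.
#'
#' @inheritParams consensusLabel
#' @param seed master seed; set `k` uses `(seed + 1009 * k) mod (2^31 - 1)`.
#' @param nInit,tol,maxIter passed to [fitGmm1d()].
#' @return a [HypoxiaLabels-class].
#' @export
labelHypoxia <- function(scoreMat, seed = 0L, posteriorCut = 0.5,
                         nInit = 5L, tol = 1e-6, maxIter = 500L) {
  stopifnot(is(scoreMat, "ScoreMatrix"))
  fits <- lapply(seq_len(ncol(scoreMat@scores)), function(k) {
    fitGmm1d(scoreMat@scores[, k],
             seed = (as.integer(seed) + 1009L * k) %% 2147483647L,
             nInit = nInit, tol = tol, maxIter = maxIter)
  })
  consensusLabel(scoreMat, fits, posteriorCut)
}
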
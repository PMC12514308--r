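#' Specify a nonlinear multivariate autoregressive ground-truth model
#'
#' Defines the forward model `x(n) = f(x_p) + noise`: a linear MVAR part
#' with coefficient tensor `A` (target x source x lag) plus an optional
#' list of nonlinear terms, each a list with elements `src`, `lag`, `tgt`,
#' `weight` and `fun` (one of `"square"`, `"scaled_tanh"`,
#' `"cross_product"`). A `cross_product` term multiplies the lagged source
#' with a second lagged channel `src2` (default: the cyclically next
#' channel). The linear part must be stable: the spectral radius of the
#' companion matrix of `A` must be below 1.
#'
#' @param M channel count.
#' @param p model order (lags), at least 1.
#' @param A numeric array M x M x p; `A[j, i, k]` couples source channel i
#'   at lag k into target channel j. Defaults to all zero.
#' @param nonlinearTerms list of nonlinear term descriptors (see above).
#' @param noiseSd innovation standard deviation per channel (recycled).
#' @return an object of class `nmvarSpec` (a validated list).
#' @examples
#' A <- array(0, c(2, 2, 1)); A[2, 1, 1] <- 0.5
#' spec <- nmvarSpec(M = 2, p = 1, A = A)
#' x <- simulateNmvar(spec, 500, seed = 1)
#' @export
nmvarSpec <- function(M, p, A = NULL, nonlinearTerms = list(), noiseSd = 1) {
  stopIfNot(p >= 1, "model order p must be >= 1")
  stopIfNot(M >= 1, "M must be >= 1")
  if (is.null(A)) A <- array(0, c(M, M, p))
  A <- array(as.numeric(A), c(M, M, p))
  funs <- c("square", "scaled_tanh", "cross_product")
  nonlinearTerms <- lapply(nonlinearTerms, function(tm) {
    stopIfNot(
      all(c("src", "lag", "tgt", "weight", "fun") %in% names(tm)),
      "each nonlinear term needs src, lag, tgt, weight, fun"
    )
    stopIfNot(tm$fun %in% funs, sprintf(
      "nonlinear function tag must be one of: %s", paste(funs, collapse = ", ")
    ))
    stopIfNot(tm$lag >= 1 && tm$lag <= p, "nonlinear term lag must lie in 1..p")
    if (tm$fun == "cross_product" && is.null(tm$src2)) tm$src2 <- tm$src %% M + 1L
    tm
  })
  rho <- companionSpectralRadius(A)
  if (rho >= 1) {
    stop(sprintf(
      "linear part is unstable: companion spectral radius %.4f >= 1", rho
    ), call. = FALSE)
  }
  structure(
    list(
      M = as.integer(M), p = as.integer(p), A = A,
      nonlinearTerms = nonlinearTerms,
      noiseSd = rep_len(as.numeric(noiseSd), M),
      spectralRadius = rho
    ),
    class = "nmvarSpec"
  )
}

companionSpectralRadius <- function(A) {
  M <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, M * p, M * p)
  for (k in seq_len(p)) comp[1:M, (k - 1) * M + 1:M] <- A[, , k]
  if (p > 1) {
    comp[(M + 1):(M * p), 1:(M * (p - 1))] <- diag(M * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a nonlinear MVAR time series
#'
#' Runs the forward model of an [nmvarSpec()]: each sample is the linear
#' combination of `p` lagged values of all channels, plus the nonlinear
#' terms evaluated at lagged values, plus Gaussian innovations. The first
#' `p` samples are drawn from the innovation distribution.
#'
#' @param spec an [nmvarSpec()].
#' @param nSamples number of samples, must exceed `10 * p`.
#' @param seed integer seed; the output is reproducible given the seed.
#' @return numeric matrix, channels x samples.
#' @export
simulateNmvar <- function(spec, nSamples, seed = NULL) {
  stopifnot(inherits(spec, "nmvarSpec"))
  stopIfNot(nSamples > 10 * spec$p, "nSamples must exceed 10 * p")
  M <- spec$M; p <- spec$p
  withSeed(seed, {
    x <- matrix(0, M, nSamples)
    innov <- matrix(rnorm(M * nSamples, sd = spec$noiseSd), M, nSamples)
    x[, seq_len(p)] <- innov[, seq_len(p)]
    for (n in (p + 1):nSamples) {
      v <- innov[, n]
      for (k in seq_len(p)) v <- v + spec$A[, , k] %*% x[, n - k]
      for (tm in spec$nonlinearTerms) {
        u <- x[tm$src, n - tm$lag]
        g <- switch(tm$fun,
          square = u^2,
          scaled_tanh = tanh(u),
          cross_product = u * x[tm$src2, n - tm$lag]
        )
        v[tm$tgt] <- v[tm$tgt] + tm$weight * g
      }
      x[, n] <- v
    }
    x
  })
}

## Random stable linear MVAR coefficients with distinct off-diagonal
## magnitudes; used by validation studies and tests.
randomStableVar <- function(M, p, seed, density = 0.5, scale = 0.4) {
  withSeed(seed, {
    repeat {
      A <- array(0, c(M, M, p))
      for (k in seq_len(p)) {
        mask <- matrix(runif(M * M) < density, M, M)
        diag(mask) <- TRUE
        vals <- matrix(runif(M * M, 0.1, 1) * sample(c(-1, 1), M * M, TRUE), M, M)
        A[, , k] <- vals * mask * scale / k
      }
      if (companionSpectralRadius(A) < 0.95) break
    }
    A
  })
}
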
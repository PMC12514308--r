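#' Iterative random-forest imputation of a feature table
#'
#' missForest-style round-robin imputation: missing cells are initialised
#' with column medians, then each incomplete column in turn (most-missing
#' last) is regressed on all other columns with a random-forest regressor
#' and its missing entries refreshed, iterating until the relative change
#' of the imputed values falls below `tol` or `maxIter` rounds are
#' reached. Deterministic under a fixed seed.
#'
#' @param table data.frame or matrix, subjects x numeric feature columns,
#'   with `NA` marking missing cells. Every column needs at least two
#'   observed values; an all-missing column is an error.
#' @param tol relative-change stopping tolerance (default 1e-3).
#' @param maxIter maximum rounds (default 10).
#' @param ntree trees per forest (default 100).
#' @param nodesize minimum leaf size of the regression trees (default 3;
#'   small, because the tables are small).
#' @param seed integer seed.
#' @return the completed table (same class and dimnames), with attributes
#'   `iterations` and `converged`.
#' @export
imputeFeatures <- function(table, tol = 1e-3, maxIter = 10, ntree = 100,
                           nodesize = 3, seed = NULL) {
  isDf <- is.data.frame(table)
  x <- as.matrix(table)
  stopIfNot(is.numeric(x), "feature table must be numeric")
  nObs <- colSums(!is.na(x))
  if (any(nObs == 0)) {
    stop(sprintf(
      "all-missing column(s): %s",
      paste(colnames(x)[nObs == 0], collapse = ", ")
    ), call. = FALSE)
  }
  stopIfNot(all(nObs >= 2), "each column needs at least 2 observed values")
  missIdx <- which(is.na(x))
  if (!length(missIdx)) {
    attr(table, "iterations") <- 0L
    attr(table, "converged") <- TRUE
    return(table)
  }
  filled <- x
  med <- apply(x, 2, median, na.rm = TRUE)
  for (j in seq_len(ncol(x))) {
    filled[is.na(x[, j]), j] <- med[j]
  }
  incomplete <- order(colSums(is.na(x)))
  incomplete <- incomplete[colSums(is.na(x))[incomplete] > 0]
  converged <- FALSE
  it <- 0L
  withSeed(seed, {
    while (it < maxIter && !converged) {
      it <- it + 1L
      prev <- filled[missIdx]
      for (j in incomplete) {
        obs <- !is.na(x[, j])
        ## feature columns are strongly inter-correlated, so consider all
        ## predictors at every split (bagging) rather than a random subset
        fit <- randomForest::randomForest(
          x = filled[obs, -j, drop = FALSE], y = x[obs, j], ntree = ntree,
          mtry = ncol(x) - 1L, nodesize = nodesize
        )
        filled[!obs, j] <- predict(fit, filled[!obs, -j, drop = FALSE])
      }
      delta <- sqrt(sum((filled[missIdx] - prev)^2)) /
        max(sqrt(sum(filled[missIdx]^2)), .Machine$double.eps)
      converged <- delta < tol
    }
  })
  out <- if (isDf) as.data.frame(filled) else filled
  dimnames(out) <- dimnames(table)
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}
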
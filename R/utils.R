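#' @useDynLib ncreann, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats aov coef cor fft lm.fit median p.adjust pt qnorm quantile
#'   rnorm runif sd t.test var wilcox.test complete.cases predict setNames
#' @importFrom utils head tail
NULL

## Run `expr` under a fixed RNG state without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive reproducible child seeds from one parent seed (kept < 2^31).
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopIfNot <- function(cond, msg, class = "ncreann_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

## Standard 3 x 3 grid over medial PFC: columns L/C/R at -1.5/0/+1.5 mm
## mediolateral, rows F/M/P at +2/0/-2 mm rostrocaudal.
#' Channel labels and planar coordinates of the 3 x 3 epidural grid
#'
#' Nine electrodes over medial prefrontal cortex, labelled by row
#' (F frontal, M medial, P posterior) and column (L left, C central,
#' R right), spaced 1.5 mm mediolaterally and 2.0 mm rostrocaudally.
#'
#' @return `gridLabels()` a character vector of nine labels;
#'   `gridCoordinates()` a two-column matrix (x_mm, y_mm) with labels as
#'   row names.
#' @export
gridLabels <- function() {
  c("FC", "FL", "FR", "MC", "ML", "MR", "PC", "PL", "PR")
}

#' @rdname gridLabels
#' @export
gridCoordinates <- function() {
  lab <- gridLabels()
  colx <- c(C = 0, L = -1.5, R = 1.5)
  rowy <- c(F = 2, M = 0, P = -2)
  xy <- cbind(
    x_mm = colx[substr(lab, 2, 2)],
    y_mm = rowy[substr(lab, 1, 1)]
  )
  rownames(xy) <- lab
  xy
}
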
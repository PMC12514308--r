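#' Mann-Whitney U test with rank-biserial effect size
#'
#' Two-sided Mann-Whitney U comparison of two independent groups: exact
#' for small samples without ties (both n <= 10), otherwise the normal
#' approximation with tie correction. `U` counts pairs where a value of
#' `a` exceeds a value of `b` (half for ties); the rank-biserial effect
#' size is `r_rb = 1 - 2U/(n_a n_b)`, so `r_rb = 1` when every `a` is
#' below every `b`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list: `U`, `p`, `effectSize`, `nA`, `nB`, `method`.
#' @export
mannWhitneyEffect <- function(a, b) {
  stopIfNot(length(a) >= 2 && length(b) >= 2,
            "each group needs at least 2 values")
  nA <- length(a); nB <- length(b)
  hasTies <- anyDuplicated(c(a, b)) > 0
  exact <- nA <= 10 && nB <= 10 && !hasTies
  wt <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  U <- unname(wt$statistic)                 # pairs with a > b (+0.5 ties)
  list(
    U = U, p = wt$p.value,
    effectSize = 1 - 2 * U / (nA * nB),
    nA = nA, nB = nB,
    method = if (exact) "exact" else "normal approximation, tie-corrected"
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment; adjusted values are at least
#' the raw values and monotone in rank.
#'
#' @param pValues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
fdrAdjust <- function(pValues) {
  stopIfNot(is.numeric(pValues) && all(is.finite(pValues)),
            "p-values must be finite numbers")
  stopIfNot(all(pValues >= 0 & pValues <= 1),
            "p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Mixed-design repeated-measures ANOVA on one feature
#'
#' Univariate mixed ANOVA with between-subject factor `group` and
#' within-subject factors `treatment` and `channel`, subject as the
#' repeated unit (`aov` with the `Error(subject/(treatment*channel))`
#' strata). Requires a complete balanced design (impute first). The
#' Greenhouse-Geisser-corrected p-value is reported alongside the
#' uncorrected one for effects involving the channel factor.
#'
#' @param table data.frame with columns `subject`, `group`, `treatment`,
#'   `channel`, `value` (one row per subject x treatment x channel).
#' @return data.frame: `effect`, `dfNum`, `dfDen`, `F`, `p`, `pGG`
#'   (`NA` where no sphericity correction applies).
#' @export
rmAnova <- function(table) {
  needed <- c("subject", "group", "treatment", "channel", "value")
  stopIfNot(all(needed %in% names(table)), sprintf(
    "table must have columns %s", paste(needed, collapse = ", ")
  ))
  tab <- table
  for (v in c("subject", "group", "treatment", "channel")) {
    tab[[v]] <- factor(tab[[v]])
  }
  counts <- table(tab$subject, tab$treatment, tab$channel)
  if (any(counts != 1) || anyNA(tab$value)) {
    stop("unbalanced or incomplete design: impute missing cells first",
         call. = FALSE)
  }
  ## drop single-level factors so collapsed designs (e.g. one group, one
  ## channel) still fit; the two-level/one-channel case reduces to the
  ## paired t-test (F = t^2)
  between <- if (nlevels(tab$group) > 1) "group" else NULL
  within <- c(
    if (nlevels(tab$treatment) > 1) "treatment" else NULL,
    if (nlevels(tab$channel) > 1) "channel" else NULL
  )
  stopIfNot(length(within) > 0, "no within-subject factor varies")
  rhs <- paste(c(between, within), collapse = " * ")
  errTerm <- sprintf("Error(subject / (%s))", paste(within, collapse = " * "))
  fit <- aov(stats::as.formula(paste("value ~", rhs, "+", errTerm)),
             data = tab)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    st <- stratum[[1]]
    effs <- trimws(rownames(st))
    for (k in seq_along(effs)) {
      if (effs[k] == "Residuals") next
      rows[[length(rows) + 1L]] <- data.frame(
        effect = gsub(":", " x ", effs[k]),
        dfNum = st$Df[k],
        dfDen = st$Df[effs == "Residuals"],
        F = st$`F value`[k],
        p = st$`Pr(>F)`[k]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ## degenerate all-equal data gives 0/0 mean squares; report no effect
  nan <- is.nan(out$F)
  out$F[nan] <- 0
  out$p[nan] <- 1
  eps <- ggEpsilon(tab)
  out$pGG <- NA_real_
  chEff <- grepl("channel", out$effect)
  if (!is.na(eps)) {
    out$pGG[chEff] <- stats::pf(
      out$F[chEff], eps * out$dfNum[chEff], eps * out$dfDen[chEff],
      lower.tail = FALSE
    )
  }
  attr(out, "ggEpsilon") <- eps
  out
}

## Greenhouse-Geisser epsilon for the channel factor, from the pooled
## within-subject covariance of channel means (averaged over treatment).
ggEpsilon <- function(tab) {
  agg <- stats::aggregate(value ~ subject + channel, data = tab, FUN = mean)
  wide <- stats::reshape(agg, idvar = "subject", timevar = "channel",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  k <- ncol(m)
  if (k < 3 || nrow(m) <= k) return(NA_real_)
  S <- stats::cov(m)
  ## double-centred covariance
  Sc <- S - matrix(rowMeans(S), k, k) - matrix(colMeans(S), k, k, byrow = TRUE) +
    mean(S)
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (den <= 0) return(NA_real_)
  min(1, num / den)
}

#' Channelwise paired t-tests between treatments
#'
#' Classical paired t-test of post versus pre per channel, with BH-FDR
#' adjustment across channels. A channel with zero-variance differences
#' is flagged: p is 1 when all differences are zero and 0 (degenerate,
#' infinite t) when the constant difference is non-zero.
#'
#' @param pre,post numeric matrices, subjects x channels, equal
#'   dimensions, at least 3 subjects.
#' @return data.frame: `channel`, `t`, `df`, `p`, `pFdr`,
#'   `zeroVariance`.
#' @export
pairedTByChannel <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopIfNot(all(dim(pre) == dim(post)), "pre and post dimensions differ")
  stopIfNot(nrow(pre) >= 3, "need at least 3 paired observations")
  nCh <- ncol(pre)
  labels <- colnames(pre) %||% as.character(seq_len(nCh))
  out <- data.frame(
    channel = labels, t = NA_real_, df = nrow(pre) - 1, p = NA_real_,
    zeroVariance = FALSE
  )
  for (ch in seq_len(nCh)) {
    d <- post[, ch] - pre[, ch]
    ## relative zero-variance guard (matches t.test's internal criterion)
    if (sd(d) < sqrt(.Machine$double.eps) * max(abs(mean(d)), 1)) {
      out$zeroVariance[ch] <- TRUE
      out$t[ch] <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      out$p[ch] <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- t.test(post[, ch], pre[, ch], paired = TRUE)
      out$t[ch] <- unname(tt$statistic)
      out$p[ch] <- tt$p.value
    }
  }
  out$pFdr <- fdrAdjust(out$p)
  out
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x`, `y` and the covariate, residualises the ranked
#' `x` and `y` on the ranked covariate by least squares, and correlates
#' the residuals; the p-value uses the t approximation with `n - 3`
#' degrees of freedom.
#'
#' @param x,y,covariate numeric vectors of common length >= 5.
#' @return list: `rho`, `p`, `n`, `df`.
#' @export
partialSpearman <- function(x, y, covariate) {
  n <- length(x)
  stopIfNot(length(y) == n && length(covariate) == n,
            "inputs must have a common length")
  stopIfNot(n >= 5, "need at least 5 observations")
  stopIfNot(sd(x) > 0 && sd(y) > 0 && sd(covariate) > 0,
            "constant input")
  rx <- rank(x); ry <- rank(y); rz <- rank(covariate)
  resid <- function(v, z) lm.fit(cbind(1, z), v)$residuals
  ex <- resid(rx, rz); ey <- resid(ry, rz)
  rho <- cor(ex, ey)
  df <- n - 3
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
       n = n, df = df)
}
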
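#' One-way ANOVA on per-group OI samples
#'
#' Classical (pooled-variance) one-way analysis of variance across groups of
#' OI values, via \code{stats::oneway.test}. When every group has zero
#' within-group variance the F ratio degenerates: unequal group means are
#' reported as \code{F = Inf, p = 0}, identical values everywhere as
#' \code{F = 0, p = 1}.
#'
#' @param groups list of numeric vectors, one per group; at least two groups
#'   with at least two finite values each.
#' @param welch use the Welch correction instead of the classical pooled
#'   test.
#' @return list with elements \code{fStatistic}, \code{pValue}, \code{df}
#'   (numerator and denominator degrees of freedom).
#' @examples
#' oneWayAnova(list(a = c(0, 1), b = c(1, 2)))
#' @export
oneWayAnova <- function(groups, welch = FALSE) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least two values")
  vals <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(vals))) stop("group values must be finite")
  g <- factor(rep(seq_along(groups), sizes))
  dfNum <- length(groups) - 1L
  dfDen <- length(vals) - length(groups)
  withinVar <- vapply(groups, stats::var, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  if (all(withinVar == 0)) {
    if (max(means) - min(means) == 0)
      return(list(fStatistic = 0, pValue = 1, df = c(dfNum, dfDen)))
    return(list(fStatistic = Inf, pValue = 0, df = c(dfNum, dfDen)))
  }
  fit <- stats::oneway.test(v ~ g, data.frame(v = vals, g = g),
                            var.equal = !welch)
  f <- unname(fit$statistic)
  p <- unname(fit$p.value)
  if (!is.finite(f)) { f <- 0; p <- 1 }
  list(fStatistic = f, pValue = p,
       df = unname(fit$parameter))
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts the m raw p-values ascending, applies the Sidak correction at each
#' step (\code{1 - (1 - p_(i))^(m - i + 1)}), enforces monotonicity with a
#' running maximum, and restores the input order.
#'
#' @param pValues numeric vector of raw p-values in \code{[0, 1]}.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holmSidak(c(0.01, 0.04))   # 1 - 0.99^2 = 0.0199, then 0.04
#' @export
holmSidak <- function(pValues) {
  if (length(pValues) == 0L) return(numeric(0))
  if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pValues)
  o <- order(pValues)
  pSorted <- pValues[o]
  adj <- 1 - (1 - pSorted)^(m - seq_len(m) + 1)
  adj <- cummax(pmin(adj, 1))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare OI values across experimental conditions
#'
#' Assembles per-condition OI samples from a per-image result table, runs the
#' one-way ANOVA, and performs all pairwise comparisons with pooled-variance
#' t statistics adjusted by the Holm-Sidak step-down method.
#'
#' @param oiTable data.frame with (at least) columns \code{condition} and
#'   \code{oi_percent}, one row per analyzed image.
#' @param conditions optional character vector of admissible condition
#'   labels; a label in the table but not in this list is an error.
#' @param welch use Welch's ANOVA instead of the classical pooled test.
#' @return a \code{\linkS4class{GroupComparison}}.
#' @examples
#' tab <- data.frame(
#'   condition = rep(c("serum-free", "PDGF"), each = 4),
#'   oi_percent = c(21, 25, 19, 30, 62, 70, 58, 66))
#' compareConditions(tab)
#' @export
compareConditions <- function(oiTable, conditions = NULL, welch = FALSE) {
  if (!is.data.frame(oiTable) ||
      !all(c("condition", "oi_percent") %in% names(oiTable)))
    stop("oiTable needs columns 'condition' and 'oi_percent'")
  if (!is.null(conditions)) {
    bad <- setdiff(unique(oiTable$condition), conditions)
    if (length(bad))
      stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  groups <- split(oiTable$oi_percent, oiTable$condition)
  if (length(groups) < 2L)
    stop("need at least two conditions to compare")
  an <- oneWayAnova(groups, welch = welch)
  labs <- names(groups)
  pairs <- utils::combn(labs, 2)
  # pooled-variance pairwise t statistics on the ANOVA residual df
  sizes <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  dfDen <- sum(sizes) - length(groups)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1))) /
    dfDen
  pRaw <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse * (1 / sizes[pr[1]] + 1 / sizes[pr[2]]))
    if (se == 0) return(if (means[pr[1]] == means[pr[2]]) 1 else 0)
    tstat <- (means[pr[1]] - means[pr[2]]) / se
    2 * stats::pt(-abs(tstat), dfDen)
  })
  pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                         p_raw = pRaw, p_adj = holmSidak(pRaw),
                         row.names = NULL)
  new("GroupComparison", groupLabels = labs, oiSamples = groups,
      fStatistic = an$fStatistic, pValue = an$pValue, pairwise = pairwise)
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison: %d conditions (%s)\n",
              length(object@groupLabels),
              paste(object@groupLabels, collapse = ", ")))
  means <- vapply(object@oiSamples[object@groupLabels], mean, numeric(1))
  cat("  group mean OI (%):",
      paste(sprintf("%s=%.1f", object@groupLabels, means), collapse = ", "),
      "\n")
  cat(sprintf("  ANOVA F = %.4g, p = %.4g\n",
              object@fStatistic, object@pValue))
  if (nrow(object@pairwise)) {
    cat("  Holm-Sidak pairwise:\n")
    for (i in seq_len(nrow(object@pairwise)))
      cat(sprintf("    %s vs %s: p_raw = %.4g, p_adj = %.4g\n",
                  object@pairwise$group1[i], object@pairwise$group2[i],
                  object@pairwise$p_raw[i], object@pairwise$p_adj[i]))
  }
})

#' Flatten a GroupComparison to a data.frame for CSV export
#'
#' @param x a \code{\linkS4class{GroupComparison}}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame, one row per pairwise comparison, with the overall
#'   ANOVA F and p repeated on each row.
#' @export
as.data.frame.GroupComparison <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(x@pairwise,
             f_statistic = x@fStatistic,
             anova_p = x@pValue,
             row.names = NULL)
}
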
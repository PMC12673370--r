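#' @include AllClasses.R
NULL

#' ROUT outlier identification for a single sample
#'
#' Robust outlier detection controlling the false discovery rate, applied
#' to the constant-location model relevant for scalar group data: the
#' robust fit is the median, the robust scale (RSDR) is the 68.27th
#' percentile of the absolute residuals with the small-n correction
#' `n / (n - 1)`, and candidate outliers are screened by a
#' Benjamini-Hochberg-style criterion on two-tailed t-derived p-values of
#' the standardized residuals at the desired maximal FDR `Q`.
#'
#' @param values numeric vector, n >= 4 (smaller samples return no
#'   outliers with a warning).
#' @param Q desired maximal false discovery rate, default 0.01.
#' @return integer indices of flagged values, with attribute `"rsdr"`.
#' @export
#' @examples
#' routOutliers(c(rnorm(19), 50))
routOutliers <- function(values, Q = 0.01) {
  n <- length(values)
  if (n < 4L) {
    warning("ROUT needs n >= 4; no outliers flagged")
    return(structure(integer(0), rsdr = NA_real_))
  }
  res <- values - stats::median(values)
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE) * n / (n - 1)
  if (rsdr <= 0) return(structure(integer(0), rsdr = 0))
  p <- 2 * stats::pt(-abs(res) / rsdr, df = n - 1)
  o <- order(p)
  thresh <- Q * seq_len(n) / n
  k <- which(p[o] <= thresh)
  flagged <- if (length(k)) sort(o[seq_len(max(k))]) else integer(0)
  structure(as.integer(flagged), rsdr = rsdr)
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p_raw)^m` over `m` comparisons; monotone in `p_raw`
#' and bounded by 1, with `p_adj = p_raw` for a single comparison.
#'
#' @param p raw p-value(s).
#' @param m number of comparisons in the family.
#' @return adjusted p-value(s).
#' @export
#' @examples
#' sidakAdjust(0.05, 3)  # 1 - 0.95^3
sidakAdjust <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  1 - (1 - p)^m
}

# exact two-sided Mann-Whitney p by complete enumeration of all
# choose(N, n1) group assignments, with midranks for ties
.mwExact <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (N - n1) / 2
  cmb <- utils::combn(N, n1)
  u <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u - mu) >= abs(uObs - mu) - 1e-9)
}

.mwApprox <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(a, b))
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  min(1, 2 * stats::pnorm(-abs(u - mu) / sqrt(sig2)))
}

.summarize <- function(x, style) {
  if (style == "median +/- IQR")
    c(center = stats::median(x), spread = stats::IQR(x))
  else c(center = mean(x), spread = stats::sd(x))
}

#' Two-group comparison
#'
#' Student's t-test (means, summarized mean +/- SD) or the Mann-Whitney U
#' test (medians, summarized median +/- IQR), two-sided. The Mann-Whitney
#' p-value is computed by exact enumeration of all group assignments for
#' combined n <= 20 (with midranks under ties) and by the
#' tie-corrected normal approximation otherwise. Optional ROUT outlier
#' screening is applied per group before testing.
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param test `"t"` or `"mannwhitney"`.
#' @param groupNames labels for the two groups.
#' @param routQ if non-`NULL`, apply [routOutliers()] per group at this Q
#'   before testing.
#' @return A [GroupComparison-class].
#' @export
#' @examples
#' compareTwo(c(1, 2, 3), c(4, 5, 6), test = "mannwhitney")
compareTwo <- function(a, b, test = c("t", "mannwhitney"),
                       groupNames = c("A", "B"), routQ = NULL) {
  test <- match.arg(test)
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  out <- data.frame(group = character(0), value = numeric(0))
  if (!is.null(routQ)) {
    ia <- routOutliers(a, routQ); ib <- routOutliers(b, routQ)
    if (length(ia)) out <- rbind(out, data.frame(group = groupNames[1],
                                                 value = a[ia]))
    if (length(ib)) out <- rbind(out, data.frame(group = groupNames[2],
                                                 value = b[ib]))
    if (length(ia)) a <- a[-ia]
    if (length(ib)) b <- b[-ib]
  }
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs n >= 2 after outlier removal")
  if (test == "t") {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    stat <- c(t = unname(tt$statistic)); p <- tt$p.value
    style <- "mean +/- SD"; name <- "t-test"
  } else {
    r <- rank(c(a, b))
    u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    p <- if (length(a) + length(b) <= 20) .mwExact(a, b) else .mwApprox(a, b)
    stat <- c(U = u)
    style <- "median +/- IQR"; name <- "Mann-Whitney U"
  }
  sa <- .summarize(a, style); sb <- .summarize(b, style)
  new("GroupComparison", test = name, groups = groupNames,
      n = c(length(a), length(b)), statistic = stat, pValue = p,
      pairwise = data.frame(), outliers = out,
      summaries = data.frame(group = groupNames,
                             n = c(length(a), length(b)),
                             center = c(sa["center"], sb["center"]),
                             spread = c(sa["spread"], sb["spread"])),
      summaryStyle = style)
}

#' One-way ANOVA with Sidak-corrected pairwise comparisons
#'
#' Omnibus one-way ANOVA over three or more groups followed by all
#' pairwise comparisons using the pooled error term, with Sidak
#' adjustment `1 - (1 - p)^m` over the `m` pairs. Optional ROUT screening
#' is applied per group first. Summaries are mean +/- SD.
#'
#' @param values numeric vector of observations.
#' @param groups factor or character vector of group labels (>= 3
#'   groups, each n >= 2).
#' @param routQ if non-`NULL`, apply [routOutliers()] per group at this
#'   Q before testing.
#' @return A [GroupComparison-class] with the pairwise table populated.
#' @export
anovaSidak <- function(values, groups, routQ = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 3)
    stop("anovaSidak needs >= 3 groups; use compareTwo for two groups")
  removed <- data.frame(group = character(0), value = numeric(0))
  if (!is.null(routQ)) {
    keep <- rep(TRUE, length(values))
    for (g in levels(groups)) {
      i <- which(groups == g)
      o <- routOutliers(values[i], routQ)
      if (length(o)) {
        keep[i[o]] <- FALSE
        removed <- rbind(removed, data.frame(group = g, value = values[i[o]]))
      }
    }
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
  mse <- an[["Mean Sq"]][2]; dfe <- an[["Df"]][2]
  lv <- levels(groups)
  means <- tapply(values, groups, mean); ns <- tapply(values, groups, length)
  pairsIdx <- utils::combn(length(lv), 2)
  m <- ncol(pairsIdx)
  pw <- do.call(rbind, lapply(seq_len(m), function(k) {
    i <- pairsIdx[1, k]; j <- pairsIdx[2, k]
    diff <- means[i] - means[j]
    se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    praw <- 2 * stats::pt(-abs(diff / se), df = dfe)
    data.frame(group1 = lv[i], group2 = lv[j], estimate = unname(diff),
               p_raw = praw, p_adj = sidakAdjust(praw, m))
  }))
  rownames(pw) <- NULL
  sm <- do.call(rbind, lapply(lv, function(g)
    data.frame(group = g, n = sum(groups == g),
               center = mean(values[groups == g]),
               spread = stats::sd(values[groups == g]))))
  new("GroupComparison", test = "one-way ANOVA + Sidak", groups = lv,
      n = as.integer(ns), statistic = c(F = Fv), pValue = p,
      pairwise = pw, outliers = removed, summaries = sm,
      summaryStyle = "mean +/- SD")
}
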
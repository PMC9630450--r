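#' @include AllClasses.R
NULL

#' Significance star mapping
#'
#' The reporting convention: `*` for p < 0.05, `**` < 0.01, `***` < 0.001,
#' `****` < 0.0001, `"ns"` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significanceStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) NA_character_
    else if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, "")
}

#' Descriptive summary per the box-plot convention
#'
#' Quartiles plus whiskers placed exactly at 1.5 x the interquartile range
#' below and above the first and third quartiles (the plotting convention the
#' reports follow).
#'
#' @param x numeric vector.
#' @return one-row data.frame with `n, mean, sd, sem, median, q1, q3,
#'   whisker_lo, whisker_hi`.
#' @export
boxStats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
             sem = stats::sd(x) / sqrt(length(x)),
             median = q[2], q1 = q[1], q3 = q[3],
             whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
}

groupSummaryTable <- function(groups) {
  out <- do.call(rbind, lapply(groups, boxStats))
  cbind(data.frame(group = names(groups)), out, row.names = NULL)
}

## ---------------------------------------------------------------------------
## Dunnett distribution: P(max_j |T_j| <= q) for the equicorrelated
## multivariate t with correlations lambda_j * lambda_k,
## lambda_j = sqrt(n_j / (n_j + n_0)). T_j = (Z_j + lambda_j Z0) / U with
## U = S/sigma, nu U^2 ~ chi^2_nu. Deterministic nested adaptive quadrature.
## ---------------------------------------------------------------------------

pDunnettMax <- function(q, lambdas, df) {
  if (q <= 0) return(0)
  sq <- sqrt(1 - lambdas^2)
  inner <- function(u) {
    # X_j = lambda_j Z0 + sqrt(1 - lambda_j^2) Z_j; integrate over Z0
    vapply(u, function(ui) {
      fz <- function(z) {
        acc <- rep(1, length(z))
        for (j in seq_along(lambdas))
          acc <- acc * (stats::pnorm((q * ui - lambdas[j] * z) / sq[j]) -
                        stats::pnorm((-q * ui - lambdas[j] * z) / sq[j]))
        acc * stats::dnorm(z)
      }
      stats::integrate(fz, -9, 9, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  if (!is.finite(df)) return(inner(1))
  # density of U = sqrt(chi^2_df / df), on the log scale for large df
  dU <- function(u)
    exp(log(2) + (df / 2) * log(df / 2) + (df - 1) * log(u) -
          df * u^2 / 2 - lgamma(df / 2))
  lo <- sqrt(stats::qchisq(1e-12, df) / df)
  hi <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  stats::integrate(function(u) dU(u) * inner(u), lo, hi,
                   rel.tol = 1e-9, abs.tol = 1e-12)$value
}

## Dunn's post-hoc z statistic and two-sided p between rank sums i, j,
## with tie correction. ranks over the pooled sample; N total.
dunnPair <- function(rbarI, rbarJ, nI, nJ, N, tieTerm) {
  se <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / nI + 1 / nJ))
  z <- (rbarI - rbarJ) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Run a statistical test with the package's reporting conventions
#'
#' The testing layer used by all analyses. Methods are chosen explicitly by
#' the caller (no silent auto-selection); all p-values are two-sided.
#' \describe{
#'   \item{welch_t / student_t}{two-sample t tests (unequal / equal
#'     variance); use [varianceGate()] to choose.}
#'   \item{mann_whitney}{two-sample rank test (exact when sample sizes allow
#'     and no ties, normal approximation with continuity correction
#'     otherwise); the reported statistic is U for the first group.}
#'   \item{dunnett}{many-to-one comparisons against `control` with pooled
#'     variance; adjusted p-values from the exact equicorrelated
#'     multivariate-t distribution by deterministic quadrature.}
#'   \item{tukey}{all-pairs comparisons (Tukey-Kramer, studentized range).}
#'   \item{kruskal_dunn}{Kruskal-Wallis gate followed by Dunn's pairwise
#'     rank comparisons (tie-corrected, Bonferroni-adjusted; all pairs, or
#'     many-to-one when `control` is given).}
#' }
#'
#' @param groups named list of numeric vectors (>= 2 values per group;
#'   >= 2 groups, exactly 2 for the two-sample methods).
#' @param method one of `"welch_t"`, `"student_t"`, `"mann_whitney"`,
#'   `"dunnett"`, `"tukey"`, `"kruskal_dunn"`.
#' @param control name of the control group (dunnett, optionally
#'   kruskal_dunn); defaults to the first group for dunnett.
#' @param unit label for the unit of analysis recorded in the report
#'   (e.g. "frame", "cell", "brain", "field").
#' @return a [TestReport-class].
#' @examples
#' runTest(list(a = rnorm(10), b = rnorm(10)), "welch_t")
#' @export
runTest <- function(groups, method = c("welch_t", "student_t", "mann_whitney",
                                       "dunnett", "tukey", "kruskal_dunn"),
                    control = NULL, unit = "cell") {
  method <- match.arg(method)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- vapply(groups, length, 1L)
  if (any(ns < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  k <- length(groups)
  two <- method %in% c("welch_t", "student_t", "mann_whitney")
  if (two && k != 2L)
    stop(sprintf("method '%s' needs exactly two groups", method), call. = FALSE)
  if (!two && k < 2L)
    stop("multiple-comparison methods need at least two groups", call. = FALSE)

  comparisons <- data.frame()
  details <- list(method = method)
  stat <- df <- p <- NA_real_

  if (method %in% c("welch_t", "student_t")) {
    tt <- stats::t.test(groups[[1]], groups[[2]],
                        var.equal = method == "student_t")
    stat <- unname(tt$statistic); df <- unname(tt$parameter)
    p <- tt$p.value
  } else if (method == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
    stat <- unname(wt$statistic)  # U for the first group
    p <- wt$p.value
    details$exact <- is.null(wt$parameter)
  } else if (method %in% c("dunnett", "tukey")) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(names(groups), ns)
    N <- sum(ns)
    df <- N - k
    if (df < 1) stop("insufficient residual degrees of freedom", call. = FALSE)
    means <- vapply(groups, mean, 0)
    s2 <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / df
    if (method == "dunnett") {
      if (is.null(control)) control <- names(groups)[1]
      if (!control %in% names(groups))
        stop("unknown control group", call. = FALSE)
      others <- setdiff(names(groups), control)
      n0 <- ns[[control]]
      lambdas <- sqrt(ns[others] / (ns[others] + n0))
      rows <- lapply(others, function(gname) {
        tj <- (means[[gname]] - means[[control]]) /
          sqrt(s2 * (1 / ns[[gname]] + 1 / n0))
        data.frame(group1 = control, group2 = gname,
                   estimate = means[[gname]] - means[[control]],
                   statistic = tj, p = 2 * stats::pt(-abs(tj), df),
                   p_adjusted = 1 - pDunnettMax(abs(tj), unname(lambdas), df))
      })
      comparisons <- do.call(rbind, rows)
      details$control <- control
      details$adjustment <- "dunnett-mvt-quadrature"
    } else {
      pairs <- utils::combn(names(groups), 2, simplify = FALSE)
      rows <- lapply(pairs, function(pr) {
        ni <- ns[[pr[1]]]; nj <- ns[[pr[2]]]
        diff <- means[[pr[2]]] - means[[pr[1]]]
        seT <- sqrt(s2 * (1 / ni + 1 / nj))
        tij <- diff / seT
        qstat <- abs(diff) / sqrt(s2 / 2 * (1 / ni + 1 / nj))
        data.frame(group1 = pr[1], group2 = pr[2], estimate = diff,
                   statistic = tij, p = 2 * stats::pt(-abs(tij), df),
                   p_adjusted = stats::ptukey(qstat, k, df, lower.tail = FALSE))
      })
      comparisons <- do.call(rbind, rows)
      details$adjustment <- "tukey-studentized-range"
    }
  } else {  # kruskal_dunn
    x <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), ns), levels = names(groups))
    kw <- stats::kruskal.test(x, g)
    stat <- unname(kw$statistic); df <- unname(kw$parameter); p <- kw$p.value
    rk <- rank(x)
    N <- length(x)
    ties <- table(x)
    tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
    rbar <- tapply(rk, g, mean)
    pairs <- if (is.null(control)) utils::combn(names(groups), 2,
                                                simplify = FALSE)
    else lapply(setdiff(names(groups), control), function(o) c(control, o))
    m <- length(pairs)
    rows <- lapply(pairs, function(pr) {
      dp <- dunnPair(rbar[[pr[1]]], rbar[[pr[2]]], ns[[pr[1]]], ns[[pr[2]]],
                     N, tieTerm)
      data.frame(group1 = pr[1], group2 = pr[2],
                 estimate = rbar[[pr[1]]] - rbar[[pr[2]]],
                 statistic = dp$z, p = dp$p,
                 p_adjusted = pmin(1, m * dp$p))
    })
    comparisons <- do.call(rbind, rows)
    details$adjustment <- "dunn-bonferroni"
    details$kruskalGate <- p
  }
  if (nrow(comparisons))
    comparisons$stars <- significanceStars(comparisons$p_adjusted)
  new("TestReport",
      testName = method, statistic = stat, df = df, pTwoSided = p,
      comparisons = comparisons, groupSummaries = groupSummaryTable(groups),
      unit = unit, details = details)
}

#' F-test variance gate for choosing between Student and Welch t
#'
#' A two-sided F test on the variance ratio at alpha = 0.05 tells the caller
#' which two-sample t test to select (equal variance: Student; unequal:
#' Welch). The decision is reported, never applied silently.
#'
#' @param groupA,groupB numeric vectors (n >= 2 each).
#' @param alpha significance level of the gate (default 0.05).
#' @return list with `decision` ("equal" or "unequal"), `pValue`,
#'   `statistic` (the variance ratio), `recommended` ("student_t" or
#'   "welch_t") and `flag` (set when both variances are zero, where "equal"
#'   is declared by convention).
#' @export
varianceGate <- function(groupA, groupB, alpha = 0.05) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("n >= 2 per group is required", call. = FALSE)
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0)
    return(list(decision = "equal", pValue = NA_real_, statistic = NaN,
                recommended = "student_t", flag = "zero variance in both groups"))
  ft <- stats::var.test(groupA, groupB)
  dec <- if (ft$p.value < alpha) "unequal" else "equal"
  list(decision = dec, pValue = ft$p.value,
       statistic = unname(ft$statistic),
       recommended = if (dec == "equal") "student_t" else "welch_t",
       flag = NA_character_)
}
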
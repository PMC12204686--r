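# Ultrastructure statistics: Mann-Whitney U (exact by enumeration, or
# normal approximation with tie and continuity corrections), per-group
# length summaries, and conformation proportions with Wilson intervals.

# U statistic for the first sample, from midranks (handles ties).
.uStat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test (implemented, exact or normal approximation)
#'
#' U is computed from rank sums with midranks for ties. The exact two-sided
#' p value is obtained by full enumeration of the choose(n1+n2, n1) label
#' assignments of the pooled data (used automatically when n1 + n2 <= 12),
#' doubling the smaller tail and capping at 1. Otherwise a normal
#' approximation with tie correction and a 0.5 continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param method "auto", "exact", or "normal_approx".
#' @param exactLimit maximum n1 + n2 for the exact method under "auto".
#' @return a [RankTestResult-class].
#' @export
mannWhitneyU <- function(x, y, method = c("auto", "exact", "normal_approx"),
                         exactLimit = 12L) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u <- .uStat(x, y)
  if (method == "auto") method <- if (N <= exactLimit) "exact" else "normal_approx"
  if (method == "exact") {
    pooled <- c(x, y)
    idx <- combn(N, n1)
    us <- apply(idx, 2, function(ii) .uStat(pooled[ii], pooled[-ii]))
    tol <- 1e-9
    pLow <- mean(us <= u + tol)
    pHigh <- mean(us >= u - tol)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    mu <- n1 * n2 / 2
    tieTab <- table(c(x, y))
    tieTerm <- sum(tieTab^3 - tieTab)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1            # all observations tied
    } else {
      z <- (u - mu)
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  new("RankTestResult", U = u, pTwoSided = p, method = method,
      n1 = as.integer(n1), n2 = as.integer(n2))
}

#' Construct a length dataset
#'
#' @param group character group label per measurement.
#' @param length_nm positive lengths in nanometres.
#' @param conformation optional per-measurement "extended"/"compact" labels.
#' @return a [LengthDataset-class].
#' @export
newLengthDataset <- function(group, length_nm, conformation = NULL) {
  if (is.null(conformation)) conformation <- rep("", length(length_nm))
  new("LengthDataset", group = as.character(group),
      length_nm = as.numeric(length_nm),
      conformation = as.character(conformation))
}

#' Read a length dataset from CSV
#'
#' Expects columns group, length_nm and optionally conformation.
#'
#' @param path CSV file path.
#' @return a [LengthDataset-class].
#' @export
readLengthCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "length_nm") %in% names(d)))
    stop("CSV must have columns group, length_nm")
  newLengthDataset(d$group, d$length_nm, d$conformation)
}

#' Per-group summaries of spirosome lengths
#'
#' @param data a [LengthDataset-class].
#' @param threshold length threshold in nm for the tail fraction (the
#'   paper-scale question of interest: how many filaments exceed 100 nm).
#' @return data.frame with group, n, mean, sd, median, fracAbove.
#' @export
lengthSummary <- function(data, threshold = 100) {
  tab <- lengthTable(data)
  groups <- sort(unique(tab$group))
  do.call(rbind, lapply(groups, function(g) {
    v <- tab$length_nm[tab$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, median = median(v),
               fracAbove = mean(v > threshold), stringsAsFactors = FALSE)
  }))
}

#' Wilson 95% score interval for a binomial proportion
#' @param k successes.
#' @param n trials.
#' @param conf confidence level.
#' @return c(lower, upper).
#' @export
wilsonInterval <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Conformation proportions with Wilson intervals
#'
#' @param counts data.frame with columns group, extended, compact (counts).
#' @param conf confidence level.
#' @return data.frame with one row per group and class, its fraction and
#'   Wilson interval.
#' @export
conformationProportions <- function(counts, conf = 0.95) {
  if (!all(c("group", "extended", "compact") %in% names(counts)))
    stop("counts needs columns group, extended, compact")
  out <- NULL
  for (i in seq_len(nrow(counts))) {
    n <- counts$extended[i] + counts$compact[i]
    if (n <= 0) stop("zero total count for group ", counts$group[i])
    for (cls in c("extended", "compact")) {
      k <- counts[[cls]][i]
      ci <- wilsonInterval(k, n, conf)
      out <- rbind(out, data.frame(
        group = counts$group[i], class = cls, n = n, count = k,
        fraction = k / n, lower = ci[["lower"]], upper = ci[["upper"]],
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
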
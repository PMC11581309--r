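# Rank-based tests used for all group comparisons: Kruskal-Wallis with tie
# correction, Dunn's post-hoc z tests with Holm step-down adjustment,
# Mann-Whitney U with exact small-sample p, and Spearman correlation with
# mid-rank tie handling. Implemented from the defining formulas; base R's
# versions serve as independent cross-checks in the test suite. Mid-ranks
# are used everywhere for ties.

.tie_sizes <- function(r) {
  tab <- table(r)
  as.numeric(tab[tab > 1])
}

#' Kruskal-Wallis rank test
#'
#' H = 12/(N(N+1)) * sum n_i (rbar_i - rbar)^2, divided by the tie
#' correction 1 - sum(t^3 - t)/(N^3 - N); p from the chi-square
#' distribution with k - 1 degrees of freedom.
#'
#' @param groups List of numeric vectors (>= 2 groups, >= 1 value each).
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 1))
  x <- unlist(groups, use.names = FALSE)
  stopifnot(all(is.finite(x)))
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- .tie_sizes(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) {
    H <- 0
    p <- 1
  } else {
    H <- H / corr
    p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  }
  list(statistic = H, df = length(groups) - 1, p_value = p,
       method = "kruskal_wallis")
}

#' Dunn's post-hoc pairwise comparisons with Holm adjustment
#'
#' For each pair (i, j), z = (rbar_i - rbar_j) / sqrt((N(N+1)/12 -
#' sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j)) on the joint ranks, two-tailed
#' normal p, followed by Holm's step-down adjustment over all pairs.
#'
#' @param groups Named (or unnamed) list of numeric vectors.
#' @return data.frame with columns `group_a`, `group_b`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_holm <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(g)
  ties <- .tie_sizes(r)
  vterm <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(vterm * (1 / n[i] + 1 / n[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = names(groups)[pairs[1, ]],
             group_b = names(groups)[pairs[2, ]],
             z = z, p_value = p,
             p_adjusted = holm_adjust(p),
             stringsAsFactors = FALSE)
}

#' Holm step-down adjustment
#'
#' Sorted raw p-values are multiplied by (m - i + 1), made monotone by a
#' cumulative maximum, and capped at 1; order-preserving and always >= the
#' raw p.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax((m - seq_len(m) + 1) * p[o]), 1)
  adj[order(o)]
}

# exact null distribution of U for sample sizes m, n (no ties), via the
# standard recurrence N(m, n, u) = N(m - 1, n, u - n) + N(m, n - 1, u)
.mwu_exact_dist <- function(m, n) {
  maxu <- m * n
  cache <- new.env(parent = emptyenv())
  count <- function(mm, nn, u) {
    if (u < 0 || u > mm * nn) return(0)
    if (mm == 0 || nn == 0) return(as.numeric(u == 0))
    key <- paste(mm, nn, u)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- count(mm - 1, nn, u - nn) + count(mm, nn - 1, u)
    cache[[key]] <- val
    val
  }
  cnt <- vapply(0:maxu, function(u) count(m, n, u), 0)
  cnt / sum(cnt)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration of the null U distribution when
#' min(n1, n2) <= `exact_threshold` and there are no ties; otherwise the
#' normal approximation with tie-corrected variance. Two-sided p doubles
#' the smaller tail (capped at 1).
#'
#' @param x,y Numeric samples.
#' @param exact_threshold Largest min(n1, n2) for which the exact
#'   distribution is enumerated (default 8).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (referring to a location shift of `x` relative to `y`).
#' @return List with `statistic` (U of `x`), `p_value`, `exact`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 8,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2  # number of (x, y) pairs with x > y (+ ties/2)
  has_ties <- length(.tie_sizes(r)) > 0
  if (!has_ties && min(n1, n2) <= exact_threshold) {
    dist <- .mwu_exact_dist(n1, n2)
    lo <- sum(dist[seq_len(U + 1)])            # P(U <= u)
    hi <- sum(dist[(U + 1):length(dist)])      # P(U >= u)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(lo, hi)),
                less = lo, greater = hi)
    return(list(statistic = U, p_value = p, exact = TRUE,
                method = "mann_whitney_u"))
  }
  N <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- .tie_sizes(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(statistic = U, p_value = 1, exact = FALSE,
                method = "mann_whitney_u"))
  z <- (U - mu) / sqrt(sigma2)
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE))
  list(statistic = U, p_value = min(1, p), exact = FALSE,
       method = "mann_whitney_u")
}

# all permutations of 1..n (n <= 9), iterative heap-free construction
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  k <- 0L
  for (i in seq_len(n)) {
    rows <- (k + 1):(k + nrow(sub))
    out[rows, 1] <- i
    out[rows, -1] <- ifelse(sub >= i, sub + 1L, sub)
    k <- k + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks (tie-corrected); the
#' two-tailed p uses the t approximation with n - 2 degrees of freedom, or
#' the exact permutation distribution when `exact = TRUE` and n <= 9.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @param exact Use the exact permutation p (n <= 9 only).
#' @return List with `rho`, `p_value`, `n`, `undefined` (TRUE when either
#'   vector has zero rank variance), `method`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired finite observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                undefined = TRUE, method = "spearman"))
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 9) stop("exact permutation p supported for n <= 9 only")
    perms <- .permutations(n)
    rx_c <- rx - mean(rx)
    ry_c <- ry - mean(ry)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    rhos <- as.numeric(matrix(ry_c[perms], nrow = nrow(perms)) %*% rx_c) /
      denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE,
       method = "spearman")
}

#' Welch's two-sample t test (convenience)
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = FALSE`; reported
#' comparisons in the package are nonparametric, this is provided for
#' completeness only.
#'
#' @param x,y Numeric samples.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
welch_t <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       method = "welch_t")
}
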
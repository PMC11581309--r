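# Codon-level divergence and selection tests.
#
# The primary estimator is the degeneracy-class (Pamilo-Bianchi-Li style)
# dN/dS with Kimura two-parameter corrections, using Kumar's site
# classification conventions; a modified Nei-Gojobori estimate with
# transition/transversion-weighted site counting is computed alongside as a
# built-in cross-check. Differences between codons differing at more than
# one position are averaged over all orderings of single-base steps
# (pathway averaging), excluding pathways that pass through stop codons.

#' Classify the degeneracy of each position of a codon
#'
#' A codon position is fourfold degenerate when every alternative base gives
#' a synonymous codon, nondegenerate when none does, and twofold otherwise
#' (this resolves the irregular isoleucine/arginine families to the twofold
#' class; changes to stop codons count as nonsynonymous).
#'
#' @param codon A single sense codon (3 uppercase bases, standard code).
#' @return Integer vector of length 3 with values 0, 2 or 4.
#' @examples
#' classify_site_degeneracy("GGG")  # 0 0 4
#' classify_site_degeneracy("ATG")  # 0 0 0
#' @export
classify_site_degeneracy <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L, nchar(codon) == 3L)
  codon <- toupper(codon)
  deg <- .degeneracy_table()
  if (!codon %in% rownames(deg))
    stop("not a sense codon of the standard code: ", codon)
  unname(deg[codon, ])
}

# all orderings of 1..k for k <= 3
.orderings <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

#' Pathway-averaged differences between two codons
#'
#' Averages synonymous/nonsynonymous and per-degeneracy-class transition/
#' transversion difference contributions over all orderings of single-base
#' steps between two sense codons. Pathways passing through a stop codon are
#' excluded; if every pathway hits a stop the pair is flagged dropped. A
#' step at a position whose degeneracy class differs between its two codons
#' contributes half to each class.
#'
#' @param codon_a,codon_b Sense codons (3 uppercase bases).
#' @return List with `sd` and `nd` (synonymous / nonsynonymous difference
#'   counts), `ts` and `tv` (length-3 vectors of transitional and
#'   transversional contributions for classes 0/2/4), `n_pathways` (valid
#'   pathway count) and `dropped`.
#' @examples
#' count_pair_differences("TTT", "GTA")  # sd 0.5, nd 1.5
#' @export
count_pair_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  gc <- .genetic_code()
  if (gc[[codon_a]] == "*" || gc[[codon_b]] == "*")
    stop("stop codons are not allowed: ", codon_a, " / ", codon_b)
  deg <- .degeneracy_table()
  diffpos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diffpos)
  zero <- c(`0` = 0, `2` = 0, `4` = 0)
  if (k == 0L)
    return(list(sd = 0, nd = 0, ts = zero, tv = zero,
                n_pathways = 1L, dropped = FALSE))
  acc <- list()
  for (ord in .orderings[[k]]) {
    cur <- codon_a
    sd <- 0; nd <- 0; ts <- zero; tv <- zero
    ok <- TRUE
    for (pos in diffpos[ord]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      b1 <- substr(cur, pos, pos); b2 <- substr(nxt, pos, pos)
      is_ts <- .is_transition(b1, b2)
      cls_from <- as.character(deg[cur, pos])
      cls_to <- as.character(deg[nxt, pos])
      if (is_ts) {
        ts[cls_from] <- ts[cls_from] + 0.5; ts[cls_to] <- ts[cls_to] + 0.5
      } else {
        tv[cls_from] <- tv[cls_from] + 0.5; tv[cls_to] <- tv[cls_to] + 0.5
      }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) acc[[length(acc) + 1L]] <- list(sd = sd, nd = nd, ts = ts, tv = tv)
  }
  if (length(acc) == 0L)
    return(list(sd = NA_real_, nd = NA_real_, ts = zero + NA_real_,
                tv = zero + NA_real_, n_pathways = 0L, dropped = TRUE))
  m <- length(acc)
  list(
    sd = sum(vapply(acc, `[[`, 0, "sd")) / m,
    nd = sum(vapply(acc, `[[`, 0, "nd")) / m,
    ts = Reduce(`+`, lapply(acc, `[[`, "ts")) / m,
    tv = Reduce(`+`, lapply(acc, `[[`, "tv")) / m,
    n_pathways = m, dropped = FALSE)
}

# Precomputed 61x61 lookup tables of pathway-averaged contributions.
.pair_tables <- function() {
  if (!is.null(.cadevo_cache$pair_tables)) return(.cadevo_cache$pair_tables)
  sense <- .sense_codons()
  n <- length(sense)
  dn <- list(sense, sense)
  tab <- list(sd = matrix(0, n, n, dimnames = dn),
              nd = matrix(0, n, n, dimnames = dn),
              dropped = matrix(FALSE, n, n, dimnames = dn))
  for (cls in c("0", "2", "4"))
    for (kind in c("ts", "tv"))
      tab[[paste0(kind, cls)]] <- matrix(0, n, n, dimnames = dn)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- count_pair_differences(sense[i], sense[j])
      if (r$dropped) { tab$dropped[i, j] <- TRUE; next }
      tab$sd[i, j] <- r$sd; tab$nd[i, j] <- r$nd
      for (cls in c("0", "2", "4")) {
        tab[[paste0("ts", cls)]][i, j] <- r$ts[cls]
        tab[[paste0("tv", cls)]][i, j] <- r$tv[cls]
      }
    }
  }
  .cadevo_cache$pair_tables <- tab
  tab
}

# Nei-Gojobori style synonymous site count per codon. Unweighted when
# kappa = 1; transition-weighted (modified NG) otherwise. Alternatives
# creating stops are excluded from both numerator and denominator.
.syn_sites_per_codon <- function(kappa = 1) {
  nb <- .codon_neighbors()
  nb <- nb[!nb$to_stop, ]
  w <- ifelse(nb$transition, kappa, 1)
  num <- tapply(w * nb$syn, list(nb$from, nb$pos), sum)
  den <- tapply(w, list(nb$from, nb$pos), sum)
  s <- num / den
  s[is.na(s)] <- 0
  rowSums(s)
}

#' Kimura two-parameter distance
#'
#' @param P,Q Proportions of transitional and transversional differences.
#' @param n Number of sites (for the delta-method variance).
#' @return List with `d`, `variance` and `saturated`.
#' @examples
#' k2p_distance(0.1, 0.05, 1000)
#' @export
k2p_distance <- function(P, Q, n) {
  stopifnot(P >= 0, Q >= 0, n > 0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(d = NA_real_, variance = NA_real_, saturated = TRUE))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  list(d = d, variance = v, saturated = FALSE)
}

# Extract the retained codon pairs from a codon alignment (pairwise
# deletion: any codon containing a gap or ambiguity in either row drops the
# pair; stop codons in either row drop the pair with a note).
.extract_codon_pairs <- function(x, y = NULL) {
  if (inherits(x, "codon_alignment")) {
    ca <- .split_codons(x$a)
    cb <- .split_codons(x$b)
  } else if (is.character(x) && !is.null(y)) {
    ca <- if (length(x) == 1L && nchar(x[1]) > 3L) .split_codons(x) else x
    cb <- if (length(y) == 1L && nchar(y[1]) > 3L) .split_codons(y) else y
    if (length(ca) != length(cb))
      stop("codon sequences differ in length: ", length(ca), " vs ", length(cb))
  } else stop("expected a codon_alignment or two codon sequences")
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  n_gap <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  stop_pair <- .is_stop_codon(ca) | .is_stop_codon(cb)
  n_stop <- sum(stop_pair)
  list(a = ca[!stop_pair], b = cb[!stop_pair],
       n_dropped_gap = n_gap, n_dropped_stop = n_stop)
}

#' Site-class and difference counts for a codon sequence pair
#'
#' Computes the inputs of the degeneracy-class dN/dS estimator: average
#' nondegenerate/twofold/fourfold site counts (L0, L2, L4) over the two
#' sequences, per-class transition and transversion difference proportions
#' (pathway-averaged), and Nei-Gojobori style site and difference totals
#' (N, S, Nd, Sd) for the cross-check estimator and the Fisher test.
#'
#' @param x A `codon_alignment`, or a character vector of codons (or a
#'   single CDS string) for the first sequence.
#' @param y Second sequence when `x` is not a `codon_alignment`.
#' @return Object of class `codon_pair_counts`.
#' @export
codon_pair_counts <- function(x, y = NULL) {
  p <- .extract_codon_pairs(x, y)
  tab <- .pair_tables()
  sense <- .sense_codons()
  ia <- match(p$a, sense)
  ib <- match(p$b, sense)
  idx <- cbind(ia, ib)
  drop_path <- tab$dropped[idx]
  n_path_dropped <- sum(drop_path)
  idx <- idx[!drop_path, , drop = FALSE]
  ia <- ia[!drop_path]; ib <- ib[!drop_path]
  n_codons <- nrow(idx)
  if (n_codons == 0L) stop("no comparable codons after pairwise deletion")
  deg <- .degeneracy_table()
  La <- table(factor(deg[ia, ], levels = c(0, 2, 4)))
  Lb <- table(factor(deg[ib, ], levels = c(0, 2, 4)))
  L <- (as.numeric(La) + as.numeric(Lb)) / 2
  names(L) <- c("0", "2", "4")
  ts <- vapply(c("0", "2", "4"),
               function(cl) sum(tab[[paste0("ts", cl)]][idx]), 0)
  tv <- vapply(c("0", "2", "4"),
               function(cl) sum(tab[[paste0("tv", cl)]][idx]), 0)
  s_ng <- .syn_sites_per_codon(1)
  S <- (sum(s_ng[p$a[!drop_path]]) + sum(s_ng[p$b[!drop_path]])) / 2
  res <- list(
    L0 = L[["0"]], L2 = L[["2"]], L4 = L[["4"]],
    P0 = if (L[["0"]] > 0) ts[["0"]] / L[["0"]] else 0,
    P2 = if (L[["2"]] > 0) ts[["2"]] / L[["2"]] else 0,
    P4 = if (L[["4"]] > 0) ts[["4"]] / L[["4"]] else 0,
    Q0 = if (L[["0"]] > 0) tv[["0"]] / L[["0"]] else 0,
    Q2 = if (L[["2"]] > 0) tv[["2"]] / L[["2"]] else 0,
    Q4 = if (L[["4"]] > 0) tv[["4"]] / L[["4"]] else 0,
    n_codons = n_codons,
    N = 3 * n_codons - S, S = S,
    Nd = sum(tab$nd[idx]), Sd = sum(tab$sd[idx]),
    n_dropped_gap = p$n_dropped_gap,
    n_dropped_stop = p$n_dropped_stop,
    n_dropped_stop_path = n_path_dropped,
    codons_a = p$a[!drop_path], codons_b = p$b[!drop_path])
  class(res) <- "codon_pair_counts"
  res
}

# A_i and B_i components of the degeneracy-class estimator with their
# partial derivatives wrt (P_i, Q_i); NA when saturated.
.k2p_components <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(saturated = TRUE))
  a <- 1 / w1
  b <- 1 / w2
  list(A = -0.5 * log(w1) + 0.25 * log(w2),
       B = -0.5 * log(w2),
       a = a, b = b, saturated = FALSE)
}

#' Estimate dN, dS and selection statistics for a codon sequence pair
#'
#' Degeneracy-class estimator: with per-class transitional/transversional
#' difference proportions (P_i, Q_i) at the L_i nondegenerate (i = 0),
#' twofold (2) and fourfold (4) sites,
#' A_i = -ln(1 - 2P_i - Q_i)/2 + ln(1 - 2Q_i)/4 and
#' B_i = -ln(1 - 2Q_i)/2, and
#' dS = (L2 A2 + L4 A4)/(L2 + L4) + B4,
#' dN = A0 + (L0 B0 + L2 B2)/(L0 + L2).
#' Variances are delta-method over the per-class (P_i, Q_i) with multinomial
#' covariances. A modified Nei-Gojobori estimate (transition-weighted site
#' counts with the transition/transversion ratio estimated from the pair,
#' Jukes-Cantor corrected) is attached as `ng` for cross-checking, and the
#' codon-based Z-test and Fisher exact test of selection are reported.
#'
#' @param x A `codon_alignment` or first codon sequence (see
#'   [codon_pair_counts()]).
#' @param y Second sequence when `x` is not a `codon_alignment`.
#' @return Object of class `selection_result` with fields `dS`, `dN`,
#'   `var_dS`, `var_dN`, `omega`, `Z`, `p_neutral`, `p_negative`,
#'   `p_positive`, `fisher_p`, `n_codons`, `counts`, `ng` and `flags`.
#' @export
estimate_dn_ds <- function(x, y = NULL) {
  cnt <- if (inherits(x, "codon_pair_counts")) x else codon_pair_counts(x, y)
  flags <- character(0)
  k0 <- .k2p_components(cnt$P0, cnt$Q0)
  k2 <- .k2p_components(cnt$P2, cnt$Q2)
  k4 <- .k2p_components(cnt$P4, cnt$Q4)
  res <- list(dS = NA_real_, dN = NA_real_, var_dS = NA_real_,
              var_dN = NA_real_, omega = NA_real_, Z = NA_real_,
              p_neutral = NA_real_, p_negative = NA_real_,
              p_positive = NA_real_, fisher_p = NA_real_,
              n_codons = cnt$n_codons, counts = cnt, ng = NULL,
              flags = flags)
  class(res) <- "selection_result"
  if (k0$saturated || k2$saturated || k4$saturated) {
    res$flags <- c(res$flags, "saturated")
    return(res)
  }
  L0 <- cnt$L0; L2 <- cnt$L2; L4 <- cnt$L4
  wS2 <- L2 / (L2 + L4); wS4 <- L4 / (L2 + L4)
  wN0 <- L0 / (L0 + L2); wN2 <- L2 / (L0 + L2)
  dS <- wS2 * k2$A + wS4 * k4$A + (-0.5 * log(1 - 2 * cnt$Q4))
  dN <- k0$A + wN0 * (-0.5 * log(1 - 2 * cnt$Q0)) +
    wN2 * (-0.5 * log(1 - 2 * cnt$Q2))
  # delta-method gradients per class: g = (d/dP, d/dQ)
  b0 <- k0$b; b2 <- k2$b; b4 <- k4$b
  gS <- list(`2` = c(wS2 * k2$a, wS2 * (k2$a - b2) / 2),
             `4` = c(wS4 * k4$a, wS4 * (k4$a - b4) / 2 + b4))
  gN <- list(`0` = c(k0$a, (k0$a - b0) / 2 + wN0 * b0),
             `2` = c(0, wN2 * b2))
  vpq <- function(P, Q, L) {
    matrix(c(P * (1 - P) / L, -P * Q / L, -P * Q / L, Q * (1 - Q) / L), 2)
  }
  quad <- function(g, P, Q, L) as.numeric(t(g) %*% vpq(P, Q, L) %*% g)
  var_dS <- quad(gS[["2"]], cnt$P2, cnt$Q2, L2) +
    quad(gS[["4"]], cnt$P4, cnt$Q4, L4)
  var_dN <- quad(gN[["0"]], cnt$P0, cnt$Q0, L0) +
    quad(gN[["2"]], cnt$P2, cnt$Q2, L2)
  res$dS <- dS; res$dN <- dN
  res$var_dS <- var_dS; res$var_dN <- var_dN
  if (dS > 0) res$omega <- dN / dS else res$flags <- c(res$flags, "omega_undefined")
  # modified Nei-Gojobori cross-check
  res$ng <- .ng_estimate(cnt)
  zt <- z_test_selection(res, "neutral")
  res$Z <- zt$statistic
  res$p_neutral <- zt$p_value
  res$p_negative <- z_test_selection(res, "negative")$p_value
  res$p_positive <- z_test_selection(res, "positive")$p_value
  res$fisher_p <- fisher_exact_selection(cnt$Nd, cnt$Sd, cnt$N, cnt$S,
                                         "positive")$p_value
  res
}

# Modified Nei-Gojobori estimate: transition/transversion ratio R estimated
# from the pooled K2P components, transition-weighted site counts,
# Jukes-Cantor correction of the per-site proportions.
.ng_estimate <- function(cnt) {
  n_sites <- 3 * cnt$n_codons
  Pall <- (cnt$P0 * cnt$L0 + cnt$P2 * cnt$L2 + cnt$P4 * cnt$L4) / n_sites
  Qall <- (cnt$Q0 * cnt$L0 + cnt$Q2 * cnt$L2 + cnt$Q4 * cnt$L4) / n_sites
  kappa <- 1
  if (Qall > 0 && (1 - 2 * Pall - Qall) > 0 && (1 - 2 * Qall) > 0) {
    A <- -0.5 * log(1 - 2 * Pall - Qall) + 0.25 * log(1 - 2 * Qall)
    B <- -0.5 * log(1 - 2 * Qall)
    # A/B is the ratio of transition to transversion distances; each site
    # offers one transition and two transversions, so the per-path weight is
    # 2A/B capped to a sane range
    if (B > 0) kappa <- min(max(2 * A / B, 0.2), 20)
  }
  s <- .syn_sites_per_codon(kappa)
  S <- (sum(s[cnt$codons_a]) + sum(s[cnt$codons_b])) / 2
  N <- n_sites - S
  pS <- cnt$Sd / S
  pN <- cnt$Nd / N
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  dS <- jc(pS); dN <- jc(pN)
  list(dS = dS, dN = dN,
       omega = if (!is.na(dS) && dS > 0) dN / dS else NA_real_,
       kappa_hat = kappa, S = S, N = N)
}

#' Codon-based Z-test of selection
#'
#' Tests the null hypothesis of strict neutrality (dN = dS) with
#' Z = (dN - dS) / sqrt(var_dN + var_dS) against a two-tailed alternative
#' (`"neutral"`), negative selection dN < dS (lower tail) or positive
#' selection dN > dS (upper tail).
#'
#' @param result A `selection_result` (or list with `dN`, `dS`, `var_dN`,
#'   `var_dS`).
#' @param alternative One of `"neutral"`, `"negative"`, `"positive"`.
#' @return List with `statistic`, `p_value`, `method`, `tails`.
#' @export
z_test_selection <- function(result,
                             alternative = c("neutral", "negative", "positive")) {
  alternative <- match.arg(alternative)
  v <- result$var_dN + result$var_dS
  if (is.na(v) || v <= 0) {
    if (!is.na(result$dN) && !is.na(result$dS) && result$dN == result$dS)
      return(list(statistic = 0, p_value = 1, method = "z_test_selection",
                  tails = alternative))
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "z_test_selection", tails = alternative))
  }
  Z <- (result$dN - result$dS) / sqrt(v)
  p <- switch(alternative,
              neutral = 2 * stats::pnorm(-abs(Z)),
              negative = stats::pnorm(Z),
              positive = stats::pnorm(Z, lower.tail = FALSE))
  list(statistic = Z, p_value = p, method = "z_test_selection",
       tails = alternative)
}

#' Fisher exact test of selection for small difference counts
#'
#' One-tailed hypergeometric test on the 2x2 table
#' [[Nd, N - Nd], [Sd, S - Sd]]. Fractional pathway-averaged counts are
#' rounded half away from zero before tabulation.
#'
#' @param Nd,Sd Nonsynonymous and synonymous difference counts.
#' @param N,S Nonsynonymous and synonymous site counts.
#' @param alternative `"positive"` (excess nonsynonymous, default),
#'   `"negative"`, or `"two.sided"`.
#' @return List with `p_value`, `table`, `method`, `tails`.
#' @export
fisher_exact_selection <- function(Nd, Sd, N, S,
                                   alternative = c("positive", "negative",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  r <- function(x) sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  Nd <- r(Nd); Sd <- r(Sd); Nr <- r(N); Sr <- r(S)
  if (Nd + Sd == 0)
    return(list(p_value = 1, table = NULL, method = "fisher_exact_selection",
                tails = alternative))
  tab <- matrix(c(Nd, Nr - Nd, Sd, Sr - Sd), nrow = 2, byrow = TRUE)
  alt <- switch(alternative, positive = "greater", negative = "less",
                two.sided = "two.sided")
  p <- stats::fisher.test(tab, alternative = alt)$p.value
  list(p_value = p, table = tab, method = "fisher_exact_selection",
       tails = alternative)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Codon-based selection estimate (", x$n_codons, " codons)\n", sep = "")
  cat(sprintf("  dS = %.5f (var %.3g)   dN = %.5f (var %.3g)\n",
              x$dS, x$var_dS, x$dN, x$var_dN))
  if (!is.na(x$omega)) cat(sprintf("  dN/dS = %.4f\n", x$omega))
  if ("omega_undefined" %in% x$flags) cat("  dN/dS undefined (dS = 0)\n")
  if ("saturated" %in% x$flags) cat("  saturated pair\n")
  if (!is.na(x$Z))
    cat(sprintf("  Z = %.3f  p(neutral) = %.4g  p(negative) = %.4g  p(positive) = %.4g\n",
                x$Z, x$p_neutral, x$p_negative, x$p_positive))
  if (!is.na(x$fisher_p)) cat(sprintf("  Fisher exact (positive) p = %.4g\n", x$fisher_p))
  invisible(x)
}
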
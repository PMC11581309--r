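# Pairwise amino-acid distances: p-distance and maximum-likelihood distance
# under the empirical JTT model with uniform rates across sites.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load the JTT amino-acid substitution model
#'
#' Parses the published Jones-Taylor-Thornton exchangeabilities and
#' equilibrium frequencies from the bundled plain-text file (PAML
#' `jones.dat` layout: 19 lower-triangle rows followed by the 20
#' frequencies) and builds the normalized rate matrix Q with its spectral
#' decomposition, so that P(t) = exp(Qt) costs one 20x20 reconstruction.
#' Q is scaled to one expected substitution per site per unit time at
#' equilibrium, so ML branch lengths are substitutions per site.
#'
#' @param path Optional path to a rate file in the same layout.
#' @return Object of class `aa_subst_model` with fields `name`, `pi`, `Q`,
#'   and the spectral factors used by [jtt_distance()].
#' @export
jtt_model <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cadevo_cache$jtt)) return(.cadevo_cache$jtt)
    path <- system.file("extdata", "jtt_jones.dat", package = "cadevo")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|Order:)", lines)]
  tokens <- as.numeric(unlist(strsplit(trimws(lines[nzchar(trimws(lines))]),
                                       "\\s+")))
  if (length(tokens) < 210) stop("rate file too short: ", path)
  ex <- tokens[1:190]
  freq <- tokens[191:210]
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  k <- 0
  for (i in 2:20) for (j in 1:(i - 1)) {
    k <- k + 1
    S[i, j] <- S[j, i] <- ex[k]
  }
  pi <- freq / sum(freq)
  names(pi) <- AA_ORDER
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(AA_ORDER, AA_ORDER)
  # symmetrized form diag(sqrt(pi)) Q diag(1/sqrt(pi)) for a stable
  # eigendecomposition of the reversible generator
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  model <- list(name = "JTT", pi = pi, Q = Q,
                lambda = eig$values,
                left = diag(1 / sp) %*% eig$vectors,
                right = t(eig$vectors) %*% diag(sp))
  class(model) <- "aa_subst_model"
  if (is.null(path) || identical(path, system.file("extdata", "jtt_jones.dat",
                                                   package = "cadevo")))
    .cadevo_cache$jtt <- model
  model
}

#' Transition probability matrix P(t) = exp(Qt) of an amino-acid model
#' @param model An `aa_subst_model`.
#' @param t Time (expected substitutions per site).
#' @return 20x20 stochastic matrix.
#' @export
model_prob_matrix <- function(model, t) {
  P <- model$left %*% (exp(model$lambda * t) * model$right)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}

# 20x20 matrix of site-pattern counts over the retained columns
.pair_count_matrix <- function(a_chars, b_chars) {
  fa <- factor(a_chars, levels = AA_ORDER)
  fb <- factor(b_chars, levels = AA_ORDER)
  table(fa, fb)
}

.retained_residues <- function(alignment) {
  keep <- pairwise_deletion_mask(alignment)
  if (length(keep) == 0L) stop("no comparable sites")
  a <- strsplit(alignment$a, "")[[1]][keep]
  b <- strsplit(alignment$b, "")[[1]][keep]
  list(a = a, b = b)
}

#' Proportion of differing amino-acid sites (p-distance)
#'
#' Columns with a gap or ambiguity symbol in either row are removed first
#' (pairwise deletion).
#'
#' @param alignment A `pairwise_alignment` over the protein alphabet.
#' @return Object of class `distance_result` with `d`, `n_sites`, `method`.
#' @export
p_distance <- function(alignment) {
  r <- .retained_residues(alignment)
  n <- length(r$a)
  res <- list(d = sum(r$a != r$b) / n, n_sites = n, method = "p-distance",
              saturated = FALSE)
  class(res) <- "distance_result"
  res
}

# log-likelihood of a site-pattern count matrix at distance t
.jtt_loglik <- function(cnt_idx, cnt_n, model, t) {
  P <- model$left %*% (exp(model$lambda * t) * model$right)
  f <- model$pi[cnt_idx[, 1]] * P[cnt_idx]
  sum(cnt_n * log(pmax(f, 1e-300)))
}

#' Maximum-likelihood JTT distance between two aligned protein sequences
#'
#' Maximizes the pairwise log-likelihood sum(log(pi[a] * P[a, b](t))) over
#' t in [0, `upper`] under the JTT model with a uniform substitution rate
#' across sites (no gamma correction), after pairwise deletion of gap and
#' ambiguity columns. An optimum pinned at the upper bound is flagged
#' saturated rather than raising an error; identical retained columns give
#' exactly 0.
#'
#' @param alignment A `pairwise_alignment` over the protein alphabet.
#' @param model An `aa_subst_model`; defaults to the bundled JTT model.
#' @param upper Upper bound of the search interval (default 10
#'   substitutions per site).
#' @return Object of class `distance_result` with `d`, `n_sites`, `method`
#'   and `saturated`.
#' @export
jtt_distance <- function(alignment, model = jtt_model(), upper = 10) {
  r <- .retained_residues(alignment)
  n <- length(r$a)
  res <- list(d = 0, n_sites = n, method = "JTT-ML", saturated = FALSE)
  class(res) <- "distance_result"
  if (all(r$a == r$b)) return(res)
  cnt <- .pair_count_matrix(r$a, r$b)
  nz <- which(cnt > 0, arr.ind = TRUE)
  cnt_n <- cnt[nz]
  opt <- stats::optimize(function(t) .jtt_loglik(nz, cnt_n, model, t),
                         interval = c(0, upper), maximum = TRUE,
                         tol = 1e-6)
  res$d <- opt$maximum
  if (opt$maximum > upper - 1e-2) {
    res$saturated <- TRUE
    res$d <- NA_real_
  }
  res
}

#' @export
print.distance_result <- function(x, ...) {
  if (x$saturated) {
    cat(sprintf("%s distance: saturated (n = %d sites)\n", x$method,
                x$n_sites))
  } else {
    cat(sprintf("%s distance: %.5f substitutions/site (n = %d sites)\n",
                x$method, x$d, x$n_sites))
  }
  invisible(x)
}
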
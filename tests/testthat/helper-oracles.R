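# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities by brute force or from first
# principles, separately from the package implementations they check.

GC_TABLE <- Biostrings::GENETIC_CODE

aa_of <- function(codon) unname(GC_TABLE[codon])

# brute-force degeneracy classifier: enumerate the 9 single-base neighbours
brute_degeneracy <- function(codon) {
  bases <- c("A", "C", "G", "T")
  vapply(1:3, function(pos) {
    b <- substr(codon, pos, pos)
    nsyn <- 0L
    for (alt in setdiff(bases, b)) {
      alt_codon <- codon
      substr(alt_codon, pos, pos) <- alt
      if (GC_TABLE[alt_codon] != "*" && GC_TABLE[alt_codon] == GC_TABLE[codon])
        nsyn <- nsyn + 1L
    }
    if (nsyn == 3L) 4L else if (nsyn == 0L) 0L else 2L
  }, 0L)
}

# brute-force pathway enumerator: recursive depth-first walk over all
# orderings of the differing positions, accumulating syn/nonsyn and
# per-class transition/transversion contributions (half to each endpoint
# class of a step), skipping pathways through stops
brute_pathways <- function(a, b) {
  purine <- function(x) x %in% c("A", "G")
  walk <- function(cur, remaining) {
    if (length(remaining) == 0)
      return(list(list(sd = 0, nd = 0,
                       ts = c(`0` = 0, `2` = 0, `4` = 0),
                       tv = c(`0` = 0, `2` = 0, `4` = 0))))
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (GC_TABLE[nxt] == "*") next
      tails <- walk(nxt, setdiff(remaining, pos))
      b1 <- substr(cur, pos, pos); b2 <- substr(nxt, pos, pos)
      is_ts <- purine(b1) == purine(b2)
      c_from <- as.character(brute_degeneracy(cur)[pos])
      c_to <- as.character(brute_degeneracy(nxt)[pos])
      syn <- GC_TABLE[nxt] == GC_TABLE[cur]
      for (tl in tails) {
        if (is_ts) {
          tl$ts[c_from] <- tl$ts[c_from] + 0.5
          tl$ts[c_to] <- tl$ts[c_to] + 0.5
        } else {
          tl$tv[c_from] <- tl$tv[c_from] + 0.5
          tl$tv[c_to] <- tl$tv[c_to] + 0.5
        }
        if (syn) tl$sd <- tl$sd + 1 else tl$nd <- tl$nd + 1
        out[[length(out) + 1]] <- tl
      }
    }
    out
  }
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- walk(a, diffpos)
  if (length(paths) == 0)
    return(list(dropped = TRUE))
  m <- length(paths)
  list(sd = sum(vapply(paths, `[[`, 0, "sd")) / m,
       nd = sum(vapply(paths, `[[`, 0, "nd")) / m,
       ts = Reduce(`+`, lapply(paths, `[[`, "ts")) / m,
       tv = Reduce(`+`, lapply(paths, `[[`, "tv")) / m,
       dropped = FALSE)
}

# dense grid-search oracle for the JTT ML distance: evaluates the pairwise
# log-likelihood on t = 0, step, 2*step, ..., upper via the spectral
# coefficients of each observed site pattern and returns the arg-max
jtt_grid_argmax <- function(alignment, model, step = 1e-4, upper = 10) {
  keep <- pairwise_deletion_mask(alignment)
  a <- strsplit(alignment$a, "")[[1]][keep]
  b <- strsplit(alignment$b, "")[[1]][keep]
  pat <- paste(a, b)
  tab <- table(pat)
  parts <- strsplit(names(tab), " ")
  ia <- match(vapply(parts, `[`, "", 1), rownames(model$Q))
  ib <- match(vapply(parts, `[`, "", 2), rownames(model$Q))
  # lik_p(t) = pi_a * sum_k left[a,k] right[k,b] exp(lambda_k t)
  coefs <- model$pi[ia] * model$left[ia, , drop = FALSE] *
    t(model$right)[ib, , drop = FALSE]
  tgrid <- seq(0, upper, by = step)
  n <- as.numeric(tab)
  best_ll <- -Inf
  best_t <- NA_real_
  chunk <- 20000L
  for (s in seq(1, length(tgrid), by = chunk)) {
    tg <- tgrid[s:min(s + chunk - 1L, length(tgrid))]
    E <- exp(outer(model$lambda, tg))          # 20 x m
    lik <- pmax(coefs %*% E, 1e-300)           # patterns x m
    ll <- as.numeric(n %*% log(lik))
    j <- which.max(ll)
    if (ll[j] > best_ll) {
      best_ll <- ll[j]
      best_t <- tg[j]
    }
  }
  best_t
}

# random gapped protein alignment with matching CDS pair (no stops)
random_gapped_pair <- function(n_cols, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  kind <- sample(c("match", "gap_a", "gap_b"), n_cols, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  cod_a <- cod_b <- character(n_cols)
  row_a <- row_b <- character(n_cols)
  for (i in seq_len(n_cols)) {
    ca <- sample(sense, 1)
    cb <- sample(sense, 1)
    if (kind[i] == "match") {
      row_a[i] <- GC_TABLE[ca]; row_b[i] <- GC_TABLE[cb]
      cod_a[i] <- ca; cod_b[i] <- cb
    } else if (kind[i] == "gap_a") {
      row_a[i] <- "-"; row_b[i] <- GC_TABLE[cb]
      cod_b[i] <- cb
    } else {
      row_a[i] <- GC_TABLE[ca]; row_b[i] <- "-"
      cod_a[i] <- ca
    }
  }
  list(aln = pairwise_alignment(paste(row_a, collapse = ""),
                                paste(row_b, collapse = ""), "protein"),
       cds_a = paste(cod_a[cod_a != ""], collapse = ""),
       cds_b = paste(cod_b[cod_b != ""], collapse = ""))
}

write_fasta_tmp <- function(named_seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(named_seqs), "\n", named_seqs), f)
  f
}
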
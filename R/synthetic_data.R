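# Seeded generators that give every pipeline stage a tested input without
# any external download: a mutation-selection codon-pair simulator with an
# event log, JTT protein-pair sampling, domain-structured ortholog
# fixtures, expression matrices with planted rank correlations, phenotype
# records, and a complete on-disk study fixture.

# Per-(kappa, omega, freqs) simulator tables: neighbour targets, per-event
# relative rates (kappa for transitions, 1 for transversions, thinned by
# omega for nonsynonymous changes, 0 into stops), cumulative choice
# probabilities and the base rate mu that makes one unit of branch length
# equal one expected synonymous substitution per (kappa-weighted)
# synonymous site under the ancestor codon distribution.
.sim_tables <- function(kappa, omega, codon_freqs = NULL) {
  sense <- .sense_codons()
  n <- length(sense)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n, n)
  stopifnot(length(codon_freqs) == n, all(codon_freqs >= 0))
  codon_freqs <- codon_freqs / sum(codon_freqs)
  key <- paste("sim", kappa, omega, paste(signif(codon_freqs, 6),
                                          collapse = ","), sep = "|")
  hit <- .cadevo_cache[[digest_key <- paste0("k", substr(key, 1, 200))]]
  if (!is.null(hit)) return(hit)
  nb <- .codon_neighbors()
  nb$from_i <- match(nb$from, sense)
  nb$to_i <- match(nb$to, sense)  # NA for stops
  rate <- ifelse(nb$transition, kappa, 1)
  rate[nb$to_stop] <- 0
  rate[!nb$to_stop & !nb$syn] <- rate[!nb$to_stop & !nb$syn] * omega
  R <- matrix(0, n, 9)      # event rates, 9 neighbours per codon
  TO <- matrix(NA_integer_, n, 9)
  SYN <- matrix(FALSE, n, 9)
  TS <- matrix(FALSE, n, 9)
  slot <- integer(n)
  for (r in seq_len(nrow(nb))) {
    i <- nb$from_i[r]
    slot[i] <- slot[i] + 1L
    R[i, slot[i]] <- rate[r]
    TO[i, slot[i]] <- nb$to_i[r]
    SYN[i, slot[i]] <- nb$syn[r]
    TS[i, slot[i]] <- nb$transition[r]
  }
  rho <- rowSums(R)
  cum <- t(apply(R, 1, cumsum))
  cum <- cum / ifelse(rho > 0, rho, 1)
  # mutational-opportunity normalization (omega excluded)
  rate_mut <- ifelse(nb$transition, kappa, 1)
  rate_mut[nb$to_stop] <- 0
  ES <- sum(codon_freqs[nb$from_i] * rate_mut * nb$syn)
  EN <- sum(codon_freqs[nb$from_i] * rate_mut * (!nb$syn & !nb$to_stop))
  mu <- 3 / (ES + EN)
  tab <- list(sense = sense, freqs = codon_freqs, R = R, TO = TO, SYN = SYN,
              TS = TS, rho = rho, cum = cum, mu = mu)
  .cadevo_cache[[digest_key]] <- tab
  tab
}

# Evolve codon states (indices into the sense-codon list) for time t under
# the tables; returns final states plus the full event log.
.evolve_lineage <- function(state, t_total, tab) {
  n <- length(state)
  tcur <- numeric(n)
  active <- seq_len(n)
  logs <- list()
  while (length(active) > 0) {
    rates <- tab$mu * tab$rho[state[active]]
    dt <- ifelse(rates > 0, stats::rexp(length(active), pmax(rates, 1e-300)),
                 Inf)
    tnew <- tcur[active] + dt
    still <- tnew <= t_total
    idx <- active[still]
    if (length(idx) == 0) break
    tcur[idx] <- tnew[still]
    u <- stats::runif(length(idx))
    cp <- tab$cum[state[idx], , drop = FALSE]
    choice <- rowSums(u > cp) + 1L
    sel <- cbind(state[idx], choice)
    to <- tab$TO[sel]
    logs[[length(logs) + 1L]] <- data.frame(
      site = idx, time = tcur[idx], from = state[idx], to = to,
      syn = tab$SYN[sel], transition = tab$TS[sel])
    state[idx] <- to
    active <- idx
  }
  events <- if (length(logs)) do.call(rbind, logs) else
    data.frame(site = integer(0), time = numeric(0), from = integer(0),
               to = integer(0), syn = logical(0), transition = logical(0))
  events <- events[order(events$site, events$time), , drop = FALSE]
  rownames(events) <- NULL
  list(state = state, events = events)
}

#' Simulate a diverging codon-sequence pair under mutation-selection
#'
#' A common ancestor is drawn from the configured codon distribution
#' (uniform over the 61 sense codons by default) and two lineages evolve
#' independently for `branch_length` each: single-base changes arise at
#' relative rate `kappa` for transitions and 1 for transversions, changes
#' creating stop codons are rejected, and nonsynonymous changes are
#' accepted with relative probability `omega`. Branch length is calibrated
#' so one unit equals one expected synonymous substitution per synonymous
#' site. Every accepted event is logged, so realized synonymous and
#' nonsynonymous counts are available as an oracle.
#'
#' @param n_codons Number of codons.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Target dN/dS (>= 0).
#' @param branch_length Expected synonymous substitutions per synonymous
#'   site per lineage (default 0.1, i.e. pairwise dS about 0.2).
#' @param seed Optional integer seed; identical configuration and seed give
#'   byte-identical output.
#' @param codon_freqs Optional length-61 ancestor codon distribution.
#' @return Object of class `codon_sim`: CDS strings `ancestor`, `a`, `b`,
#'   event logs `events_a`, `events_b`, realized counts `realized`, and the
#'   configuration.
#' @export
simulate_codon_pair <- function(n_codons, kappa = 2, omega = 1,
                                branch_length = 0.1, seed = NULL,
                                codon_freqs = NULL) {
  if (n_codons < 1) stop("n_codons must be positive")
  stopifnot(kappa >= 0, omega >= 0, branch_length >= 0)
  if (!is.null(seed)) set.seed(seed)
  tab <- .sim_tables(kappa, omega, codon_freqs)
  anc <- sample.int(length(tab$sense), n_codons, replace = TRUE,
                    prob = tab$freqs)
  la <- .evolve_lineage(anc, branch_length, tab)
  lb <- .evolve_lineage(anc, branch_length, tab)
  as_cds <- function(idx) paste(tab$sense[idx], collapse = "")
  res <- list(ancestor = as_cds(anc), a = as_cds(la$state),
              b = as_cds(lb$state),
              ancestor_idx = anc, a_idx = la$state, b_idx = lb$state,
              events_a = la$events, events_b = lb$events,
              realized = list(
                syn_a = sum(la$events$syn), nonsyn_a = sum(!la$events$syn),
                syn_b = sum(lb$events$syn), nonsyn_b = sum(!lb$events$syn)),
              config = list(n_codons = n_codons, kappa = kappa,
                            omega = omega, branch_length = branch_length,
                            seed = seed))
  class(res) <- "codon_sim"
  res
}

#' @export
print.codon_sim <- function(x, ...) {
  cat(sprintf(
    "Codon-pair simulation: %d codons, kappa = %g, omega = %g, t = %g/lineage\n",
    x$config$n_codons, x$config$kappa, x$config$omega,
    x$config$branch_length))
  cat(sprintf("  realized events: lineage a %d syn + %d nonsyn, lineage b %d syn + %d nonsyn\n",
              x$realized$syn_a, x$realized$nonsyn_a, x$realized$syn_b,
              x$realized$nonsyn_b))
  invisible(x)
}

#' Simulate an aligned protein pair under an amino-acid model
#'
#' One row is drawn from the model's equilibrium frequencies and the other
#' from the conditional distribution P(a -> b | t), i.e. the pair sits at
#' evolutionary distance `t` under the (reversible) model.
#'
#' @param n_sites Number of residues.
#' @param t Distance in substitutions per site.
#' @param model An `aa_subst_model` (default bundled JTT).
#' @param seed Optional integer seed.
#' @return A `pairwise_alignment` (gapless) over the protein alphabet.
#' @export
simulate_protein_pair <- function(n_sites, t, model = jtt_model(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- model_prob_matrix(model, t)
  a <- sample(AA_ORDER, n_sites, replace = TRUE, prob = model$pi)
  b <- vapply(a, function(aa) sample(AA_ORDER, 1L, prob = P[aa, ]), "")
  pairwise_alignment(paste(a, collapse = ""), paste(b, collapse = ""),
                     alphabet = "protein")
}

#' Expression matrix with planted per-class Spearman correlation
#'
#' For each sample, gene abundances are drawn from a Gaussian copula whose
#' rank correlation with the supplied metric vector equals the target for
#' the sample's class (Pearson parameter r = 2 sin(pi rho / 6)), then
#' mapped through exp() to nonnegative abundances; targets of exactly +/-1
#' produce a rank-preserving (or rank-reversing) transform.
#'
#' @param metric Named numeric vector (genes).
#' @param samples data.frame with columns `sample`, `class`.
#' @param rho Target Spearman correlation: a single number or a named
#'   vector keyed by class.
#' @param seed Optional integer seed.
#' @return List of class `expression_matrix`: `mat` (genes x samples,
#'   nonnegative) and `annotation` (the `samples` table).
#' @export
plant_expression_matrix <- function(metric, samples, rho, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(metric)
  if (is.null(names(metric))) names(metric) <- paste0("gene", seq_len(G))
  get_rho <- function(cl) {
    r <- if (length(rho) == 1L && is.null(names(rho))) rho else rho[[cl]]
    if (is.na(r) || abs(r) > 1) stop("invalid target correlation for class ",
                                     cl, ": ", r)
    r
  }
  zm <- stats::qnorm((rank(metric, ties.method = "average") - 0.5) / G)
  mat <- matrix(NA_real_, nrow = G, ncol = nrow(samples),
                dimnames = list(names(metric), samples$sample))
  for (j in seq_len(nrow(samples))) {
    rs <- get_rho(samples$class[j])
    if (abs(rs) == 1) {
      mat[, j] <- exp(sign(rs) * zm)
    } else {
      r <- 2 * sin(pi * rs / 6)
      z <- r * zm + sqrt(1 - r^2) * stats::rnorm(G)
      mat[, j] <- exp(z)
    }
  }
  structure(list(mat = mat, annotation = samples),
            class = "expression_matrix")
}

# default domain layout: five ~110-residue extracellular cadherin repeats
# and a cytoplasmic domain, tiling the full-length mature protein
.default_domain_layout <- function() {
  widths <- c(EC1 = 110L, EC2 = 110L, EC3 = 110L, EC4 = 110L, EC5 = 110L,
              CD = 151L)
  end <- cumsum(widths)
  start <- end - widths + 1L
  data.frame(segment = names(widths), start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

#' Ortholog-set fixture with domain-specific substitution intensities
#'
#' Builds one human reference CDS plus `n_species` descendants evolved
#' star-wise from it, with the branch length of each domain scaled by its
#' entry in `per_domain_rates`, so planted per-domain rate orderings are
#' recoverable from the estimated distances. Alignments are generated
#' gapless.
#'
#' @param n_species Number of non-human species.
#' @param domain_layout data.frame (`segment`, `start`, `end`) in
#'   mature-protein coordinates; default five 110-residue EC repeats plus a
#'   151-residue CD.
#' @param per_domain_rates Named nonnegative rates (branch-length scale per
#'   unit time) for each segment; default 0.001 everywhere.
#' @param times Divergence times (MYr) of the species; default spread over
#'   about 57 MYr.
#' @param kappa,omega Simulator parameters (see [simulate_codon_pair()]).
#' @param seed Optional integer seed.
#' @return List with `proteins` (named vector, human first), `cds`,
#'   `domain_map` (including FL), `times`, `species`.
#' @export
make_gene_fixture <- function(n_species = 4,
                              domain_layout = .default_domain_layout(),
                              per_domain_rates = NULL,
                              times = NULL, kappa = 2, omega = 0.2,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(times))
    times <- round(seq(6.7, 57, length.out = n_species), 1)
  if (is.null(per_domain_rates))
    per_domain_rates <- stats::setNames(rep(0.001, nrow(domain_layout)),
                                        domain_layout$segment)
  if (any(per_domain_rates < 0)) stop("rates must be nonnegative")
  tab <- .sim_tables(1, 1)  # tables only for the sense-codon list
  n_res <- max(domain_layout$end)
  # human reference: sense codons, no stops
  human_idx <- sample.int(61L, n_res, replace = TRUE)
  species <- paste0("species_", seq_len(n_species))
  cds <- character(n_species + 1L)
  names(cds) <- c("human", species)
  cds["human"] <- paste(tab$sense[human_idx], collapse = "")
  for (s in seq_len(n_species)) {
    out <- integer(n_res)
    for (d in seq_len(nrow(domain_layout))) {
      rng <- domain_layout$start[d]:domain_layout$end[d]
      bl <- per_domain_rates[[domain_layout$segment[d]]] * times[s]
      st <- .sim_tables(kappa, omega)
      out[rng] <- .evolve_lineage(human_idx[rng], bl, st)$state
    }
    cds[species[s]] <- paste(tab$sense[out], collapse = "")
  }
  proteins <- vapply(cds, function(x)
    paste(.translate_codons(.split_codons(x)), collapse = ""), "")
  dm <- rbind(data.frame(segment = "FL", start = 1L, end = n_res,
                         stringsAsFactors = FALSE),
              domain_layout)
  list(proteins = proteins, cds = cds, domain_map = dm, times = times,
       species = species)
}

#' Synthetic phenotype records with an optional planted rank correlation
#'
#' Generates knockout-lethality, phenotype-severity and human-disease
#' fields whose composite essentiality score has (approximately) the
#' requested Spearman correlation with `target`; with `rho = 0` the records
#' are independent of it. The latent score is drawn from a Gaussian copula
#' and discretized onto the 0-5 lattice, then decomposed into valid
#' components.
#'
#' @param genes Character vector of gene symbols.
#' @param target Optional numeric vector (same length) to correlate with.
#' @param rho Target Spearman correlation of the latent score with
#'   `target`.
#' @param seed Optional integer seed.
#' @return data.frame with columns `gene`, `knockout_lethal`, `severity`,
#'   `human_disease`.
#' @export
make_phenotype_records <- function(genes, target = NULL, rho = 0,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(genes)
  if (is.null(target) || rho == 0) {
    z <- stats::rnorm(G)
  } else {
    stopifnot(length(target) == G, abs(rho) <= 1)
    zm <- stats::qnorm((rank(target, ties.method = "average") - 0.5) / G)
    r <- 2 * sin(pi * rho / 6)
    z <- r * zm + sqrt(1 - r^2) * stats::rnorm(G)
  }
  score <- pmin(pmax(floor(stats::pnorm(z) * 6), 0), 5)
  decomp <- list(
    `0` = list(0L, "none", 0L), `1` = list(0L, "mild", 0L),
    `2` = list(0L, "severe", 0L), `3` = list(2L, "mild", 0L),
    `4` = list(2L, "severe", 0L), `5` = list(2L, "severe", 1L))
  parts <- decomp[as.character(score)]
  data.frame(
    gene = genes,
    knockout_lethal = vapply(parts, function(p) p[[1]], 0L),
    severity = vapply(parts, function(p) p[[2]], ""),
    human_disease = vapply(parts, function(p) p[[3]], 0L),
    stringsAsFactors = FALSE)
}

#' Synthetic species divergence-time table
#'
#' Nine synthetic primate-like species in three groups whose within-group
#' mean times equal the group plotting times used throughout the package
#' (apes 10.9 MYr, New World monkeys 27.5 MYr, Old World
#' monkeys/tarsiers/strepsirrhines 48.7 MYr).
#'
#' @return data.frame with columns `species`, `myr`, `group`.
#' @export
make_divergence_table <- function() {
  data.frame(
    species = paste0("species_", 1:9),
    myr = c(6.7, 8.8, 17.2, 26.0, 27.5, 29.0, 46.2, 48.7, 51.2),
    group = rep(c("apes", "new_world_monkeys",
                  "owm_tarsiers_strepsirrhines"), each = 3),
    stringsAsFactors = FALSE)
}

#' Write a complete synthetic study to disk
#'
#' Emits every input the pipeline reads, in its exact dialects: per-gene
#' aligned protein FASTA and CDS FASTA (human reference plus the species of
#' [make_divergence_table()]), a domain-topology TSV, the divergence-time
#' TSV, an expression TSV with sample-annotation TSV (rank correlation to
#' the planted per-gene rate ordering: negative in the CNS class, positive
#' elsewhere), a phenotype TSV and a LOEUF TSV. All sequence and annotation
#' content is synthetic.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes (named SYNCDH1..n).
#' @param omegas Planted dN/dS per gene (recycled).
#' @param n_codons_fl Codons in the full-length sequence; the default
#'   domain layout is scaled to fit.
#' @param rho_cns,rho_other Planted expression-metric Spearman targets for
#'   CNS and non-CNS samples.
#' @param n_cns,n_other Sample counts per class.
#' @param seed Integer seed.
#' @return Invisibly, a list of the paths written plus the planted truth.
#' @export
make_study_fixture <- function(dir, n_genes = 4,
                               omegas = c(0.1, 0.2, 0.5, 0.9),
                               n_codons_fl = 701,
                               rho_cns = -0.6, rho_other = 0.6,
                               n_cns = 13, n_other = 39, seed = 1) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  omegas <- rep_len(omegas, n_genes)
  genes <- paste0("SYNCDH", seq_len(n_genes))
  div <- make_divergence_table()
  layout <- .default_domain_layout()
  sc <- n_codons_fl / max(layout$end)
  layout$start <- as.integer(round((layout$start - 1) * sc)) + 1L
  layout$end <- as.integer(round(layout$end * sc))
  layout$end[nrow(layout)] <- n_codons_fl
  paths <- list()
  dm_all <- NULL
  mean_omega_proxy <- numeric(n_genes)
  for (gi in seq_len(n_genes)) {
    rates <- stats::setNames(rep(1e-3, nrow(layout)), layout$segment)
    fx <- make_gene_fixture(n_species = nrow(div), domain_layout = layout,
                            per_domain_rates = rates, times = div$myr,
                            kappa = 2, omega = omegas[gi])
    names(fx$cds) <- c("human", div$species)
    names(fx$proteins) <- c("human", div$species)
    pfa <- file.path(dir, paste0(genes[gi], ".protein.fasta"))
    cfa <- file.path(dir, paste0(genes[gi], ".cds.fasta"))
    writeLines(paste0(">", names(fx$proteins), "\n", fx$proteins), pfa)
    writeLines(paste0(">", names(fx$cds), "\n", fx$cds), cfa)
    paths[[paste0(genes[gi], "_protein")]] <- pfa
    paths[[paste0(genes[gi], "_cds")]] <- cfa
    dm <- fx$domain_map
    dm$gene <- genes[gi]
    dm_all <- rbind(dm_all, dm[, c("gene", "segment", "start", "end")])
    mean_omega_proxy[gi] <- omegas[gi]
  }
  dm_path <- file.path(dir, "domains.tsv")
  utils::write.table(dm_all, dm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  div_path <- file.path(dir, "divergence_times.tsv")
  utils::write.table(div, div_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  samples <- data.frame(
    sample = c(paste0("cns_", seq_len(n_cns)),
               paste0("tissue_", seq_len(n_other))),
    class = c(rep("CNS", n_cns), rep("non-CNS", n_other)),
    stringsAsFactors = FALSE)
  metric <- stats::setNames(mean_omega_proxy, genes)
  expr <- plant_expression_matrix(metric, samples,
                                  rho = c(CNS = rho_cns,
                                          `non-CNS` = rho_other))
  expr_path <- file.path(dir, "expression.tsv")
  utils::write.table(
    data.frame(gene = rownames(expr$mat), expr$mat, check.names = FALSE),
    expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann_path <- file.path(dir, "samples.tsv")
  utils::write.table(samples, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  phen <- make_phenotype_records(genes, target = metric, rho = 0.4)
  phen_path <- file.path(dir, "phenotypes.tsv")
  utils::write.table(phen, phen_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  zl <- stats::qnorm((rank(metric) - 0.5) / n_genes)
  loeuf <- data.frame(gene = genes,
                      loeuf = round(exp(0.5 * zl - 0.5), 4),
                      stringsAsFactors = FALSE)
  loeuf_path <- file.path(dir, "loeuf.tsv")
  utils::write.table(loeuf, loeuf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(dir = dir, genes = genes, omegas = omegas,
                 sequence_paths = paths, domain_map = dm_path,
                 divergence_table = div_path, expression = expr_path,
                 annotation = ann_path, phenotypes = phen_path,
                 loeuf = loeuf_path, samples = samples))
}
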
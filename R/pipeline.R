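# Config-driven orchestration: per-gene x species x segment divergence and
# selection tables, group and rate summaries, and the downstream E-R /
# essentiality / LOEUF correlation stage, with plain TSV outputs and a
# machine-readable run manifest.

.read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

.require_paths <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]])) stop("config entry missing: ", k)
    if (!file.exists(config[[k]])) stop("path does not exist: ", config[[k]])
  }
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_manifest <- function(out_dir, config, seed) {
  manifest <- list(
    package = "cadevo",
    version = as.character(utils::packageVersion("cadevo")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config)
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
}

#' Run the divergence and selection stage
#'
#' For every gene in `config$genes` and every non-human species in its
#' alignment, computes per-segment JTT and p protein distances and the
#' codon-level dS, dN, variances, dN/dS, Z-test and Fisher-test p values,
#' plus group-averaged omega, ED-CD dN differences and per-MYr rate
#' summaries. Every dropped sequence or codon is accounted for in the
#' messages emitted.
#'
#' Config entries: `sequence_dir` (files `<gene>.protein.fasta` aligned
#' with a `human` row, `<gene>.cds.fasta`), `genes` (character vector),
#' `domain_map`, `divergence_table` (paths), optional `segments` (default
#' FL, EC1-EC5, CD, ED), `out_dir`.
#'
#' @param config Path to a YAML file or a config list.
#' @param seed Integer seed recorded in the manifest (this stage is
#'   deterministic).
#' @return Invisibly, a list with `results` (long data.frame),
#'   `group_omega`, `ed_cd`, `rates`.
#' @export
run_divergence <- function(config, seed = 1) {
  config <- .read_config(config)
  .require_paths(config, c("sequence_dir", "domain_map", "divergence_table"))
  dm <- read_domain_map(config$domain_map)
  div <- read_divergence_table(config$divergence_table)
  segments <- config$segments %||% c("FL", "EC1", "EC2", "EC3", "EC4",
                                     "EC5", "CD", "ED")
  out_dir <- config$out_dir %||% tempfile("cadevo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (gene in config$genes) {
    pfa <- file.path(config$sequence_dir, paste0(gene, ".protein.fasta"))
    cfa <- file.path(config$sequence_dir, paste0(gene, ".cds.fasta"))
    prot <- read_fasta(pfa, "protein")
    cds <- read_fasta(cfa, "cds")
    if (!"human" %in% prot$id) {
      message("skipping gene without human reference: ", gene)
      next
    }
    gmap <- dm[dm$gene == gene, ]
    gmap <- .with_ed_segment(gmap)
    href <- prot$seq[prot$id == "human"]
    hcds <- cds$seq[cds$id == "human"]
    for (sp in setdiff(prot$id, "human")) {
      aln <- pairwise_alignment(href, prot$seq[prot$id == sp], "protein")
      caln <- build_codon_alignment(aln, hcds, cds$seq[cds$id == sp])
      for (seg in segments) {
        if (!seg %in% gmap$segment) next
        paln <- slice_domain(aln, gmap, seg, "a")
        cseg <- slice_domain(caln, gmap, seg, "a")
        row <- data.frame(gene = gene, species = sp, segment = seg,
                          time_myr = div$myr[match(sp, div$species)],
                          stringsAsFactors = FALSE)
        pd <- tryCatch(p_distance(paln), error = function(e) NULL)
        jd <- tryCatch(jtt_distance(paln), error = function(e) NULL)
        row$p_dist <- if (is.null(pd)) NA_real_ else pd$d
        row$jtt_dist <- if (is.null(jd)) NA_real_ else jd$d
        row$n_sites <- if (is.null(jd)) NA_integer_ else jd$n_sites
        sel <- tryCatch(estimate_dn_ds(cseg), error = function(e) NULL)
        if (is.null(sel)) {
          row[c("dS", "dN", "var_dS", "var_dN", "omega", "Z", "p_neutral",
                "p_negative", "p_positive", "fisher_p")] <- NA_real_
          row$n_codons <- NA_integer_
          row$flags <- "no_comparable_codons"
        } else {
          row$dS <- sel$dS; row$dN <- sel$dN
          row$var_dS <- sel$var_dS; row$var_dN <- sel$var_dN
          row$omega <- sel$omega; row$Z <- sel$Z
          row$p_neutral <- sel$p_neutral
          row$p_negative <- sel$p_negative
          row$p_positive <- sel$p_positive
          row$fisher_p <- sel$fisher_p
          row$n_codons <- sel$n_codons
          row$flags <- paste(sel$flags, collapse = ";")
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  results <- do.call(rbind, rows)
  group_omega <- NULL
  rates <- NULL
  ed_cd <- NULL
  for (gene in unique(results$gene)) {
    sub <- results[results$gene == gene & results$segment == "FL" &
                     !is.na(results$omega), ]
    if (nrow(sub) > 0) {
      go <- group_average_omega(
        data.frame(species = sub$species, value = sub$omega), div)
      go$gene <- gene
      group_omega <- rbind(group_omega, go)
      rs <- mean_rate_per_myr(data.frame(species = sub$species,
                                         time = sub$time_myr,
                                         value = sub$jtt_dist))
      rates <- rbind(rates, data.frame(
        gene = gene, mean_rate_percent_per_myr = rs$mean_rate_percent_per_myr,
        trend_slope = rs$trend_slope, n = rs$n, stringsAsFactors = FALSE))
    }
    gsub <- results[results$gene == gene, ]
    ec <- ed_cd_dn_difference(gsub)
    if (nrow(ec) > 0) {
      ec$gene <- gene
      ed_cd <- rbind(ed_cd, ec)
    }
  }
  .write_tsv(results, file.path(out_dir, "divergence_selection.tsv"))
  if (!is.null(group_omega))
    .write_tsv(group_omega, file.path(out_dir, "group_omega.tsv"))
  if (!is.null(rates)) .write_tsv(rates, file.path(out_dir, "rates.tsv"))
  if (!is.null(ed_cd)) .write_tsv(ed_cd, file.path(out_dir, "ed_cd_dn.tsv"))
  .write_manifest(out_dir, config, seed)
  invisible(list(results = results, group_omega = group_omega,
                 ed_cd = ed_cd, rates = rates, out_dir = out_dir))
}

# add the EC1-EC5 concatenation as a single synthetic segment spanning
# EC1 start to EC5 end (the ectodomain)
.with_ed_segment <- function(gmap) {
  if ("ED" %in% gmap$segment) return(gmap)
  ecs <- gmap[grepl("^EC[1-5]$", gmap$segment), ]
  if (nrow(ecs) == 0) return(gmap)
  rbind(gmap, data.frame(gene = gmap$gene[1], segment = "ED",
                         start = min(ecs$start), end = max(ecs$end),
                         stringsAsFactors = FALSE))
}

#' Run the expression / essentiality / LOEUF correlation stage
#'
#' Builds per-gene metric vectors (dN and omega, per species or averaged)
#' from a divergence run, correlates them with expression across samples,
#' summarizes significant fractions per sample class, and reports the
#' essentiality-score and LOEUF correlations.
#'
#' Config entries: `expression`, `annotation`, `phenotypes`, `loeuf`
#' (paths), `alpha` (default 0.05), `metric_species` (species whose dN /
#' omega vectors are used; default all), `out_dir`.
#'
#' @param config Path to a YAML file or a config list.
#' @param divergence A list returned by [run_divergence()] (or its
#'   `results` data.frame).
#' @param seed Integer seed recorded in the manifest.
#' @return Invisibly, a list with `profiles` (per species and metric),
#'   `fractions`, `essentiality`, `loeuf`.
#' @export
run_er_analysis <- function(config, divergence, seed = 1) {
  config <- .read_config(config)
  .require_paths(config, c("expression", "annotation"))
  alpha <- config$alpha %||% 0.05
  results <- if (is.data.frame(divergence)) divergence else
    divergence$results
  expr <- read_expression_matrix(config$expression, config$annotation)
  fl <- results[results$segment == "FL", ]
  species <- config$metric_species %||% unique(fl$species)
  out_dir <- config$out_dir %||% tempfile("cadevo_er_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- unique(expr$annotation$class)
  profiles <- list()
  fractions <- NULL
  for (metric_name in c("dN", "omega")) {
    per_species <- list()
    for (sp in species) {
      sub <- fl[fl$species == sp & !is.na(fl[[if (metric_name == "dN")
        "dN" else "omega"]]), ]
      v <- stats::setNames(sub[[if (metric_name == "dN") "dN" else
        "omega"]], sub$gene)
      if (length(v) < 3) next
      prof <- er_profile(v, expr, metric_name = metric_name)
      prof$species <- sp
      per_species[[sp]] <- prof
    }
    profiles[[metric_name]] <- per_species
    if (length(per_species) > 0) {
      for (cl in classes) {
        for (sgn in c("negative", "positive")) {
          fr <- significant_fraction_any(per_species, cl, alpha, sgn)
          fractions <- rbind(fractions, data.frame(
            metric = metric_name, class = cl, sign = sgn,
            fraction = fr$fraction, n_significant = fr$n_significant,
            n_total = fr$n_total, mode = "any_species",
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  # essentiality: correlate scores with per-gene mean dN and omega over
  # the analysed species
  essent <- NULL
  if (!is.null(config$phenotypes) && file.exists(config$phenotypes)) {
    ph <- read_phenotype_table(config$phenotypes)
    sc <- score_essentiality(ph)
    mean_by_gene <- function(col) {
      v <- tapply(fl[[col]], fl$gene, mean, na.rm = TRUE)
      stats::setNames(as.numeric(v), names(v))
    }
    essent <- list(
      dN = tryCatch(correlate_essentiality(sc, mean_by_gene("dN"), "dN"),
                    error = function(e) NULL),
      omega = tryCatch(correlate_essentiality(sc, mean_by_gene("omega"),
                                              "omega"),
                       error = function(e) NULL),
      scores = sc)
    .write_tsv(sc, file.path(out_dir, "essentiality_scores.tsv"))
  }
  loeuf_rep <- NULL
  if (!is.null(config$loeuf) && file.exists(config$loeuf)) {
    lo <- utils::read.delim(config$loeuf, stringsAsFactors = FALSE)
    lvec <- stats::setNames(lo$loeuf, lo$gene)
    ov <- tapply(fl$omega, fl$gene, mean, na.rm = TRUE)
    loeuf_rep <- list(
      vs_omega = tryCatch(
        loeuf_correlations(lvec, metric = stats::setNames(as.numeric(ov),
                                                          names(ov))),
        error = function(e) NULL),
      profile = tryCatch(loeuf_correlations(lvec, expression = expr),
                         error = function(e) NULL))
    if (!is.null(loeuf_rep$profile))
      .write_tsv(loeuf_rep$profile, file.path(out_dir, "loeuf_profile.tsv"))
  }
  all_profiles <- do.call(rbind, unlist(profiles, recursive = FALSE))
  if (!is.null(all_profiles))
    .write_tsv(all_profiles, file.path(out_dir, "er_profiles.tsv"))
  if (!is.null(fractions))
    .write_tsv(fractions, file.path(out_dir, "significant_fractions.tsv"))
  .write_manifest(out_dir, config, seed)
  invisible(list(profiles = profiles, fractions = fractions,
                 essentiality = essent, loeuf = loeuf_rep,
                 out_dir = out_dir))
}

#' Run pipeline stages by verb
#'
#' `simulate` writes a synthetic study with [make_study_fixture()];
#' `divergence` runs [run_divergence()]; `er` runs [run_er_analysis()]
#' (after `divergence` if needed); `all` runs everything.
#'
#' @param config Path to a YAML config file or a config list.
#' @param verb One of `"simulate"`, `"divergence"`, `"er"`, `"all"`.
#' @param seed Integer seed for every stochastic stage.
#' @return Invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(config, verb = c("all", "simulate", "divergence",
                                          "er"), seed = 1) {
  verb <- match.arg(verb)
  config <- .read_config(config)
  out <- list()
  if (verb %in% c("simulate", "all") && !is.null(config$simulate_dir)) {
    out$fixture <- make_study_fixture(config$simulate_dir, seed = seed)
    config$sequence_dir <- config$sequence_dir %||% config$simulate_dir
    config$genes <- config$genes %||% out$fixture$genes
    config$domain_map <- config$domain_map %||% out$fixture$domain_map
    config$divergence_table <- config$divergence_table %||%
      out$fixture$divergence_table
    config$expression <- config$expression %||% out$fixture$expression
    config$annotation <- config$annotation %||% out$fixture$annotation
    config$phenotypes <- config$phenotypes %||% out$fixture$phenotypes
    config$loeuf <- config$loeuf %||% out$fixture$loeuf
  }
  if (verb %in% c("divergence", "er", "all"))
    out$divergence <- run_divergence(config, seed = seed)
  if (verb %in% c("er", "all"))
    out$er <- run_er_analysis(config, out$divergence, seed = seed)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
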
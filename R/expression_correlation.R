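# Expression-level versus evolutionary-rate (E-R) profiling: per-sample
# Spearman correlations of a per-gene metric (dN, omega or LOEUF) against
# expression across tissues or cell types, significant-fraction summaries
# by sample class, and an any-species aggregation mode.

#' Read an expression matrix with its sample annotation
#'
#' Expression TSV: genes in rows (first column `gene`), one column per
#' sample. Annotation TSV: columns `sample`, `class` covering every sample
#' column. Values must be nonnegative; gene identifiers unique.
#'
#' @param path Expression TSV.
#' @param annotation_path Sample annotation TSV.
#' @return List of class `expression_matrix` with `mat` and `annotation`.
#' @export
read_expression_matrix <- function(path, annotation_path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first expression column must be 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene identifiers")
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  if (any(mat < 0)) stop("expression values must be nonnegative")
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "class") %in% names(ann)))
    stop("annotation must have columns sample, class")
  missing <- setdiff(colnames(mat), ann$sample)
  if (length(missing) > 0)
    stop("samples without annotation: ", paste(missing, collapse = ", "))
  structure(list(mat = mat, annotation = ann), class = "expression_matrix")
}

#' Expression-rate (E-R) Spearman profile
#'
#' One two-tailed Spearman correlation of the metric vector against each
#' sample column, over the genes shared between the metric and the matrix
#' rows (matched by symbol, case-insensitively). Samples with fewer than 3
#' shared genes are skipped with a note; samples with zero expression
#' variance are kept with an `undefined` flag.
#'
#' @param metric Named per-gene numeric vector (dN, omega or LOEUF values).
#' @param expression An `expression_matrix` (see
#'   [read_expression_matrix()] or [plant_expression_matrix()]).
#' @param metric_name Label stored in the profile (`"dN"`, `"omega"`,
#'   `"LOEUF"`, ...).
#' @return data.frame of class `er_profile`: `sample`, `class`, `rho`, `p`,
#'   `n`, `metric`, `undefined`.
#' @export
er_profile <- function(metric, expression, metric_name = "dN") {
  stopifnot(inherits(expression, "expression_matrix"))
  mat <- expression$mat
  ann <- expression$annotation
  m <- match(toupper(names(metric)), toupper(rownames(mat)))
  keep <- !is.na(m)
  if (sum(!keep) > 0)
    message("genes not in expression matrix: ",
            paste(names(metric)[!keep], collapse = ", "))
  if (sum(keep) < 3)
    stop("fewer than 3 genes shared between metric and expression matrix")
  mv <- metric[keep]
  rows <- m[keep]
  out <- lapply(colnames(mat), function(s) {
    e <- mat[rows, s]
    ok <- is.finite(mv) & is.finite(e)
    if (sum(ok) < 3) {
      message("skipping sample with <3 shared genes: ", s)
      return(NULL)
    }
    r <- spearman_cor(mv[ok], e[ok])
    data.frame(sample = s,
               class = ann$class[match(s, ann$sample)],
               rho = r$rho, p = r$p_value, n = r$n,
               metric = metric_name, undefined = r$undefined,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("er_profile", class(res))
  res
}

#' Fraction of samples in a class with a significant correlation
#'
#' @param profile An `er_profile`.
#' @param class_label Class to summarize (e.g. `"CNS"`, `"neuron"`).
#' @param alpha Significance level (default 0.05, two-tailed p's as stored
#'   in the profile).
#' @param sign `"negative"`, `"positive"` or `"any"`.
#' @return List with `fraction`, `n_significant`, `n_total`.
#' @export
significant_fraction <- function(profile, class_label, alpha = 0.05,
                                 sign = c("negative", "positive", "any")) {
  sign <- match.arg(sign)
  sub <- profile[profile$class == class_label, , drop = FALSE]
  if (nrow(sub) == 0) stop("no samples in class: ", class_label)
  sig <- !sub$undefined & !is.na(sub$p) & sub$p < alpha
  sig <- sig & switch(sign,
                      negative = sub$rho < 0,
                      positive = sub$rho > 0,
                      any = TRUE)
  list(fraction = sum(sig) / nrow(sub), n_significant = sum(sig),
       n_total = nrow(sub))
}

#' Any-species significant fraction
#'
#' Given one E-R profile per species (the same samples correlated against
#' per-species metric vectors), a sample counts as significant when any
#' species' correlation is significant with the requested sign — the
#' aggregation used when reporting that a cell type shows a significant
#' anti-correlation with at least one species.
#'
#' @param profiles List of `er_profile` objects over identical samples.
#' @param class_label,alpha,sign As in [significant_fraction()].
#' @return List with `fraction`, `n_significant`, `n_total`.
#' @export
significant_fraction_any <- function(profiles, class_label, alpha = 0.05,
                                     sign = c("negative", "positive",
                                              "any")) {
  sign <- match.arg(sign)
  per <- lapply(profiles, function(p) {
    sub <- p[p$class == class_label, , drop = FALSE]
    sub <- sub[order(sub$sample), ]
    sig <- !sub$undefined & !is.na(sub$p) & sub$p < alpha
    sig & switch(sign, negative = sub$rho < 0, positive = sub$rho > 0,
                 any = TRUE)
  })
  n <- length(per[[1]])
  if (n == 0) stop("no samples in class: ", class_label)
  any_sig <- Reduce(`|`, per)
  list(fraction = sum(any_sig) / n, n_significant = sum(any_sig),
       n_total = n)
}

#' LOEUF correlations
#'
#' Correlates per-gene LOEUF (loss-of-function observed/expected upper
#' bound fraction) scores either against another per-gene metric (one
#' Spearman report) or against an expression matrix (an E-R profile with
#' metric tag `"LOEUF"`).
#'
#' @param loeuf Named per-gene numeric vector of LOEUF scores.
#' @param metric Optional named per-gene vector (e.g. omega) for a single
#'   correlation.
#' @param expression Optional `expression_matrix` for a per-sample profile.
#' @return A Spearman report list (metric mode) or an `er_profile`
#'   (expression mode).
#' @export
loeuf_correlations <- function(loeuf, metric = NULL, expression = NULL) {
  if (!is.null(metric)) {
    m <- match(toupper(names(loeuf)), toupper(names(metric)))
    keep <- !is.na(m)
    if (sum(keep) < 3) stop("fewer than 3 genes shared")
    r <- spearman_cor(loeuf[keep], metric[m[keep]])
    r$metric <- "LOEUF"
    return(r)
  }
  if (!is.null(expression))
    return(er_profile(loeuf, expression, metric_name = "LOEUF"))
  stop("supply either `metric` or `expression`")
}
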
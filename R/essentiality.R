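# Composite gene-essentiality scoring from curated phenotype annotations,
# and its correlation with evolutionary distance.

#' Essentiality score from phenotype annotations
#'
#' Deterministic composite: mouse knockout non-lethal = 0 / lethal = 2;
#' phenotype none = 0 / mild = 1 / severe = 2; human-disease association
#' none = 0 / associated = 1. Maximum score 5.
#'
#' @param records data.frame with columns `gene`, `knockout_lethal` (0/1 or
#'   logical), `severity` (`"none"`, `"mild"`, `"severe"`) and
#'   `human_disease` (0/1 or logical).
#' @return data.frame with columns `gene`, `lethal_component`,
#'   `severity_component`, `disease_component`, `score`.
#' @export
score_essentiality <- function(records) {
  need <- c("gene", "knockout_lethal", "severity", "human_disease")
  if (!all(need %in% names(records)))
    stop("phenotype records need columns: ", paste(need, collapse = ", "))
  sev_levels <- c(none = 0L, mild = 1L, severe = 2L)
  sev <- sev_levels[as.character(records$severity)]
  if (anyNA(sev))
    stop("severity must be one of: ", paste(names(sev_levels),
                                            collapse = ", "))
  lethal <- 2L * (as.integer(as.logical(records$knockout_lethal)))
  disease <- as.integer(as.logical(records$human_disease))
  data.frame(gene = records$gene,
             lethal_component = lethal,
             severity_component = unname(sev),
             disease_component = disease,
             score = lethal + unname(sev) + disease,
             stringsAsFactors = FALSE)
}

#' Read a phenotype annotation table
#'
#' Tab-delimited with header columns `gene`, `knockout_lethal` (0/1),
#' `severity` (none/mild/severe), `human_disease` (0/1).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotype_table <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "knockout_lethal", "severity", "human_disease")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  ph
}

#' Spearman correlation of essentiality scores with evolutionary distance
#'
#' Matches genes by symbol (case-insensitive) and delegates to
#' [spearman_cor()].
#'
#' @param scores data.frame from [score_essentiality()] (columns `gene`,
#'   `score`).
#' @param distances Named numeric vector of per-gene dN or omega values.
#' @param metric Label for the report (`"dN"` or `"omega"`).
#' @return List with `rho`, `p_value`, `n`, `metric`, `undefined`.
#' @export
correlate_essentiality <- function(scores, distances,
                                   metric = c("dN", "omega")) {
  metric <- match.arg(metric)
  m <- match(toupper(scores$gene), toupper(names(distances)))
  keep <- !is.na(m)
  if (sum(keep) < 3)
    stop("need at least 3 genes with both a score and a distance")
  r <- spearman_cor(scores$score[keep], distances[m[keep]])
  list(rho = r$rho, p_value = r$p_value, n = r$n, metric = metric,
       undefined = r$undefined)
}
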
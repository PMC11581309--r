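# Assembly of per-gene, per-species, per-domain estimates into the summary
# quantities: group-averaged dN/dS, ED minus CD dN differences, and average
# substitution rates per million years with least-squares trends.

#' Group-averaged dN/dS with standard errors
#'
#' Arithmetic mean and standard error of the mean of omega within each
#' species group of the divergence table; the group plotting time is the
#' mean divergence time of its members (apes 10.9 MYr, New World monkeys
#' 27.5 MYr and Old World monkeys/tarsiers/strepsirrhines 48.7 MYr for the
#' bundled synthetic table). Empty groups are omitted with a warning;
#' species lacking a group assignment are an error.
#'
#' @param series data.frame with columns `species` and `value` (omega per
#'   species).
#' @param divergence_table data.frame with columns `species`, `myr`,
#'   `group`.
#' @return data.frame with columns `group`, `time_myr`, `mean`, `sem`, `n`.
#' @export
group_average_omega <- function(series, divergence_table) {
  m <- match(series$species, divergence_table$species)
  if (anyNA(m))
    stop("species missing from divergence table: ",
         paste(series$species[is.na(m)], collapse = ", "))
  grp <- divergence_table$group[m]
  if (any(is.na(grp) | grp == ""))
    stop("every species must be assigned a group")
  empty <- setdiff(unique(divergence_table$group), unique(grp))
  if (length(empty) > 0)
    warning("group(s) without data omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(split(seq_len(nrow(series)), grp), function(i) {
    v <- series$value[i]
    data.frame(group = grp[i][1],
               time_myr = mean(divergence_table$myr[m[i]]),
               mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$time_myr), ]
}

#' Per-species difference in dN between the ectodomain and the cytoplasmic
#' domain
#'
#' The ectodomain (ED) is the EC1-EC5 concatenation analysed as a single
#' segment. Species missing either segment are skipped with a note.
#'
#' @param results data.frame with columns `species`, `segment`, `dN`
#'   containing rows for segments `"ED"` and `"CD"`.
#' @return data.frame with columns `species`, `dn_ed`, `dn_cd`, `diff`.
#' @export
ed_cd_dn_difference <- function(results) {
  ed <- results[results$segment == "ED", c("species", "dN")]
  cd <- results[results$segment == "CD", c("species", "dN")]
  species <- union(ed$species, cd$species)
  keep <- species[species %in% ed$species & species %in% cd$species]
  skipped <- setdiff(species, keep)
  if (length(skipped) > 0)
    message("skipping species lacking ED or CD estimates: ",
            paste(skipped, collapse = ", "))
  dn_ed <- ed$dN[match(keep, ed$species)]
  dn_cd <- cd$dN[match(keep, cd$species)]
  data.frame(species = keep, dn_ed = dn_ed, dn_cd = dn_cd,
             diff = dn_ed - dn_cd, stringsAsFactors = FALSE)
}

#' Mean substitution rate per million years and least-squares trend
#'
#' The rate is 100 times the mean over species of value/time (percent
#' substitutions per site per MYr, the mean-of-ratios reading); the
#' least-squares slope of value against time is reported alongside for
#' transparency.
#'
#' @param series data.frame with columns `species`, `time` (MYr, > 0) and
#'   `value` (substitutions per site).
#' @return Object of class `rate_summary`: `mean_rate_percent_per_myr`,
#'   `trend_slope`, `n`.
#' @export
mean_rate_per_myr <- function(series) {
  stopifnot(all(series$time > 0))
  rate <- 100 * mean(series$value / series$time)
  slope <- if (nrow(series) >= 2 && stats::var(series$time) > 0)
    stats::cov(series$time, series$value) / stats::var(series$time)
  else NA_real_
  structure(list(mean_rate_percent_per_myr = rate, trend_slope = slope,
                 n = nrow(series)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf(
    "Mean rate: %.4f%% substitutions/site/MYr (n = %d, LS slope %.3g)\n",
    x$mean_rate_percent_per_myr, x$n, x$trend_slope))
  invisible(x)
}
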
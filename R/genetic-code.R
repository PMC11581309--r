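# Internal genetic-code machinery shared by the codon estimators and the
# simulator. Standard nuclear code only (the genes analysed are nuclear);
# everything is precomputed once per session and cached in .cadevo_cache.

.cadevo_cache <- new.env(parent = emptyenv())

BASES <- c("T", "C", "A", "G")
PURINES <- c("A", "G")

#' @noRd
.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- as.character(names(gc))
  gc
}

#' All 64 codons in TCAG order
#' @noRd
.all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES,
                  function(ab, c) paste0(rep(ab, length.out = length(ab)), c)))
}

#' The 61 sense codons of the standard code
#' @noRd
.sense_codons <- function() {
  if (!is.null(.cadevo_cache$sense)) return(.cadevo_cache$sense)
  gc <- .genetic_code()
  cods <- names(gc)[gc != "*"]
  .cadevo_cache$sense <- cods
  cods
}

.is_stop_codon <- function(codon) {
  gc <- .genetic_code()
  aa <- gc[codon]
  !is.na(aa) & aa == "*"
}

#' Translate a vector of codons; NA for codons with non-ACGT symbols
#' @noRd
.translate_codons <- function(codons) {
  gc <- .genetic_code()
  unname(gc[codons])
}

.is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES)
}

#' Split a CDS string into codons
#' @noRd
.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("coding sequence length ", n, " is not a multiple of 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Single-base neighbours of every sense codon.
#'
#' Returns a data.frame with one row per (codon, position, alternative base):
#' from, to, pos, base_from, base_to, transition, syn (synonymous amino-acid
#' change), to_stop. 61 x 9 rows.
#' @noRd
.codon_neighbors <- function() {
  if (!is.null(.cadevo_cache$neighbors)) return(.cadevo_cache$neighbors)
  gc <- .genetic_code()
  sense <- .sense_codons()
  rows <- vector("list", length(sense) * 9L)
  k <- 0L
  for (cod in sense) {
    aa <- gc[[cod]]
    for (pos in 1:3) {
      b <- substr(cod, pos, pos)
      for (alt in setdiff(BASES, b)) {
        to <- cod
        substr(to, pos, pos) <- alt
        k <- k + 1L
        rows[[k]] <- data.frame(
          from = cod, to = to, pos = pos, base_from = b, base_to = alt,
          transition = .is_transition(b, alt),
          to_stop = gc[[to]] == "*",
          syn = gc[[to]] != "*" && gc[[to]] == aa,
          stringsAsFactors = FALSE)
      }
    }
  }
  nb <- do.call(rbind, rows)
  .cadevo_cache$neighbors <- nb
  nb
}

#' Degeneracy class (0, 2 or 4) of each position of each sense codon.
#'
#' A position is fourfold degenerate if all three alternative bases give a
#' synonymous codon, nondegenerate if none does, and twofold otherwise.
#' Changes to stop codons are never synonymous. This convention resolves the
#' irregular isoleucine and arginine families to the twofold class.
#' @noRd
.degeneracy_table <- function() {
  if (!is.null(.cadevo_cache$degeneracy)) return(.cadevo_cache$degeneracy)
  nb <- .codon_neighbors()
  sense <- .sense_codons()
  deg <- matrix(0L, nrow = length(sense), ncol = 3,
                dimnames = list(sense, NULL))
  for (cod in sense) {
    for (pos in 1:3) {
      nsyn <- sum(nb$syn[nb$from == cod & nb$pos == pos])
      deg[cod, pos] <- if (nsyn == 3L) 4L else if (nsyn == 0L) 0L else 2L
    }
  }
  .cadevo_cache$degeneracy <- deg
  deg
}
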
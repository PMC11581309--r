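# Sequence and alignment input: FASTA reading with validation, pairwise
# alignments, back-translation to codon alignments, domain slicing and
# pairwise gap deletion. Multiple sequence alignment itself is consumed,
# never computed, so externally produced alignments drop straight in.

AA_SYMBOLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA_SYMBOLS <- c("A", "C", "G", "T")

#' Read a FASTA file of protein or coding sequences
#'
#' Sequences are uppercased and validated: protein records must not contain
#' an internal `*`; CDS lengths must be divisible by 3 after removal of a
#' terminal stop codon, which is trimmed with a note, and internal stop
#' codons are an error (mature coding sequence expected).
#'
#' @param path FASTA file.
#' @param kind `"protein"` or `"cds"`.
#' @return data.frame with columns `id`, `seq`, `kind`; zero rows (with a
#'   warning) for an empty file.
#' @export
read_fasta <- function(path, kind = c("protein", "cds")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(0), seq = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA at line ", nonempty[1], ": expected '>' header")
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (kind == "protein") {
    bad <- grepl("\\*", sub("\\*$", "", seqs))
    if (any(bad))
      stop("protein record(s) with internal stop symbol: ",
           paste(ids[bad], collapse = ", "))
    seqs <- sub("\\*$", "", seqs)
  } else {
    for (i in seq_along(seqs)) {
      if (nchar(seqs[i]) %% 3L != 0L)
        stop("CDS length of '", ids[i], "' is not a multiple of 3")
      cods <- .split_codons(seqs[i])
      aa <- .translate_codons(cods)
      if (!is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
        message("trimming terminal stop codon from '", ids[i], "'")
        seqs[i] <- substr(seqs[i], 1L, nchar(seqs[i]) - 3L)
        aa <- aa[-length(aa)]
      }
      if (any(!is.na(aa) & aa == "*"))
        stop("internal stop codon in CDS '", ids[i], "'")
    }
  }
  data.frame(id = ids, seq = unname(seqs), kind = kind,
             stringsAsFactors = FALSE)
}

#' Construct a pairwise alignment from two gapped rows
#'
#' Columns gapped in both rows are removed so that no all-gap column
#' survives construction; ungapping either row recovers its input sequence.
#'
#' @param a,b Gapped sequence strings of equal length (`-` is the gap).
#' @param alphabet `"protein"` or `"dna"`.
#' @return Object of class `pairwise_alignment` with fields `a`, `b`,
#'   `alphabet`.
#' @export
pairwise_alignment <- function(a, b, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("alignment rows differ in length: ", nchar(a), " vs ", nchar(b))
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  both_gap <- ca == "-" & cb == "-"
  if (any(both_gap)) {
    ca <- ca[!both_gap]; cb <- cb[!both_gap]
  }
  structure(list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""),
                 alphabet = alphabet),
            class = "pairwise_alignment")
}

.ungap <- function(s) gsub("-", "", s)

#' Back-translate a protein alignment into a codon alignment
#'
#' Each protein residue column is expanded to its source codon and each
#' protein gap to `---`; the two CDS must translate exactly to the ungapped
#' protein rows under the standard code.
#'
#' @param protein_alignment A `pairwise_alignment` over the protein
#'   alphabet.
#' @param cds_a,cds_b Ungapped coding sequences for rows a and b.
#' @return Object of class `codon_alignment` with gapped codon rows `a`,
#'   `b` (length 3x the protein alignment) and the source
#'   `protein_alignment`.
#' @export
build_codon_alignment <- function(protein_alignment, cds_a, cds_b) {
  expand_row <- function(row, cds, label) {
    chars <- strsplit(row, "")[[1]]
    res <- .ungap(row)
    cods <- .split_codons(toupper(cds))
    aa <- .translate_codons(cods)
    if (length(aa) > 0 && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
      cods <- cods[-length(cods)]
      aa <- aa[-length(aa)]
    }
    prot <- strsplit(res, "")[[1]]
    if (length(aa) != length(prot))
      stop("row ", label, ": CDS encodes ", length(aa),
           " residues but protein row has ", length(prot))
    mism <- which(is.na(aa) | aa != prot)
    if (length(mism) > 0)
      stop("row ", label, ": translation mismatch at residue ", mism[1],
           ": expected '", prot[mism[1]], "', observed '", aa[mism[1]], "'")
    out <- character(length(chars))
    k <- 0L
    for (i in seq_along(chars)) {
      if (chars[i] == "-") {
        out[i] <- "---"
      } else {
        k <- k + 1L
        out[i] <- cods[k]
      }
    }
    paste(out, collapse = "")
  }
  structure(list(a = expand_row(protein_alignment$a, cds_a, "a"),
                 b = expand_row(protein_alignment$b, cds_b, "b"),
                 protein = protein_alignment),
            class = "codon_alignment")
}

#' Columns retained under pairwise deletion
#'
#' Returns the alignment columns where neither row carries a gap or an
#' ambiguity symbol (anything outside the 20 amino acids or A/C/G/T is
#' treated as missing data). For a codon alignment, any masked position
#' removes its whole codon, and the nucleotide columns of the retained
#' codons are returned.
#'
#' @param alignment A `pairwise_alignment` or `codon_alignment`.
#' @return Integer vector of retained column indices (possibly empty).
#' @export
pairwise_deletion_mask <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) {
    ca <- strsplit(alignment$a, "")[[1]]
    cb <- strsplit(alignment$b, "")[[1]]
    ok <- ca %in% DNA_SYMBOLS & cb %in% DNA_SYMBOLS
    ncod <- length(ok) / 3L
    codon_ok <- vapply(seq_len(ncod),
                       function(j) all(ok[(3L * j - 2L):(3L * j)]), TRUE)
    return(as.integer(t(outer(which(codon_ok) * 3L - 2L, 0:2, `+`))))
  }
  valid <- if (alignment$alphabet == "protein") AA_SYMBOLS else DNA_SYMBOLS
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  which(ca %in% valid & cb %in% valid)
}

#' Slice an alignment to one protein domain
#'
#' Keeps the columns whose coordinate on the reference (human) row falls in
#' the segment's 1-based inclusive range; gap columns in the reference row
#' are assigned to the coordinate of the preceding reference residue, so
#' insertions relative to the reference stay with their segment.
#'
#' @param alignment A `pairwise_alignment` or `codon_alignment`.
#' @param domain_map data.frame with columns `segment`, `start`, `end` (a
#'   `gene` column is allowed and ignored here).
#' @param segment_name Segment to extract, e.g. `"EC1"` or `"FL"`.
#' @param reference_row `"a"` or `"b"`: the row carrying the reference
#'   coordinate system (default `"a"`).
#' @return An object of the same class restricted to the segment.
#' @export
slice_domain <- function(alignment, domain_map, segment_name,
                         reference_row = c("a", "b")) {
  reference_row <- match.arg(reference_row)
  seg <- domain_map[domain_map$segment == segment_name, , drop = FALSE]
  if (nrow(seg) == 0L) stop("segment not in domain map: ", segment_name)
  start <- seg$start[1]; end <- seg$end[1]
  is_codon <- inherits(alignment, "codon_alignment")
  prot <- if (is_codon) alignment$protein else alignment
  ref <- strsplit(prot[[reference_row]], "")[[1]]
  refcoord <- cumsum(ref != "-")
  if (end > max(refcoord))
    stop("segment ", segment_name, " (", start, "-", end,
         ") extends beyond the ", max(refcoord), "-residue reference")
  keep <- which(refcoord >= start & refcoord <= end)
  pa <- strsplit(prot$a, "")[[1]][keep]
  pb <- strsplit(prot$b, "")[[1]][keep]
  prot_out <- structure(list(a = paste(pa, collapse = ""),
                             b = paste(pb, collapse = ""),
                             alphabet = prot$alphabet),
                        class = "pairwise_alignment")
  if (!is_codon) return(prot_out)
  nt_keep <- as.integer(t(outer(keep * 3L - 2L, 0:2, `+`)))
  ca <- strsplit(alignment$a, "")[[1]][nt_keep]
  cb <- strsplit(alignment$b, "")[[1]][nt_keep]
  structure(list(a = paste(ca, collapse = ""), b = paste(cb, collapse = ""),
                 protein = prot_out),
            class = "codon_alignment")
}

#' Read a domain-topology table
#'
#' Tab-delimited with header columns `gene`, `segment`, `start`, `end` in
#' 1-based inclusive mature-protein coordinates of the human sequence.
#'
#' @param path TSV file.
#' @return data.frame, validated per gene: segments within FL,
#'   non-overlapping and ordered.
#' @export
read_domain_map <- function(path) {
  dm <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "segment", "start", "end")
  if (!all(need %in% names(dm)))
    stop("domain map must have columns: ", paste(need, collapse = ", "))
  for (g in unique(dm$gene)) {
    sub <- dm[dm$gene == g, ]
    if (any(sub$start > sub$end)) stop("segment with start > end in ", g)
    fl <- sub[sub$segment == "FL", ]
    segs <- sub[sub$segment != "FL", ]
    segs <- segs[order(segs$start), ]
    if (nrow(segs) > 1 && any(segs$start[-1] <= segs$end[-nrow(segs)]))
      stop("overlapping segments in ", g)
    if (nrow(fl) == 1 && nrow(segs) > 0 &&
        (min(segs$start) < fl$start || max(segs$end) > fl$end))
      stop("segments outside FL in ", g)
  }
  dm
}

#' Read a species divergence-time table
#'
#' Tab-delimited with header columns `species`, `myr` (divergence time from
#' human, million years, strictly positive) and optionally `group`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_divergence_table <- function(path) {
  dt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species", "myr") %in% names(dt)))
    stop("divergence table must have columns species, myr")
  if (any(!is.finite(dt$myr)) || any(dt$myr <= 0))
    stop("divergence times must be strictly positive")
  dt
}
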
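# Coding-gene model on a local genomic segment: the coordinate authority for
# guide design and edit prediction. Segment/exon/CDS coordinates are 0-based
# half-open; residue indices are 1-based (1..L).

VALID_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' @param x A character vector of DNA sequences over `ACGT`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

check_dna <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    abort(sprintf("%s must be a single non-empty string", what))
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), VALID_BASES)
  if (length(bad) > 0L) {
    abort(sprintf(
      "%s contains non-ACGT characters: %s (ambiguous bases are rejected)",
      what, paste(bad, collapse = ", ")
    ))
  }
  invisible(sequence)
}

#' Translate a coding sequence
#'
#' Standard-code translation (NCBI table 1). A terminal stop codon is
#' stripped. By default an internal stop raises an error; in permissive
#' mode (used by edit prediction, where premature stops are the signal)
#' stops are returned as `*` and nothing is stripped.
#'
#' @param cds_sequence Coding sequence, length divisible by 3, `ACGT` only.
#' @param permissive If `TRUE`, return `*` for stop codons (including the
#'   terminal one) instead of erroring on internal stops.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGAAATAG")     # "MK"
#' translate_cds("ATGTAAAAA", permissive = TRUE)  # "M*K"
#' @export
translate_cds <- function(cds_sequence, permissive = FALSE) {
  check_dna(cds_sequence, "cds_sequence")
  n <- nchar(cds_sequence)
  if (n %% 3L != 0L) {
    abort("CDS length not divisible by 3")
  }
  codons <- substring(cds_sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (permissive) {
    return(paste(aa, collapse = ""))
  }
  if (length(aa) > 1L && any(aa[-length(aa)] == "*")) {
    abort(sprintf(
      "internal stop codon at codon %d", which(aa[-length(aa)] == "*")[1]
    ))
  }
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Build a validated coding-gene model
#'
#' Assembles a gene model from a genomic segment, exon intervals, strand
#' and transcript-relative CDS bounds, deriving the spliced transcript,
#' the protein and its length `L`. Exons include UTRs; the CDS bounds
#' carve the coding part out of the spliced transcript.
#'
#' @param sequence Genomic segment sequence (`ACGT` only; `N` rejected).
#' @param exons List (or 2-column matrix) of `c(start, end)` exon
#'   intervals in 0-based half-open segment coordinates, sorted and
#'   non-overlapping.
#' @param strand `"+"` or `"-"`: strand of the transcript on the segment.
#' @param cds `c(start, end)` transcript-relative 0-based half-open
#'   bounds of the CDS (on the spliced transcript read 5' to 3').
#' @param id Segment/gene identifier.
#' @param flank_bp Intron flank distance (bp) used to classify
#'   `intron_flank` positions and for guide inclusion. Default 30.
#' @return An object of class `gene_model`: a list with the validated
#'   inputs plus `transcript`, `cds_seq`, `protein`, `L`, and the
#'   per-CDS-base segment coordinate map `cds_segment_pos`.
#' @examples
#' m <- gene_model("AAATGGAATACTGAGG",
#'                 exons = list(c(1, 16)), strand = "+", cds = c(1, 13))
#' m$protein  # "MEY"
#' m$L        # 3
#' @export
gene_model <- function(sequence, exons, strand = "+", cds,
                       id = "gene", flank_bp = 30L) {
  check_dna(sequence, "segment sequence")
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (is.matrix(exons)) exons <- asplit(exons, 1)
  exons <- lapply(exons, function(e) as.integer(e))
  seg_len <- nchar(sequence)
  for (i in seq_along(exons)) {
    e <- exons[[i]]
    if (length(e) != 2L || e[1] < 0L || e[2] > seg_len || e[1] >= e[2]) {
      abort(sprintf("exon %d (%d,%d) is outside the segment or empty",
                    i, e[1], e[2]))
    }
  }
  if (length(exons) > 1L) {
    starts <- vapply(exons, `[`, integer(1), 1L)
    ends <- vapply(exons, `[`, integer(1), 2L)
    if (any(diff(starts) <= 0) || any(starts[-1] < ends[-length(ends)])) {
      abort("exons must be sorted and non-overlapping")
    }
  }

  # spliced transcript: segment positions of each transcript base, 5'->3'
  exon_pos <- unlist(lapply(exons, function(e) seq.int(e[1], e[2] - 1L)))
  seg_bases <- strsplit(sequence, "")[[1]]
  if (strand == "+") {
    tx_pos <- exon_pos
    tx_bases <- seg_bases[tx_pos + 1L]
  } else {
    tx_pos <- rev(exon_pos)
    tx_bases <- complement_base(seg_bases[tx_pos + 1L])
  }
  tx_len <- length(tx_pos)

  cds <- as.integer(cds)
  if (length(cds) != 2L || cds[1] < 0L || cds[2] > tx_len || cds[1] >= cds[2]) {
    abort("CDS bounds must lie within the spliced transcript")
  }
  cds_idx <- seq.int(cds[1] + 1L, cds[2])
  cds_seq <- paste(tx_bases[cds_idx], collapse = "")
  if (nchar(cds_seq) %% 3L != 0L) abort("CDS length not divisible by 3")
  protein <- translate_cds(cds_seq)  # errors on internal stop
  n_codons <- nchar(cds_seq) / 3L
  has_stop <- nchar(protein) == n_codons - 1L
  L <- nchar(protein)

  structure(
    list(
      id = id,
      sequence = sequence,
      exons = exons,
      strand = strand,
      cds = cds,
      flank_bp = as.integer(flank_bp),
      transcript = paste(tx_bases, collapse = ""),
      tx_segment_pos = tx_pos,
      cds_seq = cds_seq,
      cds_segment_pos = tx_pos[cds_idx],
      protein = protein,
      L = L,
      has_terminal_stop = has_stop
    ),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf(
    "<gene_model> %s: %d nt segment, %d exon(s), strand %s, protein %d aa\n",
    x$id, nchar(x$sequence), length(x$exons), x$strand, x$L
  ))
  invisible(x)
}

#' Classify segment positions relative to the gene model
#'
#' Maps 0-based segment positions to `CDS`, `UTR` (exonic non-CDS),
#' `intron_flank` (within `flank_bp` of an exon boundary but not exonic)
#' or `outside`. CDS positions also get a 1-based residue index and a
#' codon offset in `{0,1,2}` (coding-strand reading frame).
#'
#' @param model A [gene_model()].
#' @param segment_pos Integer vector of 0-based segment positions.
#' @param flank_bp Flank distance; defaults to the model's `flank_bp`.
#' @return A tibble with columns `segment_pos`, `region`, `codon_index`,
#'   `codon_offset`.
#' @export
map_position <- function(model, segment_pos, flank_bp = model$flank_bp) {
  segment_pos <- as.integer(segment_pos)
  seg_len <- nchar(model$sequence)
  if (any(segment_pos < 0L | segment_pos >= seg_len)) {
    abort("segment_pos out of range")
  }
  exonic <- rep(FALSE, seg_len)
  near <- rep(FALSE, seg_len)
  for (e in model$exons) {
    exonic[seq.int(e[1], e[2] - 1L) + 1L] <- TRUE
    lo <- max(0L, e[1] - flank_bp)
    hi <- min(seg_len - 1L, e[2] - 1L + flank_bp)
    near[seq.int(lo, hi) + 1L] <- TRUE
  }
  # residue index / offset per CDS segment position
  n_cds <- length(model$cds_segment_pos)
  codon_index_map <- rep(NA_integer_, seg_len)
  codon_offset_map <- rep(NA_integer_, seg_len)
  ord <- seq_len(n_cds)
  codon_index_map[model$cds_segment_pos + 1L] <- (ord - 1L) %/% 3L + 1L
  codon_offset_map[model$cds_segment_pos + 1L] <- (ord - 1L) %% 3L

  in_cds <- !is.na(codon_index_map[segment_pos + 1L])
  region <- dplyr::case_when(
    in_cds ~ "CDS",
    exonic[segment_pos + 1L] ~ "UTR",
    near[segment_pos + 1L] ~ "intron_flank",
    TRUE ~ "outside"
  )
  tibble(
    segment_pos = segment_pos,
    region = region,
    codon_index = ifelse(in_cds, codon_index_map[segment_pos + 1L],
                         NA_integer_),
    codon_offset = ifelse(in_cds, codon_offset_map[segment_pos + 1L],
                          NA_integer_)
  )
}
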
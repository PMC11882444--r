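# sgRNA library enumeration for base editor scanning: all 20-nt
# protospacers with an NG PAM on either strand whose editing window
# touches the exonic/flank target space, minus U6-terminator (TTTT)
# protospacers; plus control guides.

GUIDE_CATEGORIES <- c("targeting", "nontargeting_control",
                      "intergenic_control", "splice_control")

#' Editor specification
#'
#' Fixed conversion chemistry and editing window for the two deaminase
#' classes: CBE converts C to T and ABE converts A to G, both on the
#' protospacer strand, within an inclusive window of protospacer
#' positions counted 1-based from the 5' (PAM-distal) end.
#'
#' @param editor `"CBE"` or `"ABE"`.
#' @param window Length-2 inclusive protospacer-position window.
#'   Default `c(4, 8)`.
#' @return A list with `editor`, `window`, `ref_base`, `alt_base`.
#' @export
editor_spec <- function(editor = c("CBE", "ABE"), window = c(4L, 8L)) {
  editor <- match.arg(editor)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[2] > 20L ||
      window[1] > window[2]) {
    abort("window must lie within protospacer positions 1..20")
  }
  conv <- if (editor == "CBE") c("C", "T") else c("A", "G")
  structure(list(editor = editor, window = window,
                 ref_base = conv[1], alt_base = conv[2]),
            class = "editor_spec")
}

# enumerate every 20-nt protospacer with an NG PAM on both strands of a
# segment; `start` is the 0-based segment position of the protospacer's
# 5'-most base on its own strand
scan_protospacers <- function(seg) {
  scan_one <- function(strand) {
    s <- if (strand == "+") seg else reverse_complement(seg)
    n <- nchar(s)
    if (n < 22L) {
      return(tibble(protospacer = character(0), pam = character(0),
                    strand = character(0), start = integer(0)))
    }
    starts <- seq_len(n - 21L) - 1L  # 0-based on the scanned strand
    keep <- substring(s, starts + 22L, starts + 22L) == "G"  # NG rule
    starts <- starts[keep]
    if (length(starts) == 0L) {
      return(tibble(protospacer = character(0), pam = character(0),
                    strand = character(0), start = integer(0)))
    }
    seg_start <- if (strand == "+") starts else (n - 1L) - starts
    tibble(
      protospacer = substring(s, starts + 1L, starts + 20L),
      pam = substring(s, starts + 21L, starts + 22L),
      strand = strand,
      start = seg_start
    )
  }
  bind_rows(scan_one("+"), scan_one("-"))
}

# segment positions (0-based) occupied by protospacer positions `idx`
# (1-based from the 5' end on the guide's own strand)
guide_segment_pos <- function(start, strand, idx) {
  if (strand == "+") start + idx - 1L else start - (idx - 1L)
}

#' Enumerate the targeting sgRNA library for a gene model
#'
#' Scans both strands of the model's segment for 20-nt protospacers
#' followed by a PAM matching `pam_rule`, and keeps a guide iff any base
#' of the region named by `include_rule` lies within an exon or within
#' `flank_bp` of an exon boundary. Protospacers containing the
#' `homopolymer_filter` motif (a U6 terminator) are excluded.
#'
#' @param model A [gene_model()].
#' @param pam_rule PAM rule for the 2 nt 3' of the protospacer;
#'   `"NG"` (default) requires `G` at the second position.
#' @param flank_bp Intron flank distance in bp (default the model's).
#' @param include_rule Which guide bases must touch the target space:
#'   `"window"` (editing window, default), `"protospacer"` (any base),
#'   or `"cut_site"` (position 17, the nickase site).
#' @param window Editing window used by `include_rule = "window"`.
#' @param homopolymer_filter Motif excluded from protospacers
#'   (default `"TTTT"`); `NULL` disables.
#' @return A tibble of guides with columns `guide_id`, `category`,
#'   `protospacer`, `pam`, `strand`, `start` (0-based segment position
#'   of the protospacer's 5'-most base on its own strand), sorted by
#'   `(strand, start)`.
#' @export
enumerate_guides <- function(model, pam_rule = "NG",
                             flank_bp = model$flank_bp,
                             include_rule = c("window", "protospacer",
                                              "cut_site"),
                             window = c(4L, 8L),
                             homopolymer_filter = "TTTT") {
  include_rule <- match.arg(include_rule)
  seg <- model$sequence
  seg_len <- nchar(seg)
  flank_bp <- as.integer(flank_bp)

  # target space: exon +/- flank, as a logical mask over the segment
  target <- rep(FALSE, seg_len)
  for (e in model$exons) {
    lo <- max(0L, e[1] - flank_bp)
    hi <- min(seg_len - 1L, e[2] - 1L + flank_bp)
    target[seq.int(lo, hi) + 1L] <- TRUE
  }

  include_idx <- switch(include_rule,
    window = seq.int(window[1], window[2]),
    protospacer = 1:20,
    cut_site = 17L
  )

  cand <- scan_protospacers(seg)
  inc <- vapply(seq_len(nrow(cand)), function(i) {
    pos <- guide_segment_pos(cand$start[i], cand$strand[i], include_idx)
    pos <- pos[pos >= 0L & pos < seg_len]
    length(pos) > 0L && any(target[pos + 1L])
  }, logical(1))
  out <- cand[inc, ]
  if (!is.null(homopolymer_filter) && nrow(out) > 0L) {
    out <- filter(out, !stringr::str_detect(.data$protospacer,
                                            stringr::fixed(homopolymer_filter)))
  }
  out <- arrange(out, .data$strand, .data$start)
  mutate(out,
         guide_id = sprintf("%s_sg%s%04d", model$id,
                            if_else(.data$strand == "+", "p", "m"),
                            .data$start),
         category = "targeting",
         .before = 1L)
}

#' Attach negative-control guides to a library
#'
#' Non-targeting controls are random 20-mers with no exact match (on
#' either strand) in the gene segment or the decoy segment; intergenic
#' controls are real guides enumerated on the decoy segment.
#'
#' @param guides Targeting-guide tibble from [enumerate_guides()].
#' @param model The gene model the library targets.
#' @param n_nontargeting,n_intergenic Numbers of controls to add.
#' @param decoy_segment A [gene_model()] or plain DNA string for a
#'   neutral locus; required when `n_intergenic > 0`.
#' @param seed Integer seed making control generation reproducible.
#' @return The library tibble with control rows appended.
#' @export
attach_controls <- function(guides, model, n_nontargeting = 199L,
                            n_intergenic = 50L, decoy_segment = NULL,
                            seed = 1L) {
  n_nontargeting <- as.integer(n_nontargeting)
  n_intergenic <- as.integer(n_intergenic)
  stopifnot(n_nontargeting >= 0L, n_intergenic >= 0L)
  out <- guides

  decoy_seq <- NULL
  if (!is.null(decoy_segment)) {
    decoy_seq <- if (inherits(decoy_segment, "gene_model")) {
      decoy_segment$sequence
    } else {
      check_dna(decoy_segment, "decoy_segment")
    }
  }

  if (n_intergenic > 0L) {
    if (is.null(decoy_seq)) abort("intergenic controls need a decoy_segment")
    # enumerate NG-PAM guides on the decoy; no exon constraint applies
    cand <- withr_seed(seed, {
      g <- scan_protospacers(decoy_seq)
      g <- filter(g, !stringr::str_detect(.data$protospacer, "TTTT"))
      g[sample.int(nrow(g)), ]
    })
    if (nrow(cand) < n_intergenic) {
      abort(sprintf("decoy segment yields only %d intergenic candidates",
                    nrow(cand)))
    }
    ig <- head(cand, n_intergenic)
    ig <- mutate(ig,
                 guide_id = sprintf("intergenic_%04d", seq_len(n_intergenic)),
                 category = "intergenic_control")
    out <- bind_rows(out, ig)
  }

  if (n_nontargeting > 0L) {
    haystack <- c(model$sequence, reverse_complement(model$sequence),
                  if (!is.null(decoy_seq)) {
                    c(decoy_seq, reverse_complement(decoy_seq))
                  })
    nt <- withr_seed(seed + 1L, {
      found <- character(0)
      tries <- 0L
      while (length(found) < n_nontargeting && tries < 50L) {
        tries <- tries + 1L
        cand <- vapply(seq_len(n_nontargeting * 2L), function(i) {
          paste(sample(VALID_BASES, 20L, replace = TRUE), collapse = "")
        }, character(1))
        ok <- !vapply(cand, function(p) {
          any(stringr::str_detect(haystack, stringr::fixed(p)))
        }, logical(1)) & !stringr::str_detect(cand, "TTTT")
        found <- unique(c(found, cand[ok]))
      }
      if (length(found) < n_nontargeting) {
        abort("could not generate enough non-matching non-targeting controls")
      }
      head(found, n_nontargeting)
    })
    out <- bind_rows(out, tibble(
      guide_id = sprintf("nontargeting_%04d", seq_len(n_nontargeting)),
      category = "nontargeting_control",
      protospacer = nt, pam = NA_character_,
      strand = NA_character_, start = NA_integer_
    ))
  }
  out
}

# evaluate `expr` under a temporary RNG state restored on exit
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Residue coverage of an annotated library
#'
#' A residue is covered iff at least one guide (under any editor)
#' predicts a missense or nonsense change at that residue.
#'
#' @param annotated Library tibble annotated by [annotate_library()]
#'   (needs `outcome_class` and `codon_changes`).
#' @param L Protein length in residues.
#' @return A one-row tibble: `covered_count`, `total`, `percent`
#'   (one decimal), plus the covered residue set as a list-column.
#' @examples
#' # formatting matches figure-caption style: 460/534 -> 86.1
#' @export
residue_coverage <- function(annotated, L) {
  if (!all(c("outcome_class", "codon_changes") %in% names(annotated))) {
    abort("library lacks outcome annotations; run annotate_library() first")
  }
  cons <- filter(annotated,
                 .data$outcome_class %in% c("missense", "nonsense"))
  residues <- sort(unique(unlist(lapply(cons$codon_changes, function(ch) {
    if (is.null(ch) || length(ch) == 0L) return(integer(0))
    as.integer(stringr::str_match(ch, "^[A-Z*](\\d+)[A-Z*]$")[, 2])
  }))))
  residues <- residues[residues >= 1L & residues <= L]
  tibble(
    covered_count = length(residues),
    total = as.integer(L),
    percent = round(100 * length(residues) / L, 1),
    covered_residues = list(residues)
  )
}
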
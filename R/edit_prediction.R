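# Deterministic base-editing outcome prediction: every editable base in
# the protospacer window is converted simultaneously, the edited CDS is
# retranslated, and each guide is assigned one of six mutually exclusive
# classes in fixed priority order:
# nonsense > missense > silent > utr_intronic > non_editing; control
# guides are negative_control.

OUTCOME_CLASSES <- c("nonsense", "missense", "silent", "utr_intronic",
                     "non_editing", "negative_control")

#' Predict the edited sites of a guide
#'
#' Applies the editor's conversion to every matching base within the
#' editing window (protospacer positions counted 1-based from the 5'
#' end). For minus-strand guides the substitution reported on the
#' segment (coding-strand frame of reference for a plus-strand gene) is
#' the complement: CBE gives G->A, ABE gives T->C.
#'
#' @param guide One row of a guide tibble (or a list) with
#'   `protospacer`, `strand`, `start`.
#' @param model A [gene_model()].
#' @param spec An [editor_spec()].
#' @return Tibble of edited sites: `segment_pos`, `ref` and `alt` on the
#'   segment's forward strand, joined with [map_position()] columns.
#' @export
predict_edits <- function(guide, model, spec) {
  seg_len <- nchar(model$sequence)
  idx <- seq.int(spec$window[1], spec$window[2])
  pos <- guide_segment_pos(guide$start, guide$strand, idx)
  if (any(pos < 0L | pos >= seg_len)) {
    abort("guide editing window falls off the segment")
  }
  proto_base <- substring(guide$protospacer, idx, idx)
  hit <- proto_base == spec$ref_base
  pos <- pos[hit]
  if (length(pos) == 0L) {
    return(tibble(segment_pos = integer(0), ref = character(0),
                  alt = character(0), region = character(0),
                  codon_index = integer(0), codon_offset = integer(0)))
  }
  if (guide$strand == "+") {
    ref <- spec$ref_base
    alt <- spec$alt_base
  } else {
    ref <- complement_base(spec$ref_base)
    alt <- complement_base(spec$alt_base)
  }
  sites <- tibble(segment_pos = pos, ref = ref, alt = alt)
  dplyr::bind_cols(sites, select(map_position(model, pos), -"segment_pos"))
}

apply_edits_to_cds <- function(model, edits) {
  cds <- strsplit(model$cds_seq, "")[[1]]
  # segment position -> CDS index (1-based, coding order)
  hit <- match(edits$segment_pos, model$cds_segment_pos)
  in_cds <- !is.na(hit)
  if (any(in_cds)) {
    # edits are stated on the segment forward strand; CDS bases are on
    # the coding strand
    alt <- edits$alt[in_cds]
    if (model$strand == "-") alt <- complement_base(alt)
    cds[hit[in_cds]] <- alt
  }
  paste(cds, collapse = "")
}

#' Classify a guide's predicted editing outcome
#'
#' Retranslates the edited CDS and assigns exactly one outcome class
#' with priority nonsense > missense > silent > utr_intronic >
#' non_editing (controls are classified `negative_control` without
#' prediction). A new premature stop is nonsense; any amino-acid change
#' (including a changed start or terminal codon) is missense; edited
#' CDS bases with no protein change are silent; edits landing only in
#' UTR or intron flank are utr_intronic; a window with no editable base
#' is non_editing.
#'
#' @inheritParams predict_edits
#' @return A one-row tibble: `outcome_class`, `codon_changes`
#'   (list-column of `"E203G"`-style tokens; stop is `*`),
#'   `representative_residue`, `n_edited_sites`.
#' @export
classify_outcome <- function(guide, model, spec,
                             representative = c("mean", "first")) {
  representative <- match.arg(representative)
  if (!is.null(guide$category) && guide$category != "targeting") {
    return(tibble(outcome_class = "negative_control",
                  codon_changes = list(character(0)),
                  representative_residue = NA_integer_,
                  n_edited_sites = 0L))
  }
  edits <- predict_edits(guide, model, spec)
  if (nrow(edits) == 0L) {
    return(tibble(outcome_class = "non_editing",
                  codon_changes = list(character(0)),
                  representative_residue = NA_integer_,
                  n_edited_sites = 0L))
  }
  cds_edits <- filter(edits, .data$region == "CDS")
  if (nrow(cds_edits) > 0L) {
    aa_ref <- strsplit(translate_cds(model$cds_seq, permissive = TRUE),
                       "")[[1]]
    aa_alt <- strsplit(
      translate_cds(apply_edits_to_cds(model, cds_edits), permissive = TRUE),
      "")[[1]]
    changed <- which(aa_ref != aa_alt)
    tokens <- sprintf("%s%d%s", aa_ref[changed], changed, aa_alt[changed])
    new_stop <- aa_alt[changed] == "*" & aa_ref[changed] != "*"
    cls <- if (any(new_stop)) {
      "nonsense"
    } else if (length(changed) > 0L) {
      "missense"
    } else {
      "silent"
    }
    rep_res <- if (length(changed) == 0L) {
      NA_integer_
    } else if (representative == "first") {
      as.integer(changed[1])
    } else {
      round_half_away(mean(changed))
    }
    return(tibble(outcome_class = cls, codon_changes = list(tokens),
                  representative_residue = rep_res,
                  n_edited_sites = nrow(edits)))
  }
  # edits exist but none in the CDS
  tibble(outcome_class = "utr_intronic",
         codon_changes = list(character(0)),
         representative_residue = NA_integer_,
         n_edited_sites = nrow(edits))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Annotate a guide library with editing outcomes
#'
#' Crosses targeting guides with the requested editors and attaches the
#' predicted outcome class, codon changes and representative residue;
#' control guides are carried once per editor with class
#' `negative_control`.
#'
#' @param library Guide tibble from [enumerate_guides()] /
#'   [attach_controls()].
#' @param model A [gene_model()].
#' @param editors Character vector among `"CBE"`, `"ABE"`.
#' @param window Editing window passed to [editor_spec()].
#' @param representative Rule for the guide's residue assignment:
#'   `"mean"` (arithmetic mean of altered residues, half away from
#'   zero) or `"first"`.
#' @return The library tibble with one row per guide x editor and added
#'   columns `editor`, `outcome_class`, `codon_changes`,
#'   `representative_residue`, `n_edited_sites`.
#' @export
annotate_library <- function(library, model, editors = c("CBE", "ABE"),
                             window = c(4L, 8L),
                             representative = c("mean", "first")) {
  representative <- match.arg(representative)
  stopifnot(all(editors %in% c("CBE", "ABE")))
  purrr::map_dfr(editors, function(ed) {
    spec <- editor_spec(ed, window)
    ann <- purrr::map_dfr(seq_len(nrow(library)), function(i) {
      classify_outcome(as.list(library[i, ]), model, spec,
                       representative = representative)
    })
    dplyr::bind_cols(mutate(library, editor = ed, .after = "category"), ann)
  })
}

#' Format codon-change tokens for flat-file output
#' @param codon_changes List-column of character vectors.
#' @return Semicolon-joined strings (empty string when no change).
#' @export
format_codon_changes <- function(codon_changes) {
  vapply(codon_changes, paste, character(1), collapse = ";")
}

parse_codon_changes <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";")[[1]]
  })
}
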
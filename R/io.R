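# Flat-file interchange. Everything is TSV (tab, LF, UTF-8, header
# row, '.' decimal) with floats canonically formatted as %.9g so that
# writer/reader pairs round-trip bit-stably; gene models travel as
# FASTA + a small JSON sidecar.

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.9g", x))
}

write_tsv_canonical <- function(x, path) {
  out <- mutate(x, across(dplyr::where(is.double), fmt_num))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write / load a gene model (FASTA + JSON sidecar)
#'
#' The segment goes to FASTA; structure goes to a JSON sidecar
#' `{id, strand, exons: [[start, end], ...], cds: [tx_start, tx_end],
#' flank_bp}` with 0-based half-open coordinates.
#'
#' @param model A [gene_model()].
#' @param fasta_path,json_path Output/input paths.
#' @return `load_gene_model()` returns a validated [gene_model()];
#'   `write_gene_model()` returns the paths invisibly.
#' @export
write_gene_model <- function(model, fasta_path, json_path) {
  seqs <- Biostrings::DNAStringSet(setNames(model$sequence, model$id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  jsonlite::write_json(
    list(id = model$id, strand = model$strand,
         exons = lapply(model$exons, as.integer),
         cds = as.integer(model$cds),
         flank_bp = model$flank_bp),
    json_path, auto_unbox = TRUE
  )
  invisible(c(fasta = fasta_path, json = json_path))
}

#' @rdname write_gene_model
#' @export
load_gene_model <- function(fasta_path, json_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    abort(sprintf("expected exactly 1 FASTA record, found %d",
                  length(seqs)))
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  req <- c("id", "strand", "exons", "cds")
  if (!all(req %in% names(meta))) {
    abort(sprintf("gene model JSON lacks field(s): %s",
                  paste(setdiff(req, names(meta)), collapse = ", ")))
  }
  exons <- if (is.matrix(meta$exons)) {
    asplit(meta$exons, 1)
  } else {
    meta$exons
  }
  gene_model(toupper(as.character(seqs[[1]])), exons = exons,
             strand = meta$strand, cds = meta$cds, id = meta$id,
             flank_bp = if (!is.null(meta$flank_bp)) meta$flank_bp else 30L)
}

#' Read exon intervals from a minimal 4-column BED file
#'
#' Columns: chrom, start, end, name; 0-based half-open as in the
#' model's segment coordinates.
#'
#' @param path BED file path.
#' @return A list of `c(start, end)` exon intervals, sorted.
#' @export
read_exons_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end",
                                             "name"),
                         col_types = "ciic", progress = FALSE)
  bed <- arrange(bed, .data$start)
  lapply(seq_len(nrow(bed)), function(i) c(bed$start[i], bed$end[i]))
}

#' Write / read a guide library TSV
#'
#' Columns: `guide_id, category, protospacer, pam, strand, start`
#' plus, for annotated libraries, `editor, outcome_class,
#' codon_changes` (semicolon-joined tokens) and
#' `representative_residue`. Editor is empty for control guides in
#' unannotated libraries.
#'
#' @param library Library tibble.
#' @param path File path.
#' @return `read_library_tsv()` returns the library tibble with
#'   `codon_changes` re-expanded to a list-column when present.
#' @export
write_library_tsv <- function(library, path) {
  out <- library
  if ("codon_changes" %in% names(out)) {
    out$codon_changes <- format_codon_changes(out$codon_changes)
  }
  out <- select(out, -dplyr::any_of("covered_residues"))
  write_tsv_canonical(out, path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path) {
  lib <- readr::read_tsv(path, progress = FALSE,
                         col_types = readr::cols(
                           guide_id = "c", category = "c",
                           protospacer = "c", pam = "c", strand = "c",
                           start = "i", .default = readr::col_guess()))
  if ("codon_changes" %in% names(lib)) {
    lib$codon_changes <- parse_codon_changes(lib$codon_changes)
  }
  if ("representative_residue" %in% names(lib)) {
    lib$representative_residue <- as.integer(lib$representative_residue)
  }
  lib
}

#' Read an sgRNA count matrix with its sample sheet
#'
#' Counts TSV: `guide_id` plus one integer column per sample. Sample
#' sheet TSV: `sample_id, role, replicate, condition`. Counts are
#' integer-checked; duplicate guides, unknown roles, missing sample
#' columns and a missing plasmid sample are rejected.
#'
#' @param counts_path,sample_sheet_path File paths.
#' @return List with `counts` and `sample_sheet` tibbles.
#' @export
read_counts <- function(counts_path, sample_sheet_path) {
  sheet <- readr::read_tsv(sample_sheet_path, progress = FALSE,
                           col_types = readr::cols(
                             sample_id = "c", role = "c",
                             .default = readr::col_guess()))
  validate_sample_sheet(sheet)
  counts <- readr::read_tsv(counts_path, progress = FALSE,
                            col_types = readr::cols(guide_id = "c",
                                                    .default = "d"))
  if (anyDuplicated(counts$guide_id)) {
    abort(sprintf("duplicate guide_id in counts: %s",
                  counts$guide_id[duplicated(counts$guide_id)][1]))
  }
  missing <- setdiff(sheet$sample_id, names(counts))
  if (length(missing) > 0L) {
    abort(sprintf("counts file lacks sample column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (s in sheet$sample_id) {
    v <- counts[[s]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L) {
      abort(sprintf(
        "non-integer or negative count at row %d, column %s",
        bad[1], s))
    }
    counts[[s]] <- as.integer(v)
  }
  list(counts = counts[, c("guide_id", sheet$sample_id)],
       sample_sheet = sheet)
}

#' @rdname read_counts
#' @param counts,sample_sheet Tibbles to write.
#' @export
write_counts <- function(counts, sample_sheet, counts_path,
                         sample_sheet_path) {
  write_tsv_canonical(counts, counts_path)
  write_tsv_canonical(sample_sheet, sample_sheet_path)
  invisible(c(counts = counts_path, sample_sheet = sample_sheet_path))
}

#' Write a scored-guides TSV
#'
#' Columns: `guide_id, category, editor, outcome_class,
#' representative_residue, score, hit_flag, excluded_zero_plasmid`.
#'
#' @param scored Scored tibble from [score_screen()] / [call_hits()].
#' @param path File path.
#' @export
write_scores_tsv <- function(scored, path) {
  cols <- intersect(c("guide_id", "category", "editor", "outcome_class",
                      "representative_residue", "score", "hit_flag",
                      "excluded_zero_plasmid", "condition"),
                    names(scored))
  write_tsv_canonical(select(scored, dplyr::all_of(cols)), path)
}

#' @rdname write_scores_tsv
#' @export
read_scores_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", category = "c",
                    representative_residue = "i", score = "d",
                    .default = readr::col_guess()))
}

#' Write a residue track and its clusters
#'
#' Track TSV columns: `residue, n_sgrnas, loess_score, interpolated,
#' p_emp, p_adj, neglog10_padj, in_cluster`. Cluster TSV columns:
#' `gene, start_res, end_res, width, min_p_adj`.
#'
#' @param track A `residue_track` from [residue_clustering()].
#' @param track_path,clusters_path File paths (`clusters_path`
#'   optional).
#' @param gene Gene label written into the cluster table.
#' @export
write_track_tsv <- function(track, track_path, clusters_path = NULL,
                            gene = "gene") {
  write_tsv_canonical(as_tibble(track), track_path)
  if (!is.null(clusters_path)) {
    cl <- mutate(clusters(track), gene = gene, .before = 1L)
    write_tsv_canonical(cl, clusters_path)
  }
  invisible(track_path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(track_path) {
  readr::read_tsv(track_path, progress = FALSE,
                  col_types = readr::cols(
                    residue = "i", n_sgrnas = "i", interpolated = "l",
                    in_cluster = "l", .default = "d"))
}

#' Read a titration table
#'
#' TSV with columns `dose`, `response` and optionally `replicate`,
#' `I520`, `I490`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_titration_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE,
                  col_types = readr::cols(.default = "d"))
}

#' Write an assay fit as JSON
#'
#' Parameters, standard errors, residual norm and convergence flag.
#'
#' @param fit An `assay_fit` object.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  td <- tidy(fit)
  gl <- glance(fit)
  jsonlite::write_json(
    list(model = fit$model,
         parameters = setNames(as.list(td$estimate), td$term),
         std_errors = setNames(as.list(td$std.error), td$term),
         residual_norm = sqrt(gl$rss),
         converged = gl$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
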
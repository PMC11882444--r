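# End-to-end convenience: simulate -> design -> annotate -> score ->
# cluster, with every intermediate written to flat files. This is the
# package's single-call interface for a whole screen analysis.

#' Run a full screen analysis pipeline
#'
#' Chains the pipeline stages on either a simulated dataset (default)
#' or user-supplied inputs, writing each interchange file into
#' `out_dir`: gene FASTA + model JSON, library TSV, counts + sample
#' sheet TSVs, scores TSV, residue track and cluster TSVs, and a truth
#' JSON when simulating.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [sim_config()] controlling the simulated dataset.
#' @param editor Editor arm to simulate and score.
#' @param n_perm Permutations for the clustering stage (default 1000
#'   here; raise for production use).
#' @param control_category Control set for hit calling.
#' @param alpha FDR level for cluster calling.
#' @return Invisibly, a list with the in-memory results: `model`,
#'   `library`, `scored`, `track`, `clusters`, `recovery`, `paths`.
#' @export
run_screen_pipeline <- function(out_dir, config = sim_config(),
                                editor = "ABE", n_perm = 1000L,
                                control_category = "intergenic_control",
                                alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)

  ds <- simulate_screen_dataset(config, editor = editor)
  write_gene_model(ds$model, p("gene.fasta"), p("gene_model.json"))
  write_library_tsv(ds$library, p("library.tsv"))
  write_counts(ds$counts, ds$sample_sheet, p("counts.tsv"),
               p("sample_sheet.tsv"))
  jsonlite::write_json(
    list(hotspot_residues = ds$hotspot_residues,
         beta = setNames(as.list(ds$truth$beta), ds$truth$guide_id)),
    p("truth.json"), auto_unbox = TRUE
  )

  scored <- score_screen(ds$counts, ds$sample_sheet, ds$library,
                         control_category = control_category)
  write_scores_tsv(scored, p("scores.tsv"))

  cc <- clustering_config(n_perm = n_perm, alpha = alpha,
                          seed = config$seed)
  track <- residue_clustering(scored, ds$model$L, cc)
  write_track_tsv(track, p("residue_track.tsv"), p("clusters.tsv"),
                  gene = ds$model$id)
  recovery <- evaluate_recovery(clusters(track), ds$hotspot_residues,
                                ds$model$L)

  invisible(list(
    model = ds$model, library = ds$library, scored = scored,
    track = track, clusters = clusters(track), recovery = recovery,
    paths = p(c("gene.fasta", "gene_model.json", "library.tsv",
                "counts.tsv", "sample_sheet.tsv", "truth.json",
                "scores.tsv", "residue_track.tsv", "clusters.tsv"))
  ))
}
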
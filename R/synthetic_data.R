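# Synthetic base-editor screens with known ground truth. The generator
# mirrors the screen design the pipeline targets: a tiled sgRNA library
# on a simulated coding gene, one plasmid sample, three unsorted and
# three sorted (GFP+) replicate samples, non-targeting and intergenic
# controls, negative-binomial counts, and planted residue hotspots
# acting multiplicatively (in log2 units) on sorting probability.

#' Simulation configuration
#'
#' Defaults reflect the emulated screen design: 3 replicates, 199
#' non-targeting and 50 intergenic controls, a mean sequencing depth of
#' 500 reads per guide, moderate library skew (sigma_lib = 0.5 on the
#' log scale), mild overdispersion (phi = 0.05) and a hotspot effect of
#' 2 log2 units.
#'
#' @param L Protein length in residues (default 400).
#' @param hotspots List of `c(start, end)` 1-based inclusive residue
#'   intervals carrying the planted effect (default one 15-residue
#'   hotspot in the middle of the protein).
#' @param delta Planted effect size in log2 units (default 2).
#' @param sigma_lib Log-scale s.d. of plasmid library abundances
#'   (default 0.5).
#' @param phi Negative-binomial dispersion: variance = mu + phi mu^2
#'   (default 0.05; 0 gives Poisson).
#' @param depth Mean reads per guide per sample (default 500).
#' @param replicates Sorted/unsorted replicate count (default 3).
#' @param n_nontargeting,n_intergenic Control counts (defaults 199, 50).
#' @param n_exons Exon count of the simulated gene (default 2, which
#'   exercises the UTR-intronic class).
#' @param e3_mode If `TRUE`, nonsense guides anywhere in the gene also
#'   receive `delta` (loss of function of an E3 blocks reporter
#'   degradation regardless of position); default `FALSE`.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(L = 400L, hotspots = NULL, delta = 2,
                       sigma_lib = 0.5, phi = 0.05, depth = 500,
                       replicates = 3L, n_nontargeting = 199L,
                       n_intergenic = 50L, n_exons = 2L,
                       e3_mode = FALSE, seed = 1L) {
  if (is.null(hotspots)) {
    mid <- as.integer(L / 2)
    hotspots <- list(c(mid - 7L, mid + 7L))
  }
  if (is.numeric(hotspots)) hotspots <- list(hotspots)
  for (h in hotspots) {
    stopifnot(length(h) == 2L, h[1] >= 1L, h[2] <= L, h[1] <= h[2])
  }
  stopifnot(is.finite(delta), phi > 0 || phi == 0, depth > 0,
            replicates >= 1L, L >= 20L)
  structure(list(L = as.integer(L), hotspots = hotspots, delta = delta,
                 sigma_lib = sigma_lib, phi = phi, depth = depth,
                 replicates = as.integer(replicates),
                 n_nontargeting = as.integer(n_nontargeting),
                 n_intergenic = as.integer(n_intergenic),
                 n_exons = as.integer(n_exons), e3_mode = e3_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a coding gene model
#'
#' Random sense codons (ATG start, no internal stop, terminal stop),
#' optionally split across exons with intervening introns, flanked by
#' short UTRs, on a plus-strand segment.
#'
#' @param L Protein length in residues.
#' @param n_exons Number of exons (introns of 60 bp inserted between).
#' @param seed Integer seed.
#' @param utr_bp UTR length on each side (default 25 bp).
#' @param id Gene identifier.
#' @return A [gene_model()].
#' @export
simulate_gene <- function(L = 400L, n_exons = 2L, seed = 1L,
                          utr_bp = 25L, id = "simgene") {
  stopifnot(L >= 20L, n_exons >= 1L)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  withr_seed(seed, {
    codons <- c("ATG", sample(sense, L - 1L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    cds <- paste(codons, collapse = "")
    utr5 <- paste(sample(VALID_BASES, utr_bp, TRUE), collapse = "")
    utr3 <- paste(sample(VALID_BASES, utr_bp, TRUE), collapse = "")
    tx <- paste0(utr5, cds, utr3)
    tx_len <- nchar(tx)
    # split the transcript near-evenly into exons, 60-bp introns between
    cuts <- if (n_exons > 1L) {
      sort(sample(seq(40L, tx_len - 40L),  n_exons - 1L))
    } else {
      integer(0)
    }
    bounds <- c(0L, cuts, tx_len)
    intron <- function() paste(sample(VALID_BASES, 60L, TRUE), collapse = "")
    seg <- ""
    exons <- list()
    for (i in seq_len(n_exons)) {
      piece <- substr(tx, bounds[i] + 1L, bounds[i + 1L])
      if (i > 1L) seg <- paste0(seg, intron())
      exons[[i]] <- c(nchar(seg), nchar(seg) + nchar(piece))
      seg <- paste0(seg, piece)
    }
    gene_model(seg, exons = exons, strand = "+",
               cds = c(utr_bp, utr_bp + nchar(cds)), id = id)
  })
}

# per-guide true effect: delta iff a missense/nonsense-altered residue
# intersects a hotspot (nonsense anywhere if e3_mode)
guide_truth <- function(annotated, config) {
  hot <- unlist(lapply(config$hotspots, function(h) seq.int(h[1], h[2])))
  beta <- vapply(seq_len(nrow(annotated)), function(i) {
    cls <- annotated$outcome_class[i]
    if (!cls %in% c("missense", "nonsense")) return(0)
    res <- as.integer(
      stringr::str_match(annotated$codon_changes[[i]],
                         "^[A-Z*](\\d+)[A-Z*]$")[, 2])
    if (config$e3_mode && cls == "nonsense") return(config$delta)
    if (any(res %in% hot)) config$delta else 0
  }, numeric(1))
  beta
}

rnbinom_mu <- function(n, mu, phi) {
  if (phi <= 0) return(stats::rpois(n, mu))
  rnbinom(n, size = 1 / phi, mu = mu)
}

#' Simulate a pooled sorted screen from an annotated library
#'
#' Generative model: plasmid proportions `p_g` proportional to
#' `exp(Normal(0, sigma_lib^2))`; unsorted samples share the plasmid
#' proportions; sorted proportions are proportional to
#' `p_g * 2^beta_g`, where `beta_g = delta` for guides whose predicted
#' missense/nonsense residues intersect a hotspot and 0 otherwise
#' (controls 0). Counts are negative binomial with
#' `mean = depth * n_guides * proportion` and
#' `variance = mean + phi * mean^2`.
#'
#' @param annotated Annotated library (one editor's rows) from
#'   [annotate_library()] / [attach_controls()].
#' @param config A [sim_config()].
#' @return A list: `counts` (wide tibble), `sample_sheet`, `truth`
#'   (per-guide tibble with `beta`), `hotspot_residues`.
#' @export
simulate_screen <- function(annotated, config = sim_config()) {
  if (nrow(annotated) == 0L) abort("empty library")
  G <- nrow(annotated)
  beta <- guide_truth(annotated, config)
  withr_seed(config$seed + 1000L, {
    p <- exp(rnorm(G, 0, config$sigma_lib))
    p <- p / sum(p)
    p_sorted <- p * 2^beta
    p_sorted <- p_sorted / sum(p_sorted)
    total <- config$depth * G

    samples <- tibble(
      sample_id = c("plasmid",
                    paste0("unsorted_r", seq_len(config$replicates)),
                    paste0("sorted_r", seq_len(config$replicates))),
      role = c("plasmid", rep("unsorted", config$replicates),
               rep("sorted", config$replicates)),
      replicate = c(NA_integer_, seq_len(config$replicates),
                    seq_len(config$replicates)),
      condition = "screen"
    )
    counts <- tibble(guide_id = annotated$guide_id)
    for (i in seq_len(nrow(samples))) {
      prop <- if (samples$role[i] == "sorted") p_sorted else p
      counts[[samples$sample_id[i]]] <-
        rnbinom_mu(G, mu = total * prop, phi = config$phi)
    }
  })
  truth <- tibble(guide_id = annotated$guide_id,
                  category = annotated$category,
                  outcome_class = annotated$outcome_class,
                  beta = beta)
  list(counts = counts, sample_sheet = samples, truth = truth,
       hotspot_residues = sort(unique(unlist(
         lapply(config$hotspots, function(h) seq.int(h[1], h[2]))))))
}

#' Hotspot recovery metrics
#'
#' Compares called clusters with the planted hotspot residues:
#' sensitivity is the fraction of hotspot residues inside clusters,
#' residue FPR the fraction of non-hotspot residues inside clusters.
#'
#' @param clusters Cluster tibble from [residue_clustering()] /
#'   [call_clusters()].
#' @param hotspot_residues Integer vector of planted residues.
#' @param L Protein length.
#' @return One-row tibble: `sensitivity`, `residue_fpr`,
#'   `n_cluster_residues`.
#' @export
evaluate_recovery <- function(clusters, hotspot_residues, L) {
  called <- if (nrow(clusters) == 0L) {
    integer(0)
  } else {
    sort(unique(unlist(purrr::map2(clusters$start_res, clusters$end_res,
                                   seq.int))))
  }
  H <- unique(hotspot_residues)
  tibble(
    sensitivity = if (length(H) == 0L) NA_real_ else {
      length(intersect(called, H)) / length(H)
    },
    residue_fpr = length(setdiff(called, H)) / (L - length(H)),
    n_cluster_residues = length(called)
  )
}

#' Simulate a full screen dataset from scratch
#'
#' Convenience generator chaining [simulate_gene()],
#' [enumerate_guides()], [attach_controls()], [annotate_library()] and
#' [simulate_screen()] for one editor.
#'
#' @param config A [sim_config()].
#' @param editor `"ABE"` (default) or `"CBE"`.
#' @return A list with `model`, `library` (annotated), `counts`,
#'   `sample_sheet`, `truth`, `hotspot_residues`.
#' @export
simulate_screen_dataset <- function(config = sim_config(),
                                    editor = "ABE") {
  model <- simulate_gene(config$L, n_exons = config$n_exons,
                         seed = config$seed)
  guides <- enumerate_guides(model)
  decoy <- withr_seed(config$seed + 2000L, {
    paste(sample(VALID_BASES, 2000L, TRUE), collapse = "")
  })
  lib <- attach_controls(guides, model,
                         n_nontargeting = config$n_nontargeting,
                         n_intergenic = config$n_intergenic,
                         decoy_segment = decoy,
                         seed = config$seed + 3000L)
  ann <- annotate_library(lib, model, editors = editor)
  screen <- simulate_screen(ann, config)
  c(list(model = model, library = ann), screen)
}
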
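# Linear clustering of per-residue enrichment. Missense sgRNA scores,
# placed at their representative residues, are smoothed by LOESS with a
# span equal to a 20-amino-acid fraction of the data (frac = 20/L,
# local linear, tricube weights, no robustifying iterations), the
# smooth is carried to every residue 1..L by quadratic spline
# interpolation, and significance is assessed against a permutation
# null that shuffles scores over the fixed residue positions. Empirical
# p-values use the add-one estimator and are BH-adjusted across all L
# residues; clusters are maximal runs of adjusted p <= alpha.

#' Clustering configuration
#'
#' @param window_aa Sliding-window size in residues used to set the
#'   LOESS span fraction `window_aa / L` (default 20).
#' @param n_perm Number of permutations for the null (default 10000).
#' @param alpha FDR level for cluster calling (default 0.05).
#' @param plot_pseudocount Pseudocount added to adjusted p before the
#'   -log10 plotting transform (default 1e-4).
#' @param seed Integer seed for the permutation shuffle.
#' @param robustness_iterations LOESS robustifying iterations
#'   (default 0, i.e. a single weighted fit).
#' @return A list of class `clustering_config`.
#' @export
clustering_config <- function(window_aa = 20L, n_perm = 10000L,
                              alpha = 0.05, plot_pseudocount = 1e-4,
                              seed = 1L, robustness_iterations = 0L) {
  stopifnot(window_aa >= 2L, n_perm >= 1L, alpha > 0, alpha < 1)
  structure(list(window_aa = as.integer(window_aa),
                 n_perm = as.integer(n_perm), alpha = alpha,
                 plot_pseudocount = plot_pseudocount,
                 seed = as.integer(seed),
                 robustness_iterations = as.integer(robustness_iterations)),
            class = "clustering_config")
}

#' Extract clustering inputs from a scored library
#'
#' Keeps only missense sgRNAs with a usable score and a representative
#' residue inside `1..L`; duplicate guides at a residue are retained as
#' separate points.
#'
#' @param scored Scored library tibble (from [score_screen()] or
#'   [enrichment_scores()]).
#' @param L Protein length; defaults to no upper filter when `NULL`.
#' @return Tibble with `position`, `score`.
#' @export
residue_inputs <- function(scored, L = NULL) {
  out <- scored |>
    filter(.data$outcome_class == "missense",
           !is.na(.data$score),
           !is.na(.data$representative_residue)) |>
    select(position = "representative_residue", score = "score")
  if (!is.null(L)) {
    out <- filter(out, .data$position >= 1L, .data$position <= L)
  }
  if (nrow(out) == 0L) abort("no missense sgRNAs with scores")
  out
}

# quadratic interpolating B-spline through strictly increasing (x, y):
# boundary knots tripled, interior knots at midpoints of consecutive
# sites dropping the first and last midpoint. Returns a prediction
# machine reusable across many y vectors on the same x (the solve is
# precomputed, which the permutation loop relies on).
qspline_machine <- function(x, eval_at) {
  n <- length(x)
  stopifnot(n >= 3L, !is.unsorted(x, strictly = TRUE))
  mid <- (x[-1] + x[-n]) / 2
  knots <- c(rep(x[1], 3L), if (n > 3L) mid[-c(1L, n - 1L)], rep(x[n], 3L))
  B <- splines::splineDesign(knots, x, ord = 3L)
  lu <- qr(B)
  inside <- eval_at >= x[1] & eval_at <= x[n]
  Bi <- splines::splineDesign(knots, eval_at[inside], ord = 3L)
  # residues left of the first / right of the last observed position
  # take the nearest fitted value (quadratic extrapolation diverges)
  function(y) {
    coefs <- qr.coef(lu, y)
    out <- numeric(length(eval_at))
    out[inside] <- drop(Bi %*% coefs)
    out[eval_at < x[1]] <- y[1]
    out[eval_at > x[n]] <- y[n]
    out
  }
}

# LOESS fit at the observed points, duplicate positions averaged;
# returns unique positions and their fitted values
lowess_at_unique <- function(positions, scores, frac, iter = 0L) {
  fit <- lowess(positions, scores, f = frac, iter = iter, delta = 0)
  # lowess sorts by x; average fitted values at duplicated positions
  agg <- rowsum(fit$y, group = fit$x, reorder = TRUE)
  cnt <- rowsum(rep(1, length(fit$x)), group = fit$x, reorder = TRUE)
  list(x = as.numeric(rownames(agg)), y = drop(agg / cnt))
}

#' LOESS-smoothed per-residue score track
#'
#' Fits a locally weighted linear regression (tricube weights, span
#' fraction `window_aa / L` of the data points, no robustifying
#' iterations) of score on residue position, averages fitted values at
#' duplicated positions, and interpolates to every residue `1..L` with
#' a quadratic spline; residues outside the observed range are clamped
#' to the nearest fitted value.
#'
#' @param positions Integer residue positions (1..L), one per sgRNA.
#' @param scores Enrichment scores, same length.
#' @param L Protein length in residues.
#' @param config A [clustering_config()].
#' @return Tibble `residue`, `n_sgrnas`, `loess_score`, `interpolated`.
#' @export
loess_interpolate <- function(positions, scores, L,
                              config = clustering_config()) {
  stopifnot(length(positions) == length(scores))
  if (any(positions < 1 | positions > L)) {
    abort("positions must lie within 1..L")
  }
  frac <- min(1, config$window_aa / L)
  if (length(unique(positions)) < 3L) {
    abort("need at least 3 distinct residue positions for the local fit")
  }
  sm <- lowess_at_unique(positions, scores, frac,
                         iter = config$robustness_iterations)
  predict_track <- qspline_machine(sm$x, seq_len(L))
  n_sg <- tabulate(positions, nbins = L)
  tibble(
    residue = seq_len(L),
    n_sgrnas = n_sg,
    loess_score = predict_track(sm$y),
    interpolated = n_sg == 0L
  )
}

# internal fast path used by the permutation loop: precompute
# everything that depends on positions only
track_machine <- function(positions, scores, L, config) {
  frac <- min(1, config$window_aa / L)
  if (length(unique(positions)) < 3L) {
    abort("need at least 3 distinct residue positions for the local fit")
  }
  ord <- order(positions)
  px <- positions[ord]
  ux <- unique(px)
  spline_predict <- qspline_machine(ux, seq_len(L))
  iter <- config$robustness_iterations
  function(y) {
    fit <- lowess(px, y[ord], f = frac, iter = iter, delta = 0)
    agg <- drop(rowsum(fit$y, group = fit$x, reorder = TRUE))
    cnt <- drop(rowsum(rep(1, length(fit$x)), group = fit$x,
                       reorder = TRUE))
    spline_predict(agg / cnt)
  }
}

#' Permutation p-values for the residue track
#'
#' Keeps sgRNA residue positions fixed, shuffles the scores, and
#' recomputes the full LOESS + interpolation track for each of
#' `n_perm` permutations. The one-sided (enrichment) empirical p-value
#' at residue r is `(1 + #\{null track at r >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams loess_interpolate
#' @return The [loess_interpolate()] tibble with an added `p_emp`
#'   column.
#' @export
permutation_pvalues <- function(positions, scores, L,
                                config = clustering_config()) {
  track <- loess_interpolate(positions, scores, L, config)
  machine <- track_machine(positions, scores, L, config)
  observed <- track$loess_score
  exceed <- integer(L)
  withr_seed(config$seed, {
    for (b in seq_len(config$n_perm)) {
      perm <- machine(sample(scores))
      exceed <- exceed + (perm >= observed)
    }
  })
  mutate(track, p_emp = (1 + exceed) / (config$n_perm + 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, capped at 1 (wraps
#' [stats::p.adjust()]).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) abort("empty p-value vector")
  p.adjust(p, method = "BH")
}

#' Call contiguous residue clusters
#'
#' @param p_adj Adjusted p-values over residues 1..L.
#' @param alpha FDR level (default 0.05).
#' @return Tibble of 1-based inclusive intervals: `start_res`,
#'   `end_res`, `width`, `min_p_adj`; zero rows when nothing passes.
#' @export
call_clusters <- function(p_adj, alpha = 0.05) {
  sig <- p_adj <= alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  tibble(
    start_res = starts[keep],
    end_res = ends[keep],
    width = ends[keep] - starts[keep] + 1L,
    min_p_adj = vapply(keep, function(i) {
      min(p_adj[starts[i]:ends[i]])
    }, numeric(1))
  )
}

#' -log10 plotting transform for adjusted p-values
#'
#' @param p_adj Adjusted p-values.
#' @param pseudocount Added before the log (default 1e-4).
#' @return `-log10(p_adj + pseudocount)`.
#' @export
neglog_transform <- function(p_adj, pseudocount = 1e-4) {
  -log10(p_adj + pseudocount)
}

#' Per-residue linear clustering of a scored screen
#'
#' Runs the whole statistic: missense filtering, LOESS smoothing and
#' quadratic-spline interpolation to residues 1..L, the permutation
#' null, BH adjustment, the plotting transform and cluster calling.
#'
#' @param scored Scored library tibble (see [residue_inputs()]), or a
#'   tibble with `position`/`score` columns.
#' @param L Protein length.
#' @param config A [clustering_config()].
#' @return An object of class `residue_track`: the per-residue tibble
#'   (`residue`, `n_sgrnas`, `loess_score`, `interpolated`, `p_emp`,
#'   `p_adj`, `neglog10_padj`, `in_cluster`) with the cluster table
#'   as attribute `"clusters"` and the config as attribute `"config"`.
#' @export
residue_clustering <- function(scored, L, config = clustering_config()) {
  inputs <- if (all(c("position", "score") %in% names(scored))) {
    scored
  } else {
    residue_inputs(scored, L)
  }
  track <- permutation_pvalues(inputs$position, inputs$score, L, config)
  track <- track |>
    mutate(
      p_adj = bh_adjust(.data$p_emp),
      neglog10_padj = neglog_transform(.data$p_adj,
                                       config$plot_pseudocount)
    ) |>
    mutate(in_cluster = .data$p_adj <= config$alpha)
  clusters <- call_clusters(track$p_adj, config$alpha)
  structure(track, clusters = clusters, config = config,
            class = c("residue_track", class(track)))
}

#' Cluster table of a residue track
#' @param track A `residue_track` from [residue_clustering()].
#' @return The cluster tibble attribute.
#' @export
clusters <- function(track) {
  attr(track, "clusters")
}
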
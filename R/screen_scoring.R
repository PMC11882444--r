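# Pooled-screen enrichment scoring. The chain follows the standard
# sorted-screen recipe: reads per million -> +1 pseudocount -> log2 ->
# subtract the plasmid-library abundance -> average replicates within
# role -> sorted minus unsorted -> subtract the non-targeting-control
# mean. Guides absent from the plasmid library are excluded up front.

SAMPLE_ROLES <- c("plasmid", "unsorted", "sorted")

validate_sample_sheet <- function(sample_sheet) {
  req <- c("sample_id", "role")
  if (!all(req %in% names(sample_sheet))) {
    abort("sample sheet needs columns sample_id, role")
  }
  bad <- setdiff(unique(sample_sheet$role), SAMPLE_ROLES)
  if (length(bad) > 0L) {
    abort(sprintf("unknown sample roles: %s", paste(bad, collapse = ", ")))
  }
  if (sum(sample_sheet$role == "plasmid") != 1L) {
    abort("exactly one plasmid sample is required per screen")
  }
  invisible(sample_sheet)
}

#' Normalize sgRNA counts to log2 reads-per-million
#'
#' Computes `log2(1 + 1e6 * count / sample_total)` per guide and sample
#' and flags guides with zero counts in the plasmid library, which are
#' excluded from all downstream scoring.
#'
#' @param counts Wide tibble: `guide_id` plus one integer column per
#'   sample.
#' @param sample_sheet Tibble with `sample_id`, `role`
#'   (plasmid/unsorted/sorted), `replicate` and optionally `condition`.
#' @return A long tibble `guide_id`, `sample_id`, `count`, `log2_rpm`,
#'   `excluded_zero_plasmid`.
#' @examples
#' # a count of 1023 in a million-read sample gives log2(1 + 1023) = 10
#' @export
normalize_counts <- function(counts, sample_sheet) {
  validate_sample_sheet(sample_sheet)
  sample_ids <- sample_sheet$sample_id
  missing <- setdiff(sample_ids, names(counts))
  if (length(missing) > 0L) {
    abort(sprintf("counts lack sample columns: %s",
                  paste(missing, collapse = ", ")))
  }
  cnt <- counts[, c("guide_id", sample_ids)]
  if (anyDuplicated(cnt$guide_id)) abort("duplicate guide_id in counts")
  vals <- as.matrix(cnt[, sample_ids])
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("counts must be non-negative integers")
  }
  totals <- colSums(vals)
  if (any(totals == 0)) {
    abort(sprintf("sample(s) with zero total reads: %s",
                  paste(sample_ids[totals == 0], collapse = ", ")))
  }
  plasmid_id <- sample_sheet$sample_id[sample_sheet$role == "plasmid"]
  excluded <- cnt$guide_id[vals[, plasmid_id] == 0]

  long <- tidyr::pivot_longer(cnt, -"guide_id",
                              names_to = "sample_id", values_to = "count")
  long <- mutate(long,
    log2_rpm = log2(1 + 1e6 * .data$count /
                      unname(.env$totals[.data$sample_id])),
    excluded_zero_plasmid = .data$guide_id %in% .env$excluded
  )
  long
}

#' Compute final normalized log2 enrichment scores
#'
#' From normalized abundances: subtracts the plasmid log2 abundance
#' from every sample, averages replicates within each role, takes
#' sorted minus unsorted, and subtracts the mean over non-targeting
#' controls so their scores centre exactly at zero. With
#' `pair_replicates = TRUE` the sorted-minus-unsorted difference is
#' instead taken per replicate before averaging (identical result when
#' replicate sets match, offered because either reading of the recipe
#' is defensible).
#'
#' @param normalized Long tibble from [normalize_counts()].
#' @param sample_sheet The sample sheet used for normalization.
#' @param library Annotated library carrying `guide_id`, `category` and
#'   (optionally) `editor`, `outcome_class`, `representative_residue`.
#' @param pair_replicates Pair sorted/unsorted by replicate before
#'   averaging (default `FALSE`: average within role first).
#' @return Tibble with one row per scored guide: library annotation
#'   columns plus `score` and `excluded_zero_plasmid`. Excluded guides
#'   are carried with `score = NA`.
#' @export
enrichment_scores <- function(normalized, sample_sheet, library,
                              pair_replicates = FALSE) {
  validate_sample_sheet(sample_sheet)
  if (!"nontargeting_control" %in% library$category) {
    abort("no nontargeting controls present; cannot centre scores")
  }
  plasmid_id <- sample_sheet$sample_id[sample_sheet$role == "plasmid"]

  dat <- left_join(normalized,
                   select(sample_sheet, "sample_id", "role",
                          dplyr::any_of("replicate")),
                   by = "sample_id")
  plasmid <- dat |>
    filter(.data$role == "plasmid") |>
    select("guide_id", plasmid_log2 = "log2_rpm")
  dat <- dat |>
    filter(.data$role != "plasmid") |>
    left_join(plasmid, by = "guide_id") |>
    mutate(rel = .data$log2_rpm - .data$plasmid_log2)

  if (pair_replicates) {
    per_rep <- dat |>
      select("guide_id", "role", "replicate", "rel") |>
      tidyr::pivot_wider(names_from = "role", values_from = "rel") |>
      mutate(diff = .data$sorted - .data$unsorted)
    scores <- per_rep |>
      group_by(.data$guide_id) |>
      summarise(raw_score = mean(.data$diff), .groups = "drop")
  } else {
    role_means <- dat |>
      group_by(.data$guide_id, .data$role) |>
      summarise(rel = mean(.data$rel), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "role", values_from = "rel")
    scores <- role_means |>
      mutate(raw_score = .data$sorted - .data$unsorted) |>
      select("guide_id", "raw_score")
  }

  excluded <- normalized |>
    distinct(.data$guide_id, .data$excluded_zero_plasmid)
  out <- library |>
    left_join(excluded, by = "guide_id") |>
    left_join(scores, by = "guide_id") |>
    mutate(raw_score = if_else(.data$excluded_zero_plasmid, NA_real_,
                               .data$raw_score))
  nt_mean <- out |>
    filter(.data$category == "nontargeting_control",
           !.data$excluded_zero_plasmid) |>
    pull("raw_score") |>
    mean()
  if (!is.finite(nt_mean)) {
    abort("all nontargeting controls excluded; cannot centre scores")
  }
  out |>
    mutate(score = .data$raw_score - nt_mean) |>
    select(-"raw_score")
}

#' Call enriched and depleted guides against a control band
#'
#' Flags guides whose score lies strictly more than `k` standard
#' deviations (sample s.d., denominator n-1) above or below the mean
#' of the chosen negative-control category.
#'
#' @param scored Tibble from [enrichment_scores()].
#' @param control_category `"intergenic_control"` (default) or
#'   `"nontargeting_control"`.
#' @param k Width of the band in control standard deviations
#'   (default 4).
#' @return `scored` with a `hit_flag` column
#'   (`enriched`/`depleted`/`none`); the thresholds are attached as
#'   attribute `"thresholds"` (a one-row tibble).
#' @export
call_hits <- function(scored,
                      control_category = c("intergenic_control",
                                           "nontargeting_control"),
                      k = 4) {
  control_category <- match.arg(control_category)
  ctrl <- scored |>
    filter(.data$category == control_category, !is.na(.data$score)) |>
    pull("score")
  if (length(ctrl) < 2L) {
    abort(sprintf("need at least 2 scored guides of category %s",
                  control_category))
  }
  mu <- mean(ctrl)
  s <- sd(ctrl)
  hi <- mu + k * s
  lo <- mu - k * s
  out <- scored |>
    mutate(hit_flag = dplyr::case_when(
      is.na(.data$score) ~ NA_character_,
      .data$score > hi ~ "enriched",
      .data$score < lo ~ "depleted",
      TRUE ~ "none"
    ))
  attr(out, "thresholds") <- tibble(
    control_category = control_category, k = k,
    control_mean = mu, control_sd = s, lower = lo, upper = hi,
    n_controls = length(ctrl)
  )
  out
}

#' Score a screen end to end
#'
#' Convenience wrapper: [normalize_counts()] then
#' [enrichment_scores()] then [call_hits()]. When the sample sheet has
#' a `condition` column with several non-plasmid conditions, each is
#' scored independently against the shared plasmid sample and the
#' results are row-bound with a `condition` column.
#'
#' @inheritParams normalize_counts
#' @inheritParams enrichment_scores
#' @inheritParams call_hits
#' @return A scored tibble as from [call_hits()].
#' @export
score_screen <- function(counts, sample_sheet, library,
                         control_category = "intergenic_control", k = 4,
                         pair_replicates = FALSE) {
  has_cond <- "condition" %in% names(sample_sheet)
  conds <- if (has_cond) {
    unique(sample_sheet$condition[sample_sheet$role != "plasmid"])
  } else {
    NA_character_
  }
  res <- purrr::map(conds, function(cond) {
    sheet <- if (has_cond) {
      filter(sample_sheet,
             .data$role == "plasmid" | .data$condition == cond)
    } else {
      sample_sheet
    }
    norm <- normalize_counts(counts, sheet)
    scored <- enrichment_scores(norm, sheet, library,
                                pair_replicates = pair_replicates)
    scored <- call_hits(scored, control_category = control_category, k = k)
    if (has_cond) scored$condition <- cond
    scored
  })
  thresholds <- purrr::map_dfr(res, attr, "thresholds")
  out <- bind_rows(res)
  attr(out, "thresholds") <- thresholds
  out
}
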
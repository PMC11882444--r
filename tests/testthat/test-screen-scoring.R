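# The scoring chain is checked against completely hand-written
# arithmetic: log2(RPM + 1) -> minus plasmid -> replicate means ->
# sorted minus unsorted -> minus non-targeting mean.

mini_sheet <- function() {
  tibble::tibble(
    sample_id = c("plasmid", "uns_r1", "uns_r2", "uns_r3",
                  "srt_r1", "srt_r2", "srt_r3"),
    role = c("plasmid", rep("unsorted", 3), rep("sorted", 3)),
    replicate = c(NA, 1:3, 1:3)
  )
}

mini_library <- function(categories) {
  tibble::tibble(
    guide_id = paste0("g", seq_along(categories)),
    category = categories,
    outcome_class = ifelse(categories == "targeting", "missense",
                           "negative_control"),
    representative_residue = ifelse(categories == "targeting",
                                    seq_along(categories), NA_integer_)
  )
}

test_that("log2 RPM+1 normalization matches hand arithmetic", {
  # sample totals exactly 1e6, so RPM equals the raw count
  counts <- tibble::tibble(
    guide_id = c("g1", "g2"),
    plasmid = c(1023L, 1000000L - 1023L),
    s1 = c(1023L, 1000000L - 1023L)
  )
  sheet <- tibble::tibble(sample_id = c("plasmid", "s1"),
                          role = c("plasmid", "sorted"),
                          replicate = c(NA, 1L))
  norm <- normalize_counts(counts, sheet)
  expect_equal(norm$log2_rpm[norm$guide_id == "g1" &
                               norm$sample_id == "plasmid"], 10)
  # zero count in a non-plasmid sample -> log2(1) = 0
  counts$s1 <- c(0L, 1000000L)
  norm <- normalize_counts(counts, sheet)
  expect_equal(norm$log2_rpm[norm$guide_id == "g1" &
                               norm$sample_id == "s1"], 0)
})

test_that("guides with zero plasmid counts are excluded from scores", {
  lib <- mini_library(c("targeting", "targeting",
                        "nontargeting_control", "nontargeting_control"))
  counts <- tibble::tibble(
    guide_id = lib$guide_id,
    plasmid = c(0L, 100L, 100L, 100L),
    uns_r1 = 100L, uns_r2 = 100L, uns_r3 = 100L,
    srt_r1 = 100L, srt_r2 = 100L, srt_r3 = 100L
  )
  scored <- score_screen(counts, mini_sheet(), lib,
                         control_category = "nontargeting_control")
  expect_true(scored$excluded_zero_plasmid[1])
  expect_true(is.na(scored$score[1]))
  expect_false(any(is.na(scored$score[-1])))
})

test_that("toy screen reproduces the worked two-guide example", {
  # equal totals: plasmid and unsorted 1023 for both guides; sorted
  # doubles guide A only; B is the non-targeting control
  filler <- 1000000L - 2L * 1023L
  counts <- tibble::tibble(
    guide_id = c("A", "B", "filler"),
    plasmid = c(1023L, 1023L, filler),
    s_uns = c(1023L, 1023L, filler),
    s_srt = c(2047L, 1023L, filler - 1024L)
  )
  sheet <- tibble::tibble(sample_id = c("plasmid", "s_uns", "s_srt"),
                          role = c("plasmid", "unsorted", "sorted"),
                          replicate = c(NA, 1L, 1L))
  lib <- tibble::tibble(
    guide_id = c("A", "B", "filler"),
    category = c("targeting", "nontargeting_control", "targeting"),
    outcome_class = c("missense", "negative_control", "missense"),
    representative_residue = c(1L, NA, 2L)
  )
  scored <- enrichment_scores(normalize_counts(counts, sheet), sheet, lib)
  a <- scored$score[scored$guide_id == "A"]
  b <- scored$score[scored$guide_id == "B"]
  expect_equal(b, 0)
  expect_equal(a, log2(2048) - log2(1024), tolerance = 1e-12)
})

test_that("the full chain reproduces an independently hand-computed
           6-guide x 7-sample table to 1e-12", {
  lib <- mini_library(c("targeting", "targeting", "targeting",
                        "nontargeting_control", "nontargeting_control",
                        "intergenic_control"))
  set.seed(90)
  samples <- mini_sheet()$sample_id
  counts <- tibble::tibble(guide_id = lib$guide_id)
  for (s in samples) {
    counts[[s]] <- as.integer(sample(50:5000, 6))
  }
  scored <- score_screen(counts, mini_sheet(), lib,
                         control_category = "nontargeting_control")

  # independent arithmetic, written as plain matrix algebra
  m <- as.matrix(counts[, samples])
  logab <- log2(1 + 1e6 * sweep(m, 2, colSums(m), "/"))
  rel <- logab[, -1] - logab[, 1]
  uns <- rowMeans(rel[, 1:3])
  srt <- rowMeans(rel[, 4:6])
  raw <- srt - uns
  final <- raw - mean(raw[4:5])
  expect_equal(scored$score, final, tolerance = 1e-12)
  # non-targeting controls centre at exactly zero
  expect_equal(mean(scored$score[4:5]), 0, tolerance = 1e-14)
})

test_that("per-replicate pairing equals role-averaging for matched
           replicate sets", {
  lib <- mini_library(c("targeting", "targeting",
                        "nontargeting_control", "nontargeting_control"))
  set.seed(91)
  counts <- tibble::tibble(guide_id = lib$guide_id)
  for (s in mini_sheet()$sample_id) {
    counts[[s]] <- as.integer(sample(100:2000, 4))
  }
  norm <- normalize_counts(counts, mini_sheet())
  s1 <- enrichment_scores(norm, mini_sheet(), lib)
  s2 <- enrichment_scores(norm, mini_sheet(), lib, pair_replicates = TRUE)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("scores are invariant to per-sample sequencing depth", {
  lib <- mini_library(c("targeting", "targeting",
                        "nontargeting_control", "nontargeting_control"))
  set.seed(92)
  counts <- tibble::tibble(guide_id = lib$guide_id)
  for (s in mini_sheet()$sample_id) {
    counts[[s]] <- as.integer(sample(100:2000, 4))
  }
  scaled <- counts
  scaled$srt_r2 <- scaled$srt_r2 * 7L  # deeper sequencing of one sample
  s1 <- score_screen(counts, mini_sheet(), lib,
                     control_category = "nontargeting_control")
  s2 <- score_screen(scaled, mini_sheet(), lib,
                     control_category = "nontargeting_control")
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("hit calling uses mean +/- k sd of the chosen controls with
           strict inequality", {
  lib <- mini_library(c("targeting", "targeting", "targeting",
                        rep("intergenic_control", 3)))
  scored <- dplyr::mutate(lib,
                          score = c(4.5, -4.5, 3.9, -1, 0, 1),
                          excluded_zero_plasmid = FALSE)
  out <- call_hits(scored, control_category = "intergenic_control", k = 4)
  expect_equal(out$hit_flag[1:3], c("enriched", "depleted", "none"))
  thr <- attr(out, "thresholds")
  expect_equal(thr$control_mean, 0)
  expect_equal(thr$control_sd, 1)   # sample sd, n-1 denominator
  expect_equal(c(thr$lower, thr$upper), c(-4, 4))
})

test_that("degenerate designs are rejected with clear errors", {
  lib <- mini_library(c("targeting", "targeting"))
  counts <- tibble::tibble(guide_id = c("g1", "g2"),
                           plasmid = c(1L, 2L), s1 = c(3L, 4L))
  sheet <- tibble::tibble(sample_id = c("plasmid", "s1"),
                          role = c("plasmid", "sorted"),
                          replicate = c(NA, 1L))
  expect_error(enrichment_scores(normalize_counts(counts, sheet),
                                 sheet, lib),
               "nontargeting")
  zero <- counts; zero$s1 <- c(0L, 0L)
  expect_error(normalize_counts(zero, sheet), "zero total")
  two_plasmid <- dplyr::mutate(sheet, role = c("plasmid", "plasmid"))
  expect_error(normalize_counts(counts, two_plasmid),
               "exactly one plasmid")
  scored <- dplyr::mutate(lib, score = c(1, 2),
                          excluded_zero_plasmid = FALSE)
  expect_error(call_hits(scored), "at least 2")
})
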
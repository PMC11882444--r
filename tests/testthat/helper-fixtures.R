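# Shared fixtures and independent oracles. Oracles deliberately use a
# different implementation route from the package code they check.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# two-exon toy gene: CDS "ATGGAATACTGA" -> protein "MEY", L = 3,
# split across exons with a 9-bp intron
toy_model <- function() {
  # exon1 = 5'UTR "CC" + "ATGGA", exon2 = "ATACTGA" + 3'UTR "GG"
  seg <- paste0("TT", "CCATGGA", "AGTTCGGCA", "ATACTGAGG", "AA")
  gene_model(seg,
             exons = list(c(2L, 9L), c(18L, 27L)),
             strand = "+", cds = c(2L, 14L), id = "toy",
             flank_bp = 5L)
}

# single-exon gene around a given CDS with UTR padding; convenient for
# hand-placed guides
cds_model <- function(cds, utr5 = "GGGGG", utr3 = "CCCCC", id = "g",
                      flank_bp = 30L) {
  seg <- paste0(utr5, cds, utr3)
  gene_model(seg, exons = list(c(0L, nchar(seg))), strand = "+",
             cds = c(nchar(utr5), nchar(utr5) + nchar(cds)), id = id,
             flank_bp = flank_bp)
}

# random valid gene: L residues, single exon, via independent codon
# sampling (not simulate_gene)
random_cds <- function(L, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c("ATG", sample(sense, L - 1, replace = TRUE), "TGA"),
        collapse = "")
}

comp_base <- function(b) unname(COMP[b])

# --- brute-force guide enumeration oracle -----------------------------
# tests every 20-mer start on both strands directly in segment
# coordinates (no reverse-complement scan)
oracle_enumerate <- function(model, flank_bp = model$flank_bp,
                             window = 4:8) {
  seg <- strsplit(model$sequence, "")[[1]]
  n <- length(seg)
  in_target <- rep(FALSE, n)
  for (e in model$exons) {
    lo <- max(0, e[1] - flank_bp); hi <- min(n - 1, e[2] - 1 + flank_bp)
    in_target[(lo:hi) + 1] <- TRUE
  }
  rows <- list()
  # plus strand: 5'-most base at s (0-based), PAM at s+20, s+21
  for (s in 0:(n - 22)) {
    if (seg[s + 22] != "G") next
    proto <- paste(seg[(s + 1):(s + 20)], collapse = "")
    if (grepl("TTTT", proto, fixed = TRUE)) next
    wpos <- s + window - 1
    if (!any(in_target[wpos + 1])) next
    rows[[length(rows) + 1]] <- list(
      protospacer = proto,
      pam = paste(seg[(s + 21):(s + 22)], collapse = ""),
      strand = "+", start = s)
  }
  # minus strand: 5'-most base at t (0-based); protospacer base i sits
  # at segment position t - (i - 1), read as the complement
  for (t in 21:(n - 1)) {
    if (comp_base(seg[t - 21 + 1]) != "G") next
    proto <- paste(comp_base(seg[(t:(t - 19)) + 1]), collapse = "")
    if (grepl("TTTT", proto, fixed = TRUE)) next
    wpos <- t - (window - 1)
    if (!any(in_target[wpos + 1])) next
    rows[[length(rows) + 1]] <- list(
      protospacer = proto,
      pam = paste(comp_base(seg[((t - 20):(t - 21)) + 1]), collapse = ""),
      strand = "-", start = t)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  dplyr::arrange(out, strand, start)
}

# --- brute-force outcome classification oracle ------------------------
# substitutes window bases directly in the segment string, re-splices
# and re-translates codon by codon
oracle_classify <- function(guide, model, editor) {
  conv <- if (editor == "CBE") c("C", "T") else c("A", "G")
  seg <- strsplit(model$sequence, "")[[1]]
  n <- length(seg)
  window <- 4:8
  pos <- if (guide$strand == "+") {
    guide$start + window - 1
  } else {
    guide$start - (window - 1)
  }
  proto_bases <- strsplit(guide$protospacer, "")[[1]][window]
  hit <- proto_bases == conv[1]
  edit_pos <- pos[hit]
  if (length(edit_pos) == 0) return("non_editing")
  seg2 <- seg
  for (p in edit_pos) {
    seg2[p + 1] <- if (guide$strand == "+") conv[2] else comp_base(conv[2])
  }
  splice <- function(sg) {
    ex <- unlist(lapply(model$exons, function(e) (e[1]:(e[2] - 1)) + 1))
    tx <- sg[ex]
    if (model$strand == "-") tx <- rev(comp_base(tx))
    cds <- tx[(model$cds[1] + 1):model$cds[2]]
    paste(cds, collapse = "")
  }
  gc <- Biostrings::GENETIC_CODE
  trans <- function(cds) {
    m <- matrix(strsplit(cds, "")[[1]], nrow = 3)
    unname(gc[apply(m, 2, paste, collapse = "")])
  }
  aa0 <- trans(splice(seg))
  aa1 <- trans(splice(seg2))
  # any edit inside the CDS?
  cds_pos <- model$cds_segment_pos
  if (!any(edit_pos %in% cds_pos)) return("utr_intronic")
  diff <- which(aa0 != aa1)
  if (any(aa1[diff] == "*" & aa0[diff] != "*")) return("nonsense")
  if (length(diff) > 0) return("missense")
  "silent"
}

oracle_representative <- function(guide, model, editor) {
  conv <- if (editor == "CBE") c("C", "T") else c("A", "G")
  seg <- strsplit(model$sequence, "")[[1]]
  window <- 4:8
  pos <- if (guide$strand == "+") guide$start + window - 1 else
    guide$start - (window - 1)
  proto_bases <- strsplit(guide$protospacer, "")[[1]][window]
  edit_pos <- pos[proto_bases == conv[1]]
  seg2 <- seg
  for (p in edit_pos) {
    seg2[p + 1] <- if (guide$strand == "+") conv[2] else comp_base(conv[2])
  }
  splice <- function(sg) {
    ex <- unlist(lapply(model$exons, function(e) (e[1]:(e[2] - 1)) + 1))
    tx <- sg[ex]
    if (model$strand == "-") tx <- rev(comp_base(tx))
    tx[(model$cds[1] + 1):model$cds[2]]
  }
  gc <- Biostrings::GENETIC_CODE
  trans <- function(v) {
    m <- matrix(v, nrow = 3)
    unname(gc[apply(m, 2, paste, collapse = "")])
  }
  diff <- which(trans(splice(seg)) != trans(splice(seg2)))
  if (length(diff) == 0) return(NA_integer_)
  m <- mean(diff)
  as.integer(sign(m) * floor(abs(m) + 0.5))
}

# --- independent tricube locally-weighted linear regression -----------
# textbook definition, q = floor(f * n) nearest neighbours as in the
# classical lowess routine
oracle_lowess <- function(x, y, f) {
  n <- length(x)
  q <- max(min(floor(f * n + 1e-7), n), 2)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    dq <- sort(d, partial = q)[q]
    cutoff <- if (dq > 0) dq else 1
    u <- d / cutoff
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    if (dq == 0) w <- as.numeric(d == 0)
    xw <- x[w > 0]; yw <- y[w > 0]; ww <- w[w > 0]
    if (length(unique(xw)) == 1) {
      sum(ww * yw) / sum(ww)
    } else {
      fit <- stats::lm.wfit(cbind(1, xw), yw, ww)
      sum(fit$coefficients * c(1, x[i]))
    }
  }, numeric(1))
}

# --- brute-force Benjamini-Hochberg (step-up definition) --------------
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  ranked <- p[ord] * n / seq_len(n)
  # step-up: adjusted p_(i) = min over j >= i of ranked_(j), capped at 1
  for (i in seq_len(n)) {
    adj[ord[i]] <- min(1, min(ranked[i:n]))
  }
  adj
}

# --- bisection root for the binding quadratic -------------------------
oracle_bound_bisect <- function(A_T, B_T, K_D) {
  if (A_T == 0 || B_T == 0) return(0)
  g <- function(ab) (A_T - ab) * (B_T - ab) - K_D * ab
  lo <- 0; hi <- min(A_T, B_T)
  if (g(hi) == 0) return(hi)
  # bisect to floating-point exhaustion
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid == lo || mid == hi) break
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
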
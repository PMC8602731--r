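# Independent brute-force oracles used to cross-check the implementation.

# per-base coverage and weighted identity for one query
oracle_coverage_identity <- function(qstart, qend, pident, alen, query_length) {
  covered <- logical(query_length)
  for (i in seq_along(qstart)) {
    lo <- max(qstart[i], 0) + 1L
    hi <- min(qend[i], query_length)
    if (hi >= lo) covered[lo:hi] <- TRUE
  }
  list(
    coverage = sum(covered) / query_length,
    identity = sum(pident * alen) / sum(alen)
  )
}

# best retained hit by explicit scan (filter, then sort by the tie-break chain)
oracle_best_hit <- function(hits, max_evalue, min_bitscore) {
  kept <- hits[hits$evalue < max_evalue & hits$bitscore > min_bitscore, ]
  if (nrow(kept) == 0) {
    return(NULL)
  }
  ord <- order(-kept$bitscore, kept$evalue, kept$subject_id)
  kept[ord[1], ]
}

# row-wise breadth by explicit nested loops
oracle_breadth <- function(raw, meta, threshold) {
  groups <- unique(meta$replicate_group)
  out <- integer(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    b <- 0L
    for (g in groups) {
      members <- meta$sample_id[meta$replicate_group == g]
      total <- 0
      for (s in members) total <- total + raw[[s]][i]
      if (total >= threshold) b <- b + 1L
    }
    out[i] <- b
  }
  out
}

# Pearson r and two-sided p from first principles
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
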
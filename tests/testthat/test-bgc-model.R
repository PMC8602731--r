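contig_tbl <- function(lengths, ids = sprintf("c%03d", seq_along(lengths))) {
  tibble::tibble(contig_id = ids, length = lengths, assembly_id = "asm01")
}

test_that("contig eligibility uses a strict length threshold", {
  ct <- contig_tbl(c(4999, 5000, 5001))
  expect_equal(eligible_contigs(ct)$length, 5001)
  expect_equal(nrow(eligible_contigs(ct[0, ])), 0)
  # brute-force oracle on random lengths
  withr::local_seed(101)
  lens <- sample(1000:10000, 100, replace = TRUE)
  ct <- contig_tbl(lens)
  expect_equal(
    eligible_contigs(ct, 5000)$contig_id,
    ct$contig_id[sapply(lens, function(l) l > 5000)]
  )
})

test_that("full-length calls follow the contig-edge predicate", {
  ct <- contig_tbl(60000, "c1")
  bgc <- function(s, e) {
    tibble::tibble(bgc_id = "b1", contig_id = "c1", start = s, end = e)
  }
  expect_false(classify_full_length(bgc(0, 40000), ct)$full_length)
  expect_true(classify_full_length(bgc(5000, 55000), ct)$full_length)
  expect_false(classify_full_length(bgc(5000, 60000), ct)$full_length)
  # 500 random placements across a margin sweep equal the direct inequality
  withr::local_seed(7)
  n <- 500
  clen <- 50000
  s <- sample(0:(clen - 1000), n, replace = TRUE)
  e <- s + sample(500:999, n, replace = TRUE)
  bgcs <- tibble::tibble(
    bgc_id = sprintf("b%03d", seq_len(n)), contig_id = "c1", start = s, end = e
  )
  ct <- contig_tbl(clen, "c1")
  for (margin in c(0, 100, 5000)) {
    got <- classify_full_length(bgcs, ct, edge_margin = margin)$full_length
    expect_equal(got, s > margin & (clen - e) > margin)
  }
})

test_that("full-length is monotone in the edge margin", {
  withr::local_seed(8)
  n <- 200
  clen <- 30000
  s <- sample(0:(clen - 2000), n, replace = TRUE)
  bgcs <- tibble::tibble(
    bgc_id = sprintf("b%03d", 1:n), contig_id = "c1",
    start = s, end = s + 1500
  )
  ct <- contig_tbl(clen, "c1")
  prev <- classify_full_length(bgcs, ct, edge_margin = 0)$full_length
  for (margin in c(10, 100, 1000, 10000)) {
    cur <- classify_full_length(bgcs, ct, edge_margin = margin)$full_length
    expect_true(all(prev | !cur)) # truncated never becomes full-length
    prev <- cur
  }
})

test_that("a BGC span exceeding its contig raises a consistency error", {
  ct <- contig_tbl(10000, "c1")
  bad <- tibble::tibble(bgc_id = "b1", contig_id = "c1", start = 500, end = 10500)
  expect_error(classify_full_length(bad, ct), class = "bgcdiel_consistency_error")
  orphan <- tibble::tibble(bgc_id = "b1", contig_id = "nope", start = 0, end = 10)
  expect_error(classify_full_length(orphan, ct), class = "bgcdiel_consistency_error")
})

one_bgc <- function(len = 1000) {
  tibble::tibble(bgc_id = "b1", contig_id = "c1", start = 0, end = len)
}

hit_row <- function(qs, qe, pid, subject = "s1", bits = 500) {
  tibble::tibble(
    query_id = "b1", subject_id = subject, percent_identity = pid,
    alignment_length = qe - qs, mismatch = 0L, gapopen = 0L,
    qstart = qs, qend = qe, sstart = 1L, send = qe - qs,
    evalue = 1e-50, bitscore = bits
  )
}

test_that("novelty classification handles no-hit, clear-hit, and the overlapping-hit worked example", {
  no_hits <- classify_novelty(one_bgc(), hit_row(0, 0, 0)[0, ])
  expect_true(no_hits$novel)
  expect_equal(no_hits$hit_coverage, 0)

  clear <- classify_novelty(one_bgc(), hit_row(0, 900, 95))
  expect_false(clear$novel)

  # two overlapping hits to one subject: [0,600) at 80%, [400,900) at 70%
  # on a 1000 bp query -> union 900 bp (coverage 0.9), weighted identity
  # (600*80 + 500*70) / 1100 = 75.4545... -> known
  two <- classify_novelty(
    one_bgc(1000),
    dplyr::bind_rows(hit_row(0, 600, 80), hit_row(400, 900, 70))
  )
  expect_equal(two$hit_coverage, 0.9)
  expect_equal(two$hit_identity, (600 * 80 + 500 * 70) / 1100)
  expect_false(two$novel)
})

test_that("novelty coverage and identity match a per-base brute-force oracle", {
  withr::local_seed(21)
  for (rep in 1:30) {
    qlen <- sample(500:2000, 1)
    k <- sample(1:5, 1)
    qs <- sample(0:(qlen - 100), k, replace = TRUE)
    qe <- pmin(qs + sample(50:800, k, replace = TRUE), qlen)
    pid <- runif(k, 50, 100)
    hits <- purrr::map_dfr(
      seq_len(k),
      ~ hit_row(qs[.x], qe[.x], pid[.x], subject = "s1")
    )
    got <- classify_novelty(one_bgc(qlen), hits)
    want <- oracle_coverage_identity(qs, qe, pid, qe - qs, qlen)
    expect_equal(got$hit_coverage, want$coverage, tolerance = 1e-12)
    expect_equal(got$hit_identity, want$identity, tolerance = 1e-12)
    expect_equal(
      got$novel,
      !(want$coverage >= 0.80 && want$identity >= 75)
    )
  }
})

test_that("novelty is decided on the best subject only, and both thresholds must pass", {
  # strong decoy subject with high coverage but pooled from a weaker hit
  hits <- dplyr::bind_rows(
    hit_row(0, 900, 90, subject = "best", bits = 1000),
    hit_row(0, 990, 95, subject = "weak", bits = 10)
  )
  got <- classify_novelty(one_bgc(1000), hits)
  expect_equal(got$hit_coverage, 0.9) # best subject's span, not the decoy's
  pooled <- classify_novelty(one_bgc(1000), hits, subject_strategy = "all_subjects")
  expect_equal(pooled$hit_coverage, 0.99)
  # mixed cases are novel under the both-thresholds rule
  expect_true(classify_novelty(one_bgc(1000), hit_row(0, 990, 60))$novel)
  expect_true(classify_novelty(one_bgc(1000), hit_row(0, 300, 99))$novel)
  # boundary equality counts toward known
  exact <- classify_novelty(one_bgc(1000), hit_row(0, 800, 75))
  expect_false(exact$novel)
})

test_that("novelty is monotone in its thresholds", {
  withr::local_seed(31)
  for (rep in 1:20) {
    qlen <- 1000
    k <- sample(1:3, 1)
    qs <- sample(0:800, k, replace = TRUE)
    qe <- pmin(qs + sample(100:600, k, replace = TRUE), qlen)
    hits <- purrr::map_dfr(
      seq_len(k),
      ~ hit_row(qs[.x], qe[.x], runif(1, 60, 95))
    )
    base <- classify_novelty(one_bgc(qlen), hits)$novel
    for (ident in c(80, 90, 100)) {
      expect_true(classify_novelty(one_bgc(qlen), hits,
        min_identity = ident
      )$novel >= base)
    }
    for (cov in c(0.9, 0.95, 1)) {
      expect_true(classify_novelty(one_bgc(qlen), hits,
        min_coverage = cov
      )$novel >= base)
    }
  }
})

test_that("nonpositive query length is rejected", {
  bad <- tibble::tibble(bgc_id = "b1", contig_id = "c1", start = 100, end = 100)
  expect_error(classify_novelty(bad, hit_row(0, 10, 90)),
    class = "bgcdiel_argument_error"
  )
})

tax_hit <- function(evalue, bits, taxon = "Cyanobacteria|Microcoleus|x",
                    query = "b1") {
  tibble::tibble(
    query_id = query, subject_id = taxon, percent_identity = 90,
    alignment_length = 100L, mismatch = 0L, gapopen = 0L, qstart = 0L,
    qend = 100L, sstart = 1L, send = 100L, evalue = evalue, bitscore = bits,
    subject_phylum = sub("\\|.*", "", taxon),
    subject_genus = strsplit(taxon, "|", fixed = TRUE)[[1]][2]
  )
}

test_that("taxonomy takes the best hit surviving strict E-value and bitscore filters", {
  b <- one_bgc()
  got <- assign_taxonomy(b, tax_hit(1e-20, 100))
  expect_equal(got$phylum, "Cyanobacteria")
  expect_equal(got$genus, "Microcoleus")
  # boundary: bitscore exactly 60 and evalue exactly 1e-10 are NOT retained
  expect_equal(assign_taxonomy(b, tax_hit(1e-20, 60))$phylum, "unassigned")
  expect_equal(assign_taxonomy(b, tax_hit(1e-10, 100))$phylum, "unassigned")
  expect_equal(assign_taxonomy(b, tax_hit(1e-50, 0)[0, ])$phylum, "unassigned")
})

test_that("taxonomy assignment equals an exhaustive scan oracle on random hits", {
  withr::local_seed(13)
  phyla <- c("Cyanobacteria", "Proteobacteria", "Bacteroidetes")
  hits <- purrr::map_dfr(1:50, function(i) {
    tax_hit(
      10^runif(1, -30, -2), runif(1, 20, 300),
      taxon = paste0(sample(phyla, 1), "|Genus", i, "|acc", i)
    )
  })
  got <- assign_taxonomy(one_bgc(), hits)
  want <- oracle_best_hit(hits, 1e-10, 60)
  if (is.null(want)) {
    expect_equal(got$phylum, "unassigned")
  } else {
    expect_equal(got$phylum, want$subject_phylum)
    expect_equal(got$genus, want$subject_genus)
  }
})

test_that("inventory summary arithmetic is exact", {
  bgcs <- tibble::tibble(
    bgc_id = c("b1", "b2", "b3"), contig_id = "c1",
    start = 0, end = 10000, phylum = "Cyanobacteria",
    full_length = TRUE, novel = c(TRUE, TRUE, FALSE)
  )
  s <- summarize_inventory(bgcs, by = "phylum")
  expect_equal(s$cumulative_mb[s$group == "total"], 0.03)
  expect_equal(s$n_full_length[s$group == "total"], 3)
  expect_equal(s$pct_novel[s$group == "total"], round(100 * 2 / 3, 1))
  # totals equal column sums over groups
  per <- s[s$group != "total", ]
  expect_equal(sum(per$n_bgcs), s$n_bgcs[s$group == "total"])
  # empty input
  empty <- summarize_inventory(bgcs[0, ], by = "phylum")
  expect_equal(nrow(empty), 0)
})

test_that("an inventory of 2988 clusters with 175 previously sequenced reports 94.1% novel", {
  bgcs <- tibble::tibble(
    bgc_id = sprintf("b%04d", 1:2988), contig_id = "c1",
    start = 0, end = 1000, phylum = "x",
    full_length = NA, novel = c(rep(FALSE, 175), rep(TRUE, 2988 - 175))
  )
  s <- summarize_inventory(bgcs, by = "none")
  expect_equal(s$pct_novel[s$group == "total"], 94.1)
  expect_equal(s$n_known[s$group == "total"], 175)
})
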
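meta13 <- canonical_sample_metadata()

raw_matrix <- function(counts_by_gene) {
  m <- do.call(rbind, counts_by_gene)
  colnames(m) <- meta13$sample_id
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%03d", seq_along(counts_by_gene))),
    tibble::as_tibble(m)
  )
  attr(out, "stage") <- "raw"
  out
}

test_that("low-count filter keeps genes whose row maximum reaches the threshold", {
  m <- raw_matrix(list(rep(19, 13), c(20, rep(0, 12)), rep(100, 13)))
  kept <- filter_low_counts(m)
  expect_equal(kept$gene_id, c("g002", "g003"))
  expect_equal(count_stage(kept), "filtered")
  # random matrix equals brute-force row-max filter
  withr::local_seed(14)
  r <- random_counts(200, lambda = 12)
  got <- filter_low_counts(r, 20)
  keep <- apply(as.matrix(r[, -1]), 1, max) >= 20
  expect_equal(got$gene_id, r$gene_id[keep])
})

test_that("total-count normalization scales as the worked example and conserves column sums", {
  m <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10, 90), s2 = c(150, 50))
  attr(m, "stage") <- "filtered"
  n <- normalize_totals(m)
  expect_equal(n$s1[1], 10 / 100 * 150) # = 15
  # equal totals leave the matrix unchanged
  eq <- tibble::tibble(gene_id = c("a", "b"), s1 = c(30, 70), s2 = c(60, 40))
  attr(eq, "stage") <- "filtered"
  expect_equal(as.data.frame(normalize_totals(eq)), as.data.frame(eq),
    ignore_attr = TRUE
  )
  # random matrix: all post-normalization column sums equal the mean total
  withr::local_seed(15)
  r <- filter_low_counts(random_counts(150))
  rn <- normalize_totals(r)
  totals <- colSums(as.matrix(r[, -1]))
  expect_equal(
    unname(colSums(as.matrix(rn[, -1]))),
    rep(mean(totals), 13),
    tolerance = 1e-6
  )
})

test_that("a sample with zero total counts raises a degenerate-sample error naming it", {
  m <- tibble::tibble(gene_id = "a", s1 = 5, s2 = 0)
  attr(m, "stage") <- "filtered"
  expect_error(normalize_totals(m), "s2",
    class = "bgcdiel_degenerate_sample_error"
  )
})

test_that("replicate collapse averages groups and preserves chronology", {
  m <- raw_matrix(list(seq(10, 130, by = 10)))
  mn <- normalize_totals(filter_low_counts(m))
  # all counts equal within a row after normalization of a single gene
  collapsed <- collapse_replicates(mn, meta13)
  expect_equal(count_stage(collapsed), "collapsed")
  expect_equal(
    names(collapsed)[-1],
    c(
      "T0h", "T3min", "T15min", "T1h", "T9h", "T11.5h", "T18h",
      "T72h", "T74h", "T144h"
    )
  )
  # explicit group-mean oracle on a random fixture
  withr::local_seed(16)
  r <- normalize_totals(filter_low_counts(random_counts(80)))
  got <- collapse_replicates(r, meta13)
  for (g in unique(meta13$replicate_group)) {
    members <- meta13$sample_id[meta13$replicate_group == g]
    expect_equal(got[[g]], rowMeans(as.matrix(r[members])))
  }
  # singleton groups are copied unchanged
  expect_equal(got$T0h, r$S01_0h)
})

test_that("collapse rejects samples missing from the metadata", {
  m <- tibble::tibble(gene_id = "a", mystery_sample = 5)
  attr(m, "stage") <- "normalized"
  expect_error(collapse_replicates(m, meta13), "mystery_sample",
    class = "bgcdiel_metadata_error"
  )
})

test_that("the pipeline enforces its canonical stage order", {
  r <- random_counts(10)
  expect_error(normalize_totals(collapse_replicates(r, meta13)),
    class = "bgcdiel_stage_error"
  )
  expect_error(zscore_profiles(r), class = "bgcdiel_stage_error")
  expect_error(filter_low_counts(filter_low_counts(r)),
    class = "bgcdiel_stage_error"
  )
})

test_that("transcription breadth counts timepoints with pooled raw counts above the threshold", {
  all10 <- raw_matrix(list(rep(5, 13)))
  expect_equal(transcription_breadth(all10, meta13)$breadth, 10L)
  # exactly 4 at the (singleton) 9 h group, >=5 elsewhere -> breadth 9
  x <- rep(5, 13)
  x[meta13$sample_id == "S08_9h"] <- 4
  expect_equal(transcription_breadth(raw_matrix(list(x)), meta13)$breadth, 9L)
  # pooling semantics at a duplicated timepoint: 3 + 2 pools to 5
  y <- rep(5, 13)
  y[meta13$replicate_group == "T15min"] <- c(3, 2)
  expect_equal(transcription_breadth(raw_matrix(list(y)), meta13)$breadth, 10L)
  expect_equal(
    transcription_breadth(raw_matrix(list(y)), meta13, pooling = "all")$breadth, 9L
  )
  expect_equal(
    transcription_breadth(raw_matrix(list(y)), meta13, pooling = "any")$breadth, 9L
  )
  # random matrix equals the nested-loop oracle
  withr::local_seed(17)
  r <- random_counts(120, lambda = 3)
  expect_equal(
    transcription_breadth(r, meta13, 5)$breadth,
    oracle_breadth(r, meta13, 5)
  )
})

test_that("constitutive means expressed at all timepoints, monotone in the count threshold", {
  b <- tibble::tibble(gene_id = c("a", "b"), breadth = c(10L, 9L))
  cls <- classify_constitutive(b)
  expect_equal(cls$constitutive, c(TRUE, FALSE))
  expect_error(
    classify_constitutive(tibble::tibble(gene_id = "a", breadth = 11L)),
    class = "bgcdiel_argument_error"
  )
  withr::local_seed(18)
  r <- random_counts(150, lambda = 4)
  n_const <- sapply(c(1, 3, 5, 10, 20), function(thr) {
    sum(classify_constitutive(
      transcription_breadth(r, meta13, thr)
    )$constitutive)
  })
  expect_true(all(diff(n_const) <= 0))
})

test_that("breadth distributions are proper proportions per gene set", {
  b <- tibble::tibble(gene_id = sprintf("g%d", 1:6), breadth = rep(10L, 6))
  d <- breadth_distribution(b)
  expect_equal(d$proportion[d$breadth == 10], 1)
  expect_equal(sum(d$proportion), 1)
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    gene_set = c(rep("secondary", 3), rep("core", 3))
  )
  b2 <- tibble::tibble(gene_id = sprintf("g%d", 1:6), breadth = c(1L, 2L, 3L, 10L, 10L, 10L))
  ds <- breadth_distribution(b2, genes, "secondary")
  dc <- breadth_distribution(b2, genes, "core")
  expect_equal(sum(ds$proportion), 1)
  expect_equal(sum(dc$proportion), 1)
  expect_equal(dc$proportion[dc$breadth == 10], 1)
  expect_equal(ds$n[ds$breadth %in% 1:3], rep(1L, 3))
  expect_error(breadth_distribution(b2, genes, "background"),
    class = "bgcdiel_empty_set_error"
  )
})

test_that("z-score profiles have mean 0 and unit sd; constant genes are excluded and reported", {
  collapsed <- tibble::tibble(
    gene_id = c("flat", "spike"),
    !!!setNames(
      as.list(as.data.frame(rbind(rep(3, 10), c(rep(0, 9), 10)))),
      timepoint_groups(meta13)$replicate_group
    )
  )
  attr(collapsed, "stage") <- "collapsed"
  prof <- zscore_profiles(collapsed)
  expect_equal(prof$entity_id, "spike")
  expect_equal(excluded_entities(prof)$entity_id, "flat")
  z <- as.numeric(prof[1, -1])
  expect_equal(sum(z), 0, tolerance = 1e-12)
  expect_equal(which.max(z), 10L)
  # random profiles: direct recomputation, mean 0 sd 1 within 1e-9
  withr::local_seed(19)
  r <- collapse_replicates(
    normalize_totals(filter_low_counts(random_counts(100))), meta13
  )
  p <- zscore_profiles(r)
  zm <- as.matrix(p[, -1])
  expect_true(all(abs(rowMeans(zm)) < 1e-9))
  expect_true(all(abs(apply(zm, 1, sd) - 1) < 1e-9))
  i <- match(p$entity_id[1], r$gene_id)
  x <- as.numeric(r[i, -1])
  expect_equal(as.numeric(zm[1, ]), (x - mean(x)) / sd(x), tolerance = 1e-12)
})

test_that("BGC profiles are member-gene means with empty clusters reported", {
  prof <- random_profiles(4, prefix = "g")
  genes <- tibble::tibble(
    gene_id = c(sprintf("g%03d", 1:4), "g999"),
    bgc_id = c("b1", "b2", "b2", NA, "b3")
  )
  bp <- bgc_profiles(prof, genes)
  expect_equal(bp$entity_id, c("b1", "b2"))
  # single-gene cluster equals the gene's profile
  expect_equal(as.numeric(bp[1, -1]), as.numeric(prof[1, -1]))
  # two-gene cluster is the mean
  expect_equal(
    as.numeric(bp[2, -1]),
    colMeans(as.matrix(prof[2:3, -1])),
    ignore_attr = TRUE
  )
  expect_equal(excluded_entities(bp)$entity_id, "b3")
  # mirror-image genes cancel to a flat profile
  mirror <- prof[1:2, ]
  mirror[2, -1] <- -mirror[1, -1]
  mirror$entity_id <- c("gA", "gB")
  bp2 <- bgc_profiles(mirror, tibble::tibble(
    gene_id = c("gA", "gB"), bgc_id = "bX"
  ))
  expect_equal(as.numeric(bp2[1, -1]), rep(0, 10))
})

test_that("peak assignment is the earliest-tie argmax with correct night flags", {
  groups <- timepoint_groups(meta13)$replicate_group
  mk <- function(z) {
    p <- tibble::tibble(entity_id = "e1")
    p[groups] <- as.list(z)
    p
  }
  peak_11p5 <- assign_peak(mk(c(0, 0, 0, 0, 0, 5, 0, 0, 0, 0)), meta13)
  expect_equal(peak_11p5$peak_timepoint, 11.5)
  expect_true(peak_11p5$peak_is_night)
  # tie between 9 h and 72 h resolves to 9 h, a day peak
  tie <- assign_peak(mk(c(0, 0, 0, 0, 5, 1, 1, 5, 0, 0)), meta13)
  expect_equal(tie$peak_timepoint, 9)
  expect_false(tie$peak_is_night)
  # random profiles equal an explicit argmax oracle
  withr::local_seed(20)
  p <- random_profiles(50)
  got <- assign_peak(p, meta13)
  hours <- timepoint_groups(meta13)$timepoint_hours
  for (i in seq_len(50)) {
    z <- as.numeric(p[i, -1])
    expect_equal(got$peak_timepoint[i], hours[which.max(z)])
  }
})

test_that("phylum peak summary reports per-timepoint counts and night fractions", {
  groups <- timepoint_groups(meta13)$replicate_group
  z_night <- c(0, 0, 0, 0, 0, 5, 0, 0, 0, 0)
  z_day <- c(0, 0, 0, 0, 0, 0, 0, 5, 0, 0)
  p <- tibble::tibble(entity_id = c("b1", "b2", "b3"))
  p[groups] <- as.data.frame(rbind(z_night, z_night, z_day))
  peaks <- assign_peak(p, meta13)
  tax <- tibble::tibble(
    bgc_id = c("b1", "b2", "b3", "b9"),
    phylum = c("Cyanobacteria", "Cyanobacteria", "Proteobacteria", "Ghost")
  )
  s <- phylum_peak_summary(peaks, tax)
  cy <- s[s$phylum == "Cyanobacteria", ]
  expect_equal(unique(cy$night_fraction), 1)
  expect_equal(cy$n[cy$peak_group == "T11.5h"], 2L)
  expect_equal(s$night_fraction[s$phylum == "Proteobacteria"], 0)
  expect_false("Ghost" %in% s$phylum) # absent from profiles -> omitted
})

test_that("constitutive fractions per gene set use 1-decimal percentages", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:9),
    gene_set = c(rep("secondary", 6), rep("core", 3))
  )
  cls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:9),
    breadth = 10L,
    constitutive = c(rep(c(TRUE, FALSE), 3), TRUE, TRUE, FALSE)
  )
  f <- constitutive_fractions(cls, genes)
  expect_equal(f$pct[f$gene_set == "secondary"], 50)
  expect_equal(f$pct[f$gene_set == "core"], 66.7)
  expect_equal(f$n_genes[f$gene_set == "all"], 9)
})
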
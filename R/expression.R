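#' Count-matrix stages
#'
#' Count tibbles carry a `stage` attribute (`raw`, `filtered`, `normalized`,
#' `collapsed`) so the pipeline order — filter, normalize, collapse, z-score
#' — cannot be silently violated. The constitutive/breadth analysis works on
#' raw counts and is independent of normalization.
#'
#' @name count-matrix
NULL

sample_cols <- function(m) setdiff(names(m), "gene_id")

#' @rdname count-matrix
#' @param m A count tibble.
#' @return `count_stage()` returns the stage label (`"raw"` if unset).
#' @export
count_stage <- function(m) attr(m, "stage") %||% "raw"

set_stage <- function(m, stage) {
  attr(m, "stage") <- stage
  m
}

assert_stage <- function(m, expected, fn) {
  got <- count_stage(m)
  if (!got %in% expected) {
    abort(paste0(
      fn, "() expects a ", paste(expected, collapse = "/"),
      " count matrix, got stage '", got, "'"
    ), class = "bgcdiel_stage_error")
  }
  invisible(m)
}

#' Remove genes with uniformly low counts
#'
#' Genes whose maximum raw count across all samples is below `min_max_count`
#' (default 20) are removed before normalization; such genes carry too little
#' signal for profile analysis.
#'
#' @param m Raw count tibble (`gene_id` + one column per sample).
#' @param min_max_count Keep a gene iff its row maximum is `>=` this value.
#' @return The filtered tibble (stage `filtered`), row order preserved.
#' @export
filter_low_counts <- function(m, min_max_count = 20) {
  assert_stage(m, "raw", "filter_low_counts")
  sc <- sample_cols(m)
  row_max <- do.call(pmax, c(m[sc], na.rm = TRUE))
  set_stage(m[row_max >= min_max_count, , drop = FALSE], "filtered")
}

#' Normalize counts by per-sample totals
#'
#' Each count is divided by its sample's total and multiplied by the mean
#' total across samples, so every column of the result sums to the same
#' sequencing-depth-free value.
#'
#' @param m Filtered count tibble.
#' @return The normalized tibble (stage `normalized`).
#' @export
normalize_totals <- function(m) {
  assert_stage(m, c("filtered", "raw"), "normalize_totals")
  sc <- sample_cols(m)
  totals <- purrr::map_dbl(m[sc], sum)
  if (any(totals == 0)) {
    abort(paste0(
      "sample(s) with zero total counts cannot be normalized: ",
      paste(sc[totals == 0], collapse = ", ")
    ), class = "bgcdiel_degenerate_sample_error")
  }
  target <- mean(totals)
  out <- m
  for (s in sc) out[[s]] <- m[[s]] / totals[[s]] * target
  set_stage(out, "normalized")
}

#' Average replicate samples into timepoint groups
#'
#' Collapses the sample columns to one column per replicate group (the
#' canonical design averages duplicate 15-min and triplicate 1-h samples,
#' 13 samples to 10 timepoints). Output columns are in chronological order.
#'
#' @param m Normalized count tibble.
#' @param meta Sample metadata (see [canonical_sample_metadata()]).
#' @return A collapsed tibble (stage `collapsed`) with one column per
#'   replicate group.
#' @export
collapse_replicates <- function(m, meta) {
  assert_stage(m, "normalized", "collapse_replicates")
  meta <- validate_sample_metadata(meta)
  sc <- sample_cols(m)
  unknown <- setdiff(sc, meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "sample(s) in count matrix absent from metadata: ",
      paste(unknown, collapse = ", ")
    ), class = "bgcdiel_metadata_error")
  }
  groups <- timepoint_groups(meta %>% filter(.data$sample_id %in% sc))
  out <- tibble(gene_id = m$gene_id)
  for (g in groups$replicate_group) {
    members <- meta$sample_id[meta$replicate_group == g & meta$sample_id %in% sc]
    out[[g]] <- rowMeans(as.matrix(m[members]))
  }
  set_stage(out, "collapsed")
}

#' Transcription breadth: timepoints at which a gene is expressed
#'
#' A gene counts as expressed at a timepoint when its raw mapped-transcript
#' count there reaches `threshold` (default 5). Replicates of a timepoint are
#' pooled by summation before thresholding by default; `pooling = "all"` /
#' `"any"` instead require every / any single replicate to reach the
#' threshold.
#'
#' @param raw Raw count tibble (the threshold is defined on mapped
#'   transcripts, not normalized values).
#' @param meta Sample metadata.
#' @param threshold Minimum mapped transcripts at a timepoint.
#' @param pooling Replicate handling: `"sum"` (default), `"all"`, or `"any"`.
#' @return A tibble (`gene_id`, `breadth`) with breadth in 0..(number of
#'   timepoint groups).
#' @export
transcription_breadth <- function(raw, meta, threshold = 5,
                                  pooling = c("sum", "all", "any")) {
  assert_stage(raw, "raw", "transcription_breadth")
  pooling <- match.arg(pooling)
  meta <- validate_sample_metadata(meta)
  sc <- sample_cols(raw)
  unknown <- setdiff(sc, meta$sample_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "sample(s) in count matrix absent from metadata: ",
      paste(unknown, collapse = ", ")
    ), class = "bgcdiel_metadata_error")
  }
  groups <- timepoint_groups(meta %>% filter(.data$sample_id %in% sc))
  expressed <- matrix(FALSE, nrow = nrow(raw), ncol = nrow(groups))
  for (j in seq_len(nrow(groups))) {
    members <- meta$sample_id[
      meta$replicate_group == groups$replicate_group[j] & meta$sample_id %in% sc
    ]
    sub <- as.matrix(raw[members])
    pooled <- switch(pooling,
      sum = rowSums(sub),
      all = apply(sub, 1, min),
      any = apply(sub, 1, max)
    )
    expressed[, j] <- pooled >= threshold
  }
  tibble(gene_id = raw$gene_id, breadth = as.integer(rowSums(expressed)))
}

#' Classify constitutive transcription
#'
#' A gene is constitutively transcribed when it is expressed at every
#' timepoint, i.e. its breadth equals the number of timepoint groups.
#'
#' @param breadth Tibble from [transcription_breadth()].
#' @param n_timepoints Number of timepoint groups in the design.
#' @return `breadth` with a logical `constitutive` column appended.
#' @export
classify_constitutive <- function(breadth, n_timepoints = 10) {
  breadth <- as_tibble(breadth)
  if (any(breadth$breadth < 0 | breadth$breadth > n_timepoints)) {
    abort("breadth values outside [0, n_timepoints]",
      class = "bgcdiel_argument_error"
    )
  }
  breadth %>% mutate(constitutive = .data$breadth == n_timepoints)
}

#' Distribution of transcription breadth for a gene set
#'
#' Proportion of genes at each breadth value 0..n for the chosen gene panel
#' (secondary/biosynthetic, core housekeeping, background, or all), the
#' comparison behind the core-versus-secondary constitutive-expression
#' contrast.
#'
#' @param breadth Tibble from [transcription_breadth()].
#' @param genes Gene tibble with `gene_id` and `gene_set`; optional for
#'   `gene_set = "all"`.
#' @param gene_set `"all"`, `"secondary"`, `"core"`, or `"background"`.
#' @param n_timepoints Number of timepoint groups.
#' @return A tibble (`gene_set`, `breadth` 0..n, `n`, `proportion`);
#'   proportions sum to 1.
#' @export
breadth_distribution <- function(breadth, genes = NULL, gene_set = "all",
                                 n_timepoints = 10) {
  breadth <- as_tibble(breadth)
  if (gene_set != "all") {
    if (is.null(genes)) {
      abort("`genes` is required to select a gene set",
        class = "bgcdiel_argument_error"
      )
    }
    ids <- genes$gene_id[genes$gene_set == gene_set]
    breadth <- breadth %>% filter(.data$gene_id %in% ids)
  }
  if (nrow(breadth) == 0) {
    abort(paste0("gene set '", gene_set, "' is empty"),
      class = "bgcdiel_empty_set_error"
    )
  }
  tab <- table(factor(breadth$breadth, levels = 0:n_timepoints))
  total <- nrow(breadth)
  tibble(
    gene_set = gene_set,
    breadth = 0:n_timepoints,
    n = as.integer(tab),
    proportion = as.integer(tab) / total
  )
}

#' Constitutive-transcription fractions by gene set
#'
#' @param constitutive Tibble from [classify_constitutive()].
#' @param genes Gene tibble with `gene_id` and `gene_set`.
#' @return A tibble (`gene_set`, `n_genes`, `n_constitutive`, `fraction`,
#'   `pct`), percentages to 1 decimal place, with an `all` row.
#' @export
constitutive_fractions <- function(constitutive, genes) {
  joined <- as_tibble(constitutive) %>%
    inner_join(as_tibble(genes) %>% select("gene_id", "gene_set"), by = "gene_id")
  one <- function(d, label) {
    tibble(
      gene_set = label, n_genes = nrow(d),
      n_constitutive = sum(d$constitutive),
      fraction = sum(d$constitutive) / nrow(d),
      pct = round(100 * sum(d$constitutive) / nrow(d), 1)
    )
  }
  per <- joined %>%
    group_by(.data$gene_set) %>%
    dplyr::group_map(~ one(.x, .y$gene_set)) %>%
    bind_rows()
  bind_rows(per, one(joined, "all"))
}

#' Z-score expression profiles
#'
#' Standardizes each gene's collapsed profile to mean 0 and (n-1) sample
#' standard deviation 1 across the timepoints. Genes with zero variance
#' cannot be standardized; they are excluded and listed in the `excluded`
#' attribute (also available via [excluded_entities()]).
#'
#' @param collapsed Collapsed count tibble (one column per timepoint group).
#' @return A profile tibble (`entity_id` + one z column per timepoint) of
#'   class `bgc_profiles`.
#' @export
zscore_profiles <- function(collapsed) {
  assert_stage(collapsed, "collapsed", "zscore_profiles")
  sc <- sample_cols(collapsed)
  x <- as.matrix(collapsed[sc])
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  keep <- s > 0
  z <- (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
  out <- bind_cols(
    tibble(entity_id = collapsed$gene_id[keep]),
    as_tibble(z)
  )
  attr(out, "excluded") <- tibble(
    entity_id = collapsed$gene_id[!keep],
    reason = "zero variance across timepoints"
  )
  class(out) <- c("bgc_profiles", class(out))
  out
}

#' Entities excluded from a profile table
#'
#' @param profiles A profile tibble from [zscore_profiles()] or
#'   [bgc_profiles()].
#' @return A tibble (`entity_id`, `reason`).
#' @export
excluded_entities <- function(profiles) {
  attr(profiles, "excluded") %||% tibble(entity_id = character(), reason = character())
}

#' Average gene profiles into BGC profiles
#'
#' A cluster's profile is the per-timepoint arithmetic mean of its member
#' genes' z-scores. Clusters none of whose genes survived profiling are
#' excluded and reported via [excluded_entities()].
#'
#' @param gene_profiles Profile tibble from [zscore_profiles()] (gene level).
#' @param genes Gene tibble with `gene_id` and `bgc_id`.
#' @return A BGC-level profile tibble of class `bgc_profiles`.
#' @export
bgc_profiles <- function(gene_profiles, genes) {
  genes <- as_tibble(genes)
  members <- genes %>%
    filter(!is.na(.data$bgc_id)) %>%
    select("gene_id", "bgc_id")
  joined <- as_tibble(gene_profiles) %>%
    inner_join(members, by = c(entity_id = "gene_id"))
  sc <- setdiff(names(gene_profiles), "entity_id")
  out <- joined %>%
    group_by(.data$bgc_id) %>%
    summarise(across(all_of(sc), mean), .groups = "drop") %>%
    rename(entity_id = "bgc_id") %>%
    arrange(.data$entity_id)
  lost <- setdiff(unique(members$bgc_id), joined$bgc_id)
  attr(out, "excluded") <- tibble(
    entity_id = lost,
    reason = "no member gene with a usable profile"
  )
  class(out) <- c("bgc_profiles", class(out))
  out
}

#' Assign each profile its peak timepoint
#'
#' The peak is the timepoint with the highest z-score; ties go to the
#' earliest timepoint. A peak is a night peak when its timepoint group is
#' flagged as night in the metadata (11.5 h and 18 h in the canonical
#' design).
#'
#' @param profiles Profile tibble (gene or BGC level).
#' @param meta Sample metadata.
#' @return A tibble (`entity_id`, `peak_group`, `peak_timepoint`,
#'   `peak_is_night`).
#' @export
assign_peak <- function(profiles, meta) {
  groups <- timepoint_groups(meta)
  sc <- setdiff(names(profiles), "entity_id")
  missing <- setdiff(sc, groups$replicate_group)
  if (length(missing) > 0) {
    abort(paste0(
      "profile column(s) not found among replicate groups: ",
      paste(missing, collapse = ", ")
    ), class = "bgcdiel_metadata_error")
  }
  # chronological column order so which.max's first-match rule breaks ties
  # toward the earliest timepoint
  ord <- groups$replicate_group[groups$replicate_group %in% sc]
  x <- as.matrix(as_tibble(profiles)[ord])
  idx <- apply(x, 1, which.max)
  g <- ord[idx]
  gi <- match(g, groups$replicate_group)
  tibble(
    entity_id = profiles$entity_id,
    peak_group = g,
    peak_timepoint = groups$timepoint_hours[gi],
    peak_is_night = groups$is_night[gi]
  )
}

#' Phylum-resolved peak-timepoint summary
#'
#' Counts how many of each phylum's BGCs peak at each timepoint, and what
#' fraction of them peak at night — the statistic behind the observation that
#' cyanobacterial secondary-metabolite transcription is concentrated at
#' night.
#'
#' @param peaks Tibble from [assign_peak()] (BGC level).
#' @param taxonomy Tibble with `bgc_id` and `phylum`; phyla absent from the
#'   profiles are omitted.
#' @return A tibble with one row per (phylum, peak timepoint): `phylum`,
#'   `peak_group`, `peak_timepoint`, `peak_is_night`, `n`, plus the
#'   phylum-level `n_total` and `night_fraction`.
#' @export
phylum_peak_summary <- function(peaks, taxonomy) {
  joined <- as_tibble(peaks) %>%
    inner_join(
      as_tibble(taxonomy) %>% select(entity_id = "bgc_id", "phylum"),
      by = "entity_id"
    )
  per_phylum <- joined %>%
    group_by(.data$phylum) %>%
    summarise(
      n_total = dplyr::n(),
      night_fraction = mean(.data$peak_is_night),
      .groups = "drop"
    )
  joined %>%
    count(.data$phylum, .data$peak_group, .data$peak_timepoint,
      .data$peak_is_night,
      name = "n"
    ) %>%
    left_join(per_phylum, by = "phylum") %>%
    arrange(.data$phylum, .data$peak_timepoint)
}
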
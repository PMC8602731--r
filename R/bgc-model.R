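#' Contigs eligible for BGC exploration
#'
#' Only contigs strictly longer than `min_len` (default 5 kb) are explored
#' for biosynthetic gene clusters; shorter contigs rarely hold a full cluster
#' and inflate fragment counts.
#'
#' @param contigs Contig tibble (`contig_id`, `length`, `assembly_id`).
#' @param min_len Minimum length in bp; the comparison is strict (`>`).
#' @return The eligible subset, order preserved.
#' @examples
#' eligible_contigs(tibble::tibble(
#'   contig_id = c("a", "b", "c"), length = c(4999, 5000, 5001),
#'   assembly_id = "asm01"
#' ))
#' @export
eligible_contigs <- function(contigs, min_len = 5000) {
  as_tibble(contigs) %>% filter(.data$length > min_len)
}

#' Classify BGCs as full-length or truncated
#'
#' A cluster is full-length when it is not truncated on either contig edge:
#' with the default margin of 0 it must start after the first base and end
#' before the last base of its contig. A positive `edge_margin` demands that
#' much clearance on both sides.
#'
#' @param bgcs BGC tibble (`bgc_id`, `contig_id`, `start`, `end`, 0-based
#'   half-open).
#' @param contigs Contig tibble with `contig_id` and `length`.
#' @param edge_margin Required clearance in bp on each side.
#' @return `bgcs` with a logical `full_length` column appended.
#' @export
classify_full_length <- function(bgcs, contigs, edge_margin = 0) {
  bgcs <- as_tibble(bgcs)
  joined <- bgcs %>%
    left_join(
      as_tibble(contigs) %>% select("contig_id", contig_length = "length"),
      by = "contig_id"
    )
  if (anyNA(joined$contig_length)) {
    missing <- unique(joined$contig_id[is.na(joined$contig_length)])
    abort(paste0(
      "BGC(s) on contig(s) absent from the contig table: ",
      paste(head(missing, 5), collapse = ", ")
    ), class = "bgcdiel_consistency_error")
  }
  bad <- joined$start < 0 | joined$end > joined$contig_length |
    joined$start >= joined$end
  if (any(bad)) {
    abort(paste0(
      "BGC span exceeds its contig (or is empty): ",
      paste(head(joined$bgc_id[bad], 5), collapse = ", ")
    ), class = "bgcdiel_consistency_error")
  }
  bgcs$full_length <- joined$start > edge_margin &
    (joined$contig_length - joined$end) > edge_margin
  bgcs
}

# union length of 0-based half-open [qstart, qend) intervals, clipped to
# [0, query_length)
interval_union_length <- function(qstart, qend, query_length) {
  ir <- IRanges::IRanges(start = pmax(qstart, 0L) + 1L, end = pmin(qend, query_length))
  ir <- ir[IRanges::width(ir) > 0]
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Classify BGC novelty from nucleotide alignment hits
#'
#' A cluster counts as previously sequenced ("known") only if reference hits
#' reach at least `min_identity` percent identity over at least
#' `min_coverage` of the query length; anything less — including mixed cases
#' with high coverage but low identity — is novel, as is a cluster with no
#' hits at all. Coverage is the length of the union of query intervals of the
#' retained hits divided by the query length; identity is the
#' alignment-length-weighted mean percent identity over those hits. By
#' default only hits to the single best subject (highest summed bitscore) are
#' used, so coverage cannot be assembled chimerically from unrelated
#' references; `subject_strategy = "all_subjects"` pools every hit instead.
#'
#' @param bgcs BGC tibble (`bgc_id`, `start`, `end`).
#' @param hits Alignment-hit tibble (see [read_blast_tab()]); `query_id`
#'   matches `bgc_id`.
#' @param min_identity Identity threshold in percent (boundary counts as
#'   known).
#' @param min_coverage Coverage threshold as a fraction (boundary counts as
#'   known).
#' @param subject_strategy `"best_subject"` (default) or `"all_subjects"`.
#' @return `bgcs` with `novel` (logical), `hit_coverage`, and `hit_identity`
#'   columns appended.
#' @export
classify_novelty <- function(bgcs, hits, min_identity = 75, min_coverage = 0.80,
                             subject_strategy = c("best_subject", "all_subjects")) {
  subject_strategy <- match.arg(subject_strategy)
  bgcs <- as_tibble(bgcs)
  qlen <- bgcs$end - bgcs$start
  if (any(qlen <= 0)) {
    abort(paste0(
      "nonpositive query length for BGC(s): ",
      paste(head(bgcs$bgc_id[qlen <= 0], 5), collapse = ", ")
    ), class = "bgcdiel_argument_error")
  }
  hits <- as_tibble(hits)
  res <- purrr::map_dfr(seq_len(nrow(bgcs)), function(i) {
    h <- hits %>% filter(.data$query_id == bgcs$bgc_id[i])
    if (nrow(h) == 0) {
      return(tibble(hit_coverage = 0, hit_identity = NA_real_, novel = TRUE))
    }
    if (subject_strategy == "best_subject") {
      best <- h %>%
        group_by(.data$subject_id) %>%
        summarise(total_bits = sum(.data$bitscore), .groups = "drop") %>%
        arrange(desc(.data$total_bits), .data$subject_id) %>%
        slice(1) %>%
        pull("subject_id")
      h <- h %>% filter(.data$subject_id == best)
    }
    cov <- interval_union_length(h$qstart, h$qend, qlen[i]) / qlen[i]
    ident <- sum(h$percent_identity * h$alignment_length) / sum(h$alignment_length)
    tibble(
      hit_coverage = cov,
      hit_identity = ident,
      novel = !(cov >= min_coverage && ident >= min_identity)
    )
  })
  bind_cols(bgcs, res)
}

#' Assign taxonomy from best retained alignment hit
#'
#' Hits are retained when their E-value is below `max_evalue` and their
#' bitscore above `min_bitscore` (both strict); the taxon of the
#' highest-bitscore survivor is assigned, with ties broken by lowest E-value
#' and then lexicographic subject id. Queries with no surviving hits are
#' unassigned.
#'
#' @param bgcs BGC tibble with `bgc_id`.
#' @param hits Alignment-hit tibble with `subject_phylum`/`subject_genus`
#'   columns (parsed from `|`-delimited subject ids by [read_blast_tab()]).
#' @param max_evalue,min_bitscore Retention thresholds.
#' @return `bgcs` with `phylum` and `genus` columns appended (`"unassigned"`
#'   when no hit survives).
#' @export
assign_taxonomy <- function(bgcs, hits, max_evalue = 1e-10, min_bitscore = 60) {
  bgcs <- as_tibble(bgcs)
  surv <- as_tibble(hits) %>%
    filter(.data$evalue < max_evalue, .data$bitscore > min_bitscore) %>%
    arrange(.data$query_id, desc(.data$bitscore), .data$evalue, .data$subject_id) %>%
    distinct(.data$query_id, .keep_all = TRUE) %>%
    select("query_id",
      phylum = "subject_phylum", genus = "subject_genus"
    )
  out <- bgcs %>%
    left_join(surv, by = c(bgc_id = "query_id")) %>%
    mutate(
      phylum = dplyr::coalesce(.data$phylum, "unassigned"),
      genus = dplyr::coalesce(.data$genus, "unassigned")
    )
  out
}

#' Summarise a BGC inventory
#'
#' Per-group counts of clusters, full-length clusters, previously sequenced
#' ("known") and novel clusters, cumulative span in Mb, and percent novel
#' (1 decimal place), with a `total` row equal to the column sums.
#'
#' @param bgcs BGC tibble with `full_length` and `novel` columns (NAs count
#'   as undetermined and are excluded from the respective counts).
#' @param contigs Contig tibble; required for `by = "assembly"`.
#' @param by Grouping: `"assembly"`, `"phylum"`, or `"none"` (totals only).
#' @return A summary tibble; the final row has `group = "total"`.
#' @examples
#' bgcs <- tibble::tibble(
#'   bgc_id = sprintf("b%02d", 1:3), contig_id = "c1",
#'   start = 0, end = 10000, phylum = "Cyanobacteria",
#'   full_length = c(TRUE, TRUE, FALSE), novel = c(TRUE, FALSE, TRUE)
#' )
#' summarize_inventory(bgcs, by = "phylum")
#' @export
summarize_inventory <- function(bgcs, contigs = NULL,
                                by = c("assembly", "phylum", "none")) {
  by <- match.arg(by)
  bgcs <- as_tibble(bgcs)
  if (nrow(bgcs) == 0) {
    return(tibble(
      group = character(), n_bgcs = integer(), n_full_length = integer(),
      n_known = integer(), n_novel = integer(), cumulative_mb = double(),
      pct_novel = double()
    ))
  }
  if (!"full_length" %in% names(bgcs)) bgcs$full_length <- NA
  if (!"novel" %in% names(bgcs)) bgcs$novel <- NA
  bgcs$group <- switch(by,
    assembly = {
      if (is.null(contigs)) {
        abort("`contigs` is required to summarise by assembly",
          class = "bgcdiel_argument_error"
        )
      }
      amap <- setNames(contigs$assembly_id, contigs$contig_id)
      unname(amap[bgcs$contig_id])
    },
    phylum = bgcs$phylum,
    none = "all"
  )
  one <- function(d, label) {
    tibble(
      group = label,
      n_bgcs = nrow(d),
      n_full_length = sum(d$full_length, na.rm = TRUE),
      n_known = sum(!d$novel, na.rm = TRUE),
      n_novel = sum(d$novel, na.rm = TRUE),
      cumulative_mb = sum(d$end - d$start) / 1e6,
      pct_novel = round(100 * sum(d$novel, na.rm = TRUE) / nrow(d), 1)
    )
  }
  per <- bgcs %>%
    group_by(.data$group) %>%
    dplyr::group_map(~ one(.x, .y$group)) %>%
    bind_rows() %>%
    arrange(.data$group)
  bind_rows(per, one(bgcs, "total"))
}
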
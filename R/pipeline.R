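#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default: contig
#' eligibility > 5 kb, full-length edge margin 0 bp, novelty thresholds 75%
#' identity over 80% coverage, taxonomy retention E < 1e-10 and bitscore
#' > 60, low-count filter at a row maximum of 20, constitutive threshold of
#' 5 mapped transcripts at every timepoint, network threshold r > 0.8, and
#' one-step Bonferroni correction.
#'
#' @param input_dir Directory holding the input files (fixture layout, see
#'   [write_fixture()]).
#' @param output_dir Directory stage outputs are written to.
#' @param min_contig_len,edge_margin,min_identity,min_coverage,max_evalue,min_bitscore,min_max_count,constitutive_threshold,r_threshold
#'   Stage tunables; see the stage functions for semantics.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param seed Seed used by [run_simulate()].
#' @return A `bgc_pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = NULL,
                            min_contig_len = 5000, edge_margin = 0,
                            min_identity = 75, min_coverage = 0.80,
                            max_evalue = 1e-10, min_bitscore = 60,
                            min_max_count = 20, constitutive_threshold = 5,
                            r_threshold = 0.8,
                            correction = c("bonferroni", "bh"),
                            seed = 1L) {
  correction <- match.arg(correction)
  check_range <- function(value, name, lo, hi) {
    if (length(value) != 1 || is.na(value) || value < lo || value > hi) {
      abort(paste0("`", name, "` must be a single value in [", lo, ", ", hi, "]"),
        class = "bgcdiel_config_error"
      )
    }
  }
  check_range(min_contig_len, "min_contig_len", 0, Inf)
  check_range(edge_margin, "edge_margin", 0, Inf)
  check_range(min_identity, "min_identity", 0, 100)
  check_range(min_coverage, "min_coverage", 0, 1)
  check_range(max_evalue, "max_evalue", 0, Inf)
  check_range(min_bitscore, "min_bitscore", 0, Inf)
  check_range(min_max_count, "min_max_count", 0, Inf)
  check_range(constitutive_threshold, "constitutive_threshold", 0, Inf)
  check_range(r_threshold, "r_threshold", -1, 1)
  structure(
    list(
      input_dir = input_dir, output_dir = output_dir,
      min_contig_len = min_contig_len, edge_margin = edge_margin,
      min_identity = min_identity, min_coverage = min_coverage,
      max_evalue = max_evalue, min_bitscore = min_bitscore,
      min_max_count = min_max_count,
      constitutive_threshold = constitutive_threshold,
      r_threshold = r_threshold, correction = correction,
      seed = as.integer(seed)
    ),
    class = "bgc_pipeline_config"
  )
}

pipeline_out <- function(config) {
  dir <- config$output_dir %||% abort("pipeline config has no output_dir",
    class = "bgcdiel_config_error"
  )
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

write_manifest <- function(config, stage, extra = list()) {
  out <- pipeline_out(config)
  manifest <- c(
    list(
      stage = stage,
      package_version = as.character(packageVersion("bgcdiel")),
      config = config[setdiff(names(config), c("input_dir", "output_dir"))]
    ),
    extra
  )
  jsonlite::write_json(
    manifest, file.path(out, paste0("manifest_", stage, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
}

require_upstream <- function(path, stage) {
  if (!file.exists(path)) {
    abort(paste0(
      "missing upstream output for ", stage, ": ", path,
      " (run the earlier stages first)"
    ), class = "bgcdiel_dependency_error")
  }
  path
}

#' Stage 1: simulate a synthetic experiment
#'
#' Generates a synthetic wet-up experiment from `config$seed` and writes the
#' fixture (including truth tables) to `config$output_dir`, along with a JSON
#' manifest recording the seed and thresholds.
#'
#' @param config A [pipeline_config()]; simulation knobs beyond the seed come
#'   from `sim` (a [sim_config()]; its seed is overridden by `config$seed`).
#' @param sim Optional [sim_config()] to override generator defaults.
#' @return The simulated `bgc_sim`, invisibly; files as side effect.
#' @export
run_simulate <- function(config, sim = NULL) {
  sim_cfg <- sim %||% sim_config(seed = config$seed)
  sim_cfg$seed <- config$seed
  sim_cfg <- validate_sim_config(sim_cfg)
  result <- simulate_bgc_experiment(sim_cfg)
  out <- pipeline_out(config)
  write_fixture(result, out)
  write_manifest(config, "simulate", list(
    n_genes = nrow(result$genes), n_bgcs = nrow(result$bgcs),
    n_samples = nrow(result$metadata)
  ))
  invisible(result)
}

#' Stage 2: annotate the BGC inventory
#'
#' Reads contigs, genes, BGCs and alignment hits from `config$input_dir`,
#' restricts to BGCs on eligible contigs, fills in full-length, novelty, and
#' taxonomy calls, and writes `bgc_annotated.tsv` plus per-assembly and
#' per-phylum `inventory_*.tsv` summaries.
#'
#' @param config A [pipeline_config()].
#' @return The annotated BGC tibble, invisibly.
#' @export
run_annotate <- function(config) {
  ind <- config$input_dir %||% abort("pipeline config has no input_dir",
    class = "bgcdiel_config_error"
  )
  contigs <- readr::read_tsv(file.path(ind, "contigs.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  bgcs <- readr::read_tsv(file.path(ind, "bgcs.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  hits <- read_blast_tab(file.path(ind, "hits.tsv"))
  ok_contigs <- eligible_contigs(contigs, config$min_contig_len)
  annotated <- bgcs %>%
    filter(.data$contig_id %in% ok_contigs$contig_id) %>%
    classify_full_length(contigs, edge_margin = config$edge_margin) %>%
    classify_novelty(hits,
      min_identity = config$min_identity,
      min_coverage = config$min_coverage
    ) %>%
    assign_taxonomy(hits,
      max_evalue = config$max_evalue,
      min_bitscore = config$min_bitscore
    )
  out <- pipeline_out(config)
  readr::write_tsv(annotated, file.path(out, "bgc_annotated.tsv"))
  readr::write_tsv(
    summarize_inventory(annotated, contigs, by = "assembly"),
    file.path(out, "inventory_by_assembly.tsv")
  )
  readr::write_tsv(
    summarize_inventory(annotated, by = "phylum"),
    file.path(out, "inventory_by_phylum.tsv")
  )
  write_manifest(config, "annotate", list(
    n_bgcs = nrow(annotated),
    n_contigs_eligible = nrow(ok_contigs)
  ))
  invisible(annotated)
}

#' Stage 3: expression pipeline
#'
#' Reads raw counts, metadata, and gene annotations from `config$input_dir`,
#' runs filter, normalize, collapse, and z-score stages, computes
#' transcription breadth and constitutive classification on raw counts, and
#' writes gene and BGC profiles, peak assignments, breadth distributions,
#' constitutive fractions, and the zero-variance exclusion report.
#'
#' @param config A [pipeline_config()].
#' @return A list of the stage tables, invisibly.
#' @export
run_expression <- function(config) {
  ind <- config$input_dir %||% abort("pipeline config has no input_dir",
    class = "bgcdiel_config_error"
  )
  counts <- read_count_matrix(file.path(ind, "counts.tsv"), stage = "raw")
  meta <- read_sample_metadata(file.path(ind, "sample_metadata.tsv"))
  genes <- read_gene_gff3(file.path(ind, "genes.gff3"))
  n_tp <- nrow(timepoint_groups(meta))

  filtered <- filter_low_counts(counts, config$min_max_count)
  if (nrow(filtered) == 0) {
    warn("all genes removed by the low-count filter; profile outputs are empty")
  }
  profiles <- NULL
  if (nrow(filtered) > 0) {
    profiles <- filtered %>%
      normalize_totals() %>%
      collapse_replicates(meta) %>%
      zscore_profiles()
  } else {
    profiles <- tibble(entity_id = character())
    attr(profiles, "excluded") <- tibble(entity_id = character(), reason = character())
  }
  breadth <- transcription_breadth(counts, meta, config$constitutive_threshold)
  constitutive <- classify_constitutive(breadth, n_timepoints = n_tp)
  fractions <- constitutive_fractions(constitutive, genes)
  dists <- purrr::map_dfr(
    intersect(c("secondary", "core", "background"), unique(genes$gene_set)),
    ~ breadth_distribution(breadth, genes, .x, n_timepoints = n_tp)
  ) %>%
    bind_rows(breadth_distribution(breadth, n_timepoints = n_tp))

  out <- pipeline_out(config)
  bgc_prof <- NULL
  peaks <- NULL
  if (nrow(profiles) > 0) {
    readr::write_tsv(as_tibble(profiles), file.path(out, "gene_profiles.tsv"))
    bgc_prof <- bgc_profiles(profiles, genes)
    readr::write_tsv(as_tibble(bgc_prof), file.path(out, "bgc_profiles.tsv"))
    peaks <- assign_peak(bgc_prof, meta)
    readr::write_tsv(peaks, file.path(out, "bgc_peaks.tsv"))
  } else {
    readr::write_tsv(tibble(entity_id = character()), file.path(out, "gene_profiles.tsv"))
    readr::write_tsv(tibble(entity_id = character()), file.path(out, "bgc_profiles.tsv"))
  }
  readr::write_tsv(constitutive, file.path(out, "constitutive.tsv"))
  readr::write_tsv(fractions, file.path(out, "constitutive_fractions.tsv"))
  readr::write_tsv(dists, file.path(out, "breadth_distribution.tsv"))
  readr::write_tsv(excluded_entities(profiles), file.path(out, "profile_exclusions.tsv"))
  write_manifest(config, "expression", list(
    n_genes_in = nrow(counts), n_genes_filtered = nrow(filtered),
    n_profiles = nrow(profiles)
  ))
  invisible(list(
    profiles = profiles, bgc_profiles = bgc_prof, peaks = peaks,
    breadth = breadth, constitutive = constitutive,
    fractions = fractions, distributions = dists
  ))
}

#' Stage 4: co-occurrence network and phylum correlations
#'
#' Reads the BGC profiles (from [run_expression()]) and annotated BGC table
#' (from [run_annotate()]), builds the r-thresholded co-occurrence network,
#' the phylum-level correlation table, and the per-phylum night-peak
#' summary, and writes `network_edges.tsv`, `network.graphml`,
#' `phylum_correlations.tsv`, and `night_peak_summary.tsv`.
#'
#' @param config A [pipeline_config()]; profiles are read from
#'   `config$output_dir` and annotations from there too.
#' @return A list with `network`, `phylum_correlations`, `peak_summary`,
#'   invisibly.
#' @export
run_network <- function(config) {
  out <- pipeline_out(config)
  prof_path <- require_upstream(file.path(out, "bgc_profiles.tsv"), "network")
  anno_path <- require_upstream(file.path(out, "bgc_annotated.tsv"), "network")
  prof <- readr::read_tsv(prof_path, show_col_types = FALSE, progress = FALSE)
  if (nrow(prof) < 2) {
    abort("fewer than 2 BGC profiles available; cannot build a network",
      class = "bgcdiel_insufficient_data_error"
    )
  }
  annotated <- readr::read_tsv(anno_path, show_col_types = FALSE, progress = FALSE)
  meta <- read_sample_metadata(
    require_upstream(file.path(config$input_dir, "sample_metadata.tsv"), "network")
  )
  net <- build_bgc_network(prof,
    node_attrs = annotated,
    r_threshold = config$r_threshold, correction = config$correction
  )
  phyla <- tryCatch(
    phylum_correlations(prof, annotated, correction = config$correction),
    bgcdiel_insufficient_groups_error = function(e) {
      warn(conditionMessage(e))
      NULL
    }
  )
  peaks <- assign_peak(prof, meta)
  peak_summary <- phylum_peak_summary(peaks, annotated)

  export_network(net, file.path(out, "network_edges.tsv"), "edge_list_tsv")
  export_network(net, file.path(out, "network.graphml"), "graphml")
  if (!is.null(phyla)) {
    readr::write_tsv(phyla, file.path(out, "phylum_correlations.tsv"))
  }
  readr::write_tsv(peak_summary, file.path(out, "night_peak_summary.tsv"))
  write_manifest(config, "network", list(
    n_nodes = nrow(net$nodes), n_edges = nrow(net$edges)
  ))
  invisible(list(
    network = net, phylum_correlations = phyla, peak_summary = peak_summary
  ))
}

#' Stage 5: collated human-readable report
#'
#' Collates the inventory, constitutive fractions, night-peak fractions, and
#' top phylum correlations of the earlier stages into one plain-text report;
#' every number is re-read from the stage outputs, so the report is
#' byte-consistent with them.
#'
#' @param config A [pipeline_config()].
#' @return The report lines, invisibly; writes `report.txt`.
#' @export
run_report <- function(config) {
  out <- pipeline_out(config)
  inv <- readr::read_tsv(
    require_upstream(file.path(out, "inventory_by_assembly.tsv"), "report"),
    show_col_types = FALSE, progress = FALSE
  )
  fractions <- readr::read_tsv(
    require_upstream(file.path(out, "constitutive_fractions.tsv"), "report"),
    show_col_types = FALSE, progress = FALSE
  )
  peak_summary <- readr::read_tsv(
    require_upstream(file.path(out, "night_peak_summary.tsv"), "report"),
    show_col_types = FALSE, progress = FALSE
  )
  net <- read_network(file.path(out, "network_edges.tsv"), "edge_list_tsv")
  phyla_path <- file.path(out, "phylum_correlations.tsv")
  phyla <- if (file.exists(phyla_path)) {
    readr::read_tsv(phyla_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  total <- inv %>% filter(.data$group == "total")
  night <- peak_summary %>%
    distinct(.data$phylum, .data$n_total, .data$night_fraction)
  lines <- c(
    "BGC inventory and diel transcription report",
    "===========================================",
    "",
    sprintf(
      "Inventory: %d BGCs (%d full-length, %d previously sequenced, %.1f%% novel, %.2f Mb cumulative span)",
      total$n_bgcs, total$n_full_length, total$n_known, total$pct_novel,
      total$cumulative_mb
    ),
    "",
    "Constitutive transcription by gene set:",
    sprintf(
      "  %-12s %6d genes, %5d constitutive (%.1f%%)",
      fractions$gene_set, fractions$n_genes, fractions$n_constitutive,
      fractions$pct
    ),
    "",
    "Night-peaking BGC fraction by phylum:",
    sprintf(
      "  %-18s %4d BGCs, %.1f%% peaking at night",
      night$phylum, night$n_total, 100 * night$night_fraction
    ),
    "",
    sprintf(
      "Co-occurrence network: %d nodes, %d edges (r > %s)",
      nrow(net$nodes), nrow(net$edges), format(net$r_threshold)
    )
  )
  if (!is.null(phyla) && nrow(phyla) > 0) {
    top <- phyla[1, ]
    lines <- c(lines, "", sprintf(
      "Top phylum correlation: %s ~ %s, r = %.3f (adjusted p = %.3g, %s)",
      top$phylum_a, top$phylum_b, top$r, top$p_adj, config$correction
    ))
  }
  readr::write_lines(lines, file.path(out, "report.txt"))
  invisible(lines)
}
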
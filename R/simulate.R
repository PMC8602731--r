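#' Diel expression templates
#'
#' Expected-count multipliers over the 10 chronological timepoint groups for
#' the three gene behaviours the generator plants: night-peaking (maximum at
#' 11.5 h, elevated at 18 h), day-peaking (maxima at 9 h and 72 h), and flat
#' (housekeeping). The wetting pulse and dry-down decay are applied on top of
#' these templates.
#'
#' @param phase `"night"`, `"day"`, or `"flat"`.
#' @return A named numeric vector of length 10 (names are replicate groups in
#'   chronological order).
#' @keywords internal
diel_template <- function(phase) {
  groups <- timepoint_groups(canonical_sample_metadata())$replicate_group
  m <- switch(phase,
    night = c(0.5, 0.5, 0.6, 0.5, 1.0, 4.0, 2.5, 0.9, 0.8, 0.5),
    day   = c(0.5, 0.6, 0.7, 0.6, 2.0, 0.6, 0.5, 4.0, 1.8, 0.8),
    flat  = rep(1, 10),
    abort(paste0("unknown phase: ", phase))
  )
  setNames(m, groups)
}

# genus used when a simulated subject sequence is labelled with a phylum
sim_genus_for <- function(phylum) {
  map <- c(
    Cyanobacteria = "Microcoleus", Proteobacteria = "Sphingomonas",
    Actinobacteria = "Rubrobacter", Bacteroidetes = "Segetibacter",
    Chloroflexi = "Roseiflexus"
  )
  ifelse(phylum %in% names(map), unname(map[phylum]), paste0(phylum, "_gen"))
}

# deterministic "first k of a shuffled index" helper; k = round(frac * n)
pick_fraction <- function(n, frac) {
  k <- round(frac * n)
  if (k == 0) integer(0) else sample.int(n, k)
}

#' Simulate a wet-up BGC transcription experiment
#'
#' Generates a community of contigs, BGCs, genes, alignment hits, and a
#' 13-sample diel transcript-count matrix with known ground truth. Counts are
#' negative-binomial with gene-level means that follow phylum-specific diel
#' templates, a wetting pulse at 15 min and 1 h, an exponential dry-down decay
#' after 72 h, and per-sample library-size factors. Replicates of a timepoint
#' share a mean and differ only by count noise and library size.
#'
#' Ground truth planted by the generator (and recorded in `$truth`):
#' * constitutive genes (expected to exceed the mapped-transcript threshold at
#'   every timepoint) versus low-expression non-constitutive genes;
#' * each BGC's diel phase (night or day peak), phylum, and genus;
#' * full-length status (interior placement) versus truncation at a contig
#'   edge;
#' * novelty: "known" BGCs receive alignment hits far above the
#'   identity/coverage thresholds, "novel" BGCs only weak (but
#'   taxonomy-informative) hits.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `bgc_sim` with elements `contigs`, `genes`, `bgcs`,
#'   `hits`, `counts` (raw count tibble, genes x samples), `metadata`,
#'   `truth` (list of `genes` and `bgcs` truth tibbles), and `config`.
#' @examples
#' sim <- simulate_bgc_experiment(sim_config(seed = 7, n_bgcs = 20,
#'   n_background_genes = 50))
#' dim(sim$counts)
#' @export
simulate_bgc_experiment <- function(config) {
  config <- validate_sim_config(config)
  withr::with_seed(config$seed, simulate_bgc_experiment_impl(config))
}

simulate_bgc_experiment_impl <- function(cfg) {
  meta <- canonical_sample_metadata()
  groups <- timepoint_groups(meta)
  ps <- cfg$phylum_specs

  ## ---- contigs -------------------------------------------------------
  contigs <- tibble(
    contig_id = sprintf("contig%04d", seq_len(cfg$n_contigs)),
    length = sample(
      seq(cfg$contig_length_range[1], cfg$contig_length_range[2]),
      cfg$n_contigs,
      replace = TRUE
    ),
    assembly_id = sprintf(
      "asm%02d", sample.int(cfg$n_assemblies, cfg$n_contigs, replace = TRUE)
    )
  )

  ## ---- BGCs ----------------------------------------------------------
  n_bgc <- cfg$n_bgcs
  bgc_id <- sprintf("bgc%04d", seq_len(n_bgc))
  n_genes_bgc <- sample(
    seq(cfg$genes_per_bgc_range[1], cfg$genes_per_bgc_range[2]),
    n_bgc,
    replace = TRUE
  )
  gene_slot <- 1500L # bp per gene footprint inside a cluster
  span <- n_genes_bgc * gene_slot
  phylum_bgc <- sample(ps$name, n_bgc, replace = TRUE, prob = ps$relative_abundance)
  classes <- c("terpene", "NRPS", "T1PKS", "RiPP", "bacteriocin", "phenazine", "hybrid")
  bgc_class <- sample(classes, n_bgc,
    replace = TRUE,
    prob = c(0.25, 0.2, 0.15, 0.18, 0.12, 0.04, 0.06)
  )

  truncated <- logical(n_bgc)
  truncated[pick_fraction(n_bgc, cfg$frac_truncated)] <- TRUE
  known <- logical(n_bgc)
  known[pick_fraction(n_bgc, cfg$frac_known)] <- TRUE

  # phase: an exact phase_fidelity fraction of each phylum's BGCs adopt the
  # phylum's phase (consistent with the exact-count planting of the other
  # truth flags); the remainder are flipped
  phylum_phase <- setNames(ps$peak_phase, ps$name)
  keep <- logical(n_bgc)
  for (ph in unique(phylum_bgc)) {
    idx <- which(phylum_bgc == ph)
    keep[idx[pick_fraction(length(idx), cfg$phase_fidelity)]] <- TRUE
  }
  phase_bgc <- ifelse(keep, phylum_phase[phylum_bgc],
    ifelse(phylum_phase[phylum_bgc] == "night", "day", "night")
  )

  # placement: interior BGCs leave >= 1 bp on both sides; truncated BGCs
  # abut the left or right contig edge
  bgc_start <- integer(n_bgc)
  bgc_contig <- character(n_bgc)
  for (i in seq_len(n_bgc)) {
    ok <- which(contigs$length >= span[i] + 2L)
    if (length(ok) == 0) {
      config_error("contig_length_range", "too short to host the largest BGC")
    }
    ci <- if (length(ok) == 1) ok else sample(ok, 1)
    clen <- contigs$length[ci]
    bgc_contig[i] <- contigs$contig_id[ci]
    if (truncated[i]) {
      bgc_start[i] <- if (runif(1) < 0.5) 0L else clen - span[i]
    } else {
      bgc_start[i] <- sample(seq(1L, clen - span[i] - 1L), 1)
    }
  }
  bgcs <- tibble(
    bgc_id = bgc_id,
    contig_id = bgc_contig,
    start = bgc_start,
    end = bgc_start + span,
    bgc_class = bgc_class
  )

  ## ---- genes ---------------------------------------------------------
  # secondary (BGC) genes, laid end-to-end inside the cluster span
  sec <- purrr::map_dfr(seq_len(n_bgc), function(i) {
    k <- n_genes_bgc[i]
    offs <- bgc_start[i] + (seq_len(k) - 1L) * gene_slot
    tibble(
      contig_id = bgc_contig[i],
      start = offs + 50L,
      end = offs + gene_slot - 50L,
      strand = sample(c("+", "-"), k, replace = TRUE),
      category = sample(c("core_biosynthetic", "additional_biosynthetic"),
        k,
        replace = TRUE, prob = c(0.35, 0.65)
      ),
      bgc_id = bgc_id[i],
      gene_set = "secondary",
      phylum = phylum_bgc[i],
      phase = phase_bgc[i]
    )
  })

  place_free_genes <- function(n, gene_set, phase) {
    if (n == 0) {
      return(tibble())
    }
    ci <- sample.int(nrow(contigs), n, replace = TRUE)
    glen <- 900L
    start <- floor(runif(n, min = 1, max = contigs$length[ci] - glen - 1))
    tibble(
      contig_id = contigs$contig_id[ci],
      start = as.integer(start),
      end = as.integer(start) + glen,
      strand = sample(c("+", "-"), n, replace = TRUE),
      category = "other",
      bgc_id = NA_character_,
      gene_set = gene_set,
      phylum = sample(ps$name, n, replace = TRUE, prob = ps$relative_abundance),
      phase = phase
    )
  }
  bg <- place_free_genes(cfg$n_background_genes, "background", NA_character_)
  if (nrow(bg) > 0) {
    # background genes follow their phylum's diel phase
    bg$phase <- unname(phylum_phase[bg$phylum])
  }
  core <- place_free_genes(cfg$n_core_genes, "core", "flat")

  genes <- bind_rows(sec, bg, core)
  genes$gene_id <- sprintf("g%06d", seq_len(nrow(genes)))
  genes <- genes %>%
    select(
      "gene_id", "contig_id", "start", "end", "strand",
      "category", "bgc_id", "gene_set", "phylum", "phase"
    )

  ## ---- constitutive flags and gene-level means -----------------------
  is_const <- logical(nrow(genes))
  for (set in c("secondary", "background", "core")) {
    idx <- which(genes$gene_set == set)
    frac <- switch(set,
      secondary = cfg$frac_constitutive,
      background = cfg$frac_constitutive_background,
      core = cfg$frac_constitutive_core
    )
    is_const[idx[pick_fraction(length(idx), frac)]] <- TRUE
  }
  base_of <- setNames(ps$base_expression, ps$name)
  core_base <- 3 # flat housekeeping baseline, below the constitutive regime
  base <- ifelse(genes$gene_set == "core", core_base, base_of[genes$phylum])
  gene_mean <- ifelse(
    is_const,
    cfg$constitutive_expression,
    rlnorm(nrow(genes), meanlog = log(base), sdlog = cfg$gene_expression_sdlog)
  )

  ## ---- expected counts and NB sampling -------------------------------
  pulse <- ifelse(groups$timepoint_hours %in% c(0.25, 1), cfg$wetting_pulse_fold, 1)
  decay <- ifelse(groups$timepoint_hours > 72,
    exp(-cfg$drydown_rate * (groups$timepoint_hours - 72)), 1
  )
  phase_levels <- c("night", "day", "flat")
  # per-phase expected multiplier at each timepoint group (chronological)
  group_mult <- sapply(phase_levels, function(p) diel_template(p) * pulse * decay)
  lib <- runif(13, cfg$library_size_range[1], cfg$library_size_range[2])
  sample_group_idx <- match(meta$replicate_group, groups$replicate_group)

  # constitutive genes are steadily transcribed: their diel amplitude is
  # strongly damped (multiplier^damping), which also keeps per-sample totals
  # stable so the diel signal of the remaining genes survives total-count
  # normalization
  phase_idx <- match(genes$phase, phase_levels)
  damp <- ifelse(is_const, cfg$constitutive_damping, 1)
  mu <- matrix(0, nrow = nrow(genes), ncol = 13)
  for (s in seq_len(13)) {
    mu[, s] <- gene_mean *
      group_mult[sample_group_idx[s], phase_idx]^damp * lib[s]
  }
  counts_mat <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = cfg$dispersion),
    nrow = nrow(mu)
  )
  colnames(counts_mat) <- meta$sample_id
  counts <- bind_cols(tibble(gene_id = genes$gene_id), as_tibble(counts_mat))
  attr(counts, "stage") <- "raw"

  ## ---- alignment hits -------------------------------------------------
  hits <- purrr::map_dfr(seq_len(n_bgc), function(i) {
    qlen <- span[i]
    subj <- paste(phylum_bgc[i], sim_genus_for(phylum_bgc[i]),
      sprintf("ref%05d", i),
      sep = "|"
    )
    if (known[i]) {
      # two overlapping high-identity hits to one subject, union ~95% of query
      b1 <- tibble(
        query_id = bgc_id[i], subject_id = subj,
        percent_identity = runif(1, 85, 97),
        qstart = 0L, qend = as.integer(round(0.55 * qlen)),
        evalue = 1e-80, bitscore = runif(1, 800, 1500)
      )
      b2 <- tibble(
        query_id = bgc_id[i], subject_id = subj,
        percent_identity = runif(1, 85, 97),
        qstart = as.integer(round(0.50 * qlen)),
        qend = as.integer(round(0.95 * qlen)),
        evalue = 1e-60, bitscore = runif(1, 600, 1200)
      )
      out <- bind_rows(b1, b2)
    } else {
      # weak hit: taxonomy-informative, far below novelty thresholds
      qs <- as.integer(round(runif(1, 0, 0.4) * qlen))
      cov <- runif(1, 0.25, 0.45)
      out <- tibble(
        query_id = bgc_id[i], subject_id = subj,
        percent_identity = runif(1, 55, 65),
        qstart = qs, qend = as.integer(qs + round(cov * qlen)),
        evalue = 1e-15, bitscore = runif(1, 100, 300)
      )
    }
    if (runif(1) < 0.3) {
      # decoy failing the taxonomy retention filter (E-value and bitscore)
      wrong <- sample(setdiff(ps$name, phylum_bgc[i]), 1)
      out <- bind_rows(out, tibble(
        query_id = bgc_id[i],
        subject_id = paste(wrong, sim_genus_for(wrong), "decoy", sep = "|"),
        percent_identity = runif(1, 90, 99),
        qstart = 0L, qend = qlen,
        evalue = 1e-4, bitscore = runif(1, 30, 55)
      ))
    }
    out
  })
  hits <- hits %>%
    mutate(
      alignment_length = .data$qend - .data$qstart,
      mismatch = as.integer(round((1 - .data$percent_identity / 100) *
        .data$alignment_length)),
      gapopen = 0L,
      sstart = 1L,
      send = .data$alignment_length,
      subject_phylum = stringr::str_split_i(.data$subject_id, stringr::fixed("|"), 1),
      subject_genus = stringr::str_split_i(.data$subject_id, stringr::fixed("|"), 2)
    ) %>%
    select(
      "query_id", "subject_id", "percent_identity", "alignment_length",
      "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
      "evalue", "bitscore", "subject_phylum", "subject_genus"
    )

  ## ---- truth tables ---------------------------------------------------
  peak_of <- function(phase) {
    v <- group_mult[, match(phase, phase_levels)]
    groups$timepoint_hours[which.max(v)] # which.max takes the earliest tie
  }
  truth_genes <- genes %>%
    mutate(
      is_constitutive = is_const,
      expected_mean = gene_mean,
      peak_timepoint = purrr::map_dbl(.data$phase, function(p) {
        if (is.na(p)) NA_real_ else peak_of(p)
      })
    ) %>%
    select(
      "gene_id", "bgc_id", "gene_set", "phylum", "phase",
      "is_constitutive", "expected_mean", "peak_timepoint"
    )
  truth_bgcs <- tibble(
    bgc_id = bgc_id,
    phylum = phylum_bgc,
    genus = sim_genus_for(phylum_bgc),
    phase = unname(phase_bgc),
    is_full_length = !truncated,
    is_novel = !known,
    peak_timepoint = purrr::map_dbl(phase_bgc, peak_of),
    peak_is_night = purrr::map_dbl(phase_bgc, peak_of) %in% c(11.5, 18)
  )

  out <- list(
    contigs = contigs,
    genes = genes %>% select(-"phylum", -"phase"),
    bgcs = bgcs,
    hits = hits,
    counts = counts,
    metadata = meta,
    truth = list(genes = truth_genes, bgcs = truth_bgcs),
    config = cfg
  )
  class(out) <- "bgc_sim"
  out
}

#' @export
print.bgc_sim <- function(x, ...) {
  cat("<bgc_sim> synthetic wet-up experiment\n")
  cat(
    "  ", nrow(x$contigs), "contigs |", nrow(x$bgcs), "BGCs |",
    nrow(x$genes), "genes |", nrow(x$metadata), "samples\n"
  )
  cat(
    "  constitutive genes:", sum(x$truth$genes$is_constitutive),
    "| full-length BGCs:", sum(x$truth$bgcs$is_full_length),
    "| novel BGCs:", sum(x$truth$bgcs$is_novel), "\n"
  )
  invisible(x)
}
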
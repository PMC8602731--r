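#' Default phylum composition for simulated biocrust communities
#'
#' A cyanobacteria-dominated community typical of early-successional biocrust:
#' filamentous cyanobacteria are the most abundant phylum and up-regulate
#' secondary metabolism at night, while the heterotrophic phyla peak during
#' the day. Bacteroidetes are given a night phase so that their simulated BGC
#' transcription tracks the cyanobacteria, mirroring the cyanosphere
#' association seen in biocrust.
#'
#' `base_expression` is the median per-sample transcript count of a typical
#' (non-constitutive) gene of that phylum at an unremarkable timepoint.
#'
#' @return A tibble with columns `name`, `relative_abundance`, `peak_phase`
#'   (`"night"` or `"day"`), and `base_expression`.
#' @export
default_phylum_specs <- function() {
  tibble(
    name = c(
      "Cyanobacteria", "Proteobacteria", "Actinobacteria",
      "Bacteroidetes", "Chloroflexi"
    ),
    relative_abundance = c(0.55, 0.15, 0.14, 0.10, 0.06),
    peak_phase = c("night", "day", "day", "night", "day"),
    base_expression = c(5, 4, 4, 4, 3)
  )
}

#' Configuration for the synthetic wet-up experiment generator
#'
#' Collects every knob of the generator with defaults chosen to emulate the
#' study conditions: a 13-sample / 10-timepoint design, a cyanobacteria-heavy
#' community with phylum-specific diel phases, a strong transcript surge at
#' 15 min and 1 h after wetting, overdispersed negative-binomial counts, a
#' small fraction of constitutively transcribed genes, and BGC inventories in
#' which a fixed fraction are truncated at a contig edge or already present in
#' reference databases.
#'
#' @param seed Integer seed; fully determines all generator output.
#' @param phylum_specs Tibble of phylum name, relative abundance, diel peak
#'   phase, and baseline expression (see [default_phylum_specs()]); relative
#'   abundances must sum to 1.
#' @param n_contigs,contig_length_range Number of contigs and their length
#'   range in bp.
#' @param n_assemblies Number of assemblies contigs are attributed to.
#' @param n_bgcs,genes_per_bgc_range Number of BGCs and the range of
#'   biosynthetic genes each contains.
#' @param n_background_genes Genes outside BGCs ("non-secondary" genes).
#' @param n_core_genes Size of the core housekeeping panel (DNA-binding and
#'   ribosomal proteins) used for the core-vs-secondary comparison.
#' @param frac_constitutive Fraction of secondary (BGC) genes planted as
#'   constitutively transcribed.
#' @param frac_constitutive_background,frac_constitutive_core Constitutive
#'   fractions for background and core genes.
#' @param constitutive_expression Per-sample mean count of a constitutive
#'   gene; must keep every timepoint above the mapped-transcript threshold
#'   with near certainty.
#' @param constitutive_damping Exponent in (0, 1] applied to the diel
#'   multiplier of constitutive genes: they are steadily transcribed, so
#'   their temporal amplitude is damped (default 0.5, i.e. square-root
#'   compression) while still following their cluster's phase.
#' @param gene_expression_sdlog Log-sd of the lognormal spread of per-gene
#'   baseline means around the phylum baseline.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed); shared by all genes.
#' @param wetting_pulse_fold Multiplier applied to expected counts at the
#'   15 min and 1 h timepoints, emulating the post-wetting transcript surge.
#' @param drydown_rate Exponential decay rate (per hour) applied to expected
#'   counts after the 72 h dry-down.
#' @param library_size_range Range of per-sample relative sequencing-depth
#'   factors.
#' @param frac_truncated Fraction of BGCs placed touching a contig edge
#'   (therefore not full-length).
#' @param frac_known Fraction of BGCs given alignment hits exceeding the
#'   known-BGC identity/coverage thresholds.
#' @param phase_fidelity Probability that a BGC adopts its phylum's diel
#'   phase; the remainder adopt the opposite phase.
#' @return A validated `bgc_sim_config` list.
#' @seealso [simulate_bgc_experiment()]
#' @export
sim_config <- function(seed = 1L,
                       phylum_specs = default_phylum_specs(),
                       n_contigs = 120,
                       contig_length_range = c(10000L, 150000L),
                       n_assemblies = 3L,
                       n_bgcs = 200L,
                       genes_per_bgc_range = c(4L, 10L),
                       n_background_genes = 1000L,
                       n_core_genes = 46L,
                       frac_constitutive = 0.06,
                       frac_constitutive_background = 0.045,
                       frac_constitutive_core = 0.18,
                       constitutive_expression = 300,
                       constitutive_damping = 0.5,
                       gene_expression_sdlog = 0.3,
                       dispersion = 10,
                       wetting_pulse_fold = 3,
                       drydown_rate = 0.005,
                       library_size_range = c(0.8, 1.2),
                       frac_truncated = 0.2,
                       frac_known = 0.06,
                       phase_fidelity = 0.8) {
  cfg <- list(
    seed = seed,
    phylum_specs = as_tibble(phylum_specs),
    n_contigs = n_contigs,
    contig_length_range = contig_length_range,
    n_assemblies = n_assemblies,
    n_bgcs = n_bgcs,
    genes_per_bgc_range = genes_per_bgc_range,
    n_background_genes = n_background_genes,
    n_core_genes = n_core_genes,
    frac_constitutive = frac_constitutive,
    frac_constitutive_background = frac_constitutive_background,
    frac_constitutive_core = frac_constitutive_core,
    constitutive_expression = constitutive_expression,
    constitutive_damping = constitutive_damping,
    gene_expression_sdlog = gene_expression_sdlog,
    dispersion = dispersion,
    wetting_pulse_fold = wetting_pulse_fold,
    drydown_rate = drydown_rate,
    library_size_range = library_size_range,
    frac_truncated = frac_truncated,
    frac_known = frac_known,
    phase_fidelity = phase_fidelity
  )
  class(cfg) <- "bgc_sim_config"
  validate_sim_config(cfg)
}

config_error <- function(field, why) {
  abort(paste0("invalid simulation config: `", field, "` ", why),
    class = "bgcdiel_config_error"
  )
}

#' Validate a simulation configuration
#'
#' @param cfg A `bgc_sim_config` object.
#' @return `cfg`, invisibly usable, after all invariant checks.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "bgc_sim_config"))
  if (length(cfg$seed) != 1 || is.na(cfg$seed) ||
    cfg$seed != as.integer(cfg$seed)) {
    config_error("seed", "must be a single integer")
  }
  ps <- cfg$phylum_specs
  need <- c("name", "relative_abundance", "peak_phase", "base_expression")
  if (!all(need %in% names(ps)) || nrow(ps) < 1) {
    config_error("phylum_specs", paste0(
      "must have >= 1 row and columns ", paste(need, collapse = ", ")
    ))
  }
  if (abs(sum(ps$relative_abundance) - 1) > 1e-9) {
    config_error("phylum_specs", "relative abundances must sum to 1")
  }
  if (any(ps$relative_abundance <= 0)) {
    config_error("phylum_specs", "relative abundances must be positive")
  }
  if (!all(ps$peak_phase %in% c("night", "day"))) {
    config_error("phylum_specs", "peak_phase must be 'night' or 'day'")
  }
  if (any(ps$base_expression <= 0)) {
    config_error("phylum_specs", "base_expression must be positive")
  }
  counts <- c(
    n_contigs = cfg$n_contigs, n_assemblies = cfg$n_assemblies,
    n_bgcs = cfg$n_bgcs, n_core_genes = cfg$n_core_genes
  )
  for (nm in names(counts)) {
    if (length(counts[[nm]]) != 1 || counts[[nm]] < 1) {
      config_error(nm, "must be a positive count")
    }
  }
  if (length(cfg$n_background_genes) != 1 || cfg$n_background_genes < 0) {
    config_error("n_background_genes", "must be a nonnegative count")
  }
  ranges <- list(
    contig_length_range = cfg$contig_length_range,
    genes_per_bgc_range = cfg$genes_per_bgc_range,
    library_size_range = cfg$library_size_range
  )
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      config_error(nm, "must be a positive, ordered (lo, hi) pair")
    }
  }
  fracs <- c(
    frac_constitutive = cfg$frac_constitutive,
    frac_constitutive_background = cfg$frac_constitutive_background,
    frac_constitutive_core = cfg$frac_constitutive_core,
    frac_truncated = cfg$frac_truncated,
    frac_known = cfg$frac_known,
    phase_fidelity = cfg$phase_fidelity
  )
  for (nm in names(fracs)) {
    if (length(fracs[[nm]]) != 1 || fracs[[nm]] < 0 || fracs[[nm]] > 1) {
      config_error(nm, "must be a fraction in [0, 1]")
    }
  }
  positives <- c(
    constitutive_expression = cfg$constitutive_expression,
    gene_expression_sdlog = cfg$gene_expression_sdlog,
    dispersion = cfg$dispersion
  )
  for (nm in names(positives)) {
    if (length(positives[[nm]]) != 1 || positives[[nm]] <= 0) {
      config_error(nm, "must be > 0")
    }
  }
  if (length(cfg$constitutive_damping) != 1 || cfg$constitutive_damping <= 0 ||
    cfg$constitutive_damping > 1) {
    config_error("constitutive_damping", "must be in (0, 1]")
  }
  if (length(cfg$wetting_pulse_fold) != 1 || cfg$wetting_pulse_fold < 1) {
    config_error("wetting_pulse_fold", "must be >= 1")
  }
  if (length(cfg$drydown_rate) != 1 || cfg$drydown_rate < 0) {
    config_error("drydown_rate", "must be >= 0")
  }
  cfg
}

#' @export
print.bgc_sim_config <- function(x, ...) {
  cat("<bgc_sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat(
    "  community:", nrow(x$phylum_specs), "phyla (",
    paste(x$phylum_specs$name, collapse = ", "), ")\n"
  )
  cat(
    "  contigs:", x$n_contigs, " BGCs:", x$n_bgcs,
    " background genes:", x$n_background_genes,
    " core genes:", x$n_core_genes, "\n"
  )
  cat(
    "  frac constitutive (secondary/background/core):",
    x$frac_constitutive, "/", x$frac_constitutive_background, "/",
    x$frac_constitutive_core, "\n"
  )
  cat(
    "  dispersion:", x$dispersion,
    " pulse fold:", x$wetting_pulse_fold,
    " phase fidelity:", x$phase_fidelity, "\n"
  )
  invisible(x)
}
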
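# Shared synthetic fixtures, generated once per test run.

default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bgc_experiment(sim_config(seed = 1))
    }
    cache
  }
})

# small random raw count matrix with canonical sample columns
random_counts <- function(n_genes = 200, lambda = 30) {
  meta <- canonical_sample_metadata()
  m <- matrix(
    rnbinom(n_genes * nrow(meta), mu = lambda, size = 2),
    nrow = n_genes
  )
  colnames(m) <- meta$sample_id
  out <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes))),
    tibble::as_tibble(m)
  )
  attr(out, "stage") <- "raw"
  out
}

# profile tibble with arbitrary values over the canonical 10 groups
random_profiles <- function(n = 20, prefix = "e") {
  groups <- timepoint_groups(canonical_sample_metadata())$replicate_group
  m <- matrix(rnorm(n * length(groups)), nrow = n)
  colnames(m) <- groups
  dplyr::bind_cols(
    tibble::tibble(entity_id = sprintf("%s%03d", prefix, seq_len(n))),
    tibble::as_tibble(m)
  )
}
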
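#' File formats
#'
#' All pipeline stages exchange plain-text files: GFF3 for gene annotations
#' (1-based inclusive coordinates in the file, 0-based half-open in memory),
#' 12-column BLAST tabular for alignment hits, and TSV for everything else.
#' Subject taxonomy rides inside the BLAST `sseqid` field as
#' `Phylum|Genus|accession` and is parsed back on read when present.
#'
#' @name bgcdiel-io
NULL

io_abort <- function(...) abort(paste0(...), class = "bgcdiel_io_error")

#' Write/read a gene annotation table as GFF3
#'
#' Gene category is stored in a `gene_kind` attribute (antiSMASH-style
#' vocabulary), BGC membership in `bgc_id`, and the core/secondary/background
#' panel in `gene_set`.
#'
#' @param genes Gene tibble (`gene_id`, `contig_id`, `start`, `end`, `strand`,
#'   `category`, `bgc_id`, `gene_set`) with 0-based half-open coordinates.
#' @param path File path.
#' @return `write_gene_gff3()` returns `path` invisibly; `read_gene_gff3()`
#'   returns the gene tibble.
#' @export
write_gene_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = ifelse(genes$strand == ".", "*", genes$strand)
  )
  S4Vectors::mcols(gr)$source <- "bgcdiel"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$gene_kind <- genes$category
  S4Vectors::mcols(gr)$bgc_id <- genes$bgc_id
  S4Vectors::mcols(gr)$gene_set <- genes$gene_set
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_gff3
#' @export
read_gene_gff3 <- function(path) {
  if (!file.exists(path)) io_abort("no such GFF3 file: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) io_abort("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  strand <- as.character(BiocGenerics::strand(gr))
  tibble(
    gene_id = as.character(S4Vectors::mcols(gr)$ID),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand == "*", ".", strand),
    category = as.character(S4Vectors::mcols(gr)$gene_kind),
    bgc_id = as.character(S4Vectors::mcols(gr)$bgc_id),
    gene_set = as.character(S4Vectors::mcols(gr)$gene_set)
  )
}

blast_cols <- c(
  "query_id", "subject_id", "percent_identity", "alignment_length",
  "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
  "evalue", "bitscore"
)

#' Write/read alignment hits in BLAST 12-column tabular format
#'
#' The classic `outfmt 6` dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), no header, 1-based
#' inclusive query coordinates on disk. The reader tolerates `#` comment
#' lines and reports the line number of any malformed row.
#'
#' @param hits Hit tibble with 0-based half-open `qstart`/`qend`.
#' @param path File path.
#' @return `write_blast_tab()` returns `path` invisibly; `read_blast_tab()`
#'   the hit tibble (with `subject_phylum`/`subject_genus` parsed from
#'   `subject_id` when it is `|`-delimited).
#' @export
write_blast_tab <- function(hits, path) {
  out <- hits %>%
    mutate(
      qstart = .data$qstart + 1L, # to 1-based inclusive
      evalue = format(.data$evalue, digits = 3, scientific = TRUE),
      percent_identity = round(.data$percent_identity, 3),
      bitscore = round(.data$bitscore, 1)
    ) %>%
    select(all_of(blast_cols))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_blast_tab
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) io_abort("no such alignment file: ", path)
  lines <- readr::read_lines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(keep)[which(nf != 12)[1]]
    io_abort(
      "malformed alignment line ", bad, " in ", path,
      ": expected 12 tab-separated fields, found ", nf[which(nf != 12)[1]]
    )
  }
  if (length(fields) == 0) {
    return(tibble(
      query_id = character(), subject_id = character(),
      percent_identity = double(), alignment_length = integer(),
      mismatch = integer(), gapopen = integer(), qstart = integer(),
      qend = integer(), sstart = integer(), send = integer(),
      evalue = double(), bitscore = double(),
      subject_phylum = character(), subject_genus = character()
    ))
  }
  m <- do.call(rbind, fields)
  numf <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      bad <- which(keep)[which(is.na(v))[1]]
      io_abort(
        "malformed alignment line ", bad, " in ", path,
        ": non-numeric value in column ", j
      )
    }
    v
  }
  out <- tibble(
    query_id = m[, 1], subject_id = m[, 2],
    percent_identity = numf(3), alignment_length = as.integer(numf(4)),
    mismatch = as.integer(numf(5)), gapopen = as.integer(numf(6)),
    qstart = as.integer(numf(7)) - 1L, # back to 0-based half-open
    qend = as.integer(numf(8)),
    sstart = as.integer(numf(9)), send = as.integer(numf(10)),
    evalue = numf(11), bitscore = numf(12)
  )
  has_tax <- stringr::str_detect(out$subject_id, stringr::fixed("|"))
  out$subject_phylum <- ifelse(has_tax,
    stringr::str_split_i(out$subject_id, stringr::fixed("|"), 1), NA_character_
  )
  out$subject_genus <- ifelse(has_tax,
    stringr::str_split_i(out$subject_id, stringr::fixed("|"), 2), NA_character_
  )
  out
}

#' Write/read a transcript count matrix
#'
#' TSV with a `gene_id` column followed by one column per sample. The
#' processing stage (`raw`, `filtered`, `normalized`, `collapsed`) is carried
#' as an attribute, not in the file.
#'
#' @param m Count tibble.
#' @param path File path.
#' @param stage Stage label to attach on read.
#' @return The path (writer, invisibly) or the count tibble (reader).
#' @export
write_count_matrix <- function(m, path) {
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, stage = "raw") {
  if (!file.exists(path)) io_abort("no such count matrix: ", path)
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(m)) {
    io_abort("count matrix ", path, " lacks a gene_id column")
  }
  if (stage == "raw") {
    num <- setdiff(names(m), "gene_id")
    bad <- num[!purrr::map_lgl(m[num], ~ all(.x >= 0 & .x == round(.x), na.rm = TRUE))]
    if (length(bad) > 0) {
      io_abort(
        "raw count matrix ", path, " has non-integer or negative counts in ",
        "sample(s): ", paste(bad, collapse = ", ")
      )
    }
  }
  attr(m, "stage") <- stage
  m
}

#' Write/read sample metadata
#'
#' @param meta Sample-metadata tibble (see [canonical_sample_metadata()]).
#' @param path File path.
#' @return The path (writer, invisibly) or the validated metadata tibble.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(validate_sample_metadata(meta), path)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) io_abort("no such metadata file: ", path)
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(meta)
  as_tibble(meta)
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits every table of a [simulate_bgc_experiment()] result as plain text:
#' `genes.gff3`, `contigs.tsv`, `bgcs.tsv`, `hits.tsv` (BLAST tabular),
#' `counts.tsv`, `sample_metadata.tsv`, `truth_genes.tsv`, `truth_bgcs.tsv`.
#' All files round-trip losslessly through [read_fixture()].
#'
#' @param sim A `bgc_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "bgc_sim"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) io_abort("cannot write to directory: ", dir)
  write_gene_gff3(sim$genes, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$contigs, file.path(dir, "contigs.tsv"))
  readr::write_tsv(sim$bgcs, file.path(dir, "bgcs.tsv"))
  write_blast_tab(sim$hits, file.path(dir, "hits.tsv"))
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(sim$metadata, file.path(dir, "sample_metadata.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$bgcs, file.path(dir, "truth_bgcs.tsv"))
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Directory written by [write_fixture()] (truth tables optional,
#'   as real data has none).
#' @return A list with elements `contigs`, `genes`, `bgcs`, `hits`, `counts`,
#'   `metadata`, and (if present) `truth`.
#' @export
read_fixture <- function(dir) {
  if (!dir.exists(dir)) io_abort("no such fixture directory: ", dir)
  out <- list(
    contigs = readr::read_tsv(file.path(dir, "contigs.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    genes = read_gene_gff3(file.path(dir, "genes.gff3")),
    bgcs = readr::read_tsv(file.path(dir, "bgcs.tsv"),
      show_col_types = FALSE, progress = FALSE
    ),
    hits = read_blast_tab(file.path(dir, "hits.tsv")),
    counts = read_count_matrix(file.path(dir, "counts.tsv"), stage = "raw"),
    metadata = read_sample_metadata(file.path(dir, "sample_metadata.tsv"))
  )
  tg <- file.path(dir, "truth_genes.tsv")
  tb <- file.path(dir, "truth_bgcs.tsv")
  if (file.exists(tg) && file.exists(tb)) {
    out$truth <- list(
      genes = readr::read_tsv(tg, show_col_types = FALSE, progress = FALSE),
      bgcs = readr::read_tsv(tb, show_col_types = FALSE, progress = FALSE)
    )
  }
  out
}
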
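#' The canonical wet-up sampling design
#'
#' The wetting experiment samples biocrust transcription over three diurnal
#' cycles at ten timepoints: 0 h (immediately before wetting), 3 min, 15 min
#' (duplicate), 1 h (triplicate), 9 h, 11.5 h, 18 h, 72 h (immediately before
#' dry-down), and two post-dry-down samples taken 2 h and 3 days later
#' (recorded here as 74 h and 144 h; only their chronological order matters
#' downstream). The 11.5 h and 18 h samples are collected at night; all others
#' during the day. Replicates collapse the 13 samples to 10 timepoint groups.
#'
#' @return A tibble with one row per sample and columns `sample_id`,
#'   `timepoint_hours`, `is_night`, and `replicate_group`.
#' @examples
#' canonical_sample_metadata()
#' @export
canonical_sample_metadata <- function() {
  hours <- c(0, 0.05, 0.25, 0.25, 1, 1, 1, 9, 11.5, 18, 72, 74, 144)
  groups <- c(
    "T0h", "T3min", "T15min", "T15min", "T1h", "T1h", "T1h",
    "T9h", "T11.5h", "T18h", "T72h", "T74h", "T144h"
  )
  reps <- c("", "", "a", "b", "a", "b", "c", "", "", "", "", "", "")
  tibble(
    sample_id = paste0(
      "S", sprintf("%02d", seq_along(hours)), "_", sub("^T", "", groups),
      ifelse(reps == "", "", paste0("_", reps))
    ),
    timepoint_hours = hours,
    is_night = hours %in% c(11.5, 18),
    replicate_group = groups
  )
}

#' Validate a sample-metadata table
#'
#' Checks the structural invariants expression functions rely on: required
#' columns, unique sample ids, and consistent hour / night flags within each
#' replicate group.
#'
#' @param meta A data frame with columns `sample_id`, `timepoint_hours`,
#'   `is_night`, `replicate_group`.
#' @return `meta`, invisibly, as a tibble.
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "timepoint_hours", "is_night", "replicate_group")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    abort(paste0(
      "sample metadata is missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "bgcdiel_metadata_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("sample metadata has duplicated sample_id values",
      class = "bgcdiel_metadata_error"
    )
  }
  bad <- as_tibble(meta) %>%
    group_by(.data$replicate_group) %>%
    summarise(
      n_hours = dplyr::n_distinct(.data$timepoint_hours),
      n_night = dplyr::n_distinct(.data$is_night),
      .groups = "drop"
    ) %>%
    filter(.data$n_hours > 1 | .data$n_night > 1)
  if (nrow(bad) > 0) {
    abort(paste0(
      "replicate group(s) with inconsistent hours or night flags: ",
      paste(bad$replicate_group, collapse = ", ")
    ), class = "bgcdiel_metadata_error")
  }
  invisible(as_tibble(meta))
}

#' Replicate groups in chronological order
#'
#' @param meta A sample-metadata table (see [canonical_sample_metadata()]).
#' @return A tibble with one row per replicate group, ordered by
#'   `timepoint_hours`, with columns `replicate_group`, `timepoint_hours`,
#'   `is_night`, and `n_samples`.
#' @export
timepoint_groups <- function(meta) {
  validate_sample_metadata(meta)
  as_tibble(meta) %>%
    group_by(.data$replicate_group) %>%
    summarise(
      timepoint_hours = .data$timepoint_hours[1],
      is_night = .data$is_night[1],
      n_samples = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$timepoint_hours)
}
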
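#' Call species from gel band patterns
#'
#' The decision procedure behind the assay readout. Per lane, every band is
#' compared against the assay's diagnostic key (a band matches an entry when
#' its size is within that entry's tolerance) and against the control window:
#'
#' * no bands at all: `assay_failure` -- the absence of any amplification
#'   must never be read as absence of a species (false-negative guard);
#' * bands matching two or more distinct key entries: `ambiguous`;
#' * exactly one key entry matched, control band present: `identified`;
#' * exactly one key entry matched, no control: `assay_failure` unless
#'   `waive_control = TRUE` (the whole-locus control is variably faint in
#'   practice), in which case `identified`;
#' * no key entry matched, control present: `non_target`;
#' * no key entry matched, no control: `assay_failure`.
#'
#' A band counts as the control when its `classification` is `"control"`, or
#' -- for hand-entered patterns without classifications -- when its size
#' falls inside the assay's control size window.
#'
#' @param bands a `band_pattern` from [simulate_assay()], or any tibble with
#'   `lane` and `size_bp` (optional `classification`). Lanes listed in the
#'   `lanes` attribute but absent from the table are called as empty lanes.
#' @param assay an `assay_definition`.
#' @param waive_control accept a diagnostic band without the control band.
#' @return a tibble with one row per lane: `lane`, `outcome` (`identified`,
#'   `non_target`, `assay_failure`, `ambiguous`), `taxon` (`NA` unless
#'   identified), `supporting_bands` (comma-separated sizes), `notes`.
#' @export
call_species <- function(bands, assay, waive_control = FALSE) {
  validate_assay(assay)
  bands <- tibble::as_tibble(bands)
  if (!nrow(bands) && !"lane" %in% names(bands)) {
    bands <- tibble::tibble(lane = character(0), size_bp = numeric(0))
  }
  if (!"classification" %in% names(bands)) bands$classification <- NA_character_
  lanes <- unique(c(attr(bands, "lanes"), bands$lane))
  key <- assay$diagnostic_key
  rows <- lapply(lanes, function(ln) {
    b <- bands[bands$lane == ln, ]
    if (!nrow(b)) {
      return(tibble::tibble(lane = ln, outcome = "assay_failure", taxon = NA_character_,
                            supporting_bands = "", notes = "no amplification"))
    }
    hit_taxa <- character(0); hit_sizes <- numeric(0)
    key_matched <- rep(FALSE, nrow(b))
    for (i in seq_len(nrow(key))) {
      m <- abs(b$size_bp - key$expected_bp[i]) <= key$tolerance_bp[i]
      if (any(m)) {
        hit_taxa <- c(hit_taxa, key$taxon[i])
        hit_sizes <- c(hit_sizes, b$size_bp[m][1])
        key_matched <- key_matched | m
      }
    }
    # a hand-entered band that already matches the diagnostic key never
    # doubles as the positive control
    is_control <- b$classification %in% "control" |
      (is.na(b$classification) & !key_matched &
         b$size_bp >= assay$control_size_range[1] &
         b$size_bp <= assay$control_size_range[2])
    ctrl <- any(is_control)
    if (length(hit_taxa) >= 2L) {
      tibble::tibble(lane = ln, outcome = "ambiguous", taxon = NA_character_,
                     supporting_bands = paste(sort(unique(hit_sizes)), collapse = ","),
                     notes = paste("bands match:", paste(hit_taxa, collapse = "; ")))
    } else if (length(hit_taxa) == 1L) {
      if (ctrl || waive_control) {
        tibble::tibble(lane = ln, outcome = "identified", taxon = hit_taxa,
                       supporting_bands = paste(sort(unique(c(
                         hit_sizes, b$size_bp[is_control]))), collapse = ","),
                       notes = if (ctrl) "" else "control waived")
      } else {
        tibble::tibble(lane = ln, outcome = "assay_failure", taxon = NA_character_,
                       supporting_bands = paste(hit_sizes, collapse = ","),
                       notes = "diagnostic band without positive control")
      }
    } else if (ctrl) {
      tibble::tibble(lane = ln, outcome = "non_target", taxon = NA_character_,
                     supporting_bands = paste(sort(unique(b$size_bp[is_control])),
                                              collapse = ","),
                     notes = "positive control only")
    } else {
      tibble::tibble(lane = ln, outcome = "assay_failure", taxon = NA_character_,
                     supporting_bands = paste(sort(unique(b$size_bp)), collapse = ","),
                     notes = "no control band and no diagnostic match")
    }
  })
  dplyr::bind_rows(rows)
}

#' Write species calls as TSV
#'
#' @param calls output of [call_species()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
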
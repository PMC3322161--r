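#' Read template sequences from a FASTA file
#'
#' Templates are the genomic stretches a PCR assay is run against: here,
#' typically a 5.8S--ITS2--28S ribosomal fragment per specimen. Sequences are
#' uppercased, RNA `U` is mapped to `T`, and anything outside the IUPAC DNA
#' alphabet is rejected. The taxon label is taken from the FASTA description
#' after the first whitespace when present, otherwise left `NA`.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `taxon`, `sequence` and optional
#'   region-bound columns `its2_start`, `its2_end` (1-based, closed) when the
#'   description carries an `its2=start-end` tag.
#' @seealso [write_template_fasta()], [generate_panel()]
#' @export
read_template_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not readable as FASTA: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), NA_character_)
  its2 <- stringr::str_match(ifelse(is.na(desc), "", desc), "its2=(\\d+)-(\\d+)")
  taxon <- ifelse(is.na(desc), NA_character_,
                  trimws(sub("its2=\\d+-\\d+", "", desc)))
  taxon[!is.na(taxon) & taxon == ""] <- NA_character_
  seqs <- vapply(as.character(set), normalize_dna, character(1), what = "template sequence")
  out <- tibble::tibble(
    id = id,
    taxon = unname(taxon),
    sequence = unname(seqs),
    its2_start = as.integer(its2[, 2]),
    its2_end = as.integer(its2[, 3])
  )
  validate_templates(out)
}

#' Write template sequences to FASTA
#'
#' Inverse of [read_template_fasta()]; region bounds, when present, are stored
#' as an `its2=start-end` tag in the description so a round trip preserves
#' them.
#'
#' @param templates a template tibble (`id`, `taxon`, `sequence`, optional
#'   `its2_start`/`its2_end`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template_fasta <- function(templates, path) {
  templates <- validate_templates(templates)
  desc <- rep("", nrow(templates))
  if ("taxon" %in% names(templates)) {
    desc <- ifelse(is.na(templates$taxon), desc, paste0(" ", templates$taxon))
  }
  if ("its2_start" %in% names(templates)) {
    has <- !is.na(templates$its2_start) & !is.na(templates$its2_end)
    desc[has] <- paste0(desc[has], " its2=", templates$its2_start[has], "-",
                        templates$its2_end[has])
  }
  lines <- character(0)
  for (i in seq_len(nrow(templates))) {
    lines <- c(lines,
               paste0(">", templates$id[i], desc[i]),
               gsub("(.{70})", "\\1\n", templates$sequence[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Validate a template table
#'
#' Checks ids are unique and non-empty, sequences are IUPAC DNA, and region
#' bounds (when given) are ordered and inside the sequence.
#'
#' @param templates a data frame with at least `id` and `sequence`.
#' @return the validated templates as a tibble (sequences normalized).
#' @export
validate_templates <- function(templates) {
  templates <- tibble::as_tibble(templates)
  stopifnot(all(c("id", "sequence") %in% names(templates)))
  if (any(is.na(templates$id) | templates$id == "")) stop("template ids must be non-empty")
  if (anyDuplicated(templates$id)) {
    stop("duplicate template ids: ",
         paste(unique(templates$id[duplicated(templates$id)]), collapse = ", "))
  }
  empty <- !nzchar(templates$sequence) | is.na(templates$sequence)
  if (any(empty)) {
    stop("empty sequence for template(s): ", paste(templates$id[empty], collapse = ", "))
  }
  templates$sequence <- vapply(
    seq_len(nrow(templates)),
    function(i) tryCatch(normalize_dna(templates$sequence[i]),
                         error = function(e) stop("template ", templates$id[i], ": ",
                                                  conditionMessage(e), call. = FALSE)),
    character(1)
  )
  if (!"taxon" %in% names(templates)) templates$taxon <- NA_character_
  if ("its2_start" %in% names(templates)) {
    has <- !is.na(templates$its2_start)
    len <- nchar(templates$sequence)
    ok <- !has | (templates$its2_start >= 1 &
                    templates$its2_end >= templates$its2_start &
                    templates$its2_end <= len)
    if (!all(ok)) {
      stop("invalid ITS2 bounds for template(s): ",
           paste(templates$id[!ok], collapse = ", "))
    }
  }
  templates
}
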
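PRIMER_ORIENTATIONS <- c("forward", "reverse")
PRIMER_ROLES <- c("species_specific", "universal_forward", "universal_reverse")

#' Read a primer table (TSV)
#'
#' The expected columns are `name`, `sequence`, `orientation`
#' (`forward`/`reverse`), `role` (`species_specific`, `universal_forward`,
#' `universal_reverse`), `target_taxon` and `expected_product_bp`; the last
#' two may be empty. Sequences may carry bench-style 5'/3' decorations
#' (`5'GCGAGG...3'`, with straight or typographic primes) and internal
#' whitespace; both are stripped.
#'
#' @param path path to a tab-separated primer table.
#' @return a validated primer tibble (see [validate_primers()]).
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  required <- c("name", "sequence", "orientation", "role")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("primer table missing column(s): ", paste(missing, collapse = ", "))
  if (!"target_taxon" %in% names(df)) df$target_taxon <- NA_character_
  if (!"expected_product_bp" %in% names(df)) df$expected_product_bp <- NA_integer_
  df$sequence <- vapply(df$sequence, strip_primer_decorations, character(1))
  validate_primers(tibble::as_tibble(df))
}

# "5'GCGAGGCACACCTCGGCAC3'" (straight or typographic primes, optional spaces)
# -> "GCGAGGCACACCTCGGCAC"
strip_primer_decorations <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  x <- gsub("^5[′']", "", x)
  x <- gsub("3[′']$", "", x)
  x
}

#' Write a primer table to TSV
#'
#' @param primers a primer tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  primers <- validate_primers(primers)
  utils::write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate a primer table
#'
#' Enforces the primer contract: non-empty unique names, IUPAC DNA sequences
#' of length >= 10 (uppercased, `U` mapped to `T`), known orientation and role
#' tokens, positive expected product sizes when given. Primers containing
#' IUPAC ambiguity codes are accepted and flagged in the returned `ambiguous`
#' column.
#'
#' @param primers a data frame with columns `name`, `sequence`, `orientation`,
#'   `role`, and optionally `target_taxon`, `expected_product_bp`.
#' @param min_len minimum primer length (default 10).
#' @return the validated tibble with normalized sequences and an `ambiguous`
#'   logical column.
#' @export
validate_primers <- function(primers, min_len = 10L) {
  primers <- tibble::as_tibble(primers)
  required <- c("name", "sequence", "orientation", "role")
  stopifnot(all(required %in% names(primers)))
  if (any(is.na(primers$name) | primers$name == "")) stop("primer names must be non-empty")
  if (anyDuplicated(primers$name)) {
    stop("duplicate primer names: ",
         paste(unique(primers$name[duplicated(primers$name)]), collapse = ", "))
  }
  primers$sequence <- vapply(
    seq_len(nrow(primers)),
    function(i) tryCatch(normalize_dna(primers$sequence[i], what = "primer sequence"),
                         error = function(e) stop("primer ", primers$name[i], ": ",
                                                  conditionMessage(e), call. = FALSE)),
    character(1)
  )
  short <- nchar(primers$sequence) < min_len
  if (any(short)) {
    stop("primer(s) shorter than ", min_len, " nt: ",
         paste(primers$name[short], collapse = ", "))
  }
  bad_or <- !primers$orientation %in% PRIMER_ORIENTATIONS
  if (any(bad_or)) {
    stop("unknown orientation '", primers$orientation[bad_or][1], "' for primer ",
         primers$name[bad_or][1], " (expected forward/reverse)")
  }
  bad_role <- !primers$role %in% PRIMER_ROLES
  if (any(bad_role)) {
    stop("unknown role '", primers$role[bad_role][1], "' for primer ",
         primers$name[bad_role][1],
         " (expected species_specific/universal_forward/universal_reverse)")
  }
  if (!"target_taxon" %in% names(primers)) primers$target_taxon <- NA_character_
  if (!"expected_product_bp" %in% names(primers)) primers$expected_product_bp <- NA_integer_
  primers$expected_product_bp <- as.integer(primers$expected_product_bp)
  bad_bp <- !is.na(primers$expected_product_bp) & primers$expected_product_bp <= 0L
  if (any(bad_bp)) stop("expected_product_bp must be positive for: ",
                        paste(primers$name[bad_bp], collapse = ", "))
  primers$ambiguous <- has_ambiguity(primers$sequence)
  primers[c("name", "sequence", "orientation", "role", "target_taxon",
            "expected_product_bp", "ambiguous")]
}
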
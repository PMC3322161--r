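#' Define a multiplex assay
#'
#' An assay bundles the primer mix with its gel-reading key: which universal
#' pair produces the positive control, which diagnostic band size identifies
#' which taxon (with a per-entry tolerance), and the size window in which the
#' whole-locus control band is expected.
#'
#' @param name assay label.
#' @param primers a primer tibble (see [validate_primers()]) with exactly one
#'   `universal_forward` and one `universal_reverse` primer.
#' @param diagnostic_key a tibble/data frame with columns `taxon`,
#'   `expected_bp` and optionally `tolerance_bp`.
#' @param control_size_range numeric length-2, min and max plausible control
#'   band size in bp.
#' @param tolerance_bp default tolerance applied to key entries lacking one.
#'   The default, 25 bp, reflects agarose gel size-reading precision.
#' @return an object of class `assay_definition`.
#' @export
assay_definition <- function(name, primers, diagnostic_key,
                             control_size_range = c(860, 1500),
                             tolerance_bp = 25) {
  primers <- validate_primers(primers)
  key <- tibble::as_tibble(diagnostic_key)
  stopifnot(all(c("taxon", "expected_bp") %in% names(key)))
  if (!"tolerance_bp" %in% names(key)) key$tolerance_bp <- tolerance_bp
  key$tolerance_bp[is.na(key$tolerance_bp)] <- tolerance_bp
  key$expected_bp <- as.numeric(key$expected_bp)
  x <- structure(
    list(name = name,
         primers = primers,
         control_pair = c(
           forward = primers$name[primers$role == "universal_forward"][1],
           reverse = primers$name[primers$role == "universal_reverse"][1]),
         diagnostic_key = key[c("taxon", "expected_bp", "tolerance_bp")],
         control_size_range = as.numeric(control_size_range)),
    class = "assay_definition")
  validate_assay(x)
}

#' Validate an assay definition
#'
#' Checks the structural invariants: exactly one universal primer per
#' direction; diagnostic sizes pairwise separated by more than twice the
#' larger of the two tolerances (so no band can ever match two key entries);
#' control range ordered.
#'
#' @param assay an `assay_definition`.
#' @return the assay, invisibly on success.
#' @export
validate_assay <- function(assay) {
  stopifnot(inherits(assay, "assay_definition"))
  roles <- assay$primers$role
  if (sum(roles == "universal_forward") != 1L || sum(roles == "universal_reverse") != 1L) {
    stop("assay must contain exactly one universal_forward and one universal_reverse primer")
  }
  key <- assay$diagnostic_key
  if (anyDuplicated(key$taxon)) stop("duplicate taxa in diagnostic key")
  if (nrow(key) > 1L) {
    for (i in seq_len(nrow(key) - 1L)) {
      for (j in seq.int(i + 1L, nrow(key))) {
        gap <- abs(key$expected_bp[i] - key$expected_bp[j])
        need <- 2 * max(key$tolerance_bp[i], key$tolerance_bp[j])
        if (gap <= need) {
          stop("diagnostic sizes for ", key$taxon[i], " and ", key$taxon[j],
               " are only ", gap, " bp apart (need > ", need, ")")
        }
      }
    }
  }
  r <- assay$control_size_range
  if (length(r) != 2L || !(r[1] < r[2])) stop("control_size_range must be (min, max) with min < max")
  invisible(assay)
}

#' @export
print.assay_definition <- function(x, ...) {
  cat("<assay_definition> ", x$name, "\n", sep = "")
  cat("  primers: ", nrow(x$primers), " (",
      sum(x$primers$role == "species_specific"), " species-specific + universal pair ",
      paste(x$control_pair, collapse = "/"), ")\n", sep = "")
  cat("  control band window: ", x$control_size_range[1], "-",
      x$control_size_range[2], " bp\n", sep = "")
  cat("  diagnostic key:\n")
  k <- x$diagnostic_key[order(x$diagnostic_key$expected_bp), ]
  for (i in seq_len(nrow(k))) {
    cat(sprintf("    %-18s %5.0f bp (+/- %.0f)\n", k$taxon[i], k$expected_bp[i],
                k$tolerance_bp[i]))
  }
  invisible(x)
}

#' Write an assay definition to a YAML file
#'
#' @param assay an `assay_definition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_yaml <- function(assay, path) {
  validate_assay(assay)
  obj <- list(
    name = assay$name,
    control_size_range = as.numeric(assay$control_size_range),
    primers = lapply(seq_len(nrow(assay$primers)), function(i) {
      p <- as.list(assay$primers[i, c("name", "sequence", "orientation", "role",
                                      "target_taxon", "expected_product_bp")])
      p[!vapply(p, function(v) length(v) == 1 && is.na(v), logical(1))]
    }),
    diagnostic_key = lapply(seq_len(nrow(assay$diagnostic_key)), function(i) {
      as.list(assay$diagnostic_key[i, ])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an assay definition from YAML
#'
#' @param path path to a YAML file written by [write_assay_yaml()] (or edited
#'   by hand in the same structure).
#' @return an `assay_definition`.
#' @export
read_assay_yaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- yaml::read_yaml(path)
  primers <- dplyr::bind_rows(lapply(obj$primers, function(p) {
    tibble::tibble(
      name = p$name, sequence = p$sequence, orientation = p$orientation,
      role = p$role,
      target_taxon = p$target_taxon %||% NA_character_,
      expected_product_bp = p$expected_product_bp %||% NA_integer_)
  }))
  key <- dplyr::bind_rows(lapply(obj$diagnostic_key, tibble::as_tibble))
  assay_definition(obj$name, primers, key,
                   control_size_range = unlist(obj$control_size_range))
}

# Placeholder sequences for the shark universal ITS2 primers (FISH5.8SF /
# FISH28SR). The real primer sequences are published elsewhere and are not
# bundled; these synthetic stand-ins bind the conserved flanks of the
# synthetic panels and should be overridden with the real sequences for work
# on real data.
UNIVERSAL_PLACEHOLDERS <- tibble::tibble(
  name = c("FISH5.8SF", "FISH28SR"),
  sequence = c("GTCGCTACGACCCTTGGGAT", "CGTGAACCACCTAGCTATCG"),
  orientation = c("forward", "reverse"),
  role = c("universal_forward", "universal_reverse"),
  target_taxon = NA_character_,
  expected_product_bp = NA_integer_
)

SHARPNOSE_TAXA <- c("R. acutus", "R. porosus", "R. longurio", "R. terranovae",
                    "R. oligolinx", "R. taylori", "R. lalandei")

#' Load the packaged sharpnose-shark assay
#'
#' Returns the published nonaplex assay (seven species-specific ITS2 primers
#' plus the universal pair) or a single-species triplex subset of it. The two
#' universal primers ship as named placeholders with synthetic sequences --
#' their real sequences are published separately -- and can be overridden.
#'
#' @param which `"nonaplex"` or `"triplex"`.
#' @param taxon for `which = "triplex"`, the target taxon (one of the seven
#'   sharpnose species, e.g. `"R. porosus"`).
#' @param universal optional 2-row primer tibble replacing the universal
#'   placeholder pair (roles `universal_forward` and `universal_reverse`).
#' @param tolerance_bp gel-reading tolerance for the diagnostic key.
#' @return an `assay_definition`.
#' @examples
#' nona <- load_packaged_assay("nonaplex")
#' tri <- load_packaged_assay("triplex", taxon = "R. lalandei")
#' @export
load_packaged_assay <- function(which = c("nonaplex", "triplex"), taxon = NULL,
                                universal = NULL, tolerance_bp = 25) {
  which <- match.arg(which)
  tsv <- system.file("extdata", "sharpnose_ssp_primers.tsv", package = "silicoplex",
                     mustWork = TRUE)
  ssp <- read_primer_table(tsv)
  uni <- if (is.null(universal)) UNIVERSAL_PLACEHOLDERS else {
    u <- validate_primers(universal)
    stopifnot(nrow(u) == 2L,
              sum(u$role == "universal_forward") == 1L,
              sum(u$role == "universal_reverse") == 1L)
    u[c("name", "sequence", "orientation", "role", "target_taxon", "expected_product_bp")]
  }
  if (which == "triplex") {
    if (is.null(taxon) || !taxon %in% ssp$target_taxon) {
      stop("triplex requires a target taxon; valid taxa: ",
           paste(sort(unique(ssp$target_taxon)), collapse = ", "))
    }
    ssp <- ssp[ssp$target_taxon == taxon, ]
  }
  primers <- dplyr::bind_rows(ssp[names(UNIVERSAL_PLACEHOLDERS)], uni)
  key <- tibble::tibble(taxon = ssp$target_taxon, expected_bp = ssp$expected_product_bp)
  assay_definition(
    name = if (which == "nonaplex") "sharpnose-nonaplex" else paste0("sharpnose-triplex-", taxon),
    primers = primers, diagnostic_key = key,
    control_size_range = c(860, 1500), tolerance_bp = tolerance_bp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
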
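# IUPAC nucleotide alphabet, complement and compatibility rules shared by the
# scanner, the primer parsers and the synthetic generator.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_EXPAND)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

# compat[p, t]: does primer letter p anneal to template letter t?
# A primer ambiguity code matches any base consistent with it; an ambiguity
# code in the template only matches a literally identical primer letter
# (conservative for diagnostics: an unknown template base never rescues a hit).
.build_compat <- function() {
  m <- matrix(FALSE, 15L, 15L, dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  for (p in IUPAC_LETTERS) {
    for (t in IUPAC_LETTERS) {
      if (t %in% c("A", "C", "G", "T")) {
        m[p, t] <- t %in% IUPAC_EXPAND[[p]]
      } else {
        m[p, t] <- identical(p, t)
      }
    }
  }
  m
}

IUPAC_COMPAT <- .build_compat()

#' Reverse complement of a DNA string
#'
#' Handles the full IUPAC alphabet. Input is uppercased first.
#'
#' @param x a single DNA string.
#' @return a single string, the reverse complement.
#' @examples
#' revcomp("ACGT")
#' revcomp("ARN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1]])
  bad <- setdiff(unique(ch), IUPAC_LETTERS)
  if (length(bad)) {
    stop("non-IUPAC characters in sequence: ", paste(bad, collapse = ", "))
  }
  paste(IUPAC_COMPLEMENT[ch], collapse = "")
}

# Normalize a raw sequence string: uppercase, U -> T, reject non-IUPAC.
normalize_dna <- function(x, what = "sequence") {
  x <- gsub("[[:space:]]", "", toupper(x))
  x <- gsub("U", "T", x, fixed = TRUE)
  ch <- unique(strsplit(x, "", fixed = TRUE)[[1]])
  bad <- setdiff(ch, c(IUPAC_LETTERS, "-"))
  if (length(bad)) {
    stop(what, " contains non-IUPAC characters: ", paste(bad, collapse = ", "))
  }
  x
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

has_ambiguity <- function(x) grepl("[^ACGT-]", x)
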
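#' Primer annealing policy
#'
#' Encodes "failure to anneal" as a testable rule: a primer binds a template
#' site when the total number of mismatched positions is at most
#' `max_mismatches` *and* the `three_prime_anchor` 3'-terminal bases match
#' exactly. The 3' anchor rule reflects that polymerase extension requires a
#' matched 3' end; it is the working mechanism behind species-specific
#' primers whose diagnostic mismatch sits at the 3' end.
#'
#' @param max_mismatches maximum mismatches tolerated across the whole primer
#'   (default 2).
#' @param three_prime_anchor number of 3'-terminal positions that must match
#'   exactly (default 3).
#' @param max_product_bp longest product considered amplifiable (default
#'   2000).
#' @param both_strands search both strands (default TRUE).
#' @param min_primer_len primers shorter than this are rejected up front.
#' @return a list of class `binding_policy`.
#' @export
binding_policy <- function(max_mismatches = 2L, three_prime_anchor = 3L,
                           max_product_bp = 2000L, both_strands = TRUE,
                           min_primer_len = 10L) {
  stopifnot(max_mismatches >= 0L, three_prime_anchor >= 0L, max_product_bp > 0L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 three_prime_anchor = as.integer(three_prime_anchor),
                 max_product_bp = as.integer(max_product_bp),
                 both_strands = isTRUE(both_strands),
                 min_primer_len = as.integer(min_primer_len)),
            class = "binding_policy")
}

# Vectorised mismatch scan of one oriented primer over every offset of a
# template. Returns mismatch count per offset and whether the anchor rows
# (indices into the oriented primer) are all exact.
scan_offsets <- function(primer_chars, template_idx, anchor_rows) {
  m <- length(primer_chars)
  n <- length(template_idx)
  if (m > n) return(list(start = integer(0), mismatches = integer(0),
                         anchor_ok = logical(0)))
  starts <- seq_len(n - m + 1L)
  p_idx <- match(primer_chars, IUPAC_LETTERS)
  # m x S matrix of template letter indices under each offset
  pos <- outer(0:(m - 1L), starts, "+")
  ok <- IUPAC_COMPAT[cbind(rep(p_idx, times = length(starts)),
                           template_idx[pos])]
  dim(ok) <- c(m, length(starts))
  mm <- colSums(!ok)
  anchor_ok <- if (length(anchor_rows)) {
    colSums(!ok[anchor_rows, , drop = FALSE]) == 0L
  } else rep(TRUE, length(starts))
  list(start = starts, mismatches = as.integer(mm), anchor_ok = anchor_ok)
}

#' Find primer binding sites on templates
#'
#' Scans every offset of every template for annealing sites of every primer,
#' on both strands, under a [binding_policy()]. A plus-strand site means the
#' primer sequence matches the template slice directly (the primer extends
#' rightwards, acting as a forward primer); a minus-strand site means the
#' primer matches the reverse complement of the slice (it extends leftwards,
#' acting as a reverse primer). Ambiguity codes in the primer match any
#' consistent template base; ambiguity in the template counts as a mismatch
#' unless literally identical.
#'
#' @param templates a template tibble (`id`, `sequence`); a single template
#'   row works too.
#' @param primers a primer tibble (see [validate_primers()]).
#' @param policy a [binding_policy()].
#' @return a tibble with columns `template_id`, `primer_name`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based closed on the plus strand),
#'   `mismatches`, sorted by template, primer and start. A primer longer than
#'   the template simply yields no sites.
#' @export
find_binding_sites <- function(templates, primers, policy = binding_policy()) {
  templates <- validate_templates(templates)
  primers <- validate_primers(primers, min_len = policy$min_primer_len)
  res <- vector("list", nrow(templates) * nrow(primers) * 2L)
  k <- 0L
  anchor <- policy$three_prime_anchor
  for (ti in seq_len(nrow(templates))) {
    tmpl <- templates$sequence[ti]
    t_idx <- match(seq_chars(tmpl), IUPAC_LETTERS)
    for (pi in seq_len(nrow(primers))) {
      pseq <- primers$sequence[pi]
      m <- nchar(pseq)
      a <- min(anchor, m)
      # plus strand: primer as given; 3' end = rightmost rows
      sc <- scan_offsets(seq_chars(pseq), t_idx,
                         anchor_rows = if (a) seq.int(m - a + 1L, m) else integer(0))
      hit <- sc$mismatches <= policy$max_mismatches & sc$anchor_ok
      if (any(hit)) {
        k <- k + 1L
        res[[k]] <- tibble::tibble(
          template_id = templates$id[ti], primer_name = primers$name[pi],
          strand = "+", start = sc$start[hit], end = sc$start[hit] + m - 1L,
          mismatches = sc$mismatches[hit])
      }
      if (policy$both_strands) {
        # minus strand: scan the reverse complement; its leftmost rows are the
        # primer's 3' end
        sc <- scan_offsets(seq_chars(revcomp(pseq)), t_idx,
                           anchor_rows = if (a) seq_len(a) else integer(0))
        hit <- sc$mismatches <= policy$max_mismatches & sc$anchor_ok
        if (any(hit)) {
          k <- k + 1L
          res[[k]] <- tibble::tibble(
            template_id = templates$id[ti], primer_name = primers$name[pi],
            strand = "-", start = sc$start[hit], end = sc$start[hit] + m - 1L,
            mismatches = sc$mismatches[hit])
        }
      }
    }
  }
  out <- if (k) dplyr::bind_rows(res[seq_len(k)]) else tibble::tibble(
    template_id = character(0), primer_name = character(0), strand = character(0),
    start = integer(0), end = integer(0), mismatches = integer(0))
  dplyr::arrange(out, .data$template_id, .data$primer_name, .data$start)
}

#' Predict PCR products of a primer mix on templates
#'
#' Pairs every plus-strand (forward-acting) binding site with every
#' downstream minus-strand (reverse-acting) site and reports the product each
#' pair would amplify, up to the policy's maximum product size. Products are
#' classified by the roles of the two primers: `control` when both are the
#' universal pair, `diagnostic` when a species-specific primer extends to the
#' universal reverse primer, `nonspecific` otherwise.
#'
#' @inheritParams find_binding_sites
#' @return a tibble with columns `template_id`, `forward_primer`,
#'   `reverse_primer`, `start`, `end` (1-based closed product coordinates),
#'   `length_bp`, `classification`.
#' @export
predict_amplicons <- function(templates, primers, policy = binding_policy()) {
  primers <- validate_primers(primers, min_len = policy$min_primer_len)
  sites <- find_binding_sites(templates, primers, policy)
  role <- stats::setNames(primers$role, primers$name)
  plen <- stats::setNames(nchar(primers$sequence), primers$name)
  out <- list()
  for (tid in unique(sites$template_id)) {
    s <- sites[sites$template_id == tid, ]
    fw <- s[s$strand == "+", ]
    rv <- s[s$strand == "-", ]
    if (!nrow(fw) || !nrow(rv)) next
    grid <- tidyr::expand_grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
    len <- rv$end[grid$r] - fw$start[grid$f] + 1L
    min_len <- plen[fw$primer_name[grid$f]] + plen[rv$primer_name[grid$r]]
    keep <- len >= min_len & len <= policy$max_product_bp
    if (!any(keep)) next
    grid <- grid[keep, ]; len <- len[keep]
    frole <- role[fw$primer_name[grid$f]]
    rrole <- role[rv$primer_name[grid$r]]
    cls <- dplyr::case_when(
      frole == "universal_forward" & rrole == "universal_reverse" ~ "control",
      frole == "species_specific" & rrole == "universal_reverse" ~ "diagnostic",
      TRUE ~ "nonspecific")
    out[[length(out) + 1L]] <- tibble::tibble(
      template_id = tid,
      forward_primer = fw$primer_name[grid$f],
      reverse_primer = rv$primer_name[grid$r],
      start = fw$start[grid$f], end = rv$end[grid$r],
      length_bp = as.integer(len), classification = cls)
  }
  if (!length(out)) {
    return(tibble::tibble(template_id = character(0), forward_primer = character(0),
                          reverse_primer = character(0), start = integer(0),
                          end = integer(0), length_bp = integer(0),
                          classification = character(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$template_id, .data$start, .data$length_bp)
}

#' Simulate a multiplex assay: expected gel band pattern per template
#'
#' Runs [predict_amplicons()] with the assay's primer mix and reduces the
#' products to the band pattern a gel lane would show: one band per distinct
#' product size, sorted large to small (gel order, largest nearest the well).
#' No amplification-competition model is applied; every eligible product
#' becomes a band. The positive-control band can optionally be tagged
#' `faint`, mirroring the variably faint whole-locus control seen when
#' species-specific products dominate the reaction.
#'
#' @param templates template tibble; each template becomes one lane.
#' @param assay an `assay_definition`.
#' @param policy a [binding_policy()].
#' @param faint_control tag control bands with intensity `"faint"` instead of
#'   `"strong"`.
#' @return a tibble of class `band_pattern`: `lane` (template id), `size_bp`,
#'   `intensity`, `classification`; lanes with no products contribute zero
#'   rows but are recorded in the `lanes` attribute.
#' @export
simulate_assay <- function(templates, assay, policy = binding_policy(),
                           faint_control = FALSE) {
  validate_assay(assay)
  templates <- validate_templates(templates)
  amp <- predict_amplicons(templates, assay$primers, policy)
  bands <- amp |>
    dplyr::distinct(.data$template_id, .data$length_bp, .data$classification) |>
    dplyr::transmute(
      lane = .data$template_id, size_bp = .data$length_bp,
      intensity = ifelse(faint_control & .data$classification == "control",
                         "faint", "strong"),
      classification = .data$classification) |>
    dplyr::arrange(.data$lane, dplyr::desc(.data$size_bp))
  attr(bands, "lanes") <- templates$id
  class(bands) <- c("band_pattern", class(bands))
  bands
}

#' Write binding sites as BED
#'
#' BED uses 0-based half-open coordinates; the tibble's 1-based closed
#' `start`/`end` become `start - 1`/`end`. The score column carries the
#' mismatch count.
#'
#' @param sites output of [find_binding_sites()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$template_id,
                    chromStart = sites$start - 1L,
                    chromEnd = sites$end,
                    name = sites$primer_name,
                    score = sites$mismatches,
                    strand = sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write amplicon predictions as TSV
#'
#' Coordinates are 1-based and closed.
#'
#' @param amplicons output of [predict_amplicons()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_tsv <- function(amplicons, path) {
  utils::write.table(amplicons, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
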
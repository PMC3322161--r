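#' Read a multiple sequence alignment from FASTA
#'
#' Rows must be equal length; gaps as `-`. Taxon labels come from the FASTA
#' description (after the first whitespace) or default to the record id.
#'
#' @param path aligned FASTA path.
#' @return a tibble `id`, `taxon`, `sequence` with equal-length sequences.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("alignment file is empty: ", path)
  nm <- names(set)
  id <- sub("\\s.*$", "", nm)
  taxon <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), id)
  seqs <- vapply(as.character(set), normalize_dna, character(1))
  if (length(unique(nchar(seqs))) != 1L) stop("alignment rows differ in length")
  tibble::tibble(id = id, taxon = unname(taxon), sequence = unname(seqs))
}

#' Find diagnostic alignment columns for one target taxon
#'
#' Scans every alignment column and reports those where the target base
#' differs from at least one non-target row. A column is *fully* diagnostic
#' when the target base is absent from every non-target row -- the condition
#' a species-specific primer's 3' anchor must sit on.
#'
#' @param msa an alignment tibble (`id`, `taxon`, `sequence`, equal lengths).
#' @param target_taxon the taxon to design for; all its rows must agree at a
#'   column for the column to count.
#' @return a tibble with `column` (alignment coordinate), `target_pos`
#'   (1-based ungapped position on the target sequence), `target_state`,
#'   `nontarget_states` (collapsed string), `discriminates` (list column of
#'   differing non-target taxa) and `fully_diagnostic`.
#' @export
find_diagnostic_sites <- function(msa, target_taxon) {
  msa <- tibble::as_tibble(msa)
  stopifnot(all(c("taxon", "sequence") %in% names(msa)))
  if (!target_taxon %in% msa$taxon) stop("target taxon not in alignment: ", target_taxon)
  rows <- lapply(msa$sequence, seq_chars)
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, rows)
  is_t <- msa$taxon == target_taxon
  tmat <- mat[is_t, , drop = FALSE]
  nmat <- mat[!is_t, , drop = FALSE]
  ntaxa <- msa$taxon[!is_t]
  if (!nrow(nmat)) stop("alignment needs at least one non-target row")

  target_base <- tmat[1L, ]
  consistent <- colSums(tmat != rep(target_base, each = nrow(tmat))) == 0L
  target_pos <- cumsum(target_base != "-")

  out <- list()
  for (j in seq_len(len)) {
    tb <- target_base[j]
    if (!consistent[j] || tb == "-") next
    diffs <- nmat[, j] != tb
    if (!any(diffs)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      column = j, target_pos = target_pos[j], target_state = tb,
      nontarget_states = paste(sort(unique(nmat[, j])), collapse = ""),
      discriminates = list(sort(unique(ntaxa[diffs]))),
      fully_diagnostic = all(diffs))
  }
  if (!length(out)) {
    return(tibble::tibble(column = integer(0), target_pos = integer(0),
                          target_state = character(0), nontarget_states = character(0),
                          discriminates = list(), fully_diagnostic = logical(0)))
  }
  dplyr::bind_rows(out)
}

#' Primer melting temperature
#'
#' Basic formulas popularised by simple oligo calculators: the Wallace rule
#' `2(A+T) + 4(G+C)` for primers shorter than 14 nt, and the GC-adjusted
#' formula `64.9 + 41 (GC - 16.4) / N` otherwise.
#'
#' @param sequence primer string (vectorised).
#' @return melting temperature in degrees Celsius.
#' @export
primer_tm <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    ch <- seq_chars(s)
    n <- length(ch)
    gc <- sum(ch %in% c("G", "C", "S"))
    at <- sum(ch %in% c("A", "T", "W"))
    if (n < 14) 2 * at + 4 * gc else 64.9 + 41 * (gc - 16.4) / n
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC fraction of a sequence
#' @param sequence DNA string (vectorised).
#' @return fraction of G/C bases.
#' @export
gc_fraction <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    ch <- seq_chars(s)
    mean(ch %in% c("G", "C", "S"))
  }, numeric(1), USE.NAMES = FALSE)
}

# does the reverse complement of the 3'-terminal run of length k occur
# anywhere in the primer? (two copies of the primer could anneal 3'-to-3')
self_dimer_3prime <- function(sequence, k = 4L) {
  n <- nchar(sequence)
  if (n < k) return(FALSE)
  tail3 <- substr(sequence, n - k + 1L, n)
  grepl(revcomp(tail3), sequence, fixed = TRUE)
}

# any k-mer whose reverse complement occurs >= min_loop positions downstream
hairpin_flag <- function(sequence, k = 4L, min_loop = 3L) {
  n <- nchar(sequence)
  if (n < 2L * k + min_loop) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    kmer_rc <- revcomp(substr(sequence, i, i + k - 1L))
    rest_at <- i + k + min_loop
    if (rest_at + k - 1L > n) break
    if (grepl(kmer_rc, substr(sequence, rest_at, n), fixed = TRUE)) return(TRUE)
  }
  FALSE
}

#' Primer design constraints
#'
#' Composition bounds for candidate species-specific primers. Defaults are
#' consistent with the published sharpnose primers: 18--25 nt, Tm 55--70 C
#' (GC-adjusted formula), GC fraction 0.40--0.70, no 4-base self-complementary
#' 3' run.
#'
#' @param min_len,max_len allowed primer length range (nt).
#' @param tm_min,tm_max allowed melting temperature range (Celsius, per
#'   [primer_tm()]).
#' @param gc_min,gc_max allowed GC fraction range.
#' @param anchor_len how many 3'-terminal positions must cover at least one
#'   fully diagnostic site.
#' @param forbid_self_dimer drop candidates whose 3' 4-mer is self
#'   complementary elsewhere in the primer.
#' @return a list of class `primer_constraints`.
#' @export
primer_constraints <- function(min_len = 18L, max_len = 25L,
                               tm_min = 55, tm_max = 70,
                               gc_min = 0.40, gc_max = 0.70,
                               anchor_len = 3L, forbid_self_dimer = TRUE) {
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 tm_min = tm_min, tm_max = tm_max, gc_min = gc_min, gc_max = gc_max,
                 anchor_len = as.integer(anchor_len),
                 forbid_self_dimer = isTRUE(forbid_self_dimer)),
            class = "primer_constraints")
}

#' Enumerate candidate species-specific primers for one taxon
#'
#' Slides windows of every allowed length over the target's ungapped
#' sequence, keeping windows whose 3'-terminal `anchor_len` positions cover
#' at least one fully diagnostic site (so every congener carries a 3'-anchor
#' mismatch) and which satisfy the composition constraints. Each candidate
#' carries its mismatch profile against every non-target taxon in the
#' alignment window.
#'
#' @param msa alignment tibble (`id`, `taxon`, `sequence`).
#' @param target_taxon taxon to design for.
#' @param constraints a [primer_constraints()].
#' @param max_sites cap on fully diagnostic sites used as anchors (an evenly
#'   spread subset is kept); bounds the window count for highly divergent
#'   targets.
#' @return a tibble of candidates: `name`, `target_taxon`, `sequence`,
#'   `start`, `end` (1-based ungapped target coordinates), `tm_celsius`,
#'   `gc_fraction`, `self_dimer`, `hairpin`, `min_mismatches_vs_nontargets`,
#'   `anchor_mismatch_all_nontargets`, plus list columns `mismatches_by_taxon`
#'   and `anchor_mismatch_by_taxon`. Empty (with a message) when no window
#'   satisfies the constraints.
#' @export
enumerate_candidates <- function(msa, target_taxon,
                                 constraints = primer_constraints(),
                                 max_sites = Inf) {
  sites <- find_diagnostic_sites(msa, target_taxon)
  full <- sites[sites$fully_diagnostic, ]
  if (!nrow(full)) {
    message("no fully diagnostic site for ", target_taxon, "; no candidates")
    return(empty_candidates())
  }
  if (nrow(full) > max_sites) {
    full <- full[unique(round(seq(1L, nrow(full), length.out = max_sites))), ]
  }
  msa <- tibble::as_tibble(msa)
  trow <- which(msa$taxon == target_taxon)[1]
  tchars <- seq_chars(msa$sequence[trow])
  ungapped <- tchars[tchars != "-"]
  tlen <- length(ungapped)
  col_of_pos <- which(tchars != "-")          # ungapped pos -> alignment column
  nont <- msa[msa$taxon != target_taxon, ]
  nrows <- lapply(nont$sequence, seq_chars)

  ends <- unique(unlist(lapply(full$target_pos, function(q)
    q + 0:(constraints$anchor_len - 1L))))
  ends <- ends[ends <= tlen]
  out <- list()
  for (e in sort(ends)) {
    for (L in constraints$min_len:constraints$max_len) {
      s <- e - L + 1L
      if (s < 1L) next
      anchor_range <- (e - constraints$anchor_len + 1L):e
      if (!any(full$target_pos %in% anchor_range)) next
      pseq <- paste(ungapped[s:e], collapse = "")
      tm <- primer_tm(pseq); gc <- gc_fraction(pseq)
      sd_flag <- self_dimer_3prime(pseq); hp <- hairpin_flag(pseq)
      if (tm < constraints$tm_min || tm > constraints$tm_max) next
      if (gc < constraints$gc_min || gc > constraints$gc_max) next
      if (constraints$forbid_self_dimer && sd_flag) next
      cols <- col_of_pos[s:e]
      anchor_cols <- col_of_pos[anchor_range]
      mm_by <- vapply(seq_len(nrow(nont)), function(i)
        sum(nrows[[i]][cols] != tchars[cols]), integer(1))
      am_by <- vapply(seq_len(nrow(nont)), function(i)
        any(nrows[[i]][anchor_cols] != tchars[anchor_cols]), logical(1))
      mm_taxon <- tapply(mm_by, nont$taxon, min)
      am_taxon <- tapply(am_by, nont$taxon, all)
      out[[length(out) + 1L]] <- tibble::tibble(
        name = paste0(gsub("[^A-Za-z0-9]", "", target_taxon), "-", s, "-", L),
        target_taxon = target_taxon, sequence = pseq,
        start = s, end = e,
        tm_celsius = tm, gc_fraction = gc,
        self_dimer = sd_flag, hairpin = hp,
        min_mismatches_vs_nontargets = min(mm_taxon),
        anchor_mismatch_all_nontargets = all(am_taxon),
        mismatches_by_taxon = list(mm_taxon),
        anchor_mismatch_by_taxon = list(am_taxon))
    }
  }
  if (!length(out)) {
    message("no window satisfies the constraints for ", target_taxon)
    return(empty_candidates())
  }
  dplyr::bind_rows(out)
}

empty_candidates <- function() {
  tibble::tibble(name = character(0), target_taxon = character(0),
                 sequence = character(0), start = integer(0), end = integer(0),
                 tm_celsius = numeric(0), gc_fraction = numeric(0),
                 self_dimer = logical(0), hairpin = logical(0),
                 min_mismatches_vs_nontargets = integer(0),
                 anchor_mismatch_all_nontargets = logical(0),
                 mismatches_by_taxon = list(), anchor_mismatch_by_taxon = list())
}

#' Screen candidate primers against a non-target template panel
#'
#' A candidate survives only if it has *zero* binding sites (under the
#' policy, either strand) on every non-target template -- the in-silico
#' analogue of testing each putative primer against the non-target specimen
#' panel. Rejections name the first offending template.
#'
#' @param candidates tibble from [enumerate_candidates()].
#' @param nontarget_panel template tibble of non-target sequences.
#' @param policy a [binding_policy()].
#' @return the candidates tibble with logical `retained` and character
#'   `offending_template` columns; filter on `retained` for the surviving
#'   set.
#' @export
screen_specificity <- function(candidates, nontarget_panel,
                               policy = binding_policy()) {
  stopifnot(nrow(nontarget_panel) > 0L)
  nontarget_panel <- validate_templates(nontarget_panel)
  if (!nrow(candidates)) {
    candidates$retained <- logical(0)
    candidates$offending_template <- character(0)
    return(candidates)
  }
  primers <- tibble::tibble(name = candidates$name, sequence = candidates$sequence,
                            orientation = "forward", role = "species_specific")
  hits <- find_binding_sites(nontarget_panel, primers, policy)
  first_offender <- hits |>
    dplyr::group_by(.data$primer_name) |>
    dplyr::summarise(offending_template = .data$template_id[1L], .groups = "drop")
  candidates$retained <- !candidates$name %in% first_offender$primer_name
  candidates$offending_template <-
    first_offender$offending_template[match(candidates$name, first_offender$primer_name)]
  candidates
}

#' Select one primer per taxon to maximise the diagnostic size ladder
#'
#' Given per-taxon candidates, each with a predicted product size, chooses
#' one candidate per taxon so that the minimum pairwise product-size gap is
#' as large as possible. Candidates whose product lands within
#' `control_buffer_bp` of the positive-control size window are excluded
#' first (a diagnostic band must not co-migrate with another species'
#' control band). Search is exhaustive over distinct size combinations when
#' that space is small, otherwise greedy with pairwise-swap refinement. Ties
#' are broken by a larger summed mismatch count against non-targets, then by
#' lexicographic primer name.
#'
#' @param candidates tibble with at least `name`, `target_taxon`,
#'   `predicted_product_bp` and optionally `min_mismatches_vs_nontargets`.
#' @param min_gap_bp required minimum pairwise gap; the result errors
#'   (explicit infeasibility) when even the best assignment falls short.
#' @param control_range optional numeric length-2 control window to avoid.
#' @param control_buffer_bp clearance required from the control window.
#' @param exhaustive_limit switch to greedy search above this many
#'   combinations.
#' @return an object of class `ladder_design`: `chosen` (one row per taxon),
#'   `min_pairwise_gap_bp`, `min_gap_to_control_range_bp`.
#' @export
select_ladder <- function(candidates, min_gap_bp = 100,
                          control_range = NULL, control_buffer_bp = 50,
                          exhaustive_limit = 2e5) {
  candidates <- tibble::as_tibble(candidates)
  stopifnot(all(c("name", "target_taxon", "predicted_product_bp") %in% names(candidates)))
  if (!nrow(candidates)) stop("no candidates supplied for any taxon")
  if (!"min_mismatches_vs_nontargets" %in% names(candidates)) {
    candidates$min_mismatches_vs_nontargets <- 0L
  }
  input_taxa <- sort(unique(candidates$target_taxon))
  if (!is.null(control_range)) {
    clear <- candidates$predicted_product_bp < control_range[1] - control_buffer_bp |
      candidates$predicted_product_bp > control_range[2] + control_buffer_bp
    dropped <- candidates[!clear, ]
    candidates <- candidates[clear, ]
  }
  taxa <- input_taxa
  groups <- lapply(taxa, function(tx) {
    g <- candidates[candidates$target_taxon == tx, ]
    # one best representative per distinct size: tie-break by mismatches then name
    g <- g[order(g$predicted_product_bp, -g$min_mismatches_vs_nontargets, g$name), ]
    g[!duplicated(g$predicted_product_bp), ]
  })
  missing <- taxa[vapply(groups, nrow, integer(1)) == 0L]
  if (length(missing)) stop("no eligible candidate for taxon: ",
                            paste(missing, collapse = ", "))
  sizes <- lapply(groups, function(g) g$predicted_product_bp)

  n_comb <- prod(vapply(sizes, length, integer(1)))
  score_assign <- function(idx) {
    s <- vapply(seq_along(idx), function(k) sizes[[k]][idx[k]], numeric(1))
    if (length(s) < 2L) return(Inf)
    min(stats::dist(s))
  }
  if (n_comb <= exhaustive_limit) {
    grid <- expand.grid(lapply(sizes, seq_along))
    best_gap <- -Inf; best <- NULL
    for (r in seq_len(nrow(grid))) {
      idx <- as.integer(grid[r, ])
      g <- score_assign(idx)
      if (g > best_gap + 1e-9) { best_gap <- g; best <- list(idx) }
      else if (abs(g - best_gap) <= 1e-9) best <- c(best, list(idx))
    }
  } else {
    # greedy: place taxa in order of fewest options; then swap-refine
    ord <- order(vapply(sizes, length, integer(1)))
    idx <- integer(length(sizes))
    placed <- numeric(0)
    for (k in ord) {
      gaps <- vapply(sizes[[k]], function(s)
        if (!length(placed)) Inf else min(abs(placed - s)), numeric(1))
      idx[k] <- which.max(gaps)
      placed <- c(placed, sizes[[k]][idx[k]])
    }
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (k in seq_along(sizes)) {
        for (alt in seq_along(sizes[[k]])) {
          trial <- idx; trial[k] <- alt
          if (score_assign(trial) > score_assign(idx) + 1e-9) {
            idx <- trial; improved <- TRUE
          }
        }
      }
    }
    best_gap <- score_assign(idx); best <- list(idx)
  }

  # tie-breaks among equally good assignments
  pick <- best[[1L]]
  if (length(best) > 1L) {
    keyfun <- function(idx) {
      rows <- lapply(seq_along(idx), function(k) groups[[k]][idx[k], ])
      mm <- sum(vapply(rows, function(r) as.numeric(r$min_mismatches_vs_nontargets),
                       numeric(1)))
      nm <- paste(vapply(rows, function(r) r$name, character(1)), collapse = "|")
      list(mm = mm, nm = nm)
    }
    keys <- lapply(best, keyfun)
    mm <- vapply(keys, function(k) k$mm, numeric(1))
    cand <- which(mm == max(mm))
    nms <- vapply(keys[cand], function(k) k$nm, character(1))
    pick <- best[[cand[order(nms)[1L]]]]
  }

  chosen <- dplyr::bind_rows(lapply(seq_along(pick), function(k)
    groups[[k]][pick[k], ]))
  gap <- if (nrow(chosen) < 2L) Inf else min(stats::dist(chosen$predicted_product_bp))
  ctrl_gap <- if (is.null(control_range)) NA_real_ else
    min(pmin(abs(chosen$predicted_product_bp - control_range[1]),
             abs(chosen$predicted_product_bp - control_range[2])))
  if (gap < min_gap_bp) {
    stop("ladder infeasible: best achievable minimum pairwise gap is ", gap,
         " bp (< ", min_gap_bp, " bp required)")
  }
  structure(list(chosen = chosen, min_pairwise_gap_bp = gap,
                 min_gap_to_control_range_bp = ctrl_gap),
            class = "ladder_design")
}

#' @export
print.ladder_design <- function(x, ...) {
  cat("<ladder_design> ", nrow(x$chosen), " taxa, min pairwise gap ",
      x$min_pairwise_gap_bp, " bp\n", sep = "")
  print(x$chosen[c("target_taxon", "name", "predicted_product_bp")])
  invisible(x)
}

#' Tidy a ladder design
#' @param x a `ladder_design`.
#' @param ... unused.
#' @return the `chosen` tibble, one row per taxon.
#' @export
tidy.ladder_design <- function(x, ...) x$chosen

#' One-row summary of a ladder design
#' @param x a `ladder_design`.
#' @param ... unused.
#' @return a one-row tibble with taxon count and gap statistics.
#' @export
glance.ladder_design <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$chosen),
                 min_pairwise_gap_bp = x$min_pairwise_gap_bp,
                 min_gap_to_control_range_bp = x$min_gap_to_control_range_bp)
}
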
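#' Design a multiplex species-identification assay from a template panel
#'
#' Runs the whole species-specific-primer design pipeline: extract the
#' variable core alignment, find fully diagnostic sites per target taxon,
#' enumerate composition-filtered candidate primers anchored on those sites,
#' screen every candidate for zero in-silico binding on all other panel
#' templates (congeners and decoys), predict each survivor's product size
#' against the universal reverse primer, and pick one primer per taxon so
#' diagnostic band sizes form a maximally spread ladder clear of the
#' positive-control window.
#'
#' @param templates template tibble with `taxon` and `its2_start`/`its2_end`
#'   populated (e.g. from [generate_panel()] or [read_template_fasta()]).
#'   Cores must be alignable as equal-length rows unless `msa` is supplied.
#' @param targets taxa to design primers for; default every taxon with a
#'   template that is not named like a decoy.
#' @param universal 2-row primer tibble: the universal pair that must bind
#'   every template's flanks. Defaults to the packaged placeholder pair used
#'   by the synthetic generator.
#' @param msa optional pre-aligned core alignment tibble (`id`, `taxon`,
#'   `sequence`); required when cores differ in length.
#' @param constraints a [primer_constraints()].
#' @param policy a [binding_policy()] used for specificity screening and
#'   product prediction.
#' @param min_gap_bp required minimum pairwise diagnostic-size gap. The
#'   ladder search *maximises* the gap, so achieved spacing is normally well
#'   above 100 bp; the default floor, 21 bp, is the spacing below which no
#'   credible gel-reading tolerance (at least +/-10 bp) can keep the key
#'   unambiguous. When the achieved gap is below `2 * tolerance_bp` the key
#'   tolerance is tightened to fit it.
#' @param control_buffer_bp required clearance between diagnostic sizes and
#'   the control window.
#' @param tolerance_bp gel-reading tolerance for the resulting key, shrunk
#'   automatically if the achieved ladder gap demands it.
#' @param max_sizes_per_taxon cap on distinct candidate product sizes carried
#'   per taxon into ladder selection (evenly spread across the core).
#' @return a list of class `assay_design`: `assay` (an `assay_definition`),
#'   `ladder` (the `ladder_design`), `candidates` (per-taxon screened
#'   candidate tibble), `control_range` (observed control product range).
#' @export
design_assay <- function(templates, targets = NULL, universal = NULL,
                         msa = NULL, constraints = primer_constraints(),
                         policy = binding_policy(), min_gap_bp = NULL,
                         control_buffer_bp = 50, tolerance_bp = 25,
                         max_sizes_per_taxon = 24L) {
  templates <- validate_templates(templates)
  if (is.null(min_gap_bp)) min_gap_bp <- 2 * 10 + 1
  if (is.null(universal)) universal <- UNIVERSAL_PLACEHOLDERS
  universal <- validate_primers(universal)
  if (is.null(targets)) {
    targets <- setdiff(unique(templates$taxon), NA)
    targets <- targets[!grepl("^decoy", targets)]
  }
  missing <- setdiff(targets, templates$taxon)
  if (length(missing)) stop("target taxon absent from panel: ",
                            paste(missing, collapse = ", "))

  if (is.null(msa)) {
    has_core <- !is.na(templates$its2_start)
    core <- ifelse(has_core,
                   substr(templates$sequence, templates$its2_start, templates$its2_end),
                   templates$sequence)
    target_rows <- templates$taxon %in% targets
    if (length(unique(nchar(core[target_rows]))) != 1L) {
      stop("core sequences differ in length; supply a pre-aligned `msa`")
    }
    msa <- tibble::tibble(id = templates$id[target_rows],
                          taxon = templates$taxon[target_rows],
                          sequence = core[target_rows])
  }

  # core position -> full-template offset for each target's reference template
  ref_row <- vapply(targets, function(tx) which(templates$taxon == tx)[1], integer(1))
  core_offset <- ifelse(is.na(templates$its2_start[ref_row]), 0L,
                        templates$its2_start[ref_row] - 1L)

  # universal reverse annealing site (minus strand, rightmost) per reference
  ur <- universal[universal$role == "universal_reverse", ]
  uf <- universal[universal$role == "universal_forward", ]

  # composition bounds are guidelines, not physics: when a taxon's few
  # diagnostic sites offer no window inside the strict bounds, retry that
  # taxon under progressively relaxed bounds before declaring infeasibility
  tiers <- list(
    constraints,
    primer_constraints(min_len = 16L, max_len = 28L, tm_min = 52, tm_max = 72,
                       gc_min = 0.35, gc_max = 0.75,
                       anchor_len = constraints$anchor_len),
    primer_constraints(min_len = 15L, max_len = 32L, tm_min = 45, tm_max = 80,
                       gc_min = 0.25, gc_max = 0.85,
                       anchor_len = constraints$anchor_len,
                       forbid_self_dimer = FALSE))

  all_cand <- list()
  for (k in seq_along(targets)) {
    tx <- targets[k]
    cand <- empty_candidates()
    for (ti in seq_along(tiers)) {
      cand <- suppressMessages(
        enumerate_candidates(msa, tx, tiers[[ti]], max_sites = max_sizes_per_taxon))
      cand <- cand[cand$anchor_mismatch_all_nontargets, ]
      if (nrow(cand)) {
        if (ti > 1L) message("relaxed composition bounds (tier ", ti,
                             ") used for taxon ", tx)
        break
      }
    }
    if (!nrow(cand)) stop("no anchored candidate primers for taxon ", tx)
    # thin to a spread of distinct start positions before the costly screen
    starts <- sort(unique(cand$start))
    if (length(starts) > max_sizes_per_taxon) {
      keep_starts <- starts[unique(round(seq(1, length(starts),
                                             length.out = max_sizes_per_taxon)))]
    } else keep_starts <- starts
    cand <- cand |>
      dplyr::filter(.data$start %in% keep_starts) |>
      dplyr::group_by(.data$start) |>
      dplyr::arrange(dplyr::desc(.data$min_mismatches_vs_nontargets), .data$name,
                     .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()

    panel_other <- templates[templates$taxon != tx | is.na(templates$taxon), ]
    cand <- screen_specificity(cand, panel_other, policy)
    cand <- cand[cand$retained, ]
    if (!nrow(cand)) stop("all candidates for taxon ", tx,
                          " rejected by the specificity screen")

    tmpl <- templates[ref_row[k], ]
    ur_sites <- find_binding_sites(tmpl, ur, policy)
    ur_sites <- ur_sites[ur_sites$strand == "-", ]
    if (!nrow(ur_sites)) stop("universal reverse primer does not bind template of ", tx)
    ur_end <- max(ur_sites$end)
    cand$predicted_product_bp <- ur_end - (core_offset[k] + cand$start) + 1L
    all_cand[[k]] <- cand
  }
  candidates <- dplyr::bind_rows(all_cand)

  # observed whole-locus control products across the panel
  ctrl <- predict_amplicons(templates, universal, policy)
  ctrl <- ctrl[ctrl$classification == "control", ]
  if (!nrow(ctrl)) stop("universal pair produces no control product on the panel")
  control_range <- range(ctrl$length_bp)

  ladder <- select_ladder(candidates, min_gap_bp = min_gap_bp,
                          control_range = control_range,
                          control_buffer_bp = control_buffer_bp)
  tol <- min(tolerance_bp, floor((ladder$min_pairwise_gap_bp - 1) / 2))
  chosen <- ladder$chosen
  primers <- dplyr::bind_rows(
    tibble::tibble(name = chosen$name, sequence = chosen$sequence,
                   orientation = "forward", role = "species_specific",
                   target_taxon = chosen$target_taxon,
                   expected_product_bp = as.integer(chosen$predicted_product_bp)),
    uf[c("name", "sequence", "orientation", "role", "target_taxon", "expected_product_bp")],
    ur[c("name", "sequence", "orientation", "role", "target_taxon", "expected_product_bp")])
  assay <- assay_definition(
    name = paste0("designed-", length(targets), "plex"),
    primers = primers,
    diagnostic_key = tibble::tibble(taxon = chosen$target_taxon,
                                    expected_bp = chosen$predicted_product_bp),
    control_size_range = c(control_range[1] - tolerance_bp,
                           control_range[2] + tolerance_bp),
    tolerance_bp = tol)
  structure(list(assay = assay, ladder = ladder, candidates = candidates,
                 control_range = control_range),
            class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("<assay_design>\n")
  print(x$assay)
  cat("  ladder min pairwise gap: ", x$ladder$min_pairwise_gap_bp, " bp\n", sep = "")
  invisible(x)
}

#' Tidy an assay design: the chosen primer per taxon
#' @param x an `assay_design`.
#' @param ... unused.
#' @return tibble of chosen primers with predicted product sizes.
#' @export
tidy.assay_design <- function(x, ...) tidy(x$ladder)

#' One-row summary of an assay design
#' @param x an `assay_design`.
#' @param ... unused.
#' @return one-row tibble: taxa, ladder gap, control window.
#' @export
glance.assay_design <- function(x, ...) {
  tibble::tibble(n_taxa = nrow(x$ladder$chosen),
                 min_pairwise_gap_bp = x$ladder$min_pairwise_gap_bp,
                 control_min_bp = x$control_range[1],
                 control_max_bp = x$control_range[2])
}
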
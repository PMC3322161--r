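#' Gel migration positions for fragment sizes
#'
#' Log-size migration model: a ladder rung of size `s` sits at relative
#' position `log(max rung) - log(s)` (0 at the top/well end, growing down the
#' lane), and fragment positions are interpolated piecewise-linearly in
#' log-size between adjacent rungs -- which, with these rung positions, makes
#' position exactly `log(max) - log(size)` inside the ladder. Sizes outside
#' the ladder span are extrapolated with the same formula and flagged.
#'
#' @param sizes_bp numeric vector of fragment sizes.
#' @param ladder_sizes_bp numeric vector of ladder rung sizes, at least two.
#' @return a tibble with `size_bp`, `position` (relative units, strictly
#'   decreasing in log size) and `extrapolated`.
#' @export
gel_migrate <- function(sizes_bp, ladder_sizes_bp) {
  if (length(ladder_sizes_bp) < 2L) stop("ladder needs at least 2 rungs")
  stopifnot(all(sizes_bp > 0), all(ladder_sizes_bp > 0))
  ladder <- sort(unique(ladder_sizes_bp))
  rung_pos <- log(max(ladder)) - log(ladder)
  pos <- stats::approx(x = log(ladder), y = rung_pos, xout = log(sizes_bp),
                       rule = 2)$y
  outside <- sizes_bp < min(ladder) | sizes_bp > max(ladder)
  # linear extrapolation in log-size continues the same line
  pos[outside] <- log(max(ladder)) - log(sizes_bp[outside])
  tibble::tibble(size_bp = sizes_bp, position = pos, extrapolated = outside)
}

#' Are two band sizes resolvable on a gel?
#'
#' Two fragments co-migrate when their log sizes are closer than the gel's
#' resolution. The default resolution fraction 0.1 (about a 10% size
#' difference) is typical for agarose in the 100--1500 bp range.
#'
#' @param size_a,size_b fragment sizes in bp (vectorised).
#' @param resolution_fraction minimum difference in natural-log size.
#' @return logical: `TRUE` when the pair is separable.
#' @examples
#' gel_resolvable(230, 420)       # TRUE
#' gel_resolvable(420, 420)       # FALSE
#' @export
gel_resolvable <- function(size_a, size_b, resolution_fraction = 0.1) {
  stopifnot(all(size_a > 0), all(size_b > 0))
  abs(log(size_a) - log(size_b)) >= resolution_fraction
}

#' Minimum pairwise gap of a set of diagnostic sizes
#'
#' Brute force over all unordered pairs; used for ladder sanity checks.
#'
#' @param sizes_bp numeric vector of at least two sizes.
#' @return a list with `min_gap_bp` and the `pair` achieving it.
#' @export
min_pairwise_gap <- function(sizes_bp) {
  stopifnot(length(sizes_bp) >= 2L)
  best <- Inf; pair <- c(NA_real_, NA_real_)
  for (i in seq_len(length(sizes_bp) - 1L)) {
    for (j in seq.int(i + 1L, length(sizes_bp))) {
      g <- abs(sizes_bp[i] - sizes_bp[j])
      if (g < best) { best <- g; pair <- c(sizes_bp[i], sizes_bp[j]) }
    }
  }
  list(min_gap_bp = best, pair = sort(pair))
}

#' Render band patterns as a gel image
#'
#' ggplot2 rendering of simulated lanes in the style of an inverted agarose
#' gel photograph: one column per lane plus a ladder lane, band vertical
#' position from [gel_migrate()].
#'
#' @param bands a `band_pattern` from [simulate_assay()] or a tibble with
#'   `lane`, `size_bp` and optionally `intensity`.
#' @param ladder_sizes_bp ladder rung sizes; default a 1-kb-plus style ladder.
#' @return a ggplot object.
#' @export
plot_gel <- function(bands, ladder_sizes_bp = c(100, 200, 300, 400, 500, 650,
                                                850, 1000, 1650, 2000)) {
  bands <- tibble::as_tibble(bands)
  if (!"intensity" %in% names(bands)) bands$intensity <- "strong"
  lanes <- unique(c("ladder", attr(bands, "lanes") %||% unique(bands$lane)))
  df <- dplyr::bind_rows(
    tibble::tibble(lane = "ladder", size_bp = ladder_sizes_bp, intensity = "strong"),
    bands[c("lane", "size_bp", "intensity")])
  df$position <- gel_migrate(df$size_bp, ladder_sizes_bp)$position
  df$lane <- factor(df$lane, levels = lanes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$position)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = .data$intensity),
                       width = 0.7, height = 0.012, fill = "grey10") +
    ggplot2::scale_alpha_manual(values = c(strong = 1, faint = 0.35), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "migration (relative)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @rdname plot_gel
#' @param object a `band_pattern`.
#' @param ... passed to [plot_gel()].
#' @export
autoplot.band_pattern <- function(object, ...) plot_gel(object, ...)
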
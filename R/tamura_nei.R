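#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Implements the Tamura-Nei substitution distance, which allows unequal base
#' frequencies and distinguishes purine transitions (A<->G), pyrimidine
#' transitions (C<->T) and transversions. With base frequencies `g` estimated
#' from the pooled pair, purine/pyrimidine sums `gR = gA + gG`,
#' `gY = gC + gT`, observed site proportions `P1` (purine transitions), `P2`
#' (pyrimidine transitions) and `Q` (transversions):
#'
#' \deqn{d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3}
#'
#' with `k1 = 2 gA gG / gR`, `k2 = 2 gT gC / gY`,
#' `k3 = 2 (gR gY - gA gG gY/gR - gT gC gR/gY)`,
#' `w1 = 1 - P1/k1 - Q/(2 gR)`, `w2 = 1 - P2/k2 - Q/(2 gY)`,
#' `w3 = 1 - Q/(2 gR gY)`.
#'
#' If any logarithm argument is non-positive the pair is saturated: the
#' distance is returned as `Inf` with `saturated = TRUE`, never an error.
#'
#' @param pair an `alignment_pair` from [align_pair()], or a list with
#'   elements `aligned_a`, `aligned_b` (equal-length strings over
#'   `A/C/G/T/-`).
#' @param gap_policy `"pairwise_deletion"` (drop columns gapped in either
#'   sequence of this pair) or `"complete_deletion"`. For a single pair the
#'   two coincide; they differ at the matrix level, where complete deletion
#'   drops columns gapped in *any* row of the input alignment (see
#'   [tn_distance_matrix()]).
#' @return a one-row tibble of class `tn_result`: base frequencies `gA..gT`,
#'   `gR`, `gY`, proportions `P1`, `P2`, `Q`, the distance `d`
#'   (substitutions/site), `sites_used` and `saturated`.
#' @references Tamura K, Nei M (1993) Mol Biol Evol 10:512-526.
#' @export
tamura_nei_distance <- function(pair, gap_policy = c("pairwise_deletion",
                                                     "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  a <- seq_chars(toupper(pair$aligned_a))
  b <- seq_chars(toupper(pair$aligned_b))
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("no sites left after gap removal")

  pooled <- c(a, b)
  gA <- mean(pooled == "A"); gC <- mean(pooled == "C")
  gG <- mean(pooled == "G"); gT <- mean(pooled == "T")
  gR <- gA + gG; gY <- gC + gT

  is_pur <- function(x) x %in% c("A", "G")
  diff <- a != b
  ts1 <- diff & is_pur(a) & is_pur(b)             # A<->G
  ts2 <- diff & !is_pur(a) & !is_pur(b)           # C<->T
  tv <- diff & (is_pur(a) != is_pur(b))
  P1 <- mean(ts1); P2 <- mean(ts2); Q <- mean(tv)

  tn <- tn_from_proportions(gA, gC, gG, gT, P1, P2, Q)
  d <- tn$d; saturated <- tn$saturated

  out <- tibble::tibble(
    id_a = pair$id_a %||% NA_character_, id_b = pair$id_b %||% NA_character_,
    gA = gA, gC = gC, gG = gG, gT = gT, gR = gR, gY = gY,
    P1 = P1, P2 = P2, Q = Q, d = d, sites_used = n, saturated = saturated)
  class(out) <- c("tn_result", class(out))
  out
}

# Count-based core of the Tamura-Nei estimator, shared with the synthetic
# generator's incremental divergence control.
tn_from_proportions <- function(gA, gC, gG, gT, P1, P2, Q) {
  gR <- gA + gG; gY <- gC + gT
  sdiv <- function(num, den) if (num == 0) 0 else num / den
  k1 <- sdiv(2 * gA * gG, gR)
  k2 <- sdiv(2 * gT * gC, gY)
  k3 <- 2 * (gR * gY - sdiv(gA * gG * gY, gR) - sdiv(gT * gC * gR, gY))
  w1 <- 1 - sdiv(P1, k1) - sdiv(Q, 2 * gR)
  w2 <- 1 - sdiv(P2, k2) - sdiv(Q, 2 * gY)
  w3 <- 1 - sdiv(Q, 2 * gR * gY)
  saturated <- (k1 > 0 && w1 <= 0) || (k2 > 0 && w2 <= 0) || (k3 != 0 && w3 <= 0)
  d <- if (saturated) Inf else {
    term <- function(k, w) if (k == 0 || w == 1) 0 else -k * log(w)
    term(k1, w1) + term(k2, w2) + term(k3, w3)
  }
  # identical sequences give exactly zero, not accumulated rounding noise
  if (P1 == 0 && P2 == 0 && Q == 0) d <- 0
  list(d = d, saturated = saturated)
}

#' Pairwise Tamura-Nei distance matrix for a set of templates
#'
#' Aligns every pair globally (unless the input is already aligned) and
#' computes the Tamura-Nei distance for each. Distances are symmetric with a
#' zero diagonal by construction.
#'
#' @param templates a template tibble (`id`, optional `taxon`, `sequence`).
#'   With `aligned = TRUE`, sequences must be equal-length rows of one
#'   multiple alignment (gaps as `-`).
#' @param aligned if `TRUE`, skip pairwise alignment and use the sequences as
#'   alignment rows.
#' @param gap_policy passed to [tamura_nei_distance()]. Under
#'   `"complete_deletion"` with `aligned = TRUE`, columns gapped in any row
#'   are removed once, before all pairwise computations.
#' @param ... alignment parameters passed to [align_pair()].
#' @return an object of class `tn_distmat`: list with `d` (symmetric numeric
#'   matrix, ids as dimnames), `pairs` (long tibble of per-pair `tn_result`
#'   rows) and `taxa` (id -> taxon lookup). Use [generics::tidy()] /
#'   [generics::glance()] to extract tables.
#' @export
tn_distance_matrix <- function(templates, aligned = FALSE,
                               gap_policy = c("pairwise_deletion",
                                              "complete_deletion"), ...) {
  gap_policy <- match.arg(gap_policy)
  templates <- tibble::as_tibble(templates)
  stopifnot(all(c("id", "sequence") %in% names(templates)))
  if (nrow(templates) < 2L) stop("need at least 2 templates")
  seqs <- toupper(templates$sequence)
  ids <- templates$id

  if (aligned) {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("aligned = TRUE requires equal-length sequences")
    }
    if (gap_policy == "complete_deletion") {
      mat <- do.call(rbind, lapply(seqs, seq_chars))
      keep <- colSums(mat == "-") == 0L
      seqs <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
    }
  }

  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  pairs <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pr <- if (aligned) {
        list(id_a = ids[i], id_b = ids[j], aligned_a = seqs[i], aligned_b = seqs[j])
      } else {
        align_pair(seqs[i], seqs[j], id_a = ids[i], id_b = ids[j], ...)
      }
      res <- tamura_nei_distance(pr, gap_policy = gap_policy)
      d[i, j] <- d[j, i] <- res$d
      k <- k + 1L
      pairs[[k]] <- res
    }
  }
  structure(
    list(d = d, pairs = dplyr::bind_rows(pairs),
         taxa = stats::setNames(
           if ("taxon" %in% names(templates)) templates$taxon else rep(NA_character_, n),
           ids)),
    class = "tn_distmat")
}

#' @export
print.tn_distmat <- function(x, ...) {
  cat("<tn_distmat> ", nrow(x$d), " sequences, ",
      sum(x$pairs$saturated), " saturated pair(s)\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Tidy a Tamura-Nei distance matrix into a long pair table
#'
#' @param x a `tn_distmat`.
#' @param ... unused.
#' @return a tibble with one row per unordered pair: ids, taxa, the distance
#'   and its intermediate quantities.
#' @export
tidy.tn_distmat <- function(x, ...) {
  out <- x$pairs
  out$taxon_a <- unname(x$taxa[out$id_a])
  out$taxon_b <- unname(x$taxa[out$id_b])
  dplyr::relocate(out, "id_a", "id_b", "taxon_a", "taxon_b", "d")
}

#' One-row summary of a Tamura-Nei distance matrix
#'
#' Reports pair counts, the distance range, and -- when taxa have more than
#' one member -- the mean within-taxon distance alongside the mean
#' between-taxon distance.
#'
#' @param x a `tn_distmat`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.tn_distmat <- function(x, ...) {
  p <- tidy(x)
  within <- !is.na(p$taxon_a) & !is.na(p$taxon_b) & p$taxon_a == p$taxon_b
  tibble::tibble(
    n_sequences = nrow(x$d),
    n_pairs = nrow(p),
    n_saturated = sum(p$saturated),
    min_d = min(p$d), max_d = max(p$d),
    mean_within_taxon_d = if (any(within)) mean(p$d[within]) else NA_real_,
    mean_between_taxon_d = if (any(!within)) mean(p$d[!within]) else NA_real_)
}

#' Write a distance matrix as TSV
#'
#' @param x a `tn_distmat`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(x, path) {
  stopifnot(inherits(x, "tn_distmat"))
  utils::write.table(cbind(id = rownames(x$d), as.data.frame(x$d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
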
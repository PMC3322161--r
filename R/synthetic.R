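#' Configuration for a synthetic ITS2-like sequence panel
#'
#' The generator emulates the reference-sample structure of a congeneric
#' multiplex-assay study: a handful of target taxa whose ITS2-like core
#' diverges by controlled Tamura-Nei distances (spanning roughly 0.003 to
#' 0.28, a close species pair through two deep taxa), near-zero
#' intraspecific variation, deeply diverged decoy taxa standing in for
#' unrelated species, and conserved 5.8S/28S-like flanks carrying the
#' universal primer sites.
#'
#' Divergence targets are path lengths on a fixed attachment tree (for the
#' default seven taxa) because an arbitrary dense pairwise target matrix is
#' not additive, hence not realisable by any evolutionary process. Divergence
#' is applied as substitutions only (transition:transversion 2:1 by default),
#' so all panel members share one core length drawn from
#' `its2_length_range`; set `indel_rate > 0` to add indels for alignment
#' stress-testing.
#'
#' @param n_target_taxa number of target taxa (default 7; a curated tree
#'   mirroring congeneric sharpnose divergences is used at 7, a log-spaced
#'   star tree otherwise).
#' @param n_decoy_taxa number of decoy taxa generated at `decoy_distance`
#'   from the ancestor (so >= 0.2 from every target).
#' @param n_per_taxon individuals per target taxon; replicates diverge by
#'   `intra_taxon_distance`.
#' @param its2_length_range core locus length range in bp; one length is
#'   drawn per panel.
#' @param flank_length length of each conserved flank (bp).
#' @param gc_fraction GC content of the ancestral core; rDNA spacers are
#'   GC-rich.
#' @param kappa transition:transversion ratio of the substitution process.
#' @param decoy_distance Tamura-Nei distance from the ancestor to each
#'   decoy. Decoys stand in for sharks of other genera and orders, whose
#'   ITS2 divergence from the targets is deep; the default 0.45 keeps every
#'   decoy >= 0.45 from every target (well above the 0.2 floor that already
#'   separates congeners from non-congeners).
#' @param intra_taxon_distance divergence between individuals of one taxon.
#' @param embed_universal_sites place the universal primer pair's annealing
#'   sites in the flanks.
#' @param indel_rate expected indels per taxon core (default 0, substitutions
#'   only).
#' @param seed integer seed; mandatory, every run is fully reproducible.
#' @return a list of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(n_target_taxa = 7L, n_decoy_taxa = 10L,
                                   n_per_taxon = 1L,
                                   its2_length_range = c(1282L, 1365L),
                                   flank_length = 120L, gc_fraction = 0.58,
                                   kappa = 2, decoy_distance = 0.45,
                                   intra_taxon_distance = 0.0005,
                                   embed_universal_sites = TRUE,
                                   indel_rate = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(n_target_taxa >= 2L, n_decoy_taxa >= 0L,
            all(its2_length_range > 0), flank_length >= 0L,
            gc_fraction > 0, gc_fraction < 1,
            decoy_distance >= 0, decoy_distance < 0.75)
  structure(list(n_target_taxa = as.integer(n_target_taxa),
                 n_decoy_taxa = as.integer(n_decoy_taxa),
                 n_per_taxon = as.integer(n_per_taxon),
                 its2_length_range = as.integer(its2_length_range),
                 flank_length = as.integer(flank_length),
                 gc_fraction = gc_fraction, kappa = kappa,
                 decoy_distance = decoy_distance,
                 intra_taxon_distance = intra_taxon_distance,
                 embed_universal_sites = isTRUE(embed_universal_sites),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "synthetic_panel_config")
}

# attachment tree: each row attaches a node to a parent by a branch of the
# given expected Tamura-Nei length; taxon = NA marks internal nodes.
default_tree <- function(n) {
  if (n == 7L) {
    tibble::tibble(
      node = c("t1", "t2", "t3", "t4", "t5", "A", "t6", "t7"),
      parent = c("root", "root", "root", "root", "root", "root", "A", "A"),
      branch = c(0.0015, 0.0015, 0.008, 0.0075, 0.058, 0.075, 0.130, 0.147),
      taxon = c(paste0("taxon_", 1:5), NA, "taxon_6", "taxon_7"))
  } else {
    radii <- exp(seq(log(0.0015), log(0.135), length.out = n))
    tibble::tibble(node = paste0("t", seq_len(n)), parent = "root",
                   branch = radii, taxon = paste0("taxon_", seq_len(n)))
  }
}

# pairwise path lengths between taxa of an attachment tree
tree_target_distances <- function(tree) {
  depth <- c(root = 0)
  path <- list(root = character(0))
  for (i in seq_len(nrow(tree))) {
    depth[tree$node[i]] <- depth[[tree$parent[i]]] + tree$branch[i]
    path[[tree$node[i]]] <- c(path[[tree$parent[i]]], tree$node[i])
  }
  tips <- tree[!is.na(tree$taxon), ]
  n <- nrow(tips)
  d <- matrix(0, n, n, dimnames = list(tips$taxon, tips$taxon))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pi <- path[[tips$node[i]]]; pj <- path[[tips$node[j]]]
      shared <- intersect(pi, pj)
      d[i, j] <- depth[[tips$node[i]]] + depth[[tips$node[j]]] -
        2 * (if (length(shared)) max(depth[shared]) else 0)
    }
  }
  d
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                      C = c("A", "G"), T = c("A", "G"))

#' Mutate a sequence to a target Tamura-Nei divergence
#'
#' Applies single-site substitutions (transition with probability
#' `kappa / (kappa + 1)`, transversion otherwise) one at a time, measuring
#' the realized Tamura-Nei distance back to the original after each, and
#' stops at the first substitution that reaches the target. Because the
#' distance is measured rather than predicted, the realized divergence
#' overshoots the target by at most one substitution's worth.
#'
#' Uses the session RNG: seed it (or call from [generate_panel()], which
#' seeds from its config) for reproducibility.
#'
#' @param sequence DNA string over A/C/G/T.
#' @param target_d target Tamura-Nei distance in [0, 0.75).
#' @param kappa transition:transversion ratio.
#' @param max_events bail-out bound on substitution events (default five per
#'   site) -- reaching it means the target is beyond saturation for this
#'   sequence, and is an error reporting the achieved distance.
#' @param seed optional integer: seed (and afterwards restore) the RNG, for
#'   standalone reproducible use.
#' @return the mutated sequence string.
#' @export
mutate_to_divergence <- function(sequence, target_d, kappa = 2,
                                 max_events = NULL, seed = NULL) {
  stopifnot(target_d >= 0, target_d < 0.75)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
  }
  if (target_d == 0) return(sequence)
  orig <- seq_chars(normalize_dna(sequence))
  if (any(!orig %in% c("A", "C", "G", "T"))) stop("sequence must be plain A/C/G/T")
  cur <- orig
  n <- length(cur)
  if (is.null(max_events)) max_events <- 5L * n
  p_ts <- kappa / (kappa + 1)
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

  # incremental bookkeeping: pooled base counts and site-pair classification
  base_cnt <- table(factor(c(orig, cur), levels = c("A", "C", "G", "T")))
  base_cnt <- as.numeric(base_cnt); names(base_cnt) <- c("A", "C", "G", "T")
  nP1 <- 0L; nP2 <- 0L; nQ <- 0L
  pair_class <- function(a, b) {
    if (a == b) return(0L)
    if (pur[[a]] && pur[[b]]) return(1L)
    if (!pur[[a]] && !pur[[b]]) return(2L)
    3L
  }
  measure <- function() {
    tn_from_proportions(base_cnt[["A"]] / (2 * n), base_cnt[["C"]] / (2 * n),
                        base_cnt[["G"]] / (2 * n), base_cnt[["T"]] / (2 * n),
                        nP1 / n, nP2 / n, nQ / n)
  }

  d <- 0
  for (ev in seq_len(max_events)) {
    i <- sample.int(n, 1L)
    old <- cur[i]
    new <- if (stats::runif(1) < p_ts) TRANSITION[[old]] else
      sample(TRANSVERSIONS[[old]], 1L)
    oc <- pair_class(orig[i], old); nc <- pair_class(orig[i], new)
    if (oc == 1L) nP1 <- nP1 - 1L else if (oc == 2L) nP2 <- nP2 - 1L else if (oc == 3L) nQ <- nQ - 1L
    if (nc == 1L) nP1 <- nP1 + 1L else if (nc == 2L) nP2 <- nP2 + 1L else if (nc == 3L) nQ <- nQ + 1L
    base_cnt[[old]] <- base_cnt[[old]] - 1
    base_cnt[[new]] <- base_cnt[[new]] + 1
    cur[i] <- new
    prev_d <- d
    m <- measure()
    if (m$saturated) stop("saturation before reaching target divergence ", target_d)
    d <- m$d
    if (d >= target_d) {
      # nearest-achievable stop: keep the crossing substitution only if it
      # lands closer to the target than the state just before it
      if (abs(d - target_d) > abs(target_d - prev_d)) {
        cur[i] <- old
      }
      return(paste(cur, collapse = ""))
    }
  }
  stop("could not reach target divergence ", target_d,
       "; achieved ", signif(d, 4), " after ", max_events, " events")
}

#' Generate a synthetic ITS2-like panel
#'
#' Produces one template per individual: conserved flank, divergent core,
#' conserved flank, with the universal primer sites embedded in the flanks
#' (so every panel member yields the whole-locus positive-control product).
#' Target taxa diverge along the configured tree; decoys diverge
#' independently and deeply from the ancestor. Deterministic: the same
#' config (including seed) gives byte-identical output.
#'
#' @param config a [synthetic_panel_config()].
#' @return a list with `templates` (template tibble: targets then decoys,
#'   `its2_start`/`its2_end` populated) and `manifest` (list: seed, realized
#'   core length, taxa, the target distance matrix, universal primer tibble
#'   and their site coordinates, tree table).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_panel_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  L <- if (length(unique(config$its2_length_range)) == 1L) config$its2_length_range[1] else
    sample(seq.int(config$its2_length_range[1], config$its2_length_range[2]), 1L)
  fl <- config$flank_length
  flank5 <- random_dna(fl, config$gc_fraction)
  flank3 <- random_dna(fl, config$gc_fraction)
  uni <- UNIVERSAL_PLACEHOLDERS
  uf_start <- uf_end <- ur_start <- ur_end <- NA_integer_
  if (config$embed_universal_sites && fl >= 100L) {
    uf <- uni$sequence[uni$role == "universal_forward"]
    ur <- uni$sequence[uni$role == "universal_reverse"]
    uf_start <- 21L; uf_end <- uf_start + nchar(uf) - 1L
    substr(flank5, uf_start, uf_end) <- uf
    ur_end_in3 <- fl - 20L
    ur_start_in3 <- ur_end_in3 - nchar(ur) + 1L
    substr(flank3, ur_start_in3, ur_end_in3) <- revcomp(ur)
    ur_start <- fl + L + ur_start_in3
    ur_end <- fl + L + ur_end_in3
  }

  ancestor <- random_dna(L, config$gc_fraction)
  tree <- default_tree(config$n_target_taxa)
  target_d <- tree_target_distances(tree)
  node_seq <- list(root = ancestor)
  for (i in seq_len(nrow(tree))) {
    node_seq[[tree$node[i]]] <- mutate_to_divergence(
      node_seq[[tree$parent[i]]], tree$branch[i], kappa = config$kappa)
  }
  tips <- tree[!is.na(tree$taxon), ]

  # the reference panel being emulated admits well-separated fully specific
  # primer sites for every species; guarantee the analogue: each target must
  # own at least two interior columns, at least 100 bp apart, where it
  # differs from all other targets. A tip whose (few) private substitutions
  # were erased by homoplasy, landed at the core edge or clumped together
  # has its terminal branch redrawn; its divergences are unchanged.
  has_usable_site <- function(tip_idx) {
    cur <- seq_chars(node_seq[[tips$node[tip_idx]]])
    others <- lapply(tips$node[-tip_idx], function(nd) seq_chars(node_seq[[nd]]))
    diffs <- rep(TRUE, length(cur))
    for (o in others) diffs <- diffs & (o != cur)
    at <- which(diffs)
    at <- at[at >= 40L & at <= length(cur) - 3L]
    length(at) >= 2L && (max(at) - min(at)) >= 100L
  }
  for (i in seq_len(nrow(tips))) {
    attempt <- 0L
    while (!has_usable_site(i)) {
      attempt <- attempt + 1L
      if (attempt > 20L) {
        stop("could not realise a diagnosable panel: taxon ", tips$taxon[i],
             " has no private diagnostic site after 20 redraws")
      }
      parent <- tree$parent[tree$node == tips$node[i]]
      node_seq[[tips$node[i]]] <- mutate_to_divergence(
        node_seq[[parent]], tips$branch[i], kappa = config$kappa)
    }
  }

  rows <- list()
  for (i in seq_len(nrow(tips))) {
    base <- node_seq[[tips$node[i]]]
    for (k in seq_len(config$n_per_taxon)) {
      core <- if (k == 1L) base else
        mutate_to_divergence(base, config$intra_taxon_distance, kappa = config$kappa)
      if (config$indel_rate > 0) core <- apply_indels(core, config$indel_rate)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("%s_%02d", tips$taxon[i], k), taxon = tips$taxon[i],
        sequence = paste0(flank5, core, flank3),
        its2_start = fl + 1L, its2_end = fl + nchar(core))
    }
  }
  for (j in seq_len(config$n_decoy_taxa)) {
    core <- mutate_to_divergence(ancestor, config$decoy_distance, kappa = config$kappa)
    if (config$indel_rate > 0) core <- apply_indels(core, config$indel_rate)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = sprintf("decoy_%02d_01", j), taxon = sprintf("decoy_%02d", j),
      sequence = paste0(flank5, core, flank3),
      its2_start = fl + 1L, its2_end = fl + nchar(core))
  }
  templates <- dplyr::bind_rows(rows)

  list(templates = validate_templates(templates),
       manifest = list(
         seed = config$seed, core_length = L, flank_length = fl,
         taxa = tips$taxon, decoy_taxa = unique(grep("^decoy", templates$taxon, value = TRUE)),
         target_distances = target_d, tree = tree,
         universal_primers = uni,
         universal_sites = list(forward = c(start = uf_start, end = uf_end),
                                reverse = c(start = ur_start, end = ur_end)),
         config = unclass(config)))
}

# a few short (1-5 bp) indels, for alignment stress-testing only
apply_indels <- function(core, rate) {
  n_ind <- stats::rpois(1, rate)
  for (z in seq_len(n_ind)) {
    len <- sample.int(5L, 1L)
    if (stats::runif(1) < 0.5) {
      at <- sample.int(nchar(core) - len, 1L)
      core <- paste0(substr(core, 1L, at), substr(core, at + len + 1L, nchar(core)))
    } else {
      at <- sample.int(nchar(core), 1L)
      core <- paste0(substr(core, 1L, at), random_dna(len, 0.5),
                     substr(core, at + 1L, nchar(core)))
    }
  }
  core
}
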
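# Independent oracles: deliberately naive re-implementations used only to
# check the package's optimised code paths.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# naive all-offsets binding-site scan (plain A/C/G/T only), double loop
oracle_scan <- function(primer, template, max_mm, anchor) {
  p <- strsplit(primer, "")[[1]]
  tm <- strsplit(template, "")[[1]]
  m <- length(p); n <- length(tm)
  out <- list()
  add <- function(strand, start, mm) {
    out[[length(out) + 1L]] <<- data.frame(strand = strand, start = start,
                                           end = start + m - 1L, mismatches = mm)
  }
  if (m <= n) {
    for (s in 1:(n - m + 1L)) {
      mmv <- p != tm[s:(s + m - 1L)]
      # plus strand: primer 3' end is the rightmost position
      if (sum(mmv) <= max_mm && (anchor == 0 || !any(mmv[(m - anchor + 1L):m]))) {
        add("+", s, sum(mmv))
      }
      rc <- strsplit(oracle_revcomp(primer), "")[[1]]
      mmv <- rc != tm[s:(s + m - 1L)]
      # minus strand: primer 3' end is the leftmost position of the rc match
      if (sum(mmv) <= max_mm && (anchor == 0 || !any(mmv[1:anchor]))) {
        add("-", s, sum(mmv))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$strand, df$start), ]
}

# quadratic Needleman-Wunsch with linear gap cost, score only
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- (0:m) * gap
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- i * gap
    for (j in 1:m) {
      s <- if (a[i] == b[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1]
}

k2p_closed_form <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))

as_primer_row <- function(seq, name = "p1", role = "species_specific") {
  tibble::tibble(name = name, sequence = seq, orientation = "forward", role = role)
}

as_template_row <- function(seq, id = "t1", taxon = NA_character_) {
  tibble::tibble(id = id, taxon = taxon, sequence = seq)
}

# shared seeded panel, generated once per test run
shared_env <- new.env(parent = emptyenv())

shared_panel <- function() {
  if (is.null(shared_env$panel)) {
    shared_env$panel <- generate_panel(synthetic_panel_config(seed = 20260927))
  }
  shared_env$panel
}

shared_design <- function() {
  if (is.null(shared_env$design)) {
    shared_env$design <- design_assay(shared_panel()$templates)
  }
  shared_env$design
}

panel_core_templates <- function(panel, targets_only = TRUE) {
  tt <- panel$templates
  if (targets_only) tt <- tt[!grepl("^decoy", tt$taxon), ]
  tibble::tibble(id = tt$id, taxon = tt$taxon,
                 sequence = substr(tt$sequence, tt$its2_start, tt$its2_end))
}
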
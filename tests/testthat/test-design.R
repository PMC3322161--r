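toy_msa <- function() {
  tibble::tibble(
    id = c("t", "n1", "n2"),
    taxon = c("target", "other1", "other2"),
    sequence = c("ACGTACGTACGGACGTACGT",
                 "ACGTACGTACGAACGTACGT",
                 "ACGTACGTACGAACGTACGT"))
}

test_that("diagnostic sites are found where the target differs", {
  msa <- toy_msa()
  sites <- find_diagnostic_sites(msa, "target")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$column, 12L)
  expect_equal(sites$target_state, "G")
  expect_true(sites$fully_diagnostic)
  expect_setequal(sites$discriminates[[1]], c("other1", "other2"))

  same <- msa; same$sequence <- rep(msa$sequence[2], 3)
  expect_equal(nrow(find_diagnostic_sites(same, "target")), 0L)
  expect_error(find_diagnostic_sites(msa, "absent"), "absent")
})

test_that("site discovery equals a naive per-column comparison on the panel", {
  panel <- shared_panel()
  msa <- panel_core_templates(panel)
  sites <- find_diagnostic_sites(msa, "taxon_6")
  # naive oracle: direct per-column scan
  rows <- lapply(msa$sequence, function(s) strsplit(s, "")[[1]])
  tgt <- rows[[which(msa$taxon == "taxon_6")]]
  others <- rows[msa$taxon != "taxon_6"]
  naive_cols <- which(vapply(seq_along(tgt), function(j)
    any(vapply(others, function(o) o[j] != tgt[j], logical(1))), logical(1)))
  expect_equal(sites$column, naive_cols)
  naive_full <- which(vapply(seq_along(tgt), function(j)
    all(vapply(others, function(o) o[j] != tgt[j], logical(1))), logical(1)))
  expect_equal(sites$column[sites$fully_diagnostic], naive_full)
})

test_that("melting temperature and GC follow the documented formulas", {
  # published primer sequence: 19-mer, 14 G/C
  seq19 <- "GCGAGGCACACCTCGGCAC"
  expect_equal(primer_tm(seq19), 64.9 + 41 * (14 - 16.4) / 19)
  expect_equal(gc_fraction(seq19), 14 / 19)
  expect_equal(gc_fraction(paste(rep("G", 20), collapse = "")), 1.0)
  # Wallace rule below 14 nt
  expect_equal(primer_tm("ACGTACGTACGT"), 2 * 6 + 4 * 6)
})

test_that("candidates anchor their 3' end on a fully diagnostic site", {
  # single diagnostic site at the last position: all candidates must end on it
  msa <- tibble::tibble(
    id = c("t", "n"), taxon = c("target", "other"),
    sequence = c(paste0(strrep("ACGGTC", 5), "GCAGGCTGACGTTGACCGGAC"),
                 paste0(strrep("ACGGTC", 5), "GCAGGCTGACGTTGACCGGAT")))
  cons <- primer_constraints(anchor_len = 1L, tm_min = 0, tm_max = 100,
                             gc_min = 0, gc_max = 1, forbid_self_dimer = FALSE)
  cand <- enumerate_candidates(msa, "target", cons)
  expect_gt(nrow(cand), 0L)
  expect_true(all(cand$end == nchar(msa$sequence[1])))
  expect_true(all(cand$anchor_mismatch_all_nontargets))
  expect_true(all(nchar(cand$sequence) >= 18 & nchar(cand$sequence) <= 25))
})

test_that("specificity screening rejects planted primers and matches a naive screen", {
  panel <- shared_panel()
  decoys <- panel$templates[grepl("^decoy", panel$templates$taxon), ]
  planted <- substr(decoys$sequence[1], 301, 322)
  cand <- tibble::tibble(name = c("planted", "clean"),
                         target_taxon = "taxon_1",
                         sequence = c(planted, "GGATCCTTAGGCAATCCGTGAC"))
  screened <- screen_specificity(cand, decoys)
  expect_false(screened$retained[screened$name == "planted"])
  expect_equal(screened$offending_template[screened$name == "planted"], decoys$id[1])

  # naive oracle: a candidate is retained iff no template carries any site
  pol <- binding_policy()
  naive_keep <- vapply(cand$sequence, function(p) {
    !any(vapply(decoys$sequence, function(tm)
      nrow(oracle_scan(p, tm, pol$max_mismatches, pol$three_prime_anchor)) > 0,
      logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_equal(screened$retained, naive_keep)
})

test_that("retained designed candidates mismatch every congener at the 3' anchor", {
  des <- shared_design()
  expect_true(all(des$candidates$anchor_mismatch_all_nontargets))
  expect_true(all(des$candidates$min_mismatches_vs_nontargets >= 1))
})

test_that("ladder selection maximises the minimum gap with documented tie-breaks", {
  # trivial: one candidate per taxon
  cand <- tibble::tibble(name = c("a", "b"), target_taxon = c("x", "y"),
                         predicted_product_bp = c(300, 700))
  lad <- select_ladder(cand)
  expect_equal(lad$min_pairwise_gap_bp, 400)

  # 2 taxa, sizes {400,410} x {400,800}: exhaustive oracle over 4 combos
  cand <- tibble::tibble(
    name = c("x400", "x410", "y400", "y800"),
    target_taxon = c("x", "x", "y", "y"),
    predicted_product_bp = c(400, 410, 400, 800))
  combos <- expand.grid(i = 1:2, j = 3:4)
  gaps <- apply(combos, 1, function(k)
    abs(cand$predicted_product_bp[k[1]] - cand$predicted_product_bp[k[2]]))
  lad <- select_ladder(cand)
  expect_equal(lad$min_pairwise_gap_bp, max(gaps))  # 400 with (400, 800)
  expect_setequal(lad$chosen$name, c("x400", "y800"))

  # genuine tie (gap 100 both ways) resolved by lexicographic name
  tie <- tibble::tibble(name = c("x400", "y300", "y500"),
                        target_taxon = c("x", "y", "y"),
                        predicted_product_bp = c(400, 300, 500))
  expect_setequal(select_ladder(tie)$chosen$name, c("x400", "y300"))

  # explicit infeasibility
  tight <- tibble::tibble(name = c("a", "b"), target_taxon = c("x", "y"),
                          predicted_product_bp = c(400, 430))
  expect_error(select_ladder(tight, min_gap_bp = 100), "infeasible")
  expect_error(select_ladder(tight[0, ]), "no candidates")

  # the seven packaged sizes as fixed singletons: brute-force pairwise scan
  sizes <- c(230, 420, 560, 720, 850, 1150, 1300)
  cand <- tibble::tibble(name = paste0("p", sizes),
                         target_taxon = paste0("s", seq_along(sizes)),
                         predicted_product_bp = sizes)
  lad <- select_ladder(cand)
  expect_equal(lad$min_pairwise_gap_bp, min(as.numeric(dist(sizes))))
  expect_equal(lad$min_pairwise_gap_bp, 130)
})

test_that("candidates landing in the control window are excluded", {
  cand <- tibble::tibble(name = c("lo", "hi"), target_taxon = c("x", "x"),
                         predicted_product_bp = c(300, 900))
  lad <- select_ladder(cand, control_range = c(860, 1500))
  expect_equal(lad$chosen$name, "lo")
  expect_error(select_ladder(cand[2, ], control_range = c(860, 1500)),
               "no eligible candidate")
})

test_that("the designed assay achieves its ladder gap and validates", {
  des <- shared_design()
  key <- des$assay$diagnostic_key
  expect_equal(min(as.numeric(dist(key$expected_bp))), des$ladder$min_pairwise_gap_bp)
  expect_gt(des$ladder$min_pairwise_gap_bp, 2 * max(key$tolerance_bp))
  expect_silent(validate_assay(des$assay))
  expect_equal(nrow(tidy(des)), 7L)
  expect_equal(glance(des)$n_taxa, 7L)
})
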
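test_that("global alignment handles trivial and gapped cases", {
  p <- align_pair("ACGT", "ACGT")
  expect_equal(p$aligned_a, "ACGT")
  expect_equal(p$aligned_b, "ACGT")
  p <- align_pair("ACGT", "ACG", gap_open = 0, gap_extend = 2)
  gaps <- sum(strsplit(p$aligned_b, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  expect_error(align_pair("ACGT", ""), "non-empty")
  expect_error(align_pair("ACNT", "ACGT"), "A/C/G/T")
})

test_that("alignment score matches an exhaustive dynamic-programming oracle", {
  set.seed(11)
  for (r in 1:10) {
    a <- rand_dna(50); b <- rand_dna(sample(40:55, 1))
    p <- align_pair(a, b, match = 1, mismatch = -1, gap_open = 0, gap_extend = 2)
    expect_equal(p$score, oracle_nw_score(a, b, 1, -1, -2))
  }
})

test_that("identical sequences give a distance of exactly zero", {
  r <- tamura_nei_distance(list(aligned_a = "ACGTACGTAA", aligned_b = "ACGTACGTAA"))
  expect_identical(r$d, 0)
  expect_equal(r$P1 + r$P2 + r$Q, 0)
  expect_false(r$saturated)
})

test_that("distance matches a hand evaluation of the formula on counted changes", {
  # 100 repeats of ACGT: 2 A<->G, 1 C<->T, 1 A<->C changes
  a <- rep(c("A", "C", "G", "T"), 100)
  b <- a
  b[1] <- "G"; b[5] <- "G"      # two purine transitions
  b[2] <- "T"                    # one pyrimidine transition
  b[9] <- "C"                    # one transversion
  n <- 400
  # hand evaluation, written out step by step from the counts
  cnt <- table(factor(c(a, b), levels = c("A", "C", "G", "T")))
  gA <- cnt[["A"]] / (2 * n); gC <- cnt[["C"]] / (2 * n)
  gG <- cnt[["G"]] / (2 * n); gT <- cnt[["T"]] / (2 * n)
  gR <- gA + gG; gY <- gC + gT
  P1 <- 2 / n; P2 <- 1 / n; Q <- 1 / n
  hand <- -(2 * gA * gG / gR) * log(1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)) -
    (2 * gT * gC / gY) * log(1 - gY * P2 / (2 * gT * gC) - Q / (2 * gY)) -
    2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY) * log(1 - Q / (2 * gR * gY))
  r <- tamura_nei_distance(list(aligned_a = paste(a, collapse = ""),
                                aligned_b = paste(b, collapse = "")))
  expect_equal(r$d, hand, tolerance = 1e-12)
  expect_equal(r$P1, P1); expect_equal(r$P2, P2); expect_equal(r$Q, Q)
  expect_equal(r$sites_used, n)
})

test_that("distance agrees with ape's TN93 on random divergent pairs", {
  skip_if_not_installed("ape")
  set.seed(7)
  for (r in 1:8) {
    n <- 300
    a <- strsplit(rand_dna(n, gc = 0.6), "")[[1]]
    b <- a
    for (i in sample(n, 40)) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    mine <- tamura_nei_distance(list(aligned_a = paste(a, collapse = ""),
                                     aligned_b = paste(b, collapse = "")))$d
    m <- rbind(a, b); rownames(m) <- c("x", "y")
    theirs <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                                       pairwise.deletion = TRUE))
    expect_equal(mine, theirs, tolerance = 1e-12)
  }
})

test_that("with equal frequencies and balanced changes TN reduces to Kimura 2P", {
  a <- rep(c("A", "C", "G", "T"), 75)
  b <- a
  b[1] <- "G"; b[3] <- "A"    # balanced purine transitions
  b[2] <- "T"; b[4] <- "C"    # balanced pyrimidine transitions
  b[5] <- "C"; b[6] <- "A"    # balanced transversions
  r <- tamura_nei_distance(list(aligned_a = paste(a, collapse = ""),
                                aligned_b = paste(b, collapse = "")))
  expect_equal(c(r$gA, r$gC, r$gG, r$gT), rep(0.25, 4))
  expect_equal(r$d, k2p_closed_form(P = 4 / 300, Q = 2 / 300), tolerance = 1e-9)
})

test_that("saturation is flagged, never an error", {
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(rep(c("C", "T"), 25), collapse = "")
  r <- tamura_nei_distance(list(aligned_a = a, aligned_b = b))
  expect_true(r$saturated)
  expect_identical(r$d, Inf)
})

test_that("adding substitutions below saturation never decreases the distance", {
  set.seed(5)
  a <- strsplit(rand_dna(500), "")[[1]]
  b <- a
  prev <- 0
  sites <- sample(500, 60)
  for (i in sites) {
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    d <- tamura_nei_distance(list(aligned_a = paste(a, collapse = ""),
                                  aligned_b = paste(b, collapse = "")))$d
    expect_gte(d, prev - 1e-12)
    prev <- d
  }
})

test_that("distance matrix is symmetric with a zero diagonal", {
  tt <- tibble::tibble(id = c("x", "y"), sequence = c("ACGTACGTACGT", "ACGTACGTACGT"))
  dm <- tn_distance_matrix(tt)
  expect_equal(dm$d, matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))))

  panel <- shared_panel()
  cores <- panel_core_templates(panel)
  dm <- tn_distance_matrix(cores, aligned = TRUE)
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), setNames(rep(0, 7), cores$id))
  td <- tidy(dm)
  expect_equal(nrow(td), choose(7, 2))
  g <- glance(dm)
  expect_equal(g$n_sequences, 7L)
})

test_that("matrix on the synthetic panel recovers generator targets within 15%", {
  panel <- shared_panel()
  cores <- panel_core_templates(panel)
  cores$id <- cores$taxon
  dm <- tn_distance_matrix(cores, aligned = TRUE)
  tgt <- panel$manifest$target_distances[cores$taxon, cores$taxon]
  off <- upper.tri(tgt)
  rel <- abs(dm$d[off] - tgt[off]) / tgt[off]
  expect_lt(max(rel), 0.15)
})

test_that("complete deletion drops globally gapped columns before computing", {
  tt <- tibble::tibble(
    id = c("x", "y", "z"),
    sequence = c("AC-TACGT", "ACGTACGT", "ACGTACAT"))
  full <- tn_distance_matrix(tt, aligned = TRUE, gap_policy = "complete_deletion")
  # column 3 removed for all: x and y become identical
  expect_equal(full$d["x", "y"], 0)
  pw <- tn_distance_matrix(tt, aligned = TRUE, gap_policy = "pairwise_deletion")
  # y vs z unaffected by x's gap under pairwise deletion
  expect_gt(pw$d["y", "z"], full$d["x", "y"])
  expect_equal(pw$pairs$sites_used[pw$pairs$id_a == "y" & pw$pairs$id_b == "z"], 8L)
})
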
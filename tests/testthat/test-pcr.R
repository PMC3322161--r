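test_that("exact-match primer binds its template at full length, both strands", {
  s <- "ACGTACGTACGTACGTACGT"
  sites <- find_binding_sites(as_template_row(s), as_primer_row(s))
  plus <- sites[sites$strand == "+", ]
  expect_true(any(plus$start == 1 & plus$end == 20 & plus$mismatches == 0))

  # primer equal to the reverse complement of a template slice: minus strand
  tmpl <- rand_dna(200)
  set.seed(3)
  slice <- substr(tmpl, 61, 80)
  pr <- as_primer_row(revcomp(slice))
  sites <- find_binding_sites(as_template_row(tmpl), pr)
  minus <- sites[sites$strand == "-", ]
  expect_true(any(minus$start == 61 & minus$end == 80 & minus$mismatches == 0))
})

test_that("planted single-mismatch site is found exactly where expected", {
  set.seed(137)
  tmpl <- rand_dna(1000)
  primer <- substr(tmpl, 138, 157)
  # plant one internal mismatch outside the 3' anchor
  ch <- strsplit(primer, "")[[1]]
  ch[8] <- setdiff(c("A", "C", "G", "T"), ch[8])[1]
  primer <- paste(ch, collapse = "")
  policy <- binding_policy(max_mismatches = 2, three_prime_anchor = 3)
  sites <- find_binding_sites(as_template_row(tmpl), as_primer_row(primer), policy)
  plus <- sites[sites$strand == "+", ]
  naive <- oracle_scan(primer, tmpl, 2, 3)
  naive_plus <- naive[naive$strand == "+", ]
  expect_equal(plus$start, naive_plus$start)
  expect_true(any(plus$start == 138 & plus$mismatches == 1))
})

test_that("scanner equals the naive all-offsets oracle on fuzzed instances", {
  set.seed(99)
  for (r in 1:60) {
    tlen <- sample(60:400, 1)
    tmpl <- rand_dna(tlen, gc = runif(1, 0.3, 0.7))
    plen <- sample(12:25, 1)
    primer <- if (runif(1) < 0.5) rand_dna(plen) else {
      at <- sample(tlen - plen, 1)
      p <- substr(tmpl, at, at + plen - 1)
      ch <- strsplit(p, "")[[1]]
      nmut <- sample(0:3, 1)
      for (i in sample(plen, nmut)) ch[i] <- sample(c("A", "C", "G", "T"), 1)
      paste(ch, collapse = "")
    }
    mm <- sample(0:3, 1); anc <- sample(0:4, 1)
    policy <- binding_policy(max_mismatches = mm, three_prime_anchor = anc)
    got <- find_binding_sites(as_template_row(tmpl), as_primer_row(primer), policy)
    want <- oracle_scan(primer, tmpl, mm, anc)
    got <- got[order(got$strand, got$start), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$mismatches, want$mismatches)
    expect_equal(got$strand, want$strand)
  }
})

test_that("primer ambiguity codes match consistent bases; template ambiguity does not", {
  tmpl <- as_template_row("AAAACGTACGTACGTAAAA")
  pr <- as_primer_row("ACGTACGTACGT")
  pr_amb <- pr; pr_amb$sequence <- "ACGTACRTACGT"  # R = A/G matches G
  amb_sites <- find_binding_sites(tmpl, pr_amb, binding_policy(max_mismatches = 0))
  expect_equal(sum(amb_sites$strand == "+" & amb_sites$start == 4), 1L)
  expect_true(all(amb_sites$mismatches == 0))
  tmpl_amb <- as_template_row("AAAACGTACNTACGTAAAA")
  # N in the template is a mismatch for a plain primer
  sites <- find_binding_sites(tmpl_amb, pr, binding_policy(max_mismatches = 0))
  expect_equal(nrow(sites), 0L)
})

test_that("BED export shifts to 0-based half-open coordinates", {
  s <- "ACGTACGTACGTACGTACGT"
  sites <- find_binding_sites(as_template_row(s), as_primer_row(s))
  f <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(sites, f)
  bed <- read.delim(f, header = FALSE)
  row <- bed[bed$V6 == "+", ][1, ]
  expect_equal(row$V2, 0L)
  expect_equal(row$V3, 20L)
})

test_that("a primer longer than the template yields no sites, not an error", {
  sites <- find_binding_sites(as_template_row("ACGTACGTACGT"),
                              as_primer_row(rand_dna(30)))
  expect_equal(nrow(sites), 0L)
})

test_that("single primer yields no amplicon; opposing sites give the exact length", {
  tmpl <- rand_dna(800)
  set.seed(21)
  fw <- substr(tmpl, 100, 119)
  amp <- predict_amplicons(as_template_row(tmpl), as_primer_row(fw))
  expect_equal(nrow(amp[amp$forward_primer == "p1" & amp$reverse_primer == "p1", ]), 0L)

  rv <- revcomp(substr(tmpl, 581, 600))
  primers <- dplyr::bind_rows(as_primer_row(fw, "fw"),
                              as_primer_row(rv, "rv", role = "universal_reverse"))
  amp <- predict_amplicons(as_template_row(tmpl), primers)
  hit <- amp[amp$forward_primer == "fw" & amp$reverse_primer == "rv", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length_bp, 600L - 100L + 1L)
  expect_equal(hit$classification, "diagnostic")
})

test_that("product length always equals reverse end minus forward start", {
  panel <- shared_panel()
  assay <- load_packaged_assay("nonaplex")
  amp <- predict_amplicons(panel$templates[1:3, ], assay$primers)
  if (nrow(amp)) expect_equal(amp$length_bp, amp$end - amp$start + 1L)
})

test_that("adding a primer never removes an existing predicted product", {
  set.seed(31)
  tmpl <- as_template_row(rand_dna(600))
  fw <- as_primer_row(substr(tmpl$sequence, 50, 69), "fw")
  rv <- as_primer_row(revcomp(substr(tmpl$sequence, 381, 400)), "rv",
                      role = "universal_reverse")
  base <- predict_amplicons(tmpl, dplyr::bind_rows(fw, rv))
  extra <- as_primer_row(substr(tmpl$sequence, 150, 169), "mid")
  more <- predict_amplicons(tmpl, dplyr::bind_rows(fw, rv, extra))
  key <- function(x) paste(x$forward_primer, x$reverse_primer, x$start, x$end)
  expect_true(all(key(base) %in% key(more)))
  expect_gte(nrow(more), nrow(base))
})

test_that("reverse-complementing the template mirrors predictions with equal lengths", {
  set.seed(41)
  tmpl <- rand_dna(500)
  fw <- as_primer_row(substr(tmpl, 40, 59), "fw")
  rv <- as_primer_row(revcomp(substr(tmpl, 401, 420)), "rv", role = "universal_reverse")
  amp <- predict_amplicons(as_template_row(tmpl), dplyr::bind_rows(fw, rv))
  amp_rc <- predict_amplicons(as_template_row(revcomp(tmpl)),
                              dplyr::bind_rows(fw, rv))
  expect_equal(sort(amp$length_bp), sort(amp_rc$length_bp))
  # mirror-image coordinates: start' = len - end + 1
  expect_setequal(501L - amp$end, amp_rc$start)
})

test_that("assay simulation produces the expected band counts on the panel", {
  panel <- shared_panel()
  des <- shared_design()
  bands <- simulate_assay(panel$templates, des$assay)
  counts <- table(factor(bands$lane, levels = panel$templates$id))
  targets <- panel$templates$id[!grepl("^decoy", panel$templates$taxon)]
  decoys <- panel$templates$id[grepl("^decoy", panel$templates$taxon)]
  # two amplification products expected from each target: diagnostic + control
  expect_true(all(counts[targets] == 2L))
  # non-targets: the positive control amplicon only
  expect_true(all(counts[decoys] == 1L))
  expect_true(all(bands$classification[bands$lane %in% decoys] == "control"))
})

test_that("a template with no primer sites yields an empty lane", {
  assay <- load_packaged_assay("nonaplex")
  set.seed(8)
  bands <- simulate_assay(as_template_row(rand_dna(400)), assay)
  expect_equal(nrow(bands), 0L)
  expect_equal(attr(bands, "lanes"), "t1")
})
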
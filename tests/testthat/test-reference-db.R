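test_that("IUPAC matching follows the degeneracy sets", {
  expect_true(iupac_match("R", "A"))
  expect_true(iupac_match("R", "G"))
  expect_false(iupac_match("Y", "G"))
  expect_true(iupac_match("N", "T"))
  expect_false(iupac_match("S", "A"))
  expect_error(iupac_match("X", "A"), "IUPAC")
  expect_error(iupac_match("R", "R"), "concrete")
})

test_that("degenerate-primer binding sites match the examples", {
  seq <- "TTACGAATTGCAGAACCTCGTT"
  primer <- "RCGAAYTGCAGAACCTCG"
  expect_identical(find_binding_sites(seq, primer, 0), 2L)
  mutated <- sub("TGCAG", "TGAAG", seq)   # one mismatch inside the window
  expect_identical(find_binding_sites(mutated, primer, 0), integer(0))
  expect_identical(find_binding_sites(mutated, primer, 1), 2L)
  # primer longer than the template is no hit, not an error
  expect_identical(find_binding_sites("ACGT", primer, 0), integer(0))
})

test_that("binding-site search equals the exhaustive window oracle", {
  set.seed(101)
  primers <- c("RCGAAY", "NNACGT", "TACTYAATCT", "RYSWKM")
  for (case in seq_len(100)) {
    seq <- random_dna(sample(20:200, 1))
    primer <- sample(primers, 1)
    mm <- sample(0:2, 1)
    expect_identical(find_binding_sites(seq, primer, mm),
                     as.integer(bf_find_sites(seq, primer, mm)))
  }
})

test_that("amplicon prediction pairs sites and reports full labelled length", {
  set.seed(7)
  tmpl <- make_template(insert = 312)
  am <- predict_amplicons(list(id = "r1", taxon_label = "T. test",
                               sequence = tmpl))
  expect_equal(nrow(am), 1L)
  expect_equal(am$length_bases, 18 + 312 + 18)
  expect_equal(am$end - am$start, am$length_bases)

  # no reverse site -> empty
  p <- arisa_primers()
  none <- paste0("GG", concretize(p$forward), random_dna(340))
  expect_equal(nrow(predict_amplicons(list(id = "r", taxon_label = "",
                                           sequence = none))), 0L)
})

test_that("with several reverse sites the shortest valid product is kept, as brute force confirms", {
  set.seed(8)
  p <- arisa_primers()
  rc <- concretize(reverse_complement(p$reverse))
  tmpl <- paste0("GG", concretize(p$forward), random_dna(300), rc,
                 random_dna(10), rc, "AA")
  am <- predict_amplicons(list(id = "r", taxon_label = "", sequence = tmpl))
  # brute-force pairing over all site combinations
  fwd <- bf_find_sites(tmpl, p$forward, 0)
  rev <- bf_find_sites(tmpl, reverse_complement(p$reverse), 0)
  lens <- outer(fwd, rev + nchar(p$reverse), function(f, e) e - f)
  valid <- lens[lens >= 320 & lens <= 420 & lens > nchar(p$forward)]
  expect_equal(am$length_bases, min(valid))
})

test_that("amplicon lengths are strand-consistent under template reversal with swapped primer roles", {
  set.seed(12)
  p <- arisa_primers()
  for (rep in 1:5) {
    tmpl <- make_template(insert = sample(290:380, 1))
    fwd <- predict_amplicons(list(id = "a", taxon_label = "", sequence = tmpl))
    swapped <- list(forward = p$reverse, reverse = p$forward)
    rev <- predict_amplicons(list(id = "b", taxon_label = "",
                                  sequence = reverse_complement(tmpl)),
                             primers = swapped)
    expect_equal(sort(rev$length_bases), sort(fwd$length_bases))
  }
})

test_that("bin construction merges adjacent lengths and unions labels", {
  preds <- data.frame(taxon_label = c("T. oceanica", "T. oceanica"),
                      length_bases = c(348, 349))
  bt <- build_bin_table(preds)
  expect_equal(nrow(bt), 1L)
  expect_equal(bt$low, 348L)
  expect_equal(bt$high, 349L)
  expect_equal(bt$taxon_labels, "T. oceanica")

  two <- build_bin_table(data.frame(taxon_label = c("A", "B"),
                                    length_bases = c(348, 360)))
  expect_equal(nrow(two), 2L)

  # label union across merged lengths
  un <- build_bin_table(data.frame(taxon_label = c("A", "B", "A"),
                                   length_bases = c(400, 401, 401)))
  expect_equal(un$taxon_labels, "A;B")
})

test_that("bin construction is idempotent and order-independent", {
  set.seed(3)
  lens <- sample(330:410, 25, replace = TRUE)
  preds <- data.frame(taxon_label = sprintf("t%d", seq_along(lens)),
                      length_bases = lens)
  bt1 <- build_bin_table(preds)
  for (rep in 1:5) {
    perm <- preds[sample(nrow(preds)), ]
    bt2 <- build_bin_table(perm)
    expect_equal(bt2$low, bt1$low)
    expect_equal(bt2$high, bt1$high)
    expect_equal(bt2$taxon_labels, bt1$taxon_labels)
  }
  # feeding the bin bounds back in reproduces the table
  again <- build_bin_table(data.frame(
    taxon_label = rep(bt1$taxon_labels, 2),
    length_bases = c(bt1$low, bt1$high)))
  expect_equal(again$low, bt1$low)
  expect_equal(again$high, bt1$high)
})

test_that("fragment sizes map to the reference groups", {
  tab <- arisa_fixtures()$table1_bins
  expect_equal(assign_bin(348.4, tab), 1L)
  expect_equal(assign_bin(396.7, tab), 13L)
  expect_true(is.na(assign_bin(500.0, tab)))
  expect_true(is.na(assign_bin(355.0, tab)))   # no bin covers 355
  # rounding is half-up: 348.5 -> 349 stays in group 1, 349.5 -> 350 leaves it
  expect_equal(assign_bin(348.5, tab), 1L)
  expect_true(is.na(assign_bin(349.5, tab)))
})

test_that("bin assignment honours tolerance with nearest-centre tie-breaks", {
  tab <- as_bin_table(data.frame(bin_id = 1:2, low = c(348L, 352L),
                                 high = c(349L, 353L)))
  expect_true(is.na(assign_bin(350.4, tab, tolerance = 0)))
  expect_equal(assign_bin(350.4, tab, tolerance = 1), 1L)   # 350 nearer 348.5
  expect_equal(assign_bin(351.4, tab, tolerance = 1), 2L)
  # 350/351 ambiguous at tolerance 2: ties to nearest centre, then lower id
  tabsym <- as_bin_table(data.frame(bin_id = 1:2, low = c(348L, 352L),
                                    high = c(348L, 352L)))
  expect_equal(assign_bin(350, tabsym, tolerance = 2), 1L)  # exact tie -> lower id
  # any integer inside exactly one bin returns it; outside all, NA
  full <- arisa_fixtures()$table1_bins
  for (L in 320:420) {
    inside <- which(L >= full$low & L <= full$high)
    got <- assign_bin(L, full)
    if (length(inside)) expect_equal(got, full$bin_id[inside])
    else expect_true(is.na(got))
  }
  # calibration offset shifts sizes before rounding
  expect_equal(assign_bin(347.6, full, offset = 0.8), 1L)
})

test_that("bin tables round-trip through TSV", {
  bt <- arisa_fixtures()$table1_bins
  path <- withr::local_tempfile(fileext = ".tsv")
  write_bin_table(bt, path)
  back <- read_bin_table(path)
  expect_equal(as.data.frame(back), as.data.frame(bt))
})

test_that("a reference set is summarized with both span conventions", {
  span <- bin_table_span(arisa_fixtures()$table1_bins)
  expect_equal(span$span_bounds, 62)
  expect_equal(span$span_lows, 61)
})
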
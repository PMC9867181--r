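test_that("iupac_match follows set-intersection semantics", {
  expect_true(iupac_match("W", "A"))
  expect_false(iupac_match("Y", "G"))
  for (b in c("A", "C", "G", "T", "W", "B")) expect_true(iupac_match("N", b))
  expect_true(iupac_match("A", "W"))     # symmetric
  expect_error(iupac_match("-", "A"), "gap")
  expect_error(iupac_match("A", "-"), "gap")
})

test_that("find_binding_sites locates exact, clamped and degenerate sites", {
  set.seed(41)
  tmpl <- paste0(random_dna(50), ASMF, random_dna(50))
  hits <- find_binding_sites(tmpl, ASMF)
  plus <- hits[hits$strand == "plus", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(c(plus$start, plus$end), c(50, 75))
  expect_equal(plus$mismatches, 0L)

  # substituting the 3'-terminal template base kills the site under the clamp
  tmpl3 <- tmpl
  last_base <- substr(ASMF, 25, 25)                     # "T"
  substr(tmpl3, 75, 75) <- if (last_base == "T") "G" else "T"
  hits3 <- find_binding_sites(tmpl3, ASMF,
                              binding_config(max_mismatches = 2,
                                             clamp_len = 3,
                                             max_clamp_mismatches = 0))
  expect_equal(nrow(hits3[hits3$strand == "plus" & hits3$start == 50, ]), 0L)
  # without the clamp it is back, with 1 mismatch
  hits_nc <- find_binding_sites(tmpl3, ASMF,
                                binding_config(max_mismatches = 2,
                                               clamp_len = 0))
  expect_equal(hits_nc[hits_nc$start == 50, "mismatches"], 1L)

  # degenerate primer vs a concrete expansion
  j1709 <- known_primers()[["C1-J1709"]]   # AATTGGWGGWTTYGGAAAYTG
  concrete <- chartr("WYN", "ATA", j1709)  # one expansion: W->A, Y->T
  tmpl_d <- paste0(random_dna(30), concrete, random_dna(30))
  hd <- find_binding_sites(tmpl_d, j1709)
  hd <- hd[hd$strand == "plus" & hd$start == 30, ]
  expect_equal(nrow(hd), 1L)
  expect_equal(hd$mismatches, 0L)

  # primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites("ACGT", ASMF)), 0L)
})

test_that("minus-strand coordinates map back to the plus strand", {
  set.seed(42)
  tmpl <- paste0(random_dna(20), revcomp(ASMR), random_dna(10))
  hits <- find_binding_sites(tmpl, ASMR)
  minus <- hits[hits$strand == "minus", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(c(minus$start, minus$end), c(20, 38))
  # the plus-strand slice there is the reverse complement of the primer
  expect_identical(substr(tmpl, 21, 38), revcomp(ASMR))
})

test_that("degenerate template bases match only when the primer covers them", {
  # template W under primer N: subset, matches; under primer A: not
  strict <- binding_config(max_mismatches = 0)
  h1 <- find_binding_sites("AAAWAAAA", "AAANAAAA", strict)
  expect_equal(nrow(h1[h1$strand == "plus", ]), 1L)
  h2 <- find_binding_sites("AAAWAAAA", "AAAAAAAA", strict)
  expect_equal(nrow(h2[h2$strand == "plus", ]), 0L)
})

test_that("predict_amplicons reproduces the constructed 543 bp fixture", {
  tmpl <- amplicon_fixture(gap = 500)   # ASMF + 500 + revcomp(ASMR)
  expect_equal(nchar(tmpl), 543L)
  amp <- predict_amplicons(tmpl, list(fwd = ASMF, rev = ASMR))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_size, 543L)
  expect_equal(c(amp$fwd_start, amp$rev_end), c(0L, 543L))

  # missing reverse site -> empty
  no_rev <- paste0(ASMF, substr(tmpl, 26, 525))
  expect_equal(nrow(predict_amplicons(no_rev, list(fwd = ASMF, rev = ASMR))), 0L)

  # two forward sites upstream of one reverse site -> two amplicons
  tmpl2 <- paste0(ASMF, strrep("G", 40), tmpl)
  amp2 <- predict_amplicons(tmpl2, list(fwd = ASMF, rev = ASMR))
  expect_equal(nrow(amp2), 2L)
  expect_equal(sort(amp2$product_size), c(543L, 543L + 40L + 25L))
})

test_that("predicted amplicon sites re-validate under find_binding_sites", {
  set.seed(44)
  cfg <- binding_config()
  for (i in 1:20) {
    tmpl <- amplicon_fixture(gap = sample(100:400, 1),
                             pad_left = sample(0:50, 1),
                             pad_right = sample(0:50, 1),
                             seed = 400 + i)
    amp <- predict_amplicons(tmpl, list(fwd = ASMF, rev = ASMR), cfg)
    fsites <- find_binding_sites(tmpl, ASMF, cfg)
    rsites <- find_binding_sites(tmpl, ASMR, cfg)
    for (k in seq_len(nrow(amp))) {
      expect_true(any(fsites$strand == "plus" &
                      fsites$start == amp$fwd_start[k] &
                      fsites$end == amp$fwd_end[k]))
      expect_true(any(rsites$strand == "minus" &
                      rsites$start == amp$rev_start[k] &
                      rsites$end == amp$rev_end[k]))
      expect_equal(amp$product_size[k], amp$rev_end[k] - amp$fwd_start[k])
      expect_lte(amp$product_size[k], cfg$max_product)
    }
  }
})

test_that("reverse-complementing a template preserves the product-size multiset", {
  set.seed(45)
  for (i in 1:30) {
    tmpl <- amplicon_fixture(gap = sample(50:300, 1),
                             pad_left = sample(0:40, 1),
                             pad_right = sample(0:40, 1),
                             seed = 500 + i)
    pair <- list(fwd = ASMF, rev = ASMR)
    s1 <- sort(predict_amplicons(tmpl, pair)$product_size)
    s2 <- sort(predict_amplicons(revcomp(tmpl), pair)$product_size)
    expect_equal(s1, s2)
  }
})

test_that("specificity panel reproduces the planted/non-planted lane pattern", {
  panel <- fig6_analog_panel()
  lanes <- specificity_panel(panel, list(fwd = ASMF, rev = ASMR),
                             binding_config(max_mismatches = 0))
  expect_equal(nrow(lanes), 17L)                 # 16 templates + control
  expect_true(all(lanes$detected[1:4]))
  expect_false(any(lanes$detected[5:17]))
  expect_equal(lanes$lane_label[17], "control")
  expect_equal(lanes$band_sizes[[1]], 543L)

  # non-targets only -> all lanes false
  nt <- panel[panel$role == "non_target", ]
  lanes_nt <- specificity_panel(nt, list(fwd = ASMF, rev = ASMR))
  expect_false(any(lanes_nt$detected))

  # duplicated target template gives identical lane reports
  dup <- rbind(panel[1, ], panel[1, ])
  dup$id <- c("d1", "d2")
  lanes_dup <- specificity_panel(dup, list(fwd = ASMF, rev = ASMR))
  expect_identical(lanes_dup$band_sizes[[1]], lanes_dup$band_sizes[[2]])
  expect_identical(lanes_dup$detected[1], lanes_dup$detected[2])
})

test_that("mixture panel detection is sequence-determined", {
  panel <- fig6_analog_panel()
  targets <- panel[panel$role == "target", ][1, , drop = FALSE]
  background <- panel[panel$role == "non_target", ][1:2, ]
  ratios <- c("1:0", "1:1", "1:10", "1:50", "1:100", "1:1000")
  tab <- mixture_panel(targets, background, ratios,
                       list(fwd = ASMF, rev = ASMR))
  expect_true(all(tab$detected))
  expect_equal(tab$ratio, ratios)

  tab0 <- mixture_panel(targets, background, c("0:100"),
                        list(fwd = ASMF, rev = ASMR))
  expect_false(any(tab0$detected))

  # background-only panel: no target template at all
  tab_bg <- mixture_panel(targets[0, ], background, c("1:1"),
                          list(fwd = ASMF, rev = ASMR))
  expect_false(any(tab_bg$detected))
  expect_match(attr(tab, "note"), "concentration")
})

test_that("virtual gel brackets bands between ladder rungs", {
  panel <- fig6_analog_panel()
  lanes <- specificity_panel(panel[1:2, ], list(fwd = ASMF, rev = ASMR))
  gel <- virtual_gel(lanes)
  txt <- unclass(gel)
  row543 <- grep("^\\s*543", txt)
  row750 <- grep("^\\s*750", txt)
  row500 <- grep("^\\s*500", txt)
  expect_length(row543, 1L)
  expect_true(row750 < row543 && row543 < row500)   # between 750 and 500
  expect_match(txt[row543], "====")

  # empty lane: no band marks anywhere in its column; ladder-only input
  empty_lanes <- specificity_panel(
    data.frame(id = "x", species = "s", role = "non_target",
               residues = strrep("A", 200)),
    list(fwd = ASMF, rev = ASMR)
  )
  gel_e <- unclass(virtual_gel(empty_lanes))
  expect_length(gel_e, 1L + length(dl2000_ladder()))

  # band above the top rung warns
  big <- lanes[1, ]
  big$band_sizes <- list(2500L)
  expect_warning(virtual_gel(big), "above the top ladder rung")

  expect_error(virtual_gel(lanes, ladder = c(100, 500)), "descending")
})

test_that("lane report TSV carries band sizes and brackets", {
  panel <- fig6_analog_panel()
  lanes <- specificity_panel(panel[c(1, 5), ], list(fwd = ASMF, rev = ASMR))
  lines <- write_lane_report(lanes)
  expect_length(lines, 4L)   # header + 2 lanes + control
  first <- strsplit(lines[2], "\t")[[1]]
  expect_equal(first[5], "543")
  expect_equal(first[6], "500-750")
  ctrl <- strsplit(lines[4], "\t")[[1]]
  expect_equal(ctrl[4], "FALSE")
})
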
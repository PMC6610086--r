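test_that("plan_array builds the expected unit/junction/repeat geometry", {
  d <- clean_design()
  expect_length(d$units, 3)
  expect_length(d$junctions, 4)          # n + 1 junctions for n spacers
  expect_length(unique(d$junctions), 4)  # all distinct
  # insert begins and ends with a repeat (terminal repeat from backbone)
  rep_seq <- fn_profile()$repeat_seq
  expect_true(startsWith(d$predicted_insert, rep_seq))
  expect_true(endsWith(d$predicted_insert, rep_seq))
  # 7 spacers -> 8 junctions, 8 repeats in the insert
  with_seed(42, {
    sp7 <- replicate(7, rand_seq(26, c("A", "C")))
    d7 <- plan_array(sp7, fn_profile(), fn_backbone(), seed = 3)
    expect_length(d7$junctions, 8)
    n_reps <- length(gregexpr(rep_seq, d7$predicted_insert, fixed = TRUE)[[1]])
    expect_equal(n_reps, 8)
  })
})

test_that("the no-spacer control yields two consecutive repeats", {
  d0 <- plan_array(character(0), fn_profile(), fn_backbone(),
                   no_spacer_control = TRUE)
  rep_seq <- fn_profile()$repeat_seq
  expect_true(grepl(paste0(rep_seq, "GCTG", rep_seq),
                    as.character(d0$predicted_construct), fixed = TRUE))
})

test_that("plan_array validates spacers, junctions and enzyme sites", {
  p <- fn_profile(); bb <- fn_backbone()
  expect_error(plan_array("ACGT", p, bb), "length")
  bad <- paste0("ACGTCTC", strrep("A", 19))  # internal BsmBI site
  expect_error(plan_array(bad, p, bb), "recognition site")
  expect_error(plan_array(clean_trio(), p, bb,
                          junctions = c("CCCT", "CCCA", "GGGG", "GCTG")),
               "validation")
  expect_error(plan_array(clean_trio(), p, bb,
                          junctions = c("AAAA", "CCAC", "CGCC", "GCTG")),
               "backbone")
})

test_that("concatenating unit tops through junctions reproduces the insert", {
  # property over fuzzed designs
  with_seed(99, {
    for (i in 1:5) {
      n <- sample(1:5, 1)
      sp <- replicate(n, rand_seq(26, c("A", "C")))
      d <- plan_array(sp, fn_profile(), fn_backbone(), seed = i)
      units_cat <- paste(vapply(d$units, crisparray:::unit_top, ""),
                         collapse = "")
      expect_true(grepl(units_cat, as.character(d$predicted_construct),
                        fixed = TRUE))
      # junction i never overlaps the hybridizing guide: for 3'-trim the
      # junction sits after the full 26-nt spacer, so each unit core ends
      # with the spacer itself
      for (u in d$units) {
        expect_true(endsWith(crisparray:::unit_top(u), u$spacer))
      }
    }
  })
})

test_that("make_oligos reproduces the 66-nt oligo geometry and re-anneals", {
  d <- clean_design()
  op <- make_oligos(d$units[[1]])
  expect_equal(nchar(op$top_oligo), 66)
  expect_equal(nchar(op$bottom_oligo), 66)
  expect_equal(op$duplex_len, 62)
  # first-position unit: 5' CCCT overhang; bottom oligo ends geometry
  expect_true(startsWith(op$top_oligo, "CCCT"))
  expect_identical(op$left_end$seq, "CCCT")
  expect_identical(op$right_end$seq, revcomp(d$units[[1]]$jr))
  # re-anneal: duplex core is the overlap of top and revcomp(bottom)
  core <- substr(op$top_oligo, nchar(op$left_end$seq) + 1L, nchar(op$top_oligo))
  expect_identical(revcomp(op$bottom_oligo),
                   paste0(core, d$units[[1]]$jr))
})

test_that("plan_composite enforces block order and mirrors the mixed design", {
  cas9 <- sp9_profile(); cas12 <- fn_profile()
  with_seed(21, {
    sp9 <- replicate(2, rand_seq(26, c("A", "C")))
    sp12 <- replicate(2, rand_seq(26, c("A", "C")))
    d <- plan_composite(list(list(profile = cas9, spacers = sp9),
                             list(profile = cas12, spacers = sp12)))
    expect_length(d$units, 4)
    expect_equal(d$blocks$nuclease, c("SpCas9", "FnCas12a"))
    # upstream fixed Cas9 repeat and downstream Cas12a terminal repeat
    expect_true(grepl(cas9$repeat_seq, d$predicted_insert, fixed = TRUE))
    expect_true(endsWith(d$predicted_insert, cas12$repeat_seq))
    # one-spacer Cas9 block + 2-spacer Cas12a block = 3 units
    d3 <- plan_composite(list(list(profile = cas9, spacers = sp9[1]),
                              list(profile = cas12, spacers = sp12)))
    expect_length(d3$units, 3)
    # wrong order is an explicit error
    expect_error(
      plan_composite(list(list(profile = cas12, spacers = sp12),
                          list(profile = cas9, spacers = sp9))),
      "precede")
  })
})

test_that("plan_library enumerates the full combinatorial space", {
  with_seed(31, {
    vars <- lapply(1:3, function(p) replicate(5, rand_seq(26, c("A", "C"))))
    spec <- library_spec(vars)
    lib <- plan_library(spec, fn_profile(), fn_backbone())
    expect_length(lib$designs, 125)
    expect_equal(nrow(lib$oligo_sheet), 30)
    expect_length(unique(names(lib$designs)), 125)
    # all variants at one position share that position's junctions
    sheet1 <- lib$oligo_sheet[lib$oligo_sheet$position == 1 &
                                lib$oligo_sheet$strand == "top", ]
    expect_equal(unique(sheet1$left_overhang), "CCCT")
    # trivial library
    spec1 <- library_spec(list(rand_seq(26, c("A", "C"))))
    lib1 <- plan_library(spec1, fn_profile(), fn_backbone())
    expect_length(lib1$designs, 1)
    expect_equal(nrow(lib1$oligo_sheet), 2)
  })
})

test_that("protocol_sheet reports amounts, cycling and ng equivalents", {
  d <- clean_design()
  ps <- protocol_sheet(d, "single")
  expect_equal(ps$n_cycles, 25)
  expect_match(ps$cycling[1], "25 cycles")
  expect_match(ps$cycling[1], "42")
  pl <- protocol_sheet(d, "library")
  expect_equal(pl$n_cycles, 35)
  # 20 fmol of a 3000-bp backbone is ~37.1 ng by the molar-mass formula
  expect_equal(crisparray:::fmol_to_ng(20, 3000), 37.078, tolerance = 1e-3)
  bbrow <- ps$reagents[ps$reagents$species == "backbone", ]
  expect_equal(bbrow$fmol, 20)
  expect_equal(bbrow$ng,
               round(crisparray:::fmol_to_ng(20, nchar(d$backbone$sequence)), 2))
  expect_true(all(ps$reagents$fmol[ps$reagents$species != "backbone"] == 400))
})
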
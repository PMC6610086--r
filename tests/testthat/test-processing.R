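test_that("find_repeats locates repeats greedily with a mismatch budget", {
  p <- fn_profile()
  d <- clean_design()
  tx <- design_transcript(d)
  reps <- find_repeats(tx, p)
  expect_length(reps, 4)  # 3 internal + 1 terminal
  # terminal repeat with 5 substitutions is missed at max_mismatches = 3
  r <- p$repeat_seq
  mut <- r
  for (i in c(2, 8, 14, 22, 30)) {
    substr(mut, i, i) <- chartr("ACGT", "GTAC", substr(mut, i, i))
  }
  tx2 <- chartr("T", "U", paste0(r, strrep("A", 30), r, strrep("A", 30), mut))
  expect_length(find_repeats(tx2, p), 2)
  expect_length(find_repeats("AAAAUUUU", p), 0)
})

test_that("FnCas12a processing trims a 30-nt spacer region to a 23-nt guide", {
  d <- clean_design()
  crs <- process_transcript(design_transcript(d), fn_profile(), n_spacers = 3)
  internal <- Filter(function(x) x$cls == "internal", crs$crRNAs)
  expect_length(internal, 3)
  for (cr in internal) {
    expect_equal(nchar(cr$guide), 23)
    expect_equal(nchar(cr$handle), 19)
    expect_equal(cr$mature_len, 42)
    expect_equal(cr$junction_carryover, 0)
  }
  # identity recovery: guides are the first 23 nt of the input spacers
  sp <- clean_trio()
  for (i in 1:3) {
    expect_identical(chartr("U", "T", internal[[i]]$guide),
                     unname(substr(sp[i], 1, 23)))
  }
})

test_that("SpCas9 processing trims 10 nt from the 5' end leaving 20 nt", {
  p9 <- sp9_profile()
  bb9 <- make_backbone(p9, five_prime_repeat = p9, three_prime_repeat = FALSE)
  with_seed(17, {
    sp <- replicate(2, rand_seq(26, c("A", "C")))
    d <- plan_array(sp, p9, bb9)
    crs <- process_transcript(design_transcript(d), p9, n_spacers = 2)
    expect_length(crs$crRNAs, 2)
    for (i in seq_along(crs$crRNAs)) {
      cr <- crs$crRNAs[[i]]
      expect_equal(nchar(cr$guide), 20)
      # guide is the last 20 nt of the encoded spacer (junction + 6 trimmed)
      expect_identical(chartr("U", "T", cr$guide), substr(sp[i], 7, 26))
    }
    expect_true(crs$requires_trans_factors)
  })
})

test_that("extraneous crRNA emission follows the terminal repeat variant", {
  p <- fn_profile()
  for (variant in c("consensus", "native_mutated", "absent")) {
    bb <- make_backbone(p, terminal_variant = variant)
    d <- plan_array(clean_trio(), p, bb, junctions = fixture_junction_set())
    crs <- process_transcript(design_transcript(d), p, n_spacers = 3)
    n_extra <- sum(vapply(crs$crRNAs, function(x)
      x$cls == "terminal_extraneous", TRUE))
    n_internal <- sum(vapply(crs$crRNAs, function(x)
      x$cls == "internal", TRUE))
    expect_equal(n_internal, 3)
    expect_equal(n_extra, if (variant == "consensus") 1 else 0)
    if (variant == "native_mutated") {
      expect_identical(crs$terminal_call$verdict, "disrupted")
    }
  }
})

test_that("internal crRNA count equals designed spacer count (fuzzed)", {
  p <- fn_profile()
  bb <- fn_backbone()
  with_seed(23, {
    for (i in 1:5) {
      n <- sample(1:6, 1)
      sp <- replicate(n, rand_seq(26, c("A", "C")))
      d <- plan_array(sp, p, bb, seed = i)
      crs <- process_transcript(design_transcript(d), p, n_spacers = n)
      n_internal <- sum(vapply(crs$crRNAs, function(x)
        x$cls == "internal", TRUE))
      expect_equal(n_internal, n)
    }
  })
})

test_that("classify_terminal_repeat applies the critical-region rule", {
  p <- fn_profile()
  # identity: processable
  expect_identical(classify_terminal_repeat(p$repeat_seq, p)$verdict,
                   "processable")
  # substitutions inside the 3' stem: disrupted, and the stem cannot close
  r <- p$repeat_seq
  st3 <- p$hairpin$stem3
  mut <- r
  for (i in st3$start + c(0, 2, 4) + 1) {
    substr(mut, i, i) <- chartr("ACGT", "CATG", substr(mut, i, i))
  }
  call <- classify_terminal_repeat(mut, p)
  expect_identical(call$verdict, "disrupted")
  expect_true(any(call$evidence$overlaps_critical_region))
  # substitutions confined to the 5' non-critical region keep it processable
  mut2 <- r
  substr(mut2, 2, 2) <- "C"
  substr(mut2, 7, 7) <- "C"
  call2 <- classify_terminal_repeat(mut2, p)
  expect_identical(call2$verdict, "processable")
  expect_false(any(call2$evidence$overlaps_critical_region))
  # absent terminal repeat
  call3 <- classify_terminal_repeat("", p)
  expect_identical(call3$verdict, "disrupted")
  expect_identical(call3$evidence$type, "absent")
})

test_that("deviations are mapped to consensus coordinates by global alignment", {
  p <- fn_profile()
  r <- p$repeat_seq
  # single substitution at position 5 (0-based 4)
  mut <- r
  substr(mut, 5, 5) <- if (substr(r, 5, 5) == "A") "G" else "A"
  ev <- classify_terminal_repeat(mut, p)$evidence
  expect_equal(nrow(ev), 1)
  expect_equal(ev$consensus_pos, 4)
  expect_identical(ev$type, "substitution")
  # single deletion shows up as a deletion deviation
  del <- paste0(substr(r, 1, 4), substr(r, 6, nchar(r)))
  ev2 <- classify_terminal_repeat(del, p)$evidence
  expect_true("deletion" %in% ev2$type)
})
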
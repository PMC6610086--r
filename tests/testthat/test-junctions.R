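test_that("validate_overhang_set enforces the orthogonality rules", {
  # the working junction set used throughout: two members printed in the
  # protocol (CCCT, GCTG) plus two proposed ones
  expect_true(validate_overhang_set(c("CCCT", "GCTG", "TTAC", "GACA"))$ok)
  r <- validate_overhang_set(c("ACGT", "CCCT"))
  expect_false(r$ok)
  expect_true("palindrome" %in% r$violations$rule)
  r2 <- validate_overhang_set(c("CCCT", "CCCA"))
  expect_false(r2$ok)
  expect_true(any(grepl("distance 1", r2$violations$detail)))
  r3 <- validate_overhang_set(c("CCCT", "CCCT"))
  expect_true("duplicate" %in% r3$violations$rule)
  expect_error(validate_overhang_set(c("CCCT", "GC")), "same length")
  # reverse-complement similarity: AGGG is revcomp(CCCT)
  r4 <- validate_overhang_set(c("CCCT", "AGGA"))
  expect_false(r4$ok)
  expect_true("revcomp_similarity" %in% r4$violations$rule)
  # optional GC bounds
  r5 <- validate_overhang_set(c("CCCG", "GGCC"), gc_bounds = c(0.25, 0.75))
  expect_true("gc_content" %in% r5$violations$rule)
})

test_that("count_admissible_overhangs matches brute force", {
  # 256 4-mers minus 16 self-reverse-complementary ones
  expect_equal(count_admissible_overhangs(4, palindrome_only = TRUE)$count, 240)
  expect_equal(count_admissible_overhangs(1, palindrome_only = TRUE)$count, 4)
  # against an existing member: independent brute-force enumeration
  brute <- 0L
  for (cand in count_admissible_overhangs(4, palindrome_only = TRUE)$candidates) {
    ok <- ham(cand, "CCCT") >= 2 && ham(cand, revcomp("CCCT")) >= 2
    if (ok) brute <- brute + 1L
  }
  got <- count_admissible_overhangs(4, min_mismatch = 2, existing = "CCCT")
  expect_equal(got$count, brute)
  # deterministic lexicographic order
  expect_identical(got$candidates, sort(got$candidates))
})

test_that("propose_overhang_set returns valid sets and honors infeasibility", {
  for (seed in c(7, 19, 101)) {
    oh <- propose_overhang_set(4, seed = seed)
    expect_length(oh, 4)
    expect_true(validate_overhang_set(oh)$ok)
    # deterministic given seed
    oh2 <- propose_overhang_set(4, seed = seed)
    expect_identical(vapply(oh, `[[`, "", "seq"), vapply(oh2, `[[`, "", "seq"))
  }
  one <- propose_overhang_set(1, length = 1)
  expect_true(one[[1]]$seq %in% c("A", "C", "G", "T"))
  expect_error(propose_overhang_set(300, length = 4), "no admissible set")
  # proposals remain compatible with pre-existing members
  oh3 <- propose_overhang_set(2, seed = 3, existing = c("CCCT", "GCTG"))
  expect_true(validate_overhang_set(
    c("CCCT", "GCTG", vapply(oh3, `[[`, "", "seq")))$ok)
})

test_that("ligation compatibility is same-polarity revcomp matching", {
  a <- overhang("CCCT", "five_prime")
  b <- overhang("AGGG", "five_prime")
  expect_true(ligation_compatible(a, b))
  expect_false(ligation_compatible(a, overhang("AGGG", "three_prime")))
  expect_false(ligation_compatible(a, overhang("CCCT", "five_prime")))
})
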
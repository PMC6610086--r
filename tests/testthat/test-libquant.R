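test_that("simulate_reads is deterministic and respects its contract", {
  with_seed(61, {
    vars <- lapply(1:2, function(p) replicate(2, rand_seq(26, c("A", "C"))))
    lib <- plan_library(library_spec(vars), fn_profile(), fn_backbone())
  })
  reads <- simulate_reads(lib$designs, n_reads = 500, read_len = 100,
                          error_rate = 0, seed = 9)
  expect_equal(nrow(reads), 500)
  # error-free reads are exact substrings of some design insert
  inserts <- vapply(lib$designs, function(d) d$predicted_insert, "")
  ok <- vapply(reads$seq, function(s)
    any(vapply(inserts, function(i) grepl(s, i, fixed = TRUE), TRUE)), TRUE)
  expect_true(all(ok))
  # byte-identical rerun under the same seed
  reads2 <- simulate_reads(lib$designs, n_reads = 500, read_len = 100,
                           error_rate = 0, seed = 9)
  expect_identical(reads, reads2)
  # degenerate proportions: all reads from one design
  props <- c(1, 0, 0, 0)
  r3 <- simulate_reads(lib$designs, props, n_reads = 50, read_len = 100,
                       error_rate = 0, seed = 2)
  expect_true(all(vapply(r3$seq, function(s)
    grepl(s, inserts[1], fixed = TRUE) ||
      grepl(s, revcomp(inserts[1]), fixed = TRUE), TRUE)))
  expect_error(simulate_reads(lib$designs, n_reads = 10, read_len = 10000),
               "read_len")
})

test_that("assign_reads sorts reads into assigned/ambiguous/unassigned", {
  with_seed(62, {
    vars <- lapply(1:2, function(p) replicate(2, rand_seq(26, c("A", "C"))))
    lib <- plan_library(library_spec(vars), fn_profile(), fn_backbone())
  })
  inserts <- vapply(lib$designs, function(d) d$predicted_insert, "")
  # a read spanning both variable spacers is unique to its design
  uniq_read <- substr(inserts[1], 40, 170)
  # a read of pure repeat sequence matches every design
  shared_read <- substr(inserts[1], 1, 36)
  garbage <- strrep("G", 100)
  ct <- assign_reads(c(uniq_read, shared_read, garbage), lib$designs)
  expect_equal(unname(ct$counts[1]), 1)
  expect_equal(ct$ambiguous, 1)
  expect_equal(ct$unassigned, 1)
  # reverse-strand reads assign too
  ct2 <- assign_reads(revcomp(uniq_read), lib$designs)
  expect_equal(unname(ct2$counts[1]), 1)
  # adapter stripping by exact prefix
  ct3 <- assign_reads(paste0("ACGTACGT", uniq_read), lib$designs,
                      adapter = "ACGTACGT")
  expect_equal(unname(ct3$counts[1]), 1)
  # identical designs are a configuration error
  expect_error(assign_reads(uniq_read, list(a = "ACGT", b = "ACGT")),
               "not distinguishable")
})

test_that("full-coverage error-free reads lose nothing to unassigned", {
  with_seed(63, {
    vars <- lapply(1:2, function(p) replicate(2, rand_seq(26, c("A", "C"))))
    lib <- plan_library(library_spec(vars), fn_profile(), fn_backbone())
  })
  reads <- simulate_reads(lib$designs, n_reads = 400, read_len = 150,
                          error_rate = 0, seed = 31)
  ct <- assign_reads(reads, lib$designs)
  expect_equal(ct$unassigned, 0)
  expect_equal(ct$total + ct$ambiguous, 400)
})

test_that("abundance_report normalizes to mean 1 and computes marginals", {
  ct <- structure(list(counts = c(a_x = 10L, a_y = 10L, b_x = 10L,
                                  b_y = 10L, c_x = 60L, c_y = 60L),
                       total = 160L, ambiguous = 0L, unassigned = 0L),
                  class = "count_table")
  rep_ab <- abundance_report(ct)
  expect_equal(mean(rep_ab$rel_abundance), 1, tolerance = 1e-9)
  expect_equal(unname(rep_ab$rel_abundance[1]), 10 * 6 / 160)
  expect_equal(rep_ab$fold_range, 6)
  m <- rep_ab$position_marginals
  expect_equal(m$mean_rel_abundance[m$position == 1 & m$variant == "c"],
               60 * 6 / 160)
  # variant with half counts at one position drags its marginal below 1
  expect_lt(m$mean_rel_abundance[m$position == 1 & m$variant == "a"], 1)
  # 5-member worked example: counts (10,10,10,10,60)
  ct5 <- structure(list(counts = setNames(c(10L, 10L, 10L, 10L, 60L),
                                          paste0("m", 1:5)),
                        total = 100L, ambiguous = 0L, unassigned = 0L),
                   class = "count_table")
  rep5 <- abundance_report(ct5)
  expect_equal(unname(rep5$rel_abundance), c(0.5, 0.5, 0.5, 0.5, 3.0))
  expect_equal(rep5$fold_range, 6)
  expect_error(abundance_report(structure(list(counts = c(a = 0L), total = 0L),
                                          class = "count_table")), "zero")
  # uniform counts: everything 1, fold range 1
  ctu <- structure(list(counts = setNames(rep(4L, 8), letters[1:8]),
                        total = 32L, ambiguous = 0L, unassigned = 0L),
                   class = "count_table")
  repu <- abundance_report(ctu)
  expect_true(all(repu$rel_abundance == 1))
  expect_equal(repu$fold_range, 1)
})

test_that("count tables round-trip through TSV", {
  df <- data.frame(array_id = c("x", "y"), count = c(3L, 7L))
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  ct <- read_count_table(tsv)
  expect_equal(unname(ct$counts), c(3L, 7L))
  expect_equal(ct$total, 10L)
})
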
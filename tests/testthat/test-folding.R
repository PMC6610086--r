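test_that("mfe_structure handles canonical base cases", {
  expect_equal(mfe_structure("AAAAAA")$score, 0)
  s <- mfe_structure("GGGAAAACCC")
  expect_equal(s$score, 3)
  expect_equal(s$pairs$i, c(0, 1, 2))
  expect_equal(s$pairs$j, c(9, 8, 7))
  # min_loop forbids all pairs in a 4-mer
  expect_equal(mfe_structure("GCGC")$score, 0)
  # T read as U
  expect_equal(mfe_structure("GGGAAAACCC")$score,
               mfe_structure(chartr("U", "T", "GGGAAAACCC"))$score)
})

test_that("mfe_structure equals the exhaustive maximum on random sequences", {
  with_seed(303, {
    for (i in 1:40) {
      n <- sample(5:14, 1)
      seq <- rand_seq(n, c("A", "C", "G", "U"))
      structs <- enum_structures(seq)
      best <- max(vapply(structs, length, 1L))
      expect_equal(mfe_structure(seq)$score, best, label = seq)
    }
  })
})

test_that("structures are valid: nested, loop-constrained, legal pairs", {
  with_seed(97, {
    for (i in 1:30) {
      seq <- rand_seq(sample(10:40, 1), c("A", "C", "G", "U"))
      st <- mfe_structure(seq)
      if (!nrow(st$pairs)) next
      b <- strsplit(seq, "")[[1]]
      for (r in seq_len(nrow(st$pairs))) {
        i1 <- st$pairs$i[r]; j1 <- st$pairs$j[r]
        expect_gt(j1 - i1, 3)
        expect_true(paste0(b[i1 + 1], b[j1 + 1]) %in%
                      c("AU", "UA", "GC", "CG", "GU", "UG"))
        # non-crossing
        for (q in seq_len(nrow(st$pairs))) {
          i2 <- st$pairs$i[q]; j2 <- st$pairs$j[q]
          if (i1 < i2) {
            expect_true(j2 < j1 || i2 > j1)
          }
        }
      }
      # each index at most once
      idx <- c(st$pairs$i, st$pairs$j)
      expect_equal(anyDuplicated(idx), 0)
    }
  })
})

test_that("pair_probabilities matches exhaustive Boltzmann sums within 1e-9", {
  with_seed(404, {
    for (i in 1:25) {
      n <- sample(6:13, 1)
      seq <- rand_seq(n, c("A", "C", "G", "U"))
      structs <- enum_structures(seq)
      w <- exp(1)
      Z <- sum(w^vapply(structs, length, 1L))
      P <- pair_probabilities(seq, beta = 1)
      for (a in 1:(n - 1)) {
        for (b2 in (a + 1):n) {
          pe <- sum(vapply(structs, function(st) {
            has <- any(vapply(st, function(pr) pr[1] == a && pr[2] == b2, TRUE))
            has * w^length(st)
          }, 1)) / Z
          expect_equal(P[a, b2], pe, tolerance = 1e-9)
        }
      }
    }
  })
})

test_that("pair probability matrices satisfy symmetry and row-sum bounds", {
  with_seed(505, {
    for (i in 1:25) {
      seq <- rand_seq(30, c("A", "C", "G", "U"))
      P <- pair_probabilities(seq)
      expect_true(all(P >= 0 - 1e-12))
      expect_true(all(P <= 1 + 1e-12))
      expect_equal(P, t(P))
      expect_true(all(rowSums(P) <= 1 + 1e-9))
    }
    # no admissible pair: zero matrix
    expect_true(all(pair_probabilities("AAAAAAAAAA") == 0))
  })
})

test_that("screen_array gives clean arrays a clean bill in every order", {
  p <- fn_profile()
  bb <- fn_backbone()
  orders <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                 c(3, 2, 1))
  for (o in orders) {
    d <- plan_array(clean_trio()[o], p, bb, junctions = fixture_junction_set())
    r <- screen_array(d, p)
    expect_false(any(r$flags$flagged),
                 label = paste("order", paste(o, collapse = ",")))
    expect_true(all(r$hairpin_integrity >= r$p_star))
  }
})

test_that("screen_array is deterministic and validates its transcript", {
  d <- clean_design()
  r1 <- screen_array(d)
  r2 <- screen_array(d)
  expect_identical(r1$hairpin_integrity, r2$hairpin_integrity)
  expect_identical(r1$stems, r2$stems)
  expect_error(screen_array(d, transcript = "AUGCAUGCAUGC"), "match")
})

test_that("adding a complementary distal segment never raises integrity", {
  # monotonicity: a spacer complementary to the repeat's hairpin region can
  # only pull probability away from the canonical stem
  p <- fn_profile()
  bb <- fn_backbone()
  base_sp <- clean_trio()
  d0 <- plan_array(base_sp, p, bb, junctions = fixture_junction_set())
  r0 <- screen_array(d0, p)
  # replace spacer 3's head with the reverse complement of repeat 2's
  # hairpin region (stem5 through stem3)
  hp <- substr(p$repeat_seq, p$hairpin$stem5$start + 1, p$hairpin$stem3$end)
  decoy <- revcomp(hp)
  sp <- base_sp
  sp[3] <- paste0(decoy, substr(base_sp[3], nchar(decoy) + 1, 26))
  d1 <- plan_array(sp, p, bb, junctions = fixture_junction_set())
  r1 <- screen_array(d1, p)
  expect_lte(r1$hairpin_integrity[2], r0$hairpin_integrity[2])
})
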
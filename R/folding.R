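## RNA secondary structure by a maximum-pairing (Nussinov-style) dynamic
## program with Watson-Crick + G-U wobble pairs, nested structures only, and
## a Boltzmann ensemble over pair counts (weight exp(beta * pairs)) for pair
## probabilities via an inside-outside algorithm. This is deliberately a
## pair-count energy surrogate, not nearest-neighbor thermodynamics: the
## screen's conclusions rest on qualitative hairpin formation/disruption, and
## the pair-count model is small enough to verify exhaustively. A different
## folding engine can be plugged in via `fold_engine`.

PAIRABLE <- local({
  b <- c("A", "C", "G", "U")
  m <- matrix(FALSE, 4L, 4L, dimnames = list(b, b))
  m["A", "U"] <- m["U", "A"] <- TRUE
  m["G", "C"] <- m["C", "G"] <- TRUE
  m["G", "U"] <- m["U", "G"] <- TRUE
  m
})

rna_index <- function(seq) {
  x <- chartr("T", "U", toupper(as.character(seq)))
  validate_bases(x, "RNA")
  match(strsplit(x, "", fixed = TRUE)[[1L]], RNA_BASES)
}

# n x n logical matrix: may positions a and b pair (1-based, b - a > min_loop)
pairable_matrix <- function(idx, min_loop) {
  n <- length(idx)
  canp <- PAIRABLE[idx, idx, drop = FALSE]
  if (n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    canp[d <= min_loop] <- FALSE
  }
  canp
}

#' Maximum-pairing secondary structure
#'
#' Nussinov-style dynamic program maximizing the number of nested base pairs
#' (Watson-Crick plus G-U wobble; hairpin loops of at least `min_loop`
#' unpaired nt). Ties are broken deterministically toward the structure whose
#' sorted pair list is lexicographically smallest (each position pairs the
#' smallest admissible partner).
#'
#' @param seq RNA string or [nucseq()] (T is read as U).
#' @param min_loop minimum loop size (default 3).
#' @return object of class `rna_structure`: `pairs` (data.frame `i`, `j`,
#'   0-based, i < j), `score` (pair count), `n`, `db` (dot-bracket string).
#' @export
mfe_structure <- function(seq, min_loop = 3L) {
  idx <- rna_index(seq)
  n <- length(idx)
  empty <- data.frame(i = integer(), j = integer())
  if (n < min_loop + 2L) {
    return(new_structure(empty, n))
  }
  canp <- pairable_matrix(idx, min_loop)
  M <- matrix(0L, n + 1L, n + 1L)
  for (l in (min_loop + 2L):n) {
    for (i in seq_len(n - l + 1L)) {
      j <- i + l - 1L
      best <- M[i + 1L, j]
      ks <- which(canp[i, (i + min_loop + 1L):j]) + i + min_loop
      if (length(ks)) {
        inner <- M[cbind(i + 1L, pmax(ks - 1L, 1L))]
        inner[ks - 1L < i + 1L] <- 0L
        right <- M[cbind(ks + 1L, rep(j, length(ks)))]
        right[ks + 1L > j] <- 0L
        best <- max(best, max(1L + inner + right))
      }
      M[i, j] <- best
    }
  }
  # traceback, preferring to pair position i with its smallest partner
  pairs <- list()
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (i < j && M[i, j] > 0L) {
      target <- M[i, j]
      paired <- FALSE
      ks <- which(canp[i, (i + min_loop + 1L):j]) + i + min_loop
      for (k in ks) {
        inner <- if (k - 1L >= i + 1L) M[i + 1L, k - 1L] else 0L
        right <- if (k + 1L <= j) M[k + 1L, j] else 0L
        if (1L + inner + right == target) {
          pairs[[length(pairs) + 1L]] <- c(i, k)
          if (k + 1L < j + 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  pm <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(), ncol = 2L)
  df <- data.frame(i = pm[, 1L] - 1L, j = pm[, 2L] - 1L)
  df <- df[order(df$i), , drop = FALSE]
  rownames(df) <- NULL
  new_structure(df, n)
}

new_structure <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs$i + 1L] <- "("
    db[pairs$j + 1L] <- ")"
  }
  structure(list(pairs = pairs, score = nrow(pairs), n = n,
                 db = paste(db, collapse = "")),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("<rna_structure: %d nt, %d pair(s)>\n%s\n", x$n, x$score, x$db))
  invisible(x)
}

#' Base-pair probabilities under a Boltzmann pair-count ensemble
#'
#' Every nested structure S gets weight `exp(beta * |pairs(S)|)`; the
#' probability of pair (i, j) is the weighted fraction of structures that
#' contain it, computed exactly by an inside-outside dynamic program over the
#' grammar (S -> unpaired S | paired-block S | empty). `beta` is a single
#' dimensionless sharpness parameter (1 by default); there is no temperature
#' model.
#'
#' @inheritParams mfe_structure
#' @param beta ensemble sharpness (> 0).
#' @return symmetric n x n matrix of probabilities (0-based positions map to
#'   rows/cols 1..n).
#' @export
pair_probabilities <- function(seq, min_loop = 3L, beta = 1.0) {
  idx <- rna_index(seq)
  n <- length(idx)
  P <- matrix(0, n, n)
  if (n < min_loop + 2L) return(P)
  canp <- pairable_matrix(idx, min_loop)
  w <- exp(beta)
  # inside: ZS[i,j] over interval [i, j]; empty intervals are 1
  ZS <- matrix(1, n + 2L, n + 2L)
  for (l in seq_len(n)) {
    for (i in seq_len(n - l + 1L)) {
      j <- i + l - 1L
      z <- ZS[i + 1L, j]
      if (l >= min_loop + 2L) {
        ks <- which(canp[i, (i + min_loop + 1L):j]) + i + min_loop
        if (length(ks)) {
          z <- z + sum(w * ZS[cbind(i + 1L, ks - 1L)] *
                         ZS[cbind(ks + 1L, rep(j, length(ks)))])
        }
      }
      ZS[i, j] <- z
    }
  }
  # outside
  OS <- matrix(0, n + 2L, n + 2L)
  OP <- matrix(0, n + 2L, n + 2L)
  OS[1L, n] <- 1
  for (l in n:(min_loop + 2L)) {
    for (i in seq_len(n - l + 1L)) {
      j <- i + l - 1L
      os <- OS[i, j]
      if (os > 0) {
        OS[i + 1L, j] <- OS[i + 1L, j] + os
        ks <- which(canp[i, (i + min_loop + 1L):j]) + i + min_loop
        if (length(ks)) {
          OP[cbind(i, ks)] <- OP[cbind(i, ks)] +
            os * ZS[cbind(ks + 1L, rep(j, length(ks)))]
          zp <- w * ZS[cbind(i + 1L, ks - 1L)]
          OS[cbind(ks + 1L, rep(j, length(ks)))] <-
            OS[cbind(ks + 1L, rep(j, length(ks)))] + os * zp
        }
      }
      if (canp[i, j] && OP[i, j] > 0) {
        OS[i + 1L, j - 1L] <- OS[i + 1L, j - 1L] + w * OP[i, j]
      }
    }
  }
  Z <- ZS[1L, n]
  for (i in seq_len(n - min_loop - 1L)) {
    for (j in (i + min_loop + 1L):n) {
      if (canp[i, j]) {
        P[i, j] <- w * ZS[i + 1L, j - 1L] * OP[i, j] / Z
        P[j, i] <- P[i, j]
      }
    }
  }
  P
}

# pluggable engine dispatch: a user-supplied engine must provide
# $pair_probabilities(seq, min_loop, beta) and $mfe(seq, min_loop)
default_fold_engine <- function() {
  list(pair_probabilities = pair_probabilities, mfe = mfe_structure)
}

## --- array structure screen -------------------------------------------------

# transcript coordinates of the array elements of a design, for one profile:
# repeats (consensus, exact) and the transcribed spacer regions downstream
# (3'-trim) or upstream (5'-trim) of each spacer-bearing unit
array_layout <- function(design, profile) {
  tx <- as.character(design_transcript(design))
  reps <- find_repeats(tx, profile, max_mismatches = 0L)
  units <- Filter(function(u) u$nuclease == profile$name && nzchar(u$spacer),
                  design$units)
  n <- length(units)
  if (length(reps) < n) {
    stop("transcript/design mismatch: fewer consensus repeats than units",
         call. = FALSE)
  }
  three_prime <- profile$junction_side == "three_prime_of_spacer"
  spacer_iv <- vector("list", n)
  for (i in seq_len(n)) {
    if (three_prime) {
      st <- reps[[i]]$end
      spacer_iv[[i]] <- interval(st, st + profile$transcribed_spacer_total)
    } else {
      en <- reps[[i + 1L]]$start
      spacer_iv[[i]] <- interval(en - profile$transcribed_spacer_total, en)
    }
  }
  list(transcript = tx, repeats = reps[seq_len(if (three_prime) n else n + 1L)],
       spacer_iv = spacer_iv, units = units, three_prime = three_prime)
}

#' Structure-based crRNA biogenesis risk screen
#'
#' Folds the transcribed array (by default the window from the array's 5'
#' repeat through its 3' spacer; optionally the whole transcript) and flags
#' crRNAs whose biogenesis is at risk: the repeat's processing hairpin fails
#' to form (hairpin integrity — the fraction of canonical stem pairs with
#' pairing probability at least `p_star` — below `p_star`), or the spacer's
#' non-hybridizing 3' region is locked in a stem of at least `stem_len_flag`
#' consecutive high-probability pairs. Stems whose partner lies outside the
#' crRNA's own repeat-spacer unit are marked cross-unit — the signature of a
#' bridging hairpin between distant spacers.
#'
#' @param design `array_design`.
#' @param profile [nuclease_profile()] whose crRNAs are screened.
#' @param transcript optional RNA; defaults to [design_transcript()] and must
#'   match it (a mismatch is an error).
#' @param p_star pairing-probability threshold (default 0.8).
#' @param stem_len_flag consecutive-pair count that flags a spacer 3' stem.
#' @param p_explore permissive probability threshold at which stems are
#'   detected and reported (default 0.3); the flag rule itself only counts
#'   sub-runs at `p_star`, but diffusely competing stems below `p_star` are
#'   what the mutation search needs to see.
#' @param window `"array"` (5' repeat through 3' spacer) or `"transcript"`.
#' @param beta,min_loop ensemble parameters, see [pair_probabilities()].
#' @param fold_engine pluggable folding engine (see package vignette).
#' @return object of class `risk_report`.
#' @export
screen_array <- function(design, profile = design$profiles[[1L]],
                         transcript = NULL, p_star = 0.8,
                         stem_len_flag = 10L, p_explore = 0.3,
                         window = c("array", "transcript"),
                         beta = 5.0, min_loop = 3L,
                         fold_engine = default_fold_engine()) {
  window <- match.arg(window)
  lay <- array_layout(design, profile)
  if (!is.null(transcript)) {
    if (!identical(chartr("T", "U", toupper(as.character(transcript))),
                   lay$transcript)) {
      stop("supplied transcript does not match the design's transcript",
           call. = FALSE)
    }
  }
  n <- length(lay$spacer_iv)
  elements <- c(lay$repeats, lay$spacer_iv)
  w_start <- if (window == "array") {
    min(vapply(elements, function(iv) iv$start, integer(1L)))
  } else 0L
  w_end <- if (window == "array") {
    max(vapply(lay$spacer_iv, function(iv) iv$end, integer(1L)))
  } else nchar(lay$transcript)
  wseq <- substr(lay$transcript, w_start + 1L, w_end)
  P <- fold_engine$pair_probabilities(wseq, min_loop = min_loop, beta = beta)

  canon <- canonical_stem_pairs(profile)
  integrity <- numeric(n)
  for (r in seq_len(n)) {
    off <- lay$repeats[[r]]$start - w_start
    pi_ <- canon$i + off + 1L
    pj_ <- canon$j + off + 1L
    ok <- pi_ >= 1L & pj_ <= nrow(P)
    integrity[r] <- if (any(ok)) {
      mean(P[cbind(pi_[ok], pj_[ok])] >= p_star)
    } else NA_real_
  }

  # stems are detected at a permissive exploration threshold so that diffuse
  # competition (many moderately probable decoy pairings) is still reported
  # and can seed the mutation search; the flag itself only counts the
  # longest sub-run of pairs at or above p_star (len_strong)
  stems <- find_stems(P, p_explore, p_star)
  # map stems to window-global 0-based coordinates
  if (nrow(stems)) {
    stems$i_start <- stems$i_start + w_start - 1L
    stems$j_end <- stems$j_end + w_start - 1L
    stems$i_end <- stems$i_end + w_start - 1L
    stems$j_start <- stems$j_start + w_start - 1L
  }
  flags <- data.frame(crRNA = seq_len(n),
                      repeat_hairpin_disrupted = integrity < p_star,
                      spacer_3prime_stem = FALSE)
  offending <- vector("list", n)
  for (r in seq_len(n)) {
    sp <- lay$spacer_iv[[r]]
    tail_start <- sp$end - (profile$transcribed_spacer_total -
                              profile$guide_hyb_len)
    offend <- integer()
    if (nrow(stems)) {
      for (s in seq_len(nrow(stems))) {
        if (stems$len_strong[s] < stem_len_flag) next
        touches <- (stems$i_start[s] < sp$end && stems$i_end[s] >= tail_start) ||
          (stems$j_start[s] < sp$end && stems$j_end[s] >= tail_start)
        if (touches) offend <- c(offend, s)
      }
    }
    if (length(offend)) {
      flags$spacer_3prime_stem[r] <- TRUE
      offending[r] <- list(offend)
    }
  }
  # a disrupted repeat hairpin is caused either by a stem stealing its own
  # stem positions (touching) or by a bridging stem whose two sides flank
  # the repeat: an enclosing helix competes with and crossing-excludes the
  # canonical hairpin. Attach both kinds as offenders.
  if (nrow(stems)) {
    for (r in seq_len(n)) {
      if (!isTRUE(flags$repeat_hairpin_disrupted[r])) next
      rp <- lay$repeats[[r]]
      offend <- offending[[r]]
      for (s in seq_len(nrow(stems))) {
        touches <- (stems$i_start[s] < rp$end && stems$i_end[s] >= rp$start) ||
          (stems$j_start[s] < rp$end && stems$j_end[s] >= rp$start)
        encloses <- stems$i_end[s] < rp$start && stems$j_start[s] >= rp$end
        if (touches || encloses) offend <- union(offend, s)
      }
      offending[r] <- list(offend)
    }
  }
  flags$offending_stems <- I(offending)
  flags$flagged <- flags$repeat_hairpin_disrupted | flags$spacer_3prime_stem
  # cross-unit annotation: does a stem's partner side leave the unit spanning
  # its own side?
  if (nrow(stems)) {
    unit_span <- function(r) {
      interval(lay$repeats[[r]]$start,
               lay$spacer_iv[[r]]$end)
    }
    stems$cross_unit <- vapply(seq_len(nrow(stems)), function(s) {
      units_i <- which(vapply(seq_len(n), function(r) {
        us <- unit_span(r)
        stems$i_start[s] >= us$start && stems$i_end[s] < us$end
      }, logical(1L)))
      units_j <- which(vapply(seq_len(n), function(r) {
        us <- unit_span(r)
        stems$j_start[s] >= us$start && stems$j_end[s] < us$end
      }, logical(1L)))
      length(units_i) == 0L || length(units_j) == 0L ||
        !any(units_i %in% units_j)
    }, logical(1L))
  }
  ranked <- order(integrity)
  structure(list(
    window = interval(w_start, w_end), window_kind = window,
    hairpin_integrity = integrity, flags = flags, stems = stems,
    ranked_risk = ranked, p_star = p_star, stem_len_flag = stem_len_flag,
    p_explore = p_explore,
    beta = beta, min_loop = min_loop, profile = profile$name,
    layout = lay),
    class = "risk_report")
}

# maximal runs of consecutive pairs (i, j), (i+1, j-1), ... with P >=
# p_explore; len_strong is the longest sub-run at P >= p_star. 1-based
# window coordinates in, columns i_start..j_end describe the two strands of
# the stem
find_stems <- function(P, p_explore, p_star = p_explore) {
  hits <- which(P >= p_explore & upper.tri(P), arr.ind = TRUE)
  out <- data.frame(i_start = integer(), i_end = integer(),
                    j_start = integer(), j_end = integer(), len = integer(),
                    len_strong = integer(), max_p = numeric())
  if (!nrow(hits)) return(out)
  key <- paste(hits[, 1L], hits[, 2L])
  keyset <- new.env(parent = emptyenv())
  for (k in key) keyset[[k]] <- TRUE
  used <- new.env(parent = emptyenv())
  ord <- order(hits[, 1L], hits[, 2L])
  rows <- list()
  for (h in ord) {
    i <- hits[h, 1L]; j <- hits[h, 2L]
    if (!is.null(used[[paste(i, j)]])) next
    # only start a run at its outermost pair
    if (!is.null(keyset[[paste(i - 1L, j + 1L)]])) next
    len <- 0L
    ii <- i; jj <- j
    ps <- numeric()
    while (!is.null(keyset[[paste(ii, jj)]]) && ii < jj) {
      used[[paste(ii, jj)]] <- TRUE
      len <- len + 1L
      ps <- c(ps, P[ii, jj])
      ii <- ii + 1L; jj <- jj - 1L
    }
    strong <- ps >= p_star
    len_strong <- if (any(strong)) {
      runs <- rle(strong)
      max(runs$lengths[runs$values])
    } else 0L
    rows[[length(rows) + 1L]] <- data.frame(
      i_start = i, i_end = i + len - 1L,
      j_start = j - len + 1L, j_end = j, len = len,
      len_strong = len_strong, max_p = max(ps))
  }
  do.call(rbind, rows)
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report %s window [%d, %d), p* = %.2f>\n", x$window_kind,
              x$window$start, x$window$end, x$p_star))
  for (r in seq_along(x$hairpin_integrity)) {
    cat(sprintf("  crRNA %d: hairpin integrity %.2f%s\n", r,
                x$hairpin_integrity[r],
                if (x$flags$flagged[r]) "  ** FLAGGED **" else ""))
  }
  if (nrow(x$stems)) {
    long <- x$stems[x$stems$len >= x$stem_len_flag, , drop = FALSE]
    if (nrow(long)) {
      cat("  stems >=", x$stem_len_flag, "bp:\n")
      print(long, row.names = FALSE)
    }
  }
  invisible(x)
}

#' Suggest single-base substitutions that destabilize an offending stem
#'
#' Greedy search over single-base substitutions at the flagged spacer's
#' positions that participate in an offending stem, excluding the first
#' `guide_hyb_len` guide positions unless `allow_guide_edits` (editing the
#' hybridizing guide changes the target — such candidates are labelled).
#' Every candidate is re-screened; candidates are ranked by the post-mutation
#' hairpin integrity of the affected repeat, deterministically.
#'
#' @param design `array_design`.
#' @param report [screen_array()] result for `design`.
#' @param max_mut_per_spacer maximum substitutions proposed jointly (only 1
#'   supported; each candidate is a single substitution).
#' @param allow_guide_edits permit edits within the hybridizing guide region.
#' @param profile profile used in the screen.
#' @return data.frame: unit, pos_in_spacer (0-based), from, to,
#'   new_integrity, clears_flag, edits_guide; empty when nothing is flagged.
#' @export
suggest_destabilizing_mutations <- function(design, report,
                                            max_mut_per_spacer = 1L,
                                            allow_guide_edits = FALSE,
                                            profile = design$profiles[[1L]]) {
  flagged <- which(report$flags$flagged)
  empty <- data.frame(unit = integer(), pos_in_spacer = integer(),
                      from = character(), to = character(),
                      new_integrity = numeric(), clears_flag = logical(),
                      edits_guide = logical(), stringsAsFactors = FALSE)
  if (!length(flagged)) return(empty)
  lay <- report$layout
  spacers <- vapply(lay$units, `[[`, character(1L), "spacer")
  cands <- list()
  for (f in flagged) {
    offend <- report$flags$offending_stems[[f]]
    if (!length(offend)) next
    # collect transcript positions of offending stems, then intersect with
    # every spacer's editable region (the mutation is made in whichever
    # spacer hosts the stem — typically the distal, bridging spacer)
    pos_tx <- integer()
    for (s in offend) {
      st <- report$stems[s, ]
      pos_tx <- c(pos_tx, seq(st$i_start, st$i_end),
                  seq(st$j_start, st$j_end))
    }
    for (u in seq_along(spacers)) {
      sp_iv <- lay$spacer_iv[[u]]
      sp_off <- if (lay$three_prime) 0L else profile$junction_len
      # spacer positions (0-based within the encoded spacer)
      for (p_tx in unique(pos_tx)) {
        rel <- p_tx - sp_iv$start
        if (lay$three_prime) {
          pos_sp <- rel  # spacer then junction
        } else {
          pos_sp <- rel - profile$junction_len  # junction then spacer
        }
        if (is.na(pos_sp) || pos_sp < 0L ||
            pos_sp >= profile$encoded_spacer_len) next
        edits_guide <- pos_sp < profile$guide_hyb_len
        if (edits_guide && !allow_guide_edits) next
        cands[[length(cands) + 1L]] <- c(unit = u, pos = pos_sp,
                                         flag = f,
                                         guide = as.integer(edits_guide))
      }
    }
  }
  if (!length(cands)) return(empty)
  cands <- unique(do.call(rbind, cands))
  rows <- list()
  for (r in seq_len(nrow(cands))) {
    u <- cands[r, "unit"]; p <- cands[r, "pos"]; f <- cands[r, "flag"]
    from <- substr(spacers[u], p + 1L, p + 1L)
    for (to in setdiff(DNA_BASES, from)) {
      new_spacers <- spacers
      substr(new_spacers[u], p + 1L, p + 1L) <- to
      new_design <- try(plan_array(new_spacers, profile, design$backbone,
                                   junctions = design$junctions),
                        silent = TRUE)
      if (inherits(new_design, "try-error")) next
      new_report <- screen_array(new_design, profile, p_star = report$p_star,
                                 stem_len_flag = report$stem_len_flag,
                                 p_explore = report$p_explore,
                                 window = report$window_kind,
                                 beta = report$beta,
                                 min_loop = report$min_loop)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, pos_in_spacer = p, from = from, to = to,
        new_integrity = new_report$hairpin_integrity[f],
        clears_flag = !new_report$flags$flagged[f],
        edits_guide = cands[r, "guide"] == 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$new_integrity, out$unit, out$pos_in_spacer, out$to), ]
  rownames(out) <- NULL
  out
}
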
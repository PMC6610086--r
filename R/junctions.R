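#' Assembly-junction overhang
#'
#' A junction overhang is the single-stranded protrusion left after Type IIS
#' digestion or built into an annealed oligo duplex. `seq` is the protruding
#' strand written 5'->3'. Two overhangs ligate iff they have the same polarity
#' and their sequences are exact reverse complements.
#'
#' @param seq DNA string, 1-8 nt (4 nt is the working default).
#' @param polarity `"five_prime"` or `"three_prime"`.
#' @export
overhang <- function(seq, polarity = c("five_prime", "three_prime")) {
  polarity <- match.arg(polarity)
  seq <- toupper(as.character(seq))
  validate_bases(seq, "DNA")
  len <- nchar(seq)
  if (len < 1L || len > 8L) stop("overhang length must be 1-8 nt", call. = FALSE)
  structure(list(seq = seq, polarity = polarity, length = len),
            class = "overhang")
}

#' @export
print.overhang <- function(x, ...) {
  cat(sprintf("<overhang %s %s>\n", x$seq,
              if (x$polarity == "five_prime") "5'" else "3'"))
  invisible(x)
}

#' Can two overhangs ligate?
#'
#' @param a,b [overhang()] objects.
#' @return logical.
#' @export
ligation_compatible <- function(a, b) {
  identical(a$polarity, b$polarity) && identical(a$seq, revcomp(b$seq))
}

is_palindromic <- function(seq) identical(seq, revcomp(seq))

as_overhang_seqs <- function(overhangs) {
  vapply(overhangs, function(o) {
    if (inherits(o, "overhang")) o$seq else toupper(as.character(o))
  }, character(1L))
}

#' Validate a set of junction overhangs for orthogonal assembly
#'
#' A junction set is admissible for one-pot assembly when no two members can
#' cross-ligate and no member can self-ligate. Checked rules: (i) no
#' palindromic member (self-ligation); (ii) every pair at Hamming distance
#' >= `min_mismatch` (a single synthesis/ligation error cannot convert one
#' junction into another); (iii) every pair also at Hamming distance >=
#' `min_mismatch` against the other's reverse complement (cross-ligation
#' risk); (iv) no duplicates. Optionally a GC-content window can be enforced.
#'
#' @param overhangs list of [overhang()]s or character vector, all same length.
#' @param min_mismatch minimum pairwise Hamming distance (default 2).
#' @param gc_bounds optional numeric length-2 vector, e.g. `c(0.25, 0.75)`;
#'   `NULL` (default) disables the GC rule.
#' @return list of class `overhang_set_report` with `ok` and a `violations`
#'   data.frame (columns: rule, members, detail).
#' @export
validate_overhang_set <- function(overhangs, min_mismatch = 2L,
                                  gc_bounds = NULL) {
  seqs <- as_overhang_seqs(overhangs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    stop("all overhangs in a set must have the same length", call. = FALSE)
  }
  viol <- list()
  add <- function(rule, members, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      rule = rule, members = paste(members, collapse = ","),
      detail = detail, stringsAsFactors = FALSE)
  }
  dup <- seqs[duplicated(seqs)]
  for (d in unique(dup)) add("duplicate", d, "sequence occurs more than once")
  for (s in unique(seqs)) {
    if (is_palindromic(s)) add("palindrome", s, "self-reverse-complementary")
  }
  if (!is.null(gc_bounds)) {
    gc <- vapply(seqs, function(s) {
      mean(strsplit(s, "", fixed = TRUE)[[1L]] %in% c("G", "C"))
    }, numeric(1L))
    for (i in which(gc < gc_bounds[1L] | gc > gc_bounds[2L])) {
      add("gc_content", seqs[i], sprintf("GC fraction %.2f outside [%.2f, %.2f]",
                                         gc[i], gc_bounds[1L], gc_bounds[2L]))
    }
  }
  n <- length(seqs)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d <- hamming(seqs[i], seqs[j])
        if (d < min_mismatch) {
          add("direct_similarity", c(seqs[i], seqs[j]),
              sprintf("Hamming distance %d < %d", d, min_mismatch))
        }
      }
    }
  }
  # cross (reverse-complement) similarity, including i == j handled by the
  # palindrome rule; i != j here
  if (n > 1L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        if (j < i) next  # symmetric: hamming(a, rc(b)) == hamming(b, rc(a))
        d <- hamming(seqs[i], revcomp(seqs[j]))
        if (d < min_mismatch) {
          add("revcomp_similarity", c(seqs[i], seqs[j]),
              sprintf("Hamming distance to reverse complement %d < %d",
                      d, min_mismatch))
        }
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(rule = character(), members = character(),
               detail = character(), stringsAsFactors = FALSE)
  structure(list(ok = nrow(violations) == 0L, violations = violations,
                 min_mismatch = min_mismatch),
            class = "overhang_set_report")
}

#' @export
print.overhang_set_report <- function(x, ...) {
  if (x$ok) {
    cat("Overhang set OK (min_mismatch =", x$min_mismatch, ")\n")
  } else {
    cat("Overhang set FAILED:\n")
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

all_kmers <- function(len) {
  if (len == 0L) return("")
  grids <- rep(list(DNA_BASES), len)
  m <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  # expand.grid varies the first column fastest; reversed columns + apply
  # gives lexicographic order
  sort(apply(m[, rev(seq_len(len)), drop = FALSE], 1L, paste, collapse = ""))
}

#' Count (and enumerate) admissible overhangs of a given length
#'
#' Enumerates all `4^length` sequences and keeps those passing the junction
#' rules against themselves and against an `existing` set, in lexicographic
#' order.
#'
#' @inheritParams validate_overhang_set
#' @param length overhang length (<= 8).
#' @param existing overhangs already committed (list or character).
#' @param palindrome_only if `TRUE`, only the palindrome rule is applied
#'   (useful for counting non-self-complementary k-mers).
#' @return list with `count` and `candidates` (character vector).
#' @export
count_admissible_overhangs <- function(length, min_mismatch = 2L,
                                       existing = character(),
                                       palindrome_only = FALSE) {
  if (length > 8L) stop("overhang length must be <= 8", call. = FALSE)
  cand <- all_kmers(length)
  keep <- !vapply(cand, is_palindromic, logical(1L))
  if (!palindrome_only && length(existing)) {
    ex <- as_overhang_seqs(existing)
    for (e in ex) {
      keep <- keep &
        vapply(cand, function(s) hamming(s, e) >= min_mismatch, logical(1L)) &
        vapply(cand, function(s) hamming(s, revcomp(e)) >= min_mismatch,
               logical(1L))
    }
  }
  out <- cand[keep]
  list(count = length(out), candidates = out)
}

#' Propose an orthogonal junction set
#'
#' Greedy selection over a seeded random permutation of all candidate k-mers:
#' a candidate is kept if the set so far plus the candidate still passes
#' [validate_overhang_set()]. Deterministic given `seed`. Infeasible requests
#' raise an explicit error; constraints are never silently relaxed.
#'
#' @param n number of overhangs required.
#' @param length overhang length (default 4 nt).
#' @param min_mismatch pairwise Hamming floor (default 2).
#' @param seed integer seed for the candidate permutation.
#' @param polarity polarity assigned to the returned overhangs.
#' @param existing overhangs that must remain compatible with the new set.
#' @return list of [overhang()]s of length `n`.
#' @export
propose_overhang_set <- function(n, length = 4L, min_mismatch = 2L, seed = 1L,
                                 polarity = "five_prime",
                                 existing = character()) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  cand <- all_kmers(length)
  if (n > base::length(cand)) {
    stop("no admissible set: more overhangs requested than candidate k-mers",
         call. = FALSE)
  }
  perm <- withr_seed(seed, sample.int(base::length(cand)))
  chosen <- as_overhang_seqs(existing)
  n_existing <- base::length(chosen)
  for (idx in perm) {
    s <- cand[idx]
    trial <- c(chosen, s)
    if (validate_overhang_set(trial, min_mismatch = min_mismatch)$ok) {
      chosen <- trial
      if (base::length(chosen) - n_existing == n) break
    }
  }
  if (base::length(chosen) - n_existing < n) {
    stop("no admissible set: constraints cannot be met for n = ", n,
         call. = FALSE)
  }
  new <- chosen[seq(n_existing + 1L, base::length(chosen))]
  lapply(new, overhang, polarity = polarity)
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
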
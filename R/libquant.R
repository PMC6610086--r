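## Combinatorial library bookkeeping: simulate amplicon reads over a set of
## designed arrays, assign reads back by exact matching, and summarize
## abundance uniformity (relative abundance normalized to mean 1, fold range,
## per-position variant marginals).

design_inserts <- function(designs) {
  if (inherits(designs, "array_design")) designs <- list(designs)
  vapply(designs, function(d) {
    if (inherits(d, "array_design")) d$predicted_insert else as.character(d)
  }, character(1L))
}

#' Simulate amplicon reads from a set of array designs
#'
#' Each read picks a design with probability `true_props`, a uniform offset
#' within the design's array insert, and per-base substitution errors at
#' `error_rate`. Deterministic given `seed`. Qualities are uniform
#' placeholders; no indels, no adapters/indexes (the real library prep's
#' index scheme is out of scope).
#'
#' @param designs list of `array_design`s (or character sequences).
#' @param true_props probability vector over designs (sums to 1).
#' @param n_reads number of reads.
#' @param read_len read length; must not exceed the shortest insert.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @return data.frame (`id`, `seq`, `qual`) with attribute `truth` (the
#'   design index each read came from).
#' @export
simulate_reads <- function(designs, true_props = NULL, n_reads = 1000L,
                           read_len = 150L, error_rate = 0.001, seed = 1L) {
  inserts <- design_inserts(designs)
  nd <- length(inserts)
  if (is.null(true_props)) true_props <- rep(1 / nd, nd)
  if (abs(sum(true_props) - 1) > 1e-8) {
    stop("true_props must sum to 1", call. = FALSE)
  }
  min_len <- min(nchar(inserts))
  if (read_len > min_len) {
    stop("read_len ", read_len, " exceeds shortest insert (", min_len, " nt)",
         call. = FALSE)
  }
  withr_seed(seed, {
    origin <- sample.int(nd, n_reads, replace = TRUE, prob = true_props)
    lens <- nchar(inserts)[origin]
    offs <- floor(runif(n_reads) * (lens - read_len + 1L))
    seqs <- substr(inserts[origin], offs + 1L, offs + read_len)
    n_err <- rbinom(n_reads, read_len, error_rate)
    for (r in which(n_err > 0L)) {
      pos <- sample.int(read_len, n_err[r])
      for (p in pos) {
        cur <- substr(seqs[r], p, p)
        substr(seqs[r], p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
      }
    }
    reads <- data.frame(
      id = sprintf("read_%d", seq_len(n_reads)),
      seq = seqs,
      qual = strrep("I", read_len),
      stringsAsFactors = FALSE)
    attr(reads, "truth") <- origin
    reads
  })
}

#' Assign reads to library members by exact matching
#'
#' A read is assigned when (after optional exact-prefix adapter stripping) it
#' occurs as an exact substring of exactly one design's insert, on either
#' strand. Reads matching several designs go to the ambiguous bucket; reads
#' matching none (sequencing errors, garbage) to the unassigned bucket.
#' Designs must be pairwise distinguishable (distinct spacer combinations);
#' identical inserts are a configuration error naming the colliding pair.
#'
#' @param reads data.frame from [simulate_reads()]/[read_fastq()], or a
#'   character vector of read sequences.
#' @param designs named list of `array_design`s (or character inserts).
#' @param min_diag_len reads shorter than this are never assigned.
#' @param adapter optional adapter sequence stripped from the read start when
#'   present as an exact prefix.
#' @return object of class `count_table`: named `counts`, `total` (assigned),
#'   `ambiguous`, `unassigned`.
#' @export
assign_reads <- function(reads, designs, min_diag_len = 20L, adapter = NULL) {
  inserts <- design_inserts(designs)
  ids <- names(inserts)
  if (is.null(ids)) ids <- sprintf("design_%d", seq_along(inserts))
  dup <- which(duplicated(inserts) | duplicated(inserts, fromLast = TRUE))
  if (length(dup)) {
    stop("designs not distinguishable: identical inserts for ",
         paste(ids[dup], collapse = ", "), call. = FALSE)
  }
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  seqs <- toupper(seqs)
  if (!is.null(adapter)) {
    adapter <- toupper(adapter)
    pref <- startsWith(seqs, adapter)
    seqs[pref] <- substr(seqs[pref], nchar(adapter) + 1L, nchar(seqs[pref]))
  }
  counts <- setNames(integer(length(ids)), ids)
  ambiguous <- 0L
  unassigned <- 0L
  # one exact-substring index per distinct read length; reads with N never
  # match (N is rejected from designs, never from reads)
  for (rl in unique(nchar(seqs))) {
    sel <- which(nchar(seqs) == rl)
    if (rl < min_diag_len) {
      unassigned <- unassigned + length(sel)
      next
    }
    index <- new.env(parent = emptyenv(), size = 4096L)
    for (d in seq_along(inserts)) {
      ins <- inserts[d]
      for (strand_seq in c(ins, revcomp(ins))) {
        L <- nchar(strand_seq)
        if (L < rl) next
        subs <- substring(strand_seq, 1:(L - rl + 1L), rl:L)
        for (s in unique(subs)) {
          prev <- index[[s]]
          if (is.null(prev)) {
            index[[s]] <- d
          } else if (!any(prev == d)) {
            index[[s]] <- c(prev, d)
          }
        }
      }
    }
    for (r in sel) {
      hit <- index[[seqs[r]]]
      if (is.null(hit)) {
        unassigned <- unassigned + 1L
      } else if (length(hit) == 1L) {
        counts[hit] <- counts[hit] + 1L
      } else {
        ambiguous <- ambiguous + 1L
      }
    }
  }
  structure(list(counts = counts, total = sum(counts),
                 ambiguous = ambiguous, unassigned = unassigned),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table: %d member(s), %d assigned, %d ambiguous, %d unassigned>\n",
              length(x$counts), x$total, x$ambiguous, x$unassigned))
  invisible(x)
}

#' Build a count table from a TSV (array_id <tab> count)
#'
#' @param path TSV path with columns `array_id`, `count`.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(counts = setNames(as.integer(df$count), df$array_id),
                 total = sum(df$count), ambiguous = 0L, unassigned = 0L),
            class = "count_table")
}

#' Abundance-uniformity report for an array library
#'
#' Relative abundance is normalized so that a perfectly uniform library has
#' every member at 1 (count x n_members / total). The fold range is the
#' ratio between the most and least abundant member with nonzero counts;
#' position marginals average relative abundance over all arrays carrying a
#' given variant at a given position, exposing position-specific
#' stoichiometry or cloning-efficiency biases.
#'
#' @param counts [assign_reads()] result (or `count_table`).
#' @param library optional [library_spec()]; member ids of the form
#'   `S1a_S2b_S3c` are parsed for position marginals.
#' @return object of class `abundance_report`.
#' @export
abundance_report <- function(counts, library = NULL) {
  ct <- counts$counts
  if (counts$total == 0L) stop("zero assigned reads", call. = FALSE)
  n <- length(ct)
  rel <- ct * n / counts$total
  nonzero <- rel[ct > 0L]
  fold_range <- max(nonzero) / min(nonzero)
  zero_members <- names(ct)[ct == 0L]
  marginals <- NULL
  parts <- strsplit(names(ct), "_", fixed = TRUE)
  npos <- unique(lengths(parts))
  if (length(npos) == 1L && npos > 1L) {
    rows <- list()
    for (p in seq_len(npos)) {
      var_at_p <- vapply(parts, `[[`, character(1L), p)
      for (v in unique(var_at_p)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = p, variant = v,
          mean_rel_abundance = mean(rel[var_at_p == v]),
          stringsAsFactors = FALSE)
      }
    }
    marginals <- do.call(rbind, rows)
  }
  structure(list(rel_abundance = rel, fold_range = fold_range,
                 zero_members = zero_members,
                 position_marginals = marginals,
                 n_members = n, total = counts$total,
                 ambiguous = counts$ambiguous,
                 unassigned = counts$unassigned),
            class = "abundance_report")
}

#' @export
print.abundance_report <- function(x, ...) {
  cat(sprintf("<abundance_report: %d members, fold range %.2f, %d zero member(s)>\n",
              x$n_members, x$fold_range, length(x$zero_members)))
  cat(sprintf("  rel abundance: min %.3f, median %.3f, max %.3f (mean 1)\n",
              min(x$rel_abundance), stats::median(x$rel_abundance),
              max(x$rel_abundance)))
  if (!is.null(x$position_marginals)) {
    print(x$position_marginals, row.names = FALSE)
  }
  invisible(x)
}
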
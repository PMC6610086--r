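## crRNA biogenesis simulation: locate repeats in a transcribed array, cut at
## the profile's cleavage offset, trim guides, and emit mature crRNAs —
## including the extraneous crRNA that a consensus-like terminal repeat
## liberates from the sequence downstream of the array.

#' Locate repeat units in an array transcript
#'
#' Scans left-to-right for non-overlapping matches to the RNA form of the
#' profile's consensus repeat, allowing up to `max_mismatches` substitutions
#' (no indels; a terminal repeat diverged enough to need indel alignment is
#' the business of [classify_terminal_repeat()], not of this scan).
#'
#' @param transcript RNA [nucseq()] or string.
#' @param profile [nuclease_profile()].
#' @param max_mismatches substitution budget per match (default 3).
#' @return list of [interval()]s, possibly empty.
#' @export
find_repeats <- function(transcript, profile, max_mismatches = 3L) {
  x <- chartr("T", "U", toupper(as.character(transcript)))
  rep_rna <- chartr("T", "U", profile$repeat_seq)
  L <- nchar(x); k <- nchar(rep_rna)
  if (L < k) return(list())
  xv <- strsplit(x, "", fixed = TRUE)[[1L]]
  rv <- strsplit(rep_rna, "", fixed = TRUE)[[1L]]
  hits <- list()
  i <- 0L
  while (i <= L - k) {
    mm <- sum(xv[(i + 1L):(i + k)] != rv)
    if (mm <= max_mismatches) {
      hits[[length(hits) + 1L]] <- interval(i, i + k)
      i <- i + k
    } else {
      i <- i + 1L
    }
  }
  hits
}

#' Classify a terminal repeat as processable or disrupted
#'
#' Aligns the observed terminal repeat against the consensus (global
#' alignment, match +1 / mismatch -1 / gap -2), maps every deviation to
#' consensus coordinates, and calls the repeat disrupted when any deviation
#' overlaps the critical region (the processing hairpin plus 4-nt flanks by
#' default) or when the hairpin no longer folds in the standalone repeat RNA
#' (at least half of the canonical stem pairs must appear in the
#' maximum-pairing structure). Native terminal repeats typically carry such
#' disruptions — the reason arrays in nature rarely emit extraneous crRNAs.
#'
#' @param terminal observed terminal repeat (DNA or RNA; empty means absent).
#' @param profile [nuclease_profile()] supplying consensus and hairpin.
#' @param critical_region optional list of [interval()]s in consensus
#'   coordinates; default hairpin span +/- 4 nt.
#' @param consensus override the consensus (defaults to the profile repeat).
#' @return object of class `terminal_repeat_call` with `verdict`,
#'   `evidence` (data.frame of deviations), `hairpin_folds`, `alignment`.
#' @export
classify_terminal_repeat <- function(terminal, profile, critical_region = NULL,
                                     consensus = NULL) {
  if (is.null(consensus)) consensus <- profile$repeat_seq
  consensus <- chartr("U", "T", toupper(as.character(consensus)))
  terminal <- chartr("U", "T", toupper(as.character(terminal)))
  if (is.null(critical_region)) {
    hp <- profile$hairpin
    if (is.null(hp)) stop("profile has no hairpin annotation", call. = FALSE)
    critical_region <- list(interval(max(0L, hp$stem5$start - 4L),
                                     min(nchar(consensus), hp$stem3$end + 4L)))
  }
  if (!nzchar(terminal)) {
    return(structure(list(
      verdict = "disrupted",
      evidence = data.frame(consensus_pos = NA_integer_, type = "absent",
                            from = "", to = "",
                            overlaps_critical_region = TRUE,
                            stringsAsFactors = FALSE),
      hairpin_folds = FALSE, alignment = NULL),
      class = "terminal_repeat_call"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(terminal), Biostrings::DNAString(consensus),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  cons_pos <- 0L
  dev <- list()
  in_critical <- function(pos) {
    any(vapply(critical_region, function(iv) pos >= iv$start && pos < iv$end,
               logical(1L)))
  }
  for (col in seq_along(pa)) {
    p <- pa[col]; s <- sa[col]
    if (s != "-") {
      if (p == "-") {
        dev[[length(dev) + 1L]] <- data.frame(
          consensus_pos = cons_pos, type = "deletion", from = s, to = "-",
          overlaps_critical_region = in_critical(cons_pos),
          stringsAsFactors = FALSE)
      } else if (p != s) {
        dev[[length(dev) + 1L]] <- data.frame(
          consensus_pos = cons_pos, type = "substitution", from = s, to = p,
          overlaps_critical_region = in_critical(cons_pos),
          stringsAsFactors = FALSE)
      }
      cons_pos <- cons_pos + 1L
    } else {
      dev[[length(dev) + 1L]] <- data.frame(
        consensus_pos = cons_pos, type = "insertion", from = "-", to = p,
        overlaps_critical_region = in_critical(cons_pos),
        stringsAsFactors = FALSE)
    }
  }
  evidence <- if (length(dev)) do.call(rbind, dev) else
    data.frame(consensus_pos = integer(), type = character(),
               from = character(), to = character(),
               overlaps_critical_region = logical(), stringsAsFactors = FALSE)
  hairpin_folds <- hairpin_folds_in(terminal, profile)
  verdict <- if (any(evidence$overlaps_critical_region) || !hairpin_folds) {
    "disrupted"
  } else {
    "processable"
  }
  structure(list(verdict = verdict, evidence = evidence,
                 hairpin_folds = hairpin_folds, alignment = aln),
            class = "terminal_repeat_call")
}

# does the profile's processing hairpin form in this (possibly mutated)
# standalone repeat? criterion: >= half of the canonical stem pairs are
# present in the maximum-pairing structure of the repeat RNA
hairpin_folds_in <- function(repeat_seq, profile) {
  hp <- profile$hairpin
  if (is.null(hp)) stop("profile lacks hairpin coordinates", call. = FALSE)
  rna <- chartr("T", "U", toupper(as.character(repeat_seq)))
  if (nchar(rna) < hp$stem3$end) return(FALSE)
  st <- mfe_structure(rna)
  canon <- canonical_stem_pairs(profile)
  if (!nrow(canon)) return(FALSE)
  present <- 0L
  if (nrow(st$pairs)) {
    key <- paste(st$pairs$i, st$pairs$j)
    present <- sum(paste(canon$i, canon$j) %in% key)
  }
  present >= ceiling(nrow(canon) / 2)
}

# canonical hairpin pairs (0-based repeat coordinates): outermost stem5 base
# pairs outermost stem3 base
canonical_stem_pairs <- function(profile) {
  hp <- profile$hairpin
  w <- interval_width(hp$stem5)
  data.frame(i = hp$stem5$start + seq_len(w) - 1L,
             j = hp$stem3$end - seq_len(w))
}

#' @export
print.terminal_repeat_call <- function(x, ...) {
  cat(sprintf("<terminal_repeat_call: %s (%d deviation(s), hairpin folds: %s)>\n",
              x$verdict, nrow(x$evidence), x$hairpin_folds))
  invisible(x)
}

#' Simulate crRNA biogenesis from an array transcript
#'
#' Locates repeats, cuts each processable repeat at the profile's cleavage
#' offset and emits mature crRNAs. For 3'-trim nucleases (Cas12a/Cas13a) a
#' crRNA is the repeat-derived handle plus the downstream guide trimmed to
#' `mature_spacer_len`; if the final repeat is consensus-like (processable
#' per [classify_terminal_repeat()]) an extraneous crRNA is additionally
#' emitted whose guide comes from the non-array sequence downstream of the
#' terminal repeat. For 5'-trim nucleases (Cas9) the guide is the encoded
#' spacer minus the 5' trim (junction plus whatever reaches
#' `mature_spacer_len`); maturation requires trans factors (tracrRNA, RNase
#' III), which is recorded, not mechanistically simulated.
#'
#' @param transcript RNA [nucseq()] or string.
#' @param profile [nuclease_profile()].
#' @param terminator_pos optional 0-based transcript position where the
#'   terminator starts (guides never extend past it).
#' @param n_spacers optional known number of designed spacers (e.g. from the
#'   design); without it the last repeat is deemed terminal when less than
#'   one transcribed spacer length remains downstream of it.
#' @param max_mismatches repeat-scan budget, see [find_repeats()].
#' @return object of class `crrna_set`: list with `crRNAs` (list of `crrna`
#'   records), `terminal_call`, `requires_trans_factors`, `notes`.
#' @export
process_transcript <- function(transcript, profile, terminator_pos = NULL,
                               n_spacers = NULL, max_mismatches = 3L) {
  if (is.null(profile$hairpin) || is.null(profile$cleavage_offset)) {
    stop("profile incomplete: hairpin and cleavage_offset are required ",
         "for processing simulation", call. = FALSE)
  }
  x <- chartr("T", "U", toupper(as.character(transcript)))
  L <- nchar(x)
  if (is.null(terminator_pos)) terminator_pos <- L
  reps <- find_repeats(x, profile, max_mismatches)
  notes <- character()
  crRNAs <- list()
  if (!length(reps)) {
    return(structure(list(crRNAs = crRNAs, terminal_call = NULL,
                          requires_trans_factors = profile$requires_trans_factors,
                          notes = "no repeats found"), class = "crrna_set"))
  }
  k <- length(reps)
  three_prime <- profile$junction_side == "three_prime_of_spacer"
  carry <- max(0L, profile$mature_spacer_len - profile$encoded_spacer_len)
  terminal_call <- NULL

  if (three_prime) {
    # is the last repeat a terminal repeat (no designed spacer downstream)?
    last_is_terminal <- if (!is.null(n_spacers)) {
      k == n_spacers + 1L
    } else {
      (terminator_pos - reps[[k]]$end) <= profile$transcribed_spacer_total
    }
    n_internal <- if (last_is_terminal) k - 1L else k
    for (r in seq_len(n_internal)) {
      iv <- reps[[r]]
      handle <- substr(x, iv$start + profile$cleavage_offset + 1L, iv$end)
      gstart <- iv$end
      gend <- min(gstart + profile$mature_spacer_len,
                  if (r < k) reps[[r + 1L]]$start else terminator_pos)
      guide <- substr(x, gstart + 1L, gend)
      crRNAs[[length(crRNAs) + 1L]] <- new_crrna(
        interval(iv$start + profile$cleavage_offset, gend),
        handle, guide, "internal", carry)
    }
    if (last_is_terminal) {
      iv <- reps[[k]]
      terminal_seq <- substr(x, iv$start + 1L, iv$end)
      terminal_call <- classify_terminal_repeat(terminal_seq, profile)
      if (terminal_call$verdict == "processable") {
        handle <- substr(x, iv$start + profile$cleavage_offset + 1L, iv$end)
        gend <- min(iv$end + profile$mature_spacer_len, terminator_pos)
        guide <- substr(x, iv$end + 1L, gend)
        crRNAs[[length(crRNAs) + 1L]] <- new_crrna(
          interval(iv$start + profile$cleavage_offset, gend),
          handle, guide, "terminal_extraneous", 0L)
      } else {
        notes <- c(notes, paste(
          "terminal repeat disrupted: no extraneous crRNA emitted;",
          "a standalone trimmed repeat product (~26 nt) may still accumulate",
          "in some hosts (not emitted)"))
      }
    }
  } else {
    # 5'-trim (Cas9-style): guides live between consecutive repeats
    trim5 <- profile$junction_len +
      max(0L, profile$encoded_spacer_len - profile$mature_spacer_len)
    for (r in seq_len(k - 1L)) {
      region_start <- reps[[r]]$end
      region_end <- reps[[r + 1L]]$start
      gstart <- min(region_start + trim5, region_end)
      guide <- substr(x, gstart + 1L, region_end)
      handle <- substr(x, reps[[r + 1L]]$start + 1L,
                       reps[[r + 1L]]$start + profile$cleavage_offset)
      crRNAs[[length(crRNAs) + 1L]] <- new_crrna(
        interval(gstart, reps[[r + 1L]]$start + profile$cleavage_offset),
        handle, guide, "internal", carry)
    }
    notes <- c(notes,
               "maturation requires trans factors (tracrRNA + RNase III); modeled as deterministic trimming")
  }
  if (carry > 0L) {
    warning("junction carryover of ", carry, " nt overlaps the guide 3' end; ",
            "relevant if this region hybridizes for other nucleases",
            call. = FALSE)
  }
  structure(list(crRNAs = crRNAs, terminal_call = terminal_call,
                 requires_trans_factors = profile$requires_trans_factors,
                 notes = notes),
            class = "crrna_set")
}

new_crrna <- function(source, handle, guide, cls, junction_carryover) {
  structure(list(source = source, handle = handle, guide = guide,
                 mature_len = nchar(handle) + nchar(guide), cls = cls,
                 junction_carryover = junction_carryover),
            class = "crrna")
}

#' @export
print.crrna <- function(x, ...) {
  cat(sprintf("<crRNA %s: %d nt (handle %d + guide %d) [%d, %d)>\n",
              x$cls, x$mature_len, nchar(x$handle), nchar(x$guide),
              x$source$start, x$source$end))
  invisible(x)
}

#' @export
print.crrna_set <- function(x, ...) {
  cat(sprintf("<crrna_set: %d crRNA(s)>\n", length(x$crRNAs)))
  for (cr in x$crRNAs) print(cr)
  if (!is.null(x$terminal_call)) print(x$terminal_call)
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Write mature crRNAs to FASTA
#'
#' @param crset `crrna_set`.
#' @param path output path.
#' @export
write_crrnas <- function(crset, path) {
  seqs <- vapply(crset$crRNAs, function(cr) paste0(cr$handle, cr$guide),
                 character(1L))
  names(seqs) <- vapply(seq_along(crset$crRNAs), function(i)
    sprintf("crRNA_%d_%s", i, crset$crRNAs[[i]]$cls), character(1L))
  write_fasta(seqs, path)
}
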
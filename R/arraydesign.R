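## Array design: spacers + nuclease profiles -> repeat-spacer units,
## annealing oligos, predicted construct, libraries, protocol sheet.
##
## Geometry conventions (all on the array-sense top strand):
##  * 3'-trim nucleases (Cas12a/Cas13a): unit i top strand = J[i-1] R S[i];
##    the backbone carries the terminal repeat, so the assembled array reads
##    R S1 J1 R S2 J2 ... R Sn Jn R(term).
##  * 5'-trim nucleases (Cas9): unit i top strand = J[i] S[i] R; the backbone
##    carries the upstream repeat, giving R J1 S1 R J2 S2 ... Jn Sn R.
## Junction i always falls in the trimmed, non-hybridizing part of the
## adjacent spacer's transcribed region.

DEFAULT_PROMOTER  <- "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC"
DEFAULT_TERMINATOR <- "CCAGGCATCAAATAAAACGAAAGGCTCAGTCGAAAGACTGGGCCTTTCGTTTTATCTG"

#' Construct a circular assembly backbone
#'
#' Builds the base construct for one-pot assembly: promoter, a stuffer
#' "dropout" cassette flanked by two Type IIS recognition sites oriented so
#' digestion removes the cassette together with both sites, fixed repeat(s)
#' (a 5'-side repeat for Cas9-style designs and/or a 3'-side terminal repeat
#' for Cas12a-style designs), a short downstream region, a terminator, and
#' vector filler. The exposed overhangs after digestion are the outermost
#' assembly junctions `j_left` / `j_right`.
#'
#' @param profile [nuclease_profile()] supplying the terminal repeat for
#'   3'-trim designs (ignored when `three_prime_repeat = FALSE`).
#' @param enzyme [enzyme_def()]; default BsmBI.
#' @param j_left,j_right 4-nt junctions exposed at the two backbone ends.
#' @param five_prime_repeat optional [nuclease_profile()] whose repeat is
#'   placed upstream of the dropout (Cas9-style / composite backbones).
#' @param three_prime_repeat place a terminal repeat downstream (`TRUE` for
#'   Cas12a-style backbones).
#' @param terminal_variant `"consensus"` (processable terminal repeat),
#'   `"native_mutated"` (three substitutions in the 3' stem, disrupting
#'   processing) or `"absent"`.
#' @param downstream_seq sequence between the terminal repeat and the
#'   terminator (source of the extraneous crRNA guide).
#' @param filler_len vector filler length closing the circle.
#' @return object of class `backbone_spec`.
#' @export
make_backbone <- function(profile = builtin_profile("FnCas12a"),
                          enzyme = builtin_enzyme("BsmBI"),
                          j_left = "CCCT", j_right = "GCTG",
                          five_prime_repeat = NULL,
                          three_prime_repeat = TRUE,
                          terminal_variant = c("consensus", "native_mutated",
                                               "absent"),
                          downstream_seq = "GTTAACCTTAGGAACCTTGGATCCAATGCA",
                          filler_len = 60L) {
  terminal_variant <- match.arg(terminal_variant)
  j_left <- toupper(j_left); j_right <- toupper(j_right)
  validate_bases(j_left, "DNA"); validate_bases(j_right, "DNA")
  rec <- enzyme$recognition
  dropout_core <- "ATGGCTAGCAAAGGAGAAGAACTTTTCACTGGAGTT"  # stuffer (reporter stand-in)

  term_rep <- switch(terminal_variant,
    consensus = profile$repeat_seq,
    native_mutated = mutate_terminal_repeat(profile),
    absent = "")
  if (!three_prime_repeat) term_rep <- ""

  parts <- list()
  feats <- list()
  pos <- 0L
  push <- function(seq, type, label) {
    if (!nzchar(seq)) return(invisible(NULL))
    parts[[length(parts) + 1L]] <<- seq
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, start = pos, end = pos + nchar(seq), strand = "+",
      label = label, stringsAsFactors = FALSE)
    pos <<- pos + nchar(seq)
  }

  push(DEFAULT_PROMOTER, "promoter", "promoter")
  if (!is.null(five_prime_repeat)) {
    push(five_prime_repeat$repeat_seq, "repeat",
         paste0(five_prime_repeat$name, "_5prime_repeat"))
  }
  # left cut: recognition on the bottom strand, cutting leftward (outward):
  # top strand reads J_left, 1-nt spacer, revcomp(recognition)
  dropout_start <- pos
  push(j_left, "junction", "J_left")
  push("A", "misc_feature", "spacer_nt")
  push(revcomp(rec), "protein_bind", paste0(enzyme$name, "_site_rev"))
  push(dropout_core, "misc_feature", "dropout")
  # right cut: recognition on the top strand, cutting rightward (outward)
  push(rec, "protein_bind", paste0(enzyme$name, "_site_fwd"))
  push("A", "misc_feature", "spacer_nt")
  push(j_right, "junction", "J_right")
  dropout_end <- pos  # [dropout_start, dropout_end) spans J..sites..J
  if (nzchar(term_rep)) {
    push(term_rep, "repeat", paste0(profile$name, "_terminal_repeat"))
  }
  push(downstream_seq, "misc_feature", "downstream")
  terminator_start <- pos
  push(DEFAULT_TERMINATOR, "terminator", "terminator")
  filler <- paste(rep(c("A", "C", "T", "G", "A", "T"),
                      length.out = filler_len), collapse = "")
  push(filler, "misc_feature", "vector_filler")

  seqstr <- paste(unlist(parts), collapse = "")
  features <- do.call(rbind, feats)
  bb <- structure(list(
    sequence = nucseq(seqstr, "DNA", "circular"),
    features = features,
    enzyme = enzyme,
    promoter = interval(0L, nchar(DEFAULT_PROMOTER)),
    terminator = interval(terminator_start,
                          terminator_start + nchar(DEFAULT_TERMINATOR)),
    dropout = interval(dropout_start, dropout_end),
    j_left = j_left, j_right = j_right,
    five_prime_repeat = if (is.null(five_prime_repeat)) NULL else
      five_prime_repeat$repeat_seq,
    terminal_repeat = term_rep,
    terminal_variant = if (three_prime_repeat) terminal_variant else "absent",
    profile_name = profile$name),
    class = "backbone_spec")
  frags <- digest(bb$sequence, enzyme)
  n_sites <- sum(grepl("_site_", features$label[features$type == "protein_bind"]))
  if (n_sites != 2L || length(frags) != 2L) {
    stop("backbone must carry exactly two Type IIS sites for ", enzyme$name,
         call. = FALSE)
  }
  bb
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("<backbone_spec %d bp circular, %s, junctions %s/%s, terminal repeat: %s>\n",
              nchar(x$sequence), x$enzyme$name, x$j_left, x$j_right,
              x$terminal_variant))
  invisible(x)
}

# three substitutions inside the 3' stem of the hairpin: the canonical
# disruption pattern seen in native terminal repeats
mutate_terminal_repeat <- function(profile) {
  r <- strsplit(profile$repeat_seq, "", fixed = TRUE)[[1L]]
  st <- profile$hairpin$stem3
  idx <- st$start + c(0L, 2L, 4L)
  swap <- c(A = "C", C = "A", G = "T", T = "G")
  r[idx + 1L] <- swap[r[idx + 1L]]
  paste(r, collapse = "")
}

## --- units and designs ------------------------------------------------------

new_unit <- function(profile, spacer, jl, jr, polarity_l, polarity_r,
                     position_index, block = 1L) {
  structure(list(
    nuclease = profile$name, profile = profile,
    repeat_seq = profile$repeat_seq, spacer = spacer,
    jl = jl, jr = jr,
    polarity_l = polarity_l, polarity_r = polarity_r,
    position_index = position_index, block = block),
    class = "repeat_spacer_unit")
}

# the double-stranded region of a unit on the top strand, junctions excluded
unit_core <- function(unit) {
  p <- unit$profile
  if (p$junction_side == "three_prime_of_spacer") {
    paste0(unit$repeat_seq, unit$spacer)
  } else {
    paste0(unit$spacer, unit$repeat_seq)
  }
}

# full top strand of a unit (junction regions included where the top strand
# carries them, per junction polarity)
unit_top <- function(unit) {
  left <- if (unit$polarity_l == "five_prime") unit$jl else ""
  right <- if (unit$polarity_r == "three_prime") unit$jr else ""
  paste0(left, unit_core(unit), right)
}

#' @export
print.repeat_spacer_unit <- function(x, ...) {
  cat(sprintf("<unit %d %s: J %s | spacer %s | J %s>\n", x$position_index,
              x$nuclease, x$jl,
              if (nzchar(x$spacer)) x$spacer else "(none)", x$jr))
  invisible(x)
}

#' Annealing-oligo pair for one repeat-spacer unit
#'
#' Each modular insert is formed by annealing a top and a bottom oligo whose
#' double-stranded core is repeat+spacer and whose single-stranded extensions
#' are exactly the unit's two junction overhangs. Under the default geometry
#' (36-nt repeat, 26-nt spacer, 4-nt junctions, both 5' overhangs) each oligo
#' is 66 nt and the duplex core is 62 bp.
#'
#' @param unit a `repeat_spacer_unit` from [plan_array()].
#' @return object of class `oligo_pair` with `top_oligo`, `bottom_oligo`,
#'   `duplex_len`, `left_end`, `right_end`.
#' @export
make_oligos <- function(unit) {
  core <- unit_core(unit)
  top <- unit_top(unit)
  bottom_core <- core
  bleft <- if (unit$polarity_r == "five_prime") revcomp(unit$jr) else ""
  bright <- if (unit$polarity_l == "three_prime") revcomp(unit$jl) else ""
  bottom <- paste0(bleft, revcomp(bottom_core), bright)
  structure(list(
    top_oligo = top, bottom_oligo = bottom,
    duplex_len = nchar(core),
    left_end = overhang(if (unit$polarity_l == "five_prime") unit$jl else
      revcomp(unit$jl), unit$polarity_l),
    right_end = overhang(if (unit$polarity_r == "five_prime")
      revcomp(unit$jr) else unit$jr, unit$polarity_r),
    unit = unit),
    class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair: top %d nt, bottom %d nt, duplex %d bp>\n",
              nchar(x$top_oligo), nchar(x$bottom_oligo), x$duplex_len))
  cat("  top:    5'-", x$top_oligo, "-3'\n", sep = "")
  cat("  bottom: 5'-", x$bottom_oligo, "-3'\n", sep = "")
  invisible(x)
}

check_spacer <- function(spacer, profile, enzyme, what = "spacer") {
  validate_bases(spacer, "DNA")
  if (nchar(spacer) != profile$encoded_spacer_len) {
    stop(sprintf("%s '%s' has length %d; profile %s requires %d nt",
                 what, spacer, nchar(spacer), profile$name,
                 profile$encoded_spacer_len), call. = FALSE)
  }
  if (has_enzyme_site(spacer, enzyme)) {
    stop(sprintf("%s contains a %s recognition site", what, enzyme$name),
         call. = FALSE)
  }
  invisible(spacer)
}

#' Plan a single-nuclease CRISPR array
#'
#' Turns an ordered list of spacers into a full array design: repeat-spacer
#' units with their junction overhangs, the predicted assembled insert and
#' final circular construct. Junctions are auto-proposed (seeded, orthogonal
#' under [validate_overhang_set()]) when not supplied; the two outermost
#' junctions are fixed by the backbone's exposed overhangs.
#'
#' @param spacers character vector of target-derived spacers, each of the
#'   profile's `encoded_spacer_len`; may be empty with
#'   `no_spacer_control = TRUE` to design the two-consecutive-repeats control.
#' @param profile [nuclease_profile()].
#' @param backbone [make_backbone()] result; its terminal repeat(s) must match
#'   the profile's trim side.
#' @param junctions optional character vector of all n+1 junctions (first and
#'   last must equal the backbone's `j_left`/`j_right`).
#' @param no_spacer_control design an empty array (insert is a lone repeat,
#'   yielding two consecutive repeats with the backbone's terminal repeat).
#' @param seed seed for junction proposal.
#' @param min_mismatch junction orthogonality floor.
#' @return object of class `array_design`.
#' @export
plan_array <- function(spacers, profile, backbone = NULL, junctions = NULL,
                       no_spacer_control = FALSE, seed = 1L,
                       min_mismatch = 2L) {
  if (is.null(backbone)) {
    backbone <- make_backbone(profile,
      five_prime_repeat = if (profile$junction_side == "five_prime_of_spacer")
        profile else NULL,
      three_prime_repeat = profile$junction_side == "three_prime_of_spacer")
  }
  enzyme <- backbone$enzyme
  n <- length(spacers)
  if (n == 0L && !no_spacer_control) {
    stop("no spacers given; use no_spacer_control = TRUE for an empty array",
         call. = FALSE)
  }
  for (s in spacers) check_spacer(s, profile, enzyme)
  if (has_enzyme_site(profile$repeat_seq, enzyme)) {
    stop("profile repeat contains a ", enzyme$name, " site", call. = FALSE)
  }

  if (n == 0L) {
    junctions <- c(backbone$j_left, backbone$j_right)
  } else if (is.null(junctions)) {
    fixed <- c(backbone$j_left, backbone$j_right)
    internal <- if (n > 1L) {
      vapply(propose_overhang_set(n - 1L, length = nchar(backbone$j_left),
                                  min_mismatch = min_mismatch, seed = seed,
                                  existing = fixed),
             function(o) o$seq, character(1L))
    } else character(0)
    junctions <- c(backbone$j_left, internal, backbone$j_right)
  } else {
    junctions <- toupper(junctions)
    if (length(junctions) != n + 1L) {
      stop("need n + 1 junctions for n spacers", call. = FALSE)
    }
    if (junctions[1L] != backbone$j_left ||
        junctions[n + 1L] != backbone$j_right) {
      stop("first/last junction must match the backbone's exposed overhangs (",
           backbone$j_left, ", ", backbone$j_right, ")", call. = FALSE)
    }
    rep_check <- validate_overhang_set(junctions, min_mismatch = min_mismatch)
    if (!rep_check$ok) {
      stop("junction set fails validation:\n",
           paste(rep_check$violations$detail, collapse = "\n"), call. = FALSE)
    }
  }

  three_prime <- profile$junction_side == "three_prime_of_spacer"
  units <- vector("list", max(n, 1L))
  if (n == 0L) {
    units[[1L]] <- new_unit(profile, "", junctions[1L], junctions[2L],
                            "five_prime", "five_prime", 1L)
  } else {
    for (i in seq_len(n)) {
      units[[i]] <- new_unit(profile, spacers[i], junctions[i],
                             junctions[i + 1L], "five_prime", "five_prime", i)
    }
  }
  blocks <- data.frame(nuclease = profile$name, from = 1L,
                       to = length(units), stringsAsFactors = FALSE)
  finish_design(backbone, units, junctions, blocks,
                profiles = setNames(list(profile), profile$name))
}

# assemble predicted construct/insert from backbone + ordered units
finish_design <- function(backbone, units, junctions, blocks, profiles) {
  enzyme <- backbone$enzyme
  s <- as.character(backbone$sequence)
  frag_cuts <- digest_cuts(s, enzyme, circular = TRUE)
  # two cuts; the dropout is the piece containing the recognition sites
  stopifnot(nrow(frag_cuts) == 2L)
  cuts <- frag_cuts[order(frag_cuts$top), ]
  left_top <- cuts$top[1L]; right_top <- cuts$top[2L]
  units_top <- paste(vapply(units, unit_top, character(1L)), collapse = "")
  construct <- paste0(substr(s, 1L, left_top), units_top,
                      substr(s, right_top + 1L, nchar(s)))
  if (has_enzyme_site(construct, enzyme, circular = TRUE)) {
    stop("predicted construct retains a ", enzyme$name,
         " recognition site (internal site in a unit?)", call. = FALSE)
  }
  # array insert: first repeat through the end of the array (terminal repeat
  # when the backbone provides one)
  first_rep <- units[[1L]]$repeat_seq
  if (!is.null(backbone$five_prime_repeat)) first_rep <- backbone$five_prime_repeat
  insert_start <- left_top - if (!is.null(backbone$five_prime_repeat))
    nchar(backbone$five_prime_repeat) else 0L
  if (is.null(backbone$five_prime_repeat)) {
    # 3'-trim geometry: insert starts at the first unit's repeat, which sits
    # after the ligated left junction
    insert_start <- left_top + nchar(units[[1L]]$jl)
  }
  insert_end <- left_top + nchar(units_top) +
    if (nzchar(backbone$terminal_repeat)) {
      nchar(backbone$j_right) + nchar(backbone$terminal_repeat)
    } else 0L
  predicted_insert <- substr(construct, insert_start + 1L, insert_end)
  transcript_iv <- interval(backbone$promoter$end,
                            backbone$terminator$start +
                              nchar(units_top) - (right_top - left_top))
  design <- structure(list(
    backbone = backbone, units = units, junctions = junctions,
    blocks = blocks, profiles = profiles,
    predicted_insert = predicted_insert,
    predicted_construct = nucseq(construct, "DNA", "circular"),
    transcript_region = transcript_iv),
    class = "array_design")
  design
}

#' @export
print.array_design <- function(x, ...) {
  n_sp <- sum(vapply(x$units, function(u) nzchar(u$spacer), logical(1L)))
  cat(sprintf("<array_design: %d unit(s), %d spacer(s), %d junctions, construct %d bp>\n",
              length(x$units), n_sp, length(x$junctions),
              nchar(x$predicted_construct)))
  for (u in x$units) print(u)
  cat("  junctions:", paste(x$junctions, collapse = " "), "\n")
  invisible(x)
}

#' Transcript of a designed array
#'
#' Extracts the transcribed region (promoter end through terminator start) of
#' the predicted construct and transcribes it to RNA.
#'
#' @param design [plan_array()] result.
#' @return RNA [nucseq()].
#' @export
design_transcript <- function(design) {
  dna_to_rna(design$predicted_construct, design$transcript_region)
}

#' Plan a composite (multi-nuclease) array
#'
#' Blocks of spacers for different nucleases are assembled into one insert
#' transcribed as a single array. Because Cas9-style junctions sit 5' of
#' their spacers and Cas12a/Cas13a-style junctions sit 3', every 5'-trim
#' block must precede every 3'-trim block, and the backbone must carry the
#' matching upstream (5'-trim) and terminal (3'-trim) repeats. The junction
#' between two blocks falls between two repeats and is tagged non-spacer.
#'
#' @param blocks list of `list(profile = <nuclease_profile>, spacers = <chr>)`
#'   in transcript order.
#' @param backbone [make_backbone()] with the required fixed repeats;
#'   auto-built when `NULL`.
#' @param junctions optional character vector (n_units + 1 junctions).
#' @param seed,min_mismatch junction proposal controls.
#' @return `array_design` whose `blocks` table maps units to nucleases.
#' @export
plan_composite <- function(blocks, backbone = NULL, junctions = NULL,
                           seed = 1L, min_mismatch = 2L) {
  sides <- vapply(blocks, function(b) b$profile$junction_side, character(1L))
  trim5 <- sides == "five_prime_of_spacer"
  if (any(trim5) && any(!trim5) && max(which(trim5)) > min(which(!trim5))) {
    stop("composite block order: all 5'-trim (Cas9-style) blocks must ",
         "precede 3'-trim (Cas12a/Cas13a-style) blocks, because their ",
         "junction orientations are mirrored", call. = FALSE)
  }
  if (is.null(backbone)) {
    backbone <- make_backbone(
      profile = blocks[[length(blocks)]]$profile,
      five_prime_repeat = if (any(trim5)) blocks[[which(trim5)[1L]]]$profile
        else NULL,
      three_prime_repeat = any(!trim5))
  }
  if (any(trim5) && is.null(backbone$five_prime_repeat)) {
    stop("backbone lacks the upstream fixed repeat required by a 5'-trim block",
         call. = FALSE)
  }
  if (any(!trim5) && !nzchar(backbone$terminal_repeat)) {
    stop("backbone lacks the terminal repeat required by a 3'-trim block",
         call. = FALSE)
  }
  enzyme <- backbone$enzyme
  n_units <- sum(vapply(blocks, function(b) length(b$spacers), integer(1L)))
  for (b in blocks) {
    for (s in b$spacers) check_spacer(s, b$profile, enzyme)
  }
  if (is.null(junctions)) {
    fixed <- c(backbone$j_left, backbone$j_right)
    internal <- if (n_units > 1L) {
      vapply(propose_overhang_set(n_units - 1L, length = nchar(backbone$j_left),
                                  min_mismatch = min_mismatch, seed = seed,
                                  existing = fixed),
             function(o) o$seq, character(1L))
    } else character(0)
    junctions <- c(backbone$j_left, internal, backbone$j_right)
  }
  if (length(junctions) != n_units + 1L) {
    stop("need n_units + 1 junctions", call. = FALSE)
  }
  units <- list()
  block_rows <- list()
  k <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    from <- k + 1L
    for (s in b$spacers) {
      k <- k + 1L
      units[[k]] <- new_unit(b$profile, s, junctions[k], junctions[k + 1L],
                             "five_prime", "five_prime", k, block = bi)
    }
    block_rows[[bi]] <- data.frame(nuclease = b$profile$name, from = from,
                                   to = k, stringsAsFactors = FALSE)
  }
  blocks_df <- do.call(rbind, block_rows)
  # junction at each block boundary is a scaffold (non-spacer) junction
  boundary <- blocks_df$from[-1L]
  attr(blocks_df, "non_spacer_junctions") <- boundary
  profs <- lapply(blocks, `[[`, "profile")
  names(profs) <- vapply(profs, `[[`, character(1L), "name")
  finish_design(backbone, units, junctions, blocks_df,
                profiles = profs[!duplicated(names(profs))])
}

## --- libraries --------------------------------------------------------------

#' Combinatorial library specification
#'
#' One spacer set per array position; all variants destined for the same
#' position share that position's left/right junctions, so any variant can
#' occupy its slot in the one-pot reaction.
#'
#' @param variants_per_position list of character vectors (one per position);
#'   names become variant labels (`S1a`... when unnamed).
#' @param junctions optional vector of n_positions + 1 junctions.
#' @export
library_spec <- function(variants_per_position, junctions = NULL) {
  stopifnot(is.list(variants_per_position), length(variants_per_position) >= 1L)
  vp <- lapply(seq_along(variants_per_position), function(i) {
    v <- toupper(variants_per_position[[i]])
    if (is.null(names(variants_per_position[[i]]))) {
      names(v) <- paste0("S", i, letters[seq_along(v)])
    } else {
      names(v) <- names(variants_per_position[[i]])
    }
    v
  })
  structure(list(variants_per_position = vp, junctions = junctions,
                 n_positions = length(vp),
                 n_members = prod(vapply(vp, length, integer(1L)))),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec: %d positions x (%s) variants = %d members>\n",
              x$n_positions,
              paste(vapply(x$variants_per_position, length, integer(1L)),
                    collapse = ","),
              x$n_members))
  invisible(x)
}

#' Enumerate a combinatorial array library and its oligo sheet
#'
#' Generates one [plan_array()] design per combination of position variants
#' (the library has `prod(variants)` members) and an oligo sheet with two
#' oligos per distinct (position, variant) unit — oligos are shared across
#' arrays, which is what makes one-pot library assembly economical (e.g.
#' 3 positions x 5 variants needs 30 oligos for 125 arrays).
#'
#' @param spec [library_spec()].
#' @param profile [nuclease_profile()].
#' @param backbone optional [make_backbone()].
#' @param seed junction proposal seed.
#' @return list with `designs` (named list of `array_design`) and
#'   `oligo_sheet` (data.frame: name, position, variant, strand, sequence,
#'   length, left_overhang, right_overhang).
#' @export
plan_library <- function(spec, profile, backbone = NULL, seed = 1L) {
  stopifnot(inherits(spec, "library_spec"))
  if (is.null(backbone)) {
    backbone <- make_backbone(profile,
      five_prime_repeat = if (profile$junction_side == "five_prime_of_spacer")
        profile else NULL,
      three_prime_repeat = profile$junction_side == "three_prime_of_spacer")
  }
  npos <- spec$n_positions
  junctions <- spec$junctions
  if (is.null(junctions)) {
    fixed <- c(backbone$j_left, backbone$j_right)
    internal <- if (npos > 1L) {
      vapply(propose_overhang_set(npos - 1L, length = nchar(backbone$j_left),
                                  seed = seed, existing = fixed),
             function(o) o$seq, character(1L))
    } else character(0)
    junctions <- c(backbone$j_left, internal, backbone$j_right)
  }
  combos <- expand.grid(lapply(spec$variants_per_position, names),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  # enumerate with the last position varying slowest is immaterial; fix an
  # intuitive order: first position slowest
  combos <- combos[do.call(order, as.list(combos)), , drop = FALSE]
  designs <- vector("list", nrow(combos))
  ids <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    spacers <- vapply(seq_len(npos), function(p) {
      spec$variants_per_position[[p]][[combos[r, p]]]
    }, character(1L))
    designs[[r]] <- plan_array(spacers, profile, backbone,
                               junctions = junctions)
    ids[r] <- paste(unlist(combos[r, ]), collapse = "_")
  }
  names(designs) <- ids
  sheet <- list()
  for (p in seq_len(npos)) {
    for (v in names(spec$variants_per_position[[p]])) {
      unit <- new_unit(profile, spec$variants_per_position[[p]][[v]],
                       junctions[p], junctions[p + 1L],
                       "five_prime", "five_prime", p)
      op <- make_oligos(unit)
      for (strand in c("top", "bottom")) {
        oseq <- if (strand == "top") op$top_oligo else op$bottom_oligo
        sheet[[length(sheet) + 1L]] <- data.frame(
          name = sprintf("%s_pos%d_%s", v, p, strand),
          position = p, variant = v, strand = strand, sequence = oseq,
          length = nchar(oseq),
          left_overhang = op$left_end$seq, right_overhang = op$right_end$seq,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(designs = designs, oligo_sheet = do.call(rbind, sheet),
       junctions = junctions, spec = spec, backbone = backbone)
}

#' Oligo sheet for a single design
#'
#' @param design `array_design`.
#' @return data.frame, two rows (top/bottom oligo) per unit.
#' @export
oligo_sheet <- function(design) {
  sheet <- list()
  for (u in design$units) {
    op <- make_oligos(u)
    for (strand in c("top", "bottom")) {
      oseq <- if (strand == "top") op$top_oligo else op$bottom_oligo
      sheet[[length(sheet) + 1L]] <- data.frame(
        name = sprintf("unit%d_%s", u$position_index, strand),
        position = u$position_index, variant = u$spacer, strand = strand,
        sequence = oseq, length = nchar(oseq),
        left_overhang = op$left_end$seq, right_overhang = op$right_end$seq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, sheet)
}

## --- protocol sheet ---------------------------------------------------------

# average dsDNA molar mass: bp * 617.96 + 36.04 g/mol
fmol_to_ng <- function(fmol, length_bp) {
  fmol * (length_bp * 617.96 + 36.04) / 1e6
}

#' One-pot assembly protocol sheet
#'
#' Emits reagent amounts and thermocycling parameters for the digestion-
#' ligation reaction: 400 fmol of each annealed dsDNA insert and 20 fmol of
#' backbone; 25 digestion/ligation cycles (42 C 2 min / 16 C 5 min) in single
#' mode or 35 cycles in library mode, followed by final digestion (60 C
#' 10 min) and heat inactivation (80 C 10 min). Nanogram equivalents use the
#' average dsDNA molar mass (bp x 617.96 + 36.04).
#'
#' @param design an `array_design` or the result of [plan_library()].
#' @param mode `"single"` or `"library"`.
#' @return object of class `protocol_sheet` with `reagents` (data.frame) and
#'   `cycling` (character lines).
#' @export
protocol_sheet <- function(design, mode = c("single", "library")) {
  mode <- match.arg(mode)
  if (inherits(design, "array_design")) {
    units <- design$units
    backbone <- design$backbone
    species <- data.frame(
      species = vapply(units, function(u)
        sprintf("unit%d_dsDNA", u$position_index), character(1L)),
      length_bp = vapply(units, function(u) nchar(unit_top(u)), integer(1L)),
      fmol = 400, stringsAsFactors = FALSE)
  } else {
    sheet <- design$oligo_sheet
    tops <- sheet[sheet$strand == "top", ]
    backbone <- design$backbone
    species <- data.frame(
      species = paste0(tops$variant, "_pos", tops$position, "_dsDNA"),
      length_bp = tops$length, fmol = 400, stringsAsFactors = FALSE)
  }
  species <- rbind(species, data.frame(
    species = "backbone", length_bp = nchar(backbone$sequence), fmol = 20,
    stringsAsFactors = FALSE))
  species$ng <- round(fmol_to_ng(species$fmol, species$length_bp), 2)
  n_cycles <- if (mode == "single") 25L else 35L
  cycling <- c(
    sprintf("%d cycles (42 °C 2 min / 16 °C 5 min)", n_cycles),
    "final digestion 60 °C 10 min",
    "heat inactivation 80 °C 10 min")
  structure(list(mode = mode, n_cycles = n_cycles, reagents = species,
                 cycling = cycling,
                 other = c("T4 DNA ligase 1 uL", "Type IIS enzyme 1 uL",
                           "T4 ligation buffer 2 uL", "water to 20 uL")),
            class = "protocol_sheet")
}

#' @export
print.protocol_sheet <- function(x, ...) {
  cat(sprintf("One-pot assembly protocol (%s mode)\n", x$mode))
  print(x$reagents, row.names = FALSE)
  cat(paste0("  ", x$other, collapse = "\n"), "\n")
  cat(paste0("  ", x$cycling, collapse = "\n"), "\n")
  invisible(x)
}
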
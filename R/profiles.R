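#' Nuclease processing/design profile
#'
#' Bundles the per-nuclease constants that drive array design and crRNA
#' biogenesis simulation: the consensus repeat (DNA sense), which side of the
#' spacer is trimmed during maturation (and therefore hosts the assembly
#' junction), the length bookkeeping from transcribed spacer to mature guide,
#' and the repeat hairpin coordinates used by the structure screen.
#'
#' Geometry defaults reproduce the working design: a 36-nt repeat, a 26-nt
#' target-derived spacer and a 4-nt junction, so each transcribed spacer
#' region is 30 nt and each annealing oligo is 66 nt. Cas12a/Cas13a-family
#' nucleases trim the spacer 3' end (30 nt transcribed to ~23 nt mature, with
#' only the first 20 nt hybridizing); Cas9 trims ~10 nt from the 5' end,
#' leaving a 20-nt guide, and additionally needs tracrRNA plus host RNase III.
#'
#' @param name profile name.
#' @param repeat_seq consensus repeat, DNA sense strand.
#' @param junction_side `"three_prime_of_spacer"` (Cas12a/Cas13a) or
#'   `"five_prime_of_spacer"` (Cas9): where the assembly junction sits.
#' @param encoded_spacer_len target-derived spacer length (nt).
#' @param junction_len junction overhang length (nt).
#' @param mature_spacer_len guide length after trimming (nt).
#' @param guide_hyb_len 5'-guide portion that hybridizes with the target;
#'   must not exceed `encoded_spacer_len` so the junction stays outside it.
#' @param handle_len repeat-derived nt retained on the mature crRNA.
#' @param hairpin list with `stem5` and `stem3` [interval()]s (repeat
#'   coordinates) of the processing hairpin; the loop is the gap between them.
#' @param cleavage_offset 0-based position within the repeat where the
#'   pre-crRNA is cut.
#' @param requires_trans_factors `TRUE` if maturation needs tracrRNA/RNase III.
#' @return object of class `nuclease_profile`.
#' @export
nuclease_profile <- function(name, repeat_seq,
                             junction_side = c("three_prime_of_spacer",
                                               "five_prime_of_spacer"),
                             encoded_spacer_len = 26L, junction_len = 4L,
                             mature_spacer_len = 23L, guide_hyb_len = 20L,
                             handle_len = 19L, hairpin = NULL,
                             cleavage_offset = NULL,
                             requires_trans_factors = FALSE) {
  junction_side <- match.arg(junction_side)
  repeat_seq <- toupper(as.character(repeat_seq))
  validate_bases(repeat_seq, "DNA")
  rlen <- nchar(repeat_seq)
  if (guide_hyb_len > encoded_spacer_len) {
    stop("guide_hyb_len must not exceed encoded_spacer_len ",
         "(the junction would overlap the hybridizing guide)", call. = FALSE)
  }
  if (is.null(cleavage_offset)) {
    cleavage_offset <- if (junction_side == "three_prime_of_spacer") {
      rlen - handle_len
    } else {
      handle_len
    }
  }
  if (cleavage_offset < 0L || cleavage_offset > rlen) {
    stop("cleavage_offset outside the repeat", call. = FALSE)
  }
  if (!is.null(hairpin)) {
    stopifnot(is.list(hairpin), !is.null(hairpin$stem5), !is.null(hairpin$stem3))
    for (iv in hairpin[c("stem5", "stem3")]) {
      if (iv$start < 0L || iv$end > rlen) {
        stop("hairpin interval outside the repeat", call. = FALSE)
      }
    }
    if (interval_width(hairpin$stem5) != interval_width(hairpin$stem3)) {
      stop("hairpin stems must have equal length", call. = FALSE)
    }
  }
  structure(list(
    name = name, repeat_seq = repeat_seq, junction_side = junction_side,
    encoded_spacer_len = as.integer(encoded_spacer_len),
    junction_len = as.integer(junction_len),
    transcribed_spacer_total = as.integer(encoded_spacer_len + junction_len),
    mature_spacer_len = as.integer(mature_spacer_len),
    guide_hyb_len = as.integer(guide_hyb_len),
    handle_len = as.integer(handle_len),
    hairpin = hairpin,
    cleavage_offset = as.integer(cleavage_offset),
    requires_trans_factors = isTRUE(requires_trans_factors)),
    class = "nuclease_profile")
}

#' @export
print.nuclease_profile <- function(x, ...) {
  cat(sprintf("<nuclease_profile %s>\n", x$name))
  cat(sprintf("  repeat (%d nt): %s\n", nchar(x$repeat_seq), x$repeat_seq))
  cat(sprintf("  junction: %s, %d nt; spacer %d nt encoded -> %d nt mature (%d hyb)\n",
              if (x$junction_side == "three_prime_of_spacer") "3' of spacer"
              else "5' of spacer",
              x$junction_len, x$encoded_spacer_len, x$mature_spacer_len,
              x$guide_hyb_len))
  cat(sprintf("  handle %d nt, cleavage offset %d, trans factors: %s\n",
              x$handle_len, x$cleavage_offset,
              if (x$requires_trans_factors) "tracrRNA + RNase III" else "none"))
  invisible(x)
}

# Placeholder consensus repeats. The real per-nuclease repeats are not
# shipped with this package; these synthetic 36-nt stand-ins
# carry a designed 3'-proximal hairpin (stem [19,25) / loop 4 nt /
# stem [29,35)) so the processing and folding machinery is exercised
# faithfully. Users targeting a real system must substitute the genuine
# repeat via profile config (see load_run_config()).
.placeholder_repeat <- function(prefix17) {
  stopifnot(nchar(prefix17) == 17L)
  paste0(prefix17, "GA", "GCGAGC", "AACA", "GCTCGC", "A")
}

.default_hairpin <- function() {
  list(stem5 = interval(19L, 25L), stem3 = interval(29L, 35L))
}

#' Built-in nuclease profiles
#'
#' Returns the named profile with package defaults. Repeats are synthetic
#' placeholders (see [nuclease_profile()]); lengths follow the field's
#' working numbers: FnCas12a/AsCas12a trim the transcribed 30-nt spacer
#' region to a 23-nt guide at the 3' end and retain a 19-nt repeat handle;
#' SpCas9 trims ~10 nt from the 5' end leaving a 20-nt guide and requires
#' tracrRNA/RNase III; LsCas13a is modeled like Cas12a (3'-end trimming, the
#' mature length is configurable because no consensus number exists).
#'
#' @param name one of `"FnCas12a"`, `"AsCas12a"`, `"SpCas9"`, `"LsCas13a"`.
#' @return [nuclease_profile()].
#' @export
builtin_profile <- function(name = c("FnCas12a", "AsCas12a", "SpCas9",
                                     "LsCas13a")) {
  name <- match.arg(name)
  switch(name,
    FnCas12a = nuclease_profile(
      "FnCas12a", .placeholder_repeat("AATTTCTACTAAGTGTA"),
      junction_side = "three_prime_of_spacer",
      mature_spacer_len = 23L, handle_len = 19L,
      hairpin = .default_hairpin()),
    AsCas12a = nuclease_profile(
      "AsCas12a", .placeholder_repeat("AATTACTACTCAGTGTA"),
      junction_side = "three_prime_of_spacer",
      mature_spacer_len = 23L, handle_len = 19L,
      hairpin = .default_hairpin()),
    SpCas9 = nuclease_profile(
      "SpCas9", .placeholder_repeat("GTTTGAGAGCTATGCTG"),
      junction_side = "five_prime_of_spacer",
      mature_spacer_len = 20L, handle_len = 19L,
      hairpin = .default_hairpin(),
      requires_trans_factors = TRUE),
    LsCas13a = nuclease_profile(
      "LsCas13a", .placeholder_repeat("GATTTAGACTACCTCAA"),
      junction_side = "three_prime_of_spacer",
      mature_spacer_len = 23L, handle_len = 19L,
      hairpin = .default_hairpin()))
}

#' Type IIS enzyme definition
#'
#' Cut geometry is given as offsets downstream of the recognition site's 3'
#' end on each strand; the difference sets the overhang length, and BsmBI /
#' BsaI leave 4-nt 5' overhangs (N1 spacing).
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (top strand).
#' @param top_cut_offset,bottom_cut_offset nt downstream of the recognition
#'   3' end where the top/bottom strand is cut.
#' @export
enzyme_def <- function(name, recognition, top_cut_offset, bottom_cut_offset) {
  recognition <- toupper(recognition)
  validate_bases(recognition, "DNA")
  ov <- abs(bottom_cut_offset - top_cut_offset)
  structure(list(name = name, recognition = recognition,
                 top_cut_offset = as.integer(top_cut_offset),
                 bottom_cut_offset = as.integer(bottom_cut_offset),
                 overhang_len = as.integer(ov),
                 overhang_polarity = if (bottom_cut_offset >= top_cut_offset)
                   "five_prime" else "three_prime"),
            class = "enzyme_def")
}

#' @rdname enzyme_def
#' @export
builtin_enzyme <- function(name = c("BsmBI", "BsaI")) {
  name <- match.arg(name)
  switch(name,
    BsmBI = enzyme_def("BsmBI", "CGTCTC", 1L, 5L),
    BsaI  = enzyme_def("BsaI",  "GGTCTC", 1L, 5L))
}

# does `seq` (and its reverse complement) contain the recognition site?
has_enzyme_site <- function(seq, enzyme, circular = FALSE) {
  s <- as.character(seq)
  if (circular) {
    k <- nchar(enzyme$recognition) - 1L
    s <- paste0(s, substr(s, 1L, k))
  }
  length(find_fixed(enzyme$recognition, s)) > 0L ||
    length(find_fixed(revcomp(enzyme$recognition), s)) > 0L
}
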
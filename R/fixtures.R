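## Run configuration and deterministic fixture generation tying the modules
## together: a toy backbone, toy profiles, spacer trios with known structural
## behavior, a 3 x 5 library spec, and simulated reads.

#' Load / build a run configuration
#'
#' Configuration is JSON (profiles, enzymes, thresholds, seed). Every
#' referenced profile/enzyme name must resolve; unknown names are errors.
#'
#' @param path optional JSON file; `NULL` gives the built-in defaults.
#' @return object of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- list(
    profiles = list(FnCas12a = builtin_profile("FnCas12a"),
                    AsCas12a = builtin_profile("AsCas12a"),
                    SpCas9 = builtin_profile("SpCas9"),
                    LsCas13a = builtin_profile("LsCas13a")),
    enzymes = list(BsmBI = builtin_enzyme("BsmBI"),
                   BsaI = builtin_enzyme("BsaI")),
    thresholds = list(p_star = 0.8, stem_len_flag = 10L, min_mismatch = 2L,
                      max_mismatches = 3L),
    seed = 1L)
  if (!is.null(path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(raw$seed)) cfg$seed <- as.integer(raw$seed)
    for (th in names(raw$thresholds)) {
      cfg$thresholds[[th]] <- raw$thresholds[[th]]
    }
    for (pn in names(raw$profiles)) {
      p <- raw$profiles[[pn]]
      hairpin <- if (!is.null(p$hairpin)) {
        list(stem5 = interval(p$hairpin$stem5[1L], p$hairpin$stem5[2L]),
             stem3 = interval(p$hairpin$stem3[1L], p$hairpin$stem3[2L]))
      } else NULL
      args <- list(name = pn, repeat_seq = p$repeat_seq,
                   junction_side = p$junction_side, hairpin = hairpin)
      for (f in c("encoded_spacer_len", "junction_len", "mature_spacer_len",
                  "guide_hyb_len", "handle_len", "cleavage_offset")) {
        if (!is.null(p[[f]])) args[[f]] <- as.integer(p[[f]])
      }
      if (!is.null(p$requires_trans_factors)) {
        args$requires_trans_factors <- isTRUE(p$requires_trans_factors)
      }
      cfg$profiles[[pn]] <- do.call(nuclease_profile, args)
    }
    for (en in names(raw$enzymes)) {
      e <- raw$enzymes[[en]]
      cfg$enzymes[[en]] <- enzyme_def(en, e$recognition,
                                      e$top_cut_offset, e$bottom_cut_offset)
    }
  }
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n  profiles:", paste(names(x$profiles), collapse = ", "),
      "\n  enzymes:", paste(names(x$enzymes), collapse = ", "),
      "\n  seed:", x$seed, "\n")
  invisible(x)
}

#' Junction set used by the structural fixtures
#'
#' J0/J3 are the backbone overhangs of the working protocol (CCCT / GCTG);
#' J1/J2 expose a G/C 2-mer at their start (the order-specific extension of
#' an engineered decoy stem) and stay inert elsewhere (their A/T positions
#' pair nothing against the A-rich fixture spacers).
#'
#' @return character vector of four 4-nt junctions (5' to 3' array order).
#' @export
fixture_junctions <- function() c("CCCT", "CCAA", "GGTA", "GCTG")

#' Spacer trios with known structural behavior
#'
#' `clean_trio()` returns three adenine-rich spacers with sparse cytosines
#' for distinguishability; such spacers pair almost nothing in a transcribed
#' array, so the repeat hairpins fold undisturbed and the structure screen
#' reports zero flags in all six spacer orders.
#'
#' `pathological_trio()` returns three spacers engineered so that the screen
#' flags exactly one crRNA in exactly one of the six orders (spacer order
#' A, C, B with the fixture junctions): each spacer carries G/C decoy
#' segments reverse-complementary to a (spacer 3' tail + junction start)
#' target, and only specific spacer-to-position assignments make a target
#' contiguous. In the discriminated order a single decoy helix bridges
#' spacer A's trimmed 3' end and spacer C, enclosing the intervening repeat
#' and collapsing its processing-hairpin integrity — the bridging-hairpin
#' signature — while the other five orders either form no dominant helix or
#' disrupt several crRNAs at once.
#'
#' @return character vector of three named 26-nt spacers.
#' @export
clean_trio <- function() {
  c(S1 = "AAAACAAAAAAACAAAAAAAACAAAA",
    S2 = "AAAAAAACAAAAAAAACAAAAAAACA",
    S3 = "AACAAAAAACAAAAAAAACAAAAAAA")
}

#' @rdname clean_trio
#' @export
pathological_trio <- function() {
  j <- fixture_junctions()
  c_t8 <- "CCGCCGCG"            # spacer C 3' tail (G/C pattern)
  b_t8 <- "CCCCCGGC"            # spacer B 3' tail
  a_t8 <- revcomp(c_t8)         # spacer A 3' tail, dual-use (see below)
  j2mer <- function(k) substr(j[k], 1L, 2L)
  y1 <- revcomp(paste0(a_t8, j2mer(2L)))  # fires when A occupies position 1
  y2 <- revcomp(paste0(b_t8, j2mer(3L)))  # fires when B occupies position 2
  y3 <- revcomp(paste0(c_t8, j2mer(4L)))  # fires when C occupies position 3
  y4 <- revcomp(paste0(a_t8, j2mer(3L)))  # fires when A occupies position 2
  y5 <- revcomp(paste0(c_t8, j2mer(2L)))  # fires when C occupies position 1
  # y4 ends in c_t8 and y5 ends in a_t8, so each doubles as the host
  # spacer's own tail
  c(A = paste0(y2, strrep("A", 6L), y5),
    B = paste0(y3, strrep("A", 6L), y4),
    C = paste0(strrep("A", 6L), y1, "AA", c_t8))
}

#' Generate the deterministic fixture bundle
#'
#' Writes, under `dir`: a toy circular backbone (GenBank), the built-in
#' profiles and thresholds (JSON), clean and pathological spacer trios
#' (FASTA), a 3 x 5 library specification (JSON) and a simulated amplicon
#' FASTQ over that library. Everything is deterministic given `seed` (the
#' spacer trios and backbone are fixed constants; the seed drives the library
#' variant spacers and the reads).
#'
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisible list of written paths plus the in-memory objects.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profile <- builtin_profile("FnCas12a")
  backbone <- make_backbone(profile)
  paths <- list()

  gb <- file.path(dir, "backbone.gb")
  write_genbank(list(name = "toy_backbone", sequence = backbone$sequence,
                     features = backbone$features), gb)
  paths$backbone <- gb

  cfg <- file.path(dir, "config.json")
  prof_json <- lapply(load_run_config()$profiles, function(p) {
    list(repeat_seq = p$repeat_seq, junction_side = p$junction_side,
         encoded_spacer_len = p$encoded_spacer_len,
         junction_len = p$junction_len,
         mature_spacer_len = p$mature_spacer_len,
         guide_hyb_len = p$guide_hyb_len, handle_len = p$handle_len,
         cleavage_offset = p$cleavage_offset,
         requires_trans_factors = p$requires_trans_factors,
         hairpin = list(stem5 = c(p$hairpin$stem5$start, p$hairpin$stem5$end),
                        stem3 = c(p$hairpin$stem3$start, p$hairpin$stem3$end)))
  })
  jsonlite::write_json(list(profiles = prof_json,
                            enzymes = list(BsmBI = list(
                              recognition = "CGTCTC", top_cut_offset = 1,
                              bottom_cut_offset = 5)),
                            thresholds = load_run_config()$thresholds,
                            seed = seed),
                       cfg, auto_unbox = TRUE, pretty = TRUE)
  paths$config <- cfg

  write_fasta(clean_trio(), file.path(dir, "spacers_clean.fasta"))
  write_fasta(pathological_trio(), file.path(dir, "spacers_pathological.fasta"))
  paths$spacers_clean <- file.path(dir, "spacers_clean.fasta")
  paths$spacers_pathological <- file.path(dir, "spacers_pathological.fasta")

  # 3 x 5 library: A/C-alphabet spacers generated from the seed, screened to
  # stay distinct
  variants <- withr_seed(seed, {
    lapply(1:3, function(p) {
      vapply(1:5, function(v) {
        paste(sample(c("A", "C"), 26L, replace = TRUE), collapse = "")
      }, character(1L))
    })
  })
  spec <- library_spec(variants)
  lib <- plan_library(spec, profile, backbone, seed = seed)
  lib_json <- file.path(dir, "library.json")
  jsonlite::write_json(
    list(variants_per_position = lapply(spec$variants_per_position, as.list),
         junctions = lib$junctions),
    lib_json, auto_unbox = TRUE, pretty = TRUE)
  paths$library <- lib_json
  props <- withr_seed(seed + 1L, {
    g <- stats::rgamma(length(lib$designs), shape = 5)
    g / sum(g)
  })
  reads <- simulate_reads(lib$designs, props, n_reads = 2000L,
                          read_len = 150L, error_rate = 0.001,
                          seed = seed + 2L)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(reads, fq)
  paths$reads <- fq

  invisible(list(paths = paths, backbone = backbone, profile = profile,
                 library = lib, true_props = props, reads = reads,
                 dir = dir))
}
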
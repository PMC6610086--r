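#' @importFrom stats setNames rbinom runif
#' @importFrom utils head tail write.table read.delim
NULL

DNA_BASES <- c("A", "C", "G", "T")
RNA_BASES <- c("A", "C", "G", "U")

#' Nucleic-acid sequence with explicit alphabet and topology
#'
#' A `nucseq` is an uppercase character scalar over \{A,C,G,T\} (DNA) or
#' \{A,C,G,U\} (RNA) tagged with its topology. Circular topology is only
#' meaningful for DNA constructs (plasmids); transcripts are always linear.
#' Ambiguity codes are rejected: a design must be fully specified.
#'
#' @param residues character scalar; case-insensitive on input.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param topology `"linear"` or `"circular"` (circular DNA only).
#' @param allow_empty permit the empty sequence (most operations do not).
#' @return A classed character scalar of class `nucseq`.
#' @export
nucseq <- function(residues, alphabet = c("DNA", "RNA"),
                   topology = c("linear", "circular"), allow_empty = TRUE) {
  alphabet <- match.arg(alphabet)
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("'residues' must be a single character string", call. = FALSE)
  }
  residues <- toupper(residues)
  if (!allow_empty && !nzchar(residues)) {
    stop("empty sequence not permitted here", call. = FALSE)
  }
  bases <- if (alphabet == "DNA") DNA_BASES else RNA_BASES
  if (nzchar(residues)) {
    seen <- strsplit(residues, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(seen), bases)
    if (length(bad)) {
      stop(sprintf("invalid %s character(s): %s", alphabet,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (topology == "circular" && alphabet != "DNA") {
    stop("circular topology is only supported for DNA", call. = FALSE)
  }
  structure(residues, class = "nucseq", alphabet = alphabet,
            topology = topology)
}

#' @export
print.nucseq <- function(x, ...) {
  n <- nchar(x)
  shown <- if (n > 60) paste0(substr(x, 1, 57), "...") else unclass(x)
  cat(sprintf("<nucseq %s %s, %d nt> %s\n", attr(x, "alphabet"),
              attr(x, "topology"), n, shown))
  invisible(x)
}

seq_alphabet <- function(s) {
  a <- attr(s, "alphabet")
  if (!is.null(a)) return(a)
  if (grepl("U", s, fixed = TRUE)) "RNA" else "DNA"
}

#' Reverse complement
#'
#' Works for DNA and RNA, preserving the alphabet. An involution:
#' `revcomp(revcomp(s))` equals `s`.
#'
#' @param s character scalar or [nucseq()].
#' @return Character scalar (classed if the input was).
#' @examples
#' revcomp("CCCT")  # "AGGG"
#' @export
revcomp <- function(s) {
  alph <- seq_alphabet(s)
  x <- toupper(as.character(s))
  validate_bases(x, alph)
  rc <- if (alph == "DNA") chartr("ACGT", "TGCA", x) else chartr("ACGU", "UGCA", x)
  rc <- str_rev(rc)
  if (inherits(s, "nucseq")) {
    nucseq(rc, alphabet = alph, topology = attr(s, "topology"))
  } else {
    rc
  }
}

str_rev <- function(x) {
  vapply(x, function(one) {
    paste(rev(strsplit(one, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

validate_bases <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  pat <- if (alphabet == "DNA") "^[ACGT]*$" else "^[ACGU]*$"
  if (!all(grepl(pat, x))) {
    stop(sprintf("invalid %s character in sequence", alphabet), call. = FALSE)
  }
  invisible(x)
}

#' Genomic interval (0-based, half-open)
#'
#' Coordinates follow the 0-based half-open convention `[start, end)`.
#' On circular sequences `end` may exceed the sequence length and is read
#' modulo the length (wrap-around).
#'
#' @param start,end integers with `0 <= start <= end`.
#' @param strand `"+"` (array-sense / transcribed strand) or `"-"`.
#' @export
interval <- function(start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, !is.na(start), !is.na(end))
  if (start < 0L || end < start) {
    stop("need 0 <= start <= end", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(start = start, end = end, strand = strand),
            class = "interval")
}

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("[%d, %d) %s\n", x$start, x$end, x$strand))
  invisible(x)
}

interval_width <- function(iv) iv$end - iv$start

#' Extract a region from a sequence, honoring topology and strand
#'
#' On a circular sequence the interval may wrap past the end (read modulo
#' length). On the minus strand the reverse complement of the region is
#' returned.
#'
#' @param s character scalar or [nucseq()] (DNA).
#' @param region an [interval()].
#' @return character scalar.
#' @export
extract_region <- function(s, region) {
  x <- as.character(s)
  n <- nchar(x)
  circ <- identical(attr(s, "topology"), "circular")
  if (region$end > n) {
    if (!circ) stop("region out of bounds on linear sequence", call. = FALSE)
    if (interval_width(region) > n) {
      stop("region longer than circular sequence", call. = FALSE)
    }
    x2 <- paste0(x, x)
    out <- substr(x2, region$start + 1L, region$end)
  } else {
    out <- substr(x, region$start + 1L, region$end)
  }
  if (region$strand == "-") out <- revcomp(out)
  out
}

#' Transcribe a DNA region to RNA
#'
#' Extracts `region` (strand-aware, wrap-around on circular DNA) and applies
#' the T to U substitution. The minus strand is reverse-complemented before
#' transcription, mirroring RNA polymerase reading the template strand.
#'
#' @inheritParams extract_region
#' @return RNA [nucseq()].
#' @export
dna_to_rna <- function(s, region = NULL) {
  if (is.null(region)) region <- interval(0L, nchar(as.character(s)))
  dna <- extract_region(s, region)
  nucseq(chartr("T", "U", dna), alphabet = "RNA")
}

## --- string helpers shared across modules ---------------------------------

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths", call. = FALSE)
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(va != vb)
}

# all match start positions (0-based) of fixed pattern in subject
find_fixed <- function(pattern, subject) {
  if (!nzchar(pattern) || nchar(pattern) > nchar(subject)) return(integer(0))
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1L))
}

## --- FASTA / FASTQ via Biostrings ------------------------------------------

#' Read and write multi-record FASTA
#'
#' Thin wrappers over Biostrings keeping the package's plain-character
#' sequence convention: named character vectors in, named character out.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(setNames(as.character(seqs), names(seqs)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ records
#'
#' Reads are handled as a data frame with `id`, `seq` and `qual` columns;
#' qualities are carried verbatim (the simulator emits uniform qualities and
#' the quantifier ignores them).
#'
#' @param path file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ", call. = FALSE)
  idx <- seq(1L, length(lines), by = 4L)
  data.frame(id = sub("^@", "", lines[idx]),
             seq = toupper(lines[idx + 1L]),
             qual = lines[idx + 3L],
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame as returned by `read_fastq`.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

## --- minimal GenBank flat file ---------------------------------------------

#' Read and write a minimal GenBank flat file
#'
#' Supports a single record with LOCUS (name, length, topology), a FEATURES
#' table of simple `start..end` / `complement(start..end)` locations with
#' `/label` qualifiers, and the ORIGIN sequence block. This covers annotated
#' backbones and final constructs (features: promoter, terminator, repeat,
#' spacer, junction, protein_bind for Type IIS sites). Coordinates in the
#' file are 1-based inclusive (GenBank convention) and converted to the
#' package's 0-based half-open [interval()]s.
#'
#' @param path file path.
#' @return `read_genbank`: list with `name`, `sequence` ([nucseq()]), and
#'   `features` (data.frame: type, start, end, strand, label).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)[1L]
  if (is.na(locus)) stop("not a GenBank file: no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1L]]
  name <- toks[2L]
  topology <- if (any(toks == "circular")) "circular" else "linear"
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("GenBank file lacks ORIGIN block", call. = FALSE)
  seq_lines <- lines[(ostart[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- data.frame(type = character(), start = integer(), end = integer(),
                      strand = character(), label = character(),
                      stringsAsFactors = FALSE)
  if (length(fstart)) {
    body <- lines[(fstart[1L] + 1L):(ostart[1L] - 1L)]
    key_idx <- grep("^ {5}\\S", body)
    for (k in seq_along(key_idx)) {
      ln <- body[key_idx[k]]
      type <- sub("^ {5}(\\S+).*", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+", "", ln))
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1L]]
      if (length(m) != 3L) next
      upto <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(body)
      quals <- body[seq(key_idx[k] + 1L, length.out = max(0L, upto - key_idx[k]))]
      lab <- grep("/label=", quals, value = TRUE)
      lab <- if (length(lab)) {
        sub('^.*/label="?([^"]*)"?.*$', "\\1", lab[1L])
      } else ""
      feats <- rbind(feats, data.frame(
        type = type, start = as.integer(m[2L]) - 1L, end = as.integer(m[3L]),
        strand = strand, label = lab, stringsAsFactors = FALSE))
    }
  }
  list(name = name,
       sequence = nucseq(seq, "DNA", topology),
       features = feats)
}

#' @rdname read_genbank
#' @param record list with `name`, `sequence`, `features` (as from
#'   `read_genbank`).
#' @export
write_genbank <- function(record, path) {
  seq <- as.character(record$sequence)
  topo <- attr(record$sequence, "topology")
  if (is.null(topo)) topo <- "linear"
  lines <- sprintf("LOCUS       %s %d bp    DNA     %s     SYN",
                   record$name, nchar(seq), topo)
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  feats <- record$features
  if (!is.null(feats) && nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      loc <- sprintf("%d..%d", feats$start[i] + 1L, feats$end[i])
      if (feats$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      lines <- c(lines,
                 sprintf("     %-16s%s", feats$type[i], loc),
                 sprintf("                     /label=\"%s\"", feats$label[i]))
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, nchar(seq), by = 60L)
  for (p in pos) {
    chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
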
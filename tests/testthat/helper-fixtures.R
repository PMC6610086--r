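# shared fixture builders; everything is generated in code, nothing on disk

fn_profile <- function() builtin_profile("FnCas12a")
sp9_profile <- function() builtin_profile("SpCas9")

fn_backbone <- function(...) make_backbone(fn_profile(), ...)

# a standard 3-spacer design on the clean trio with fixed junctions
clean_design <- function(order = 1:3, backbone = fn_backbone()) {
  plan_array(clean_trio()[order], fn_profile(), backbone,
             junctions = fixture_junction_set())
}

fixture_junction_set <- function() c("CCCT", "CCAA", "GGTA", "GCTG")

# random sequences under local seed without disturbing global RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

ham <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# exhaustive enumeration of all nested structures (independent oracle for
# the folding module); returns list of pair lists (1-based)
enum_structures <- function(seq, min_loop = 3L) {
  b <- strsplit(chartr("T", "U", toupper(seq)), "")[[1L]]
  canp <- function(a, bb) {
    paste0(b[a], b[bb]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    out <- list()
    for (st in rec(i + 1L, j)) out[[length(out) + 1L]] <- st
    for (k in seq_len(j)) {
      if (k <= i + min_loop) next
      if (!canp(i, k)) next
      for (L in rec(i + 1L, k - 1L)) {
        for (R in rec(k + 1L, j)) {
          out[[length(out) + 1L]] <- c(list(c(i, k)), L, R)
        }
      }
    }
    out
  }
  rec(1L, length(b))
}
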
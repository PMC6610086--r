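## Type IIS digestion and cyclic-ligation simulation.
##
## A Fragment is a double-stranded piece represented by its top strand plus
## typed single-stranded ends. For a 5' overhang the protruding strand at the
## left end is the top strand (the overhang region is part of `top`), and at
## the right end the bottom strand (not part of `top`); concatenating the top
## strands of consecutive fragments therefore reconstructs the parent
## sequence exactly.

# cut positions for every recognition site on both strands; each row is the
# (top, bottom) strand cut coordinate pair, overhang = s[top, bottom)
digest_cuts <- function(s, enzyme, circular) {
  s <- as.character(s)
  L <- nchar(s)
  rec <- enzyme$recognition
  k <- nchar(rec)
  subject <- if (circular) paste0(s, substr(s, 1L, k + enzyme$bottom_cut_offset)) else s
  fwd <- find_fixed(rec, subject)
  rev <- find_fixed(revcomp(rec), subject)
  fwd <- fwd[fwd < L]; rev <- rev[rev < L]
  cuts <- list()
  for (p in fwd) {
    cuts[[length(cuts) + 1L]] <- c(top = p + k + enzyme$top_cut_offset,
                                   bottom = p + k + enzyme$bottom_cut_offset,
                                   site = p, strand = 1L)
  }
  for (p in rev) {
    cuts[[length(cuts) + 1L]] <- c(top = p - enzyme$bottom_cut_offset,
                                   bottom = p - enzyme$top_cut_offset,
                                   site = p, strand = -1L)
  }
  if (!length(cuts)) {
    return(data.frame(top = integer(), bottom = integer(), site = integer(),
                      strand = integer()))
  }
  df <- as.data.frame(do.call(rbind, cuts))
  if (circular) {
    df$top <- df$top %% L
    df$bottom <- ((df$bottom - df$top) %% L + df$top)  # keep bottom >= top
  } else {
    bad <- df$top < 0L | df$bottom > L
    if (any(bad)) {
      stop(sprintf("cut position outside linear sequence for site at %d",
                   df$site[which(bad)[1L]]), call. = FALSE)
    }
  }
  df[order(df$top), , drop = FALSE]
}

new_fragment <- function(top, left_end, right_end, provenance = NULL,
                         id = NA_integer_, label = "") {
  structure(list(top = top, left_end = left_end, right_end = right_end,
                 provenance = provenance, id = id, label = label),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  fmt_end <- function(e) if (is.null(e)) "blunt" else
    sprintf("%s(%s)", e$seq, if (e$polarity == "five_prime") "5'" else "3'")
  cat(sprintf("<fragment %s %d nt, ends %s | %s>\n",
              if (nzchar(x$label)) x$label else x$id, nchar(x$top),
              fmt_end(x$left_end), fmt_end(x$right_end)))
  invisible(x)
}

#' Digest a sequence with a Type IIS enzyme
#'
#' Locates every recognition site on both strands, applies the enzyme's
#' offset cut geometry, and returns fragments with typed overhang ends.
#' A circular input with k sites yields k fragments; an input without sites
#' is returned unchanged as one blunt/uncut fragment. A cut falling outside
#' a linear sequence is an error naming the offending site.
#'
#' @param seq character or [nucseq()]; circular topology honored.
#' @param enzyme [enzyme_def()].
#' @return list of `fragment` objects, in sequence order.
#' @export
digest <- function(seq, enzyme) {
  s <- as.character(seq)
  circular <- identical(attr(seq, "topology"), "circular")
  L <- nchar(s)
  cuts <- digest_cuts(seq, enzyme, circular)
  if (!nrow(cuts)) {
    return(list(new_fragment(s, NULL, NULL, interval(0L, L), 1L,
                             label = "uncut")))
  }
  k <- nrow(cuts)
  frags <- list()
  ov <- function(i) {  # overhang at cut i (5' overhang assumed)
    oseq <- substr(paste0(s, s), cuts$top[i] + 1L, cuts$bottom[i])
    overhang(oseq, enzyme$overhang_polarity)
  }
  if (circular) {
    for (i in seq_len(k)) {
      j <- if (i < k) i + 1L else 1L
      from <- cuts$top[i]
      to <- if (i < k) cuts$top[j] else cuts$top[j] + L
      top <- substr(paste0(s, s), from + 1L, to)
      frags[[i]] <- new_fragment(
        top,
        left_end = ov(i),
        right_end = overhang(revcomp(substr(paste0(s, s), cuts$top[j] + 1L,
                                            cuts$bottom[j])),
                             enzyme$overhang_polarity),
        provenance = interval(from, to), id = i)
    }
  } else {
    bounds_top <- c(0L, cuts$top, L)
    for (i in seq_len(k + 1L)) {
      from <- bounds_top[i]; to <- bounds_top[i + 1L]
      left <- if (i == 1L) NULL else ov(i - 1L)
      right <- if (i == k + 1L) NULL else
        overhang(revcomp(substr(s, cuts$top[i] + 1L, cuts$bottom[i])),
                 enzyme$overhang_polarity)
      frags[[i]] <- new_fragment(substr(s, from + 1L, to), left, right,
                                 interval(from, to), i)
    }
  }
  frags
}

#' Convert a repeat-spacer unit (annealed oligo duplex) to a fragment
#'
#' @param unit `repeat_spacer_unit`.
#' @param id fragment id.
#' @return `fragment`.
#' @export
unit_fragment <- function(unit, id = NA_integer_) {
  op <- make_oligos(unit)
  new_fragment(unit_top(unit), op$left_end, op$right_end, NULL, id,
               label = sprintf("unit%d", unit$position_index))
}

ends_compatible <- function(a, b) {
  if (is.null(a$right_end) || is.null(b$left_end)) return(FALSE)  # blunt never ligates
  ligation_compatible(a$right_end, b$left_end)
}

#' Enumerate circular ligation products
#'
#' Builds the end-compatibility graph over the fragment pool and enumerates
#' every circular product of at most `max_inserts` fragments. Each physical
#' fragment is used at most once per product unless `allow_repeat_use`.
#' Products are canonicalized by rotation and returned in deterministic
#' lexicographic path order. Blunt ends never ligate. If more than
#' `max_products` products arise, enumeration stops and the result carries a
#' `truncated` attribute (never silent).
#'
#' @param fragments list of `fragment`s (ids are assigned by position).
#' @param max_inserts maximum fragments per circular product.
#' @param allow_repeat_use allow a fragment to appear multiple times.
#' @param max_products combinatorial cap (default 10000).
#' @return list of `assembly_product` objects; attribute `truncated` is TRUE
#'   when the cap was hit.
#' @export
enumerate_assemblies <- function(fragments, max_inserts = length(fragments),
                                 allow_repeat_use = FALSE,
                                 max_products = 10000L) {
  n <- length(fragments)
  for (i in seq_len(n)) fragments[[i]]$id <- i
  compat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      compat[i, j] <- ends_compatible(fragments[[i]], fragments[[j]])
    }
  }
  seen <- new.env(parent = emptyenv())
  products <- list()
  truncated <- FALSE
  emit <- function(path) {
    rots <- vapply(seq_along(path), function(r) {
      paste(c(path[r:length(path)], path[seq_len(r - 1L)]), collapse = ",")
    }, character(1L))
    key <- min(rots)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    canon <- as.integer(strsplit(key, ",", fixed = TRUE)[[1L]])
    seqstr <- paste(vapply(canon, function(i) fragments[[i]]$top,
                           character(1L)), collapse = "")
    products[[length(products) + 1L]] <<- list(path = canon, sequence = seqstr)
  }
  dfs <- function(path, used) {
    if (truncated) return(invisible(NULL))
    last <- path[length(path)]
    if (length(path) >= 1L && compat[last, path[1L]]) {
      if (length(products) >= max_products) { truncated <<- TRUE; return(invisible(NULL)) }
      emit(path)
    }
    if (length(path) >= max_inserts) return(invisible(NULL))
    for (nxt in seq_len(n)) {
      if (!compat[last, nxt]) next
      if (!allow_repeat_use && used[nxt]) next
      if (nxt == path[1L]) next  # closure handled above
      used2 <- used; used2[nxt] <- TRUE
      dfs(c(path, nxt), used2)
    }
  }
  for (start in seq_len(n)) {
    used <- logical(n); used[start] <- TRUE
    dfs(start, used)
  }
  ord <- order(vapply(products, function(p) paste(sprintf("%06d", p$path),
                                                  collapse = ","),
                      character(1L)))
  products <- products[ord]
  out <- lapply(products, function(p) {
    structure(list(topology = "circular", path = p$path,
                   sequence = nucseq(p$sequence, "DNA", "circular"),
                   redigestible = NA),
              class = "assembly_product")
  })
  attr(out, "truncated") <- truncated
  out
}

#' @export
print.assembly_product <- function(x, ...) {
  cat(sprintf("<assembly_product circular, %d fragments, %d bp%s>\n",
              length(x$path), nchar(x$sequence),
              if (isTRUE(x$redigestible)) ", re-digestible" else ""))
  invisible(x)
}

circular_equal <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  nchar(a) == nchar(b) && (a == b || length(find_fixed(b, paste0(a, a))) > 0L)
}

#' Simulate a one-pot Golden-Gate assembly reaction
#'
#' Digestion/ligation cycling is modeled by its fixed point: any circular
#' ligation product that still contains a recognition site is re-digested and
#' recycled, so only site-free products survive. The report lists survivors,
#' whether the intended design is the unique survivor, and whether the
#' dropout cassette is absent from all survivors. An intended product that is
#' itself re-digestible is a design error and is reported with the site
#' coordinates.
#'
#' @param design an `array_design` (supplies backbone, units and the intended
#'   construct), or `NULL` if `backbone`/`units` are given explicitly.
#' @param backbone,units used when `design` is `NULL`.
#' @param enzyme defaults to the backbone's enzyme.
#' @param max_inserts cap on fragments per product (default: number of pool
#'   fragments).
#' @param max_products combinatorial cap.
#' @return object of class `assembly_report`.
#' @export
simulate_golden_gate <- function(design = NULL, backbone = NULL, units = NULL,
                                 enzyme = NULL, max_inserts = NULL,
                                 max_products = 10000L) {
  if (!is.null(design)) {
    backbone <- design$backbone
    units <- design$units
  }
  if (is.null(enzyme)) enzyme <- backbone$enzyme
  bb_frags <- digest(backbone$sequence, enzyme)
  pool <- c(bb_frags, lapply(seq_along(units), function(i)
    unit_fragment(units[[i]])))
  if (is.null(max_inserts)) max_inserts <- length(pool)
  products <- enumerate_assemblies(pool, max_inserts = max_inserts,
                                   max_products = max_products)
  for (i in seq_along(products)) {
    products[[i]]$redigestible <- has_enzyme_site(products[[i]]$sequence,
                                                  enzyme, circular = TRUE)
  }
  survivors <- Filter(function(p) !p$redigestible, products)
  intended_ok <- NA
  intended_redigestible <- NA
  if (!is.null(design)) {
    intended <- design$predicted_construct
    intended_redigestible <- has_enzyme_site(intended, enzyme, circular = TRUE)
    if (intended_redigestible) {
      pos <- find_fixed(enzyme$recognition,
                        paste0(as.character(intended), as.character(intended)))
      stop("intended product is itself re-digestible (recognition site near ",
           "position ", pos[1L], ")", call. = FALSE)
    }
    intended_ok <- length(survivors) == 1L &&
      circular_equal(survivors[[1L]]$sequence, intended)
  }
  dropout_seq <- extract_region(backbone$sequence, backbone$dropout)
  dropout_absent <- !any(vapply(survivors, function(p) {
    s2 <- paste0(as.character(p$sequence), as.character(p$sequence))
    length(find_fixed(dropout_seq, s2)) > 0L
  }, logical(1L)))
  structure(list(
    n_products = length(products), survivors = survivors,
    n_survivors = length(survivors),
    intended_is_unique_survivor = intended_ok,
    dropout_absent = dropout_absent,
    truncated = isTRUE(attr(products, "truncated")),
    enzyme = enzyme$name),
    class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("Golden-Gate simulation (%s): %d circular product(s), %d survivor(s)\n",
              x$enzyme, x$n_products, x$n_survivors))
  if (!is.na(x$intended_is_unique_survivor)) {
    cat("  intended design unique survivor:", x$intended_is_unique_survivor, "\n")
  }
  cat("  dropout absent from survivors:", x$dropout_absent, "\n")
  if (x$truncated) cat("  WARNING: product enumeration truncated at cap\n")
  invisible(x)
}
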
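# Tag library construction and read scanning.
#
# Each V/D/J element is identified by 20-base sequence tags positioned
# 15 bp from its predicted RSS cleavage site, with separate tags on the
# coding and signal flanks of each RSS. Where two elements share a tag
# region, the shared tag is a non-unique "rtag" and a secondary
# discriminating "alt-tag" taken at the nearest point of divergence is used
# to tell the sharing elements apart. Tag matching is exact; allelic
# variation is handled by alternative tag versions, not fuzzy matching.

# reference coordinates of the primary tag for one segment/flank, plus the
# direction (+1/-1) pointing *away* from the RSS (where alt-tags can live)
tag_coords <- function(seg, flank) {
  r <- seg$rss_position
  if (seg$segment_class == "V") {
    if (flank == "coding") list(start = r - 34L, away = -1L)
    else list(start = r + 16L, away = +1L)
  } else if (seg$segment_class == "J") {
    if (flank == "coding") list(start = r + 16L, away = +1L)
    else list(start = r - 34L, away = -1L)
  } else {  # D: signal flanks only
    if (flank == "signal5") list(start = r - 34L, away = -1L)
    else list(start = r + D_CORE_LEN + 16L, away = +1L)
  }
}

#' Derive a 20-base tag library from a germline reference
#'
#' Emits one coding-flank and one signal-flank tag per V and J element and
#' the two signal-flank tags per D element, each positioned 15 bp from the
#' predicted RSS cleavage site. Tags shared verbatim by several elements
#' are marked as rtags, and for each sharing element an alt-tag is sought
#' at the nearest shift (away from the RSS) at which the sharing elements'
#' sequences diverge pairwise; elements for which no discriminating alt-tag
#' exists within the reference keep `NA` and scan as ambiguous.
#'
#' @param segments a [make_germline_reference()] tibble (any mix of loci).
#' @return tibble of class `tag_library` with columns `tag`, `element`,
#'   `class`, `locus`, `flank`, `offset_from_rss` (always 15), `tag_start`
#'   (reference coordinate), `is_rtag`, `alt_tag`, `alt_offset` (shift of
#'   the alt-tag start relative to the primary tag start), and list-column
#'   `variants` (allelic tag versions, empty by default).
#' @export
derive_tag_library <- function(segments) {
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- as.list(segments[i, ])
    flanks <- if (seg$segment_class == "D") c("signal5", "signal3")
              else c("coding", "signal")
    for (fl in flanks) {
      tc <- tag_coords(seg, fl)
      tag <- substr(seg$sequence, tc$start, tc$start + TAG_LEN - 1L)
      if (nchar(tag) < TAG_LEN) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tag = tag, element = seg$name, class = seg$segment_class,
        locus = seg$locus,
        flank = if (fl %in% c("signal5", "signal3")) "signal" else fl,
        offset_from_rss = TAG_RSS_OFFSET, tag_start = tc$start,
        away = tc$away)
    }
  }
  lib <- dplyr::bind_rows(rows)
  lib$is_rtag <- duplicated(lib$tag) | duplicated(lib$tag, fromLast = TRUE)
  lib$alt_tag <- NA_character_
  lib$alt_offset <- NA_integer_
  # nearest-divergence alt-tags for rtag groups
  for (tg in unique(lib$tag[lib$is_rtag])) {
    idx <- which(lib$tag == tg)
    seqs <- vapply(idx, function(k)
      get_segment(segments, lib$element[k])$sequence, character(1))
    for (s in seq_len(200L)) {
      cands <- vapply(seq_along(idx), function(k) {
        st <- lib$tag_start[idx[k]] + lib$away[idx[k]] * s
        if (st < 1L || st + TAG_LEN - 1L > nchar(seqs[k])) NA_character_
        else substr(seqs[k], st, st + TAG_LEN - 1L)
      }, character(1))
      if (anyNA(cands)) break
      if (!anyDuplicated(cands)) {
        lib$alt_tag[idx] <- cands
        lib$alt_offset[idx] <- lib$away[idx] * s
        break
      }
    }
  }
  lib$away <- NULL
  lib$variants <- replicate(nrow(lib), character(0), simplify = FALSE)
  structure(lib, class = c("tag_library", class(lib)))
}

#' Add an allelic variant tag for one element
#'
#' @param lib a [derive_tag_library()] tibble.
#' @param element,flank row selector.
#' @param variant alternative 20-mer recognised as the same element.
#' @return the updated library.
#' @export
add_tag_variant <- function(lib, element, flank, variant) {
  if (nchar(variant) != TAG_LEN) stop("variant tags must be 20 bases")
  i <- which(lib$element == element & lib$flank == flank)
  if (length(i) != 1L) stop("element/flank does not select one tag")
  lib$variants[[i]] <- c(lib$variants[[i]], variant)
  lib
}

# exact occurrences of pattern in each sequence of a DNAStringSet
match_starts <- function(pattern, subject_set) {
  m <- Biostrings::vmatchPattern(pattern, subject_set)
  starts <- Biostrings::startIndex(m)
  hits <- which(lengths(starts) > 0)
  if (length(hits) == 0L)
    return(tibble::tibble(read = integer(0), start = integer(0)))
  tibble::tibble(read = rep(hits, lengths(starts)[hits]),
                 start = unlist(starts[hits]))
}

#' Scan single-end reads for element tags
#'
#' Exact-match search for every tag (and allelic variant) on both strands.
#' rtag hits are resolved by testing each sharing element's alt-tag at its
#' expected offset in the read; a hit resolved by exactly one alt-tag is
#' assigned to that element (`via_rtag = TRUE`), otherwise it is reported
#' with `ambiguous = TRUE` and no element. Reads shorter than 20 bases
#' yield no hits.
#'
#' @param seqs character vector of read sequences (plus-strand as stored).
#' @param lib a [derive_tag_library()] tibble.
#' @return tibble of hits: `read` (index into `seqs`), `element`, `class`,
#'   `locus`, `flank`, `strand` (`"+"`/`"-"`), `start`, `end` (coordinates
#'   in the scanned orientation), `via_rtag`, `ambiguous`.
#' @export
scan_tags <- function(seqs, lib) {
  out <- list()
  oriented <- list("+" = Biostrings::DNAStringSet(seqs),
                   "-" = Biostrings::reverseComplement(
                     Biostrings::DNAStringSet(seqs)))
  or_chr <- list("+" = seqs, "-" = as.character(oriented[["-"]]))
  for (strand in c("+", "-")) {
    subj <- oriented[[strand]]
    for (tg in unique(lib$tag)) {
      hits <- match_starts(tg, subj)
      if (nrow(hits) == 0L) next
      idx <- which(lib$tag == tg)
      for (h in seq_len(nrow(hits))) {
        rd <- hits$read[h]; st <- hits$start[h]
        if (length(idx) == 1L) {
          k <- idx
          out[[length(out) + 1L]] <- tibble::tibble(
            read = rd, element = lib$element[k], class = lib$class[k],
            locus = lib$locus[k], flank = lib$flank[k], strand = strand,
            start = st, end = st + TAG_LEN - 1L,
            via_rtag = FALSE, ambiguous = FALSE)
        } else {
          ok <- vapply(idx, function(k) {
            if (is.na(lib$alt_tag[k])) return(FALSE)
            as <- st + lib$alt_offset[k]
            as >= 1L &&
              substr(or_chr[[strand]][rd], as, as + TAG_LEN - 1L) ==
                lib$alt_tag[k]
          }, logical(1))
          if (sum(ok) == 1L) {
            k <- idx[ok]
            out[[length(out) + 1L]] <- tibble::tibble(
              read = rd, element = lib$element[k], class = lib$class[k],
              locus = lib$locus[k], flank = lib$flank[k], strand = strand,
              start = st, end = st + TAG_LEN - 1L,
              via_rtag = TRUE, ambiguous = FALSE)
          } else {
            k <- idx[1]
            out[[length(out) + 1L]] <- tibble::tibble(
              read = rd, element = NA_character_, class = lib$class[k],
              locus = lib$locus[k], flank = lib$flank[k], strand = strand,
              start = st, end = st + TAG_LEN - 1L,
              via_rtag = TRUE, ambiguous = TRUE)
          }
        }
      }
    }
    # allelic variants map to their parent element
    vidx <- which(lengths(lib$variants) > 0)
    for (k in vidx) {
      for (vt in lib$variants[[k]]) {
        hits <- match_starts(vt, subj)
        for (h in seq_len(nrow(hits))) {
          out[[length(out) + 1L]] <- tibble::tibble(
            read = hits$read[h], element = lib$element[k],
            class = lib$class[k], locus = lib$locus[k],
            flank = lib$flank[k], strand = strand,
            start = hits$start[h], end = hits$start[h] + TAG_LEN - 1L,
            via_rtag = FALSE, ambiguous = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(read = integer(0), element = character(0),
                          class = character(0), locus = character(0),
                          flank = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          via_rtag = logical(0), ambiguous = logical(0)))
  dplyr::bind_rows(out)
}
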
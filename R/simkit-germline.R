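# Synthetic germline references for the three analysed TCR loci.
#
# Segments are toy stand-ins for real V/D/J gene segments, sized so a
# 250 bp read covers a full recombined junction: V segments carry a 100 bp
# coding region followed by a 40 bp recombination-signal (RSS) flank, J
# segments the mirror image, and D segments a 12 bp core between two 40 bp
# signal flanks. The RSS cleavage point is recorded per segment, as are the
# reading-frame annotations the productivity rule needs. Sequences are
# random but constructed so every segment is identifiable by a unique
# 20-mer tag positioned 15 bp from its RSS, and so germline coding regions
# carry no in-frame stop codons (as real gene segments do not).

V_CODING_LEN <- 100L
J_CODING_LEN <- 100L
SIGNAL_FLANK_LEN <- 40L
D_CORE_LEN <- 12L
TAG_LEN <- 20L
TAG_RSS_OFFSET <- 15L

stop_codons <- c("TAA", "TAG", "TGA")

# replace in-frame stop codons in chars; ph = phase of chars[1]
# (0 = codon start)
repair_stops <- function(chars, ph = 0L) {
  starts <- which((ph + seq_along(chars) - 1L) %% 3L == 0L)
  starts <- starts[starts + 2L <= length(chars)]
  for (s in starts) {
    codon <- paste(chars[s:(s + 2L)], collapse = "")
    if (codon %in% stop_codons) chars[s + 1L] <- "C"
  }
  chars
}

locus_for_chain <- function(chain) {
  switch(chain, alpha = "TRA", beta = "TRB", gamma = "TRG", delta = "TRD",
         stop("unknown chain: ", chain))
}

make_v_segment <- function(name, locus) {
  chars <- sample(dna_alphabet, V_CODING_LEN + SIGNAL_FLANK_LEN, replace = TRUE)
  chars[seq_len(V_CODING_LEN)] <- repair_stops(chars[seq_len(V_CODING_LEN)], 0L)
  list(name = name, locus = locus, segment_class = "V",
       sequence = paste(chars, collapse = ""),
       rss_position = V_CODING_LEN,
       coding_frame = V_CODING_LEN %% 3L)
}

make_j_segment <- function(name, locus) {
  frame <- sample(0:2, 1L)
  chars <- sample(dna_alphabet, SIGNAL_FLANK_LEN + J_CODING_LEN, replace = TRUE)
  idx <- (SIGNAL_FLANK_LEN + 1L):(SIGNAL_FLANK_LEN + J_CODING_LEN)
  chars[idx] <- repair_stops(chars[idx], frame)
  list(name = name, locus = locus, segment_class = "J",
       sequence = paste(chars, collapse = ""),
       rss_position = SIGNAL_FLANK_LEN,
       coding_frame = frame)
}

make_d_segment <- function(name, locus) {
  len <- SIGNAL_FLANK_LEN + D_CORE_LEN + SIGNAL_FLANK_LEN
  list(name = name, locus = locus, segment_class = "D",
       sequence = random_dna(len),
       rss_position = SIGNAL_FLANK_LEN,
       coding_frame = NA_integer_)
}

segment_tibble <- function(seglist) {
  tibble::tibble(
    name = vapply(seglist, `[[`, character(1), "name"),
    locus = vapply(seglist, `[[`, character(1), "locus"),
    segment_class = vapply(seglist, `[[`, character(1), "segment_class"),
    sequence = vapply(seglist, `[[`, character(1), "sequence"),
    rss_position = vapply(seglist, function(s) as.integer(s$rss_position),
                          integer(1)),
    coding_frame = vapply(seglist, function(s) as.integer(s$coding_frame),
                          integer(1)))
}

# the primary 20-mer tag regions of one segment (both flanks)
segment_tag_regions <- function(seg) {
  r <- seg$rss_position
  len <- nchar(seg$sequence)
  tags <- character(0)
  if (seg$segment_class == "V") {
    tags <- c(substr(seg$sequence, r - 34L, r - 15L),
              substr(seg$sequence, r + 16L, r + 35L))
  } else if (seg$segment_class == "J") {
    tags <- c(substr(seg$sequence, r + 16L, r + 35L),
              substr(seg$sequence, r - 34L, r - 15L))
  } else {
    core_end <- r + D_CORE_LEN
    tags <- c(substr(seg$sequence, r - 34L, r - 15L),
              substr(seg$sequence, core_end + 16L, core_end + 35L),
              substr(seg$sequence, r + 1L, r + D_CORE_LEN))  # core id region
  }
  tags[nchar(tags) > 0]
}

#' Generate a synthetic germline reference for one TCR locus
#'
#' Builds `n_v` V, `n_d` D and `n_j` J segments for the requested locus,
#' each with an annotated RSS cleavage position and (for V and J) a coding
#' frame. D segments are only permitted at the beta locus (the alpha and
#' gamma loci carry no D class here, and delta is excluded from analysis
#' altogether). Sequences are redrawn until every segment's tag regions are
#' unique across the reference, so a tag library derived from it is
#' unambiguous. Deterministic under `seed`.
#'
#' @param n_v,n_d,n_j segment counts; `n_v >= 1`, `n_j >= 1`; `n_d` must be
#'   0 except for locus `"TRB"` where it must be `>= 1`.
#' @param locus one of `"TRA"`, `"TRB"`, `"TRG"`.
#' @param seed integer seed.
#' @return tibble of segments (class `germline_reference`) with columns
#'   `name`, `locus`, `segment_class`, `sequence`, `rss_position`,
#'   `coding_frame`.
#' @export
make_germline_reference <- function(n_v = 8L, n_d = NULL, n_j = 4L,
                                    locus = c("TRB", "TRA", "TRG"),
                                    seed = 1L) {
  locus <- match.arg(locus)
  if (is.null(n_d)) n_d <- if (locus == "TRB") 2L else 0L
  if (n_v < 1L || n_j < 1L)
    stop("invalid reference: need at least one V and one J segment")
  if (locus %in% c("TRA", "TRG") && n_d > 0L)
    stop("invalid reference: ", locus, " carries no D segments")
  if (locus == "TRB" && n_d < 1L)
    stop("invalid reference: TRB requires at least one D segment")
  with_seed(seed, {
    segs <- c(
      lapply(seq_len(n_v), function(i)
        make_v_segment(sprintf("%sV%d", locus, i), locus)),
      if (n_d > 0L) lapply(seq_len(n_d), function(i)
        make_d_segment(sprintf("%sD%d", locus, i), locus)),
      lapply(seq_len(n_j), function(i)
        make_j_segment(sprintf("%sJ%d", locus, i), locus)))
    # redraw any segment whose tag regions collide with another's
    for (attempt in seq_len(100L)) {
      regions <- lapply(segs, segment_tag_regions)
      all_tags <- unlist(regions)
      dup <- duplicated(all_tags) | duplicated(all_tags, fromLast = TRUE)
      if (!any(dup)) break
      owner <- rep(seq_along(segs), lengths(regions))
      bad <- unique(owner[dup])[-1]  # keep the first owner, redraw the rest
      if (length(bad) == 0L) bad <- unique(owner[dup])
      for (b in bad) {
        s <- segs[[b]]
        segs[[b]] <- switch(s$segment_class,
                            V = make_v_segment(s$name, s$locus),
                            D = make_d_segment(s$name, s$locus),
                            J = make_j_segment(s$name, s$locus))
      }
    }
    out <- segment_tibble(segs)
    class(out) <- c("germline_reference", class(out))
    out
  })
}

# fetch one segment as a plain list
get_segment <- function(segments, name) {
  i <- match(name, segments$name)
  if (is.na(i)) stop("unknown segment: ", name)
  as.list(segments[i, ])
}
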
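# Simulation of single V(D)J recombination events.
#
# A coding joint is assembled as: V coding region with 0..trim_max bases
# exonuclease-trimmed from its RSS end, random non-templated (N)
# insertions, for the beta chain the (untrimmed) D core plus a second N
# stretch, then the J coding region with its RSS end trimmed. The truth
# junction is then *canonicalised* by the same divergence walk the caller
# applies: the V boundary is extended while the assembled sequence
# continues to match germline (never past the predicted cleavage point),
# and likewise for J. Clonotype identity is therefore a function of the
# assembled sequence, as with any alignment-based caller, and an error-free
# read round-trip recovers truth exactly.

# maximal canonical boundaries of a junction inside an assembled molecule.
# v_used0 = generative V prefix length, j_first0 = assembled index of the
# first generative J base, j_trim0 = generative J trim.
canonical_boundaries <- function(assembled, v, j, v_used0, j_first0, j_trim0) {
  v_rss <- v$rss_position
  k <- v_used0
  while (k < v_rss && k + 1L <= nchar(assembled) &&
         substr(assembled, k + 1L, k + 1L) == substr(v$sequence, k + 1L, k + 1L))
    k <- k + 1L
  j_cod_start <- j$rss_position
  s <- j_trim0
  first <- j_first0
  while (s > 0L && first - 1L > k &&
         substr(assembled, first - 1L, first - 1L) ==
         substr(j$sequence, j_cod_start + s, j_cod_start + s)) {
    s <- s - 1L
    first <- first - 1L
  }
  list(v_used = k, j_first = first, j_trim = s)
}

#' Simulate one V(D)J recombination event
#'
#' Draws segments uniformly for the requested chain, applies random
#' exonuclease trimming and N insertion, assembles the coding joint, and
#' records the truth: segment names, the canonical CDR3 (the nucleotides
#' between the predicted/diverged RSS cleavage boundaries -- empty when
#' trimming plus insertion leave nothing between them), and the
#' productivity flag computed with the same open-reading-frame rule the
#' caller uses ([assess_productivity()]).
#'
#' @param segments a [make_germline_reference()] tibble (one or more loci).
#' @param chain `"alpha"`, `"beta"` or `"gamma"`.
#' @param seed integer seed (`NULL` = current stream).
#' @param trim_max maximum bases trimmed from each of the V and J RSS ends
#'   (kept below the 15 bp tag-to-RSS gap so tags survive).
#' @param ins_max maximum non-templated bases per N stretch.
#' @return list with `sequence` (assembled coding joint), `v_name`,
#'   `d_name` (`NA` outside beta), `j_name`, `cdr3_nt`, `productive`,
#'   `v_used`, `j_trim`.
#' @export
simulate_recombination <- function(segments, chain = "beta", seed = NULL,
                                   trim_max = 6L, ins_max = 9L) {
  locus <- locus_for_chain(chain)
  vs <- segments[segments$locus == locus & segments$segment_class == "V", ]
  js <- segments[segments$locus == locus & segments$segment_class == "J", ]
  ds <- segments[segments$locus == locus & segments$segment_class == "D", ]
  if (nrow(vs) == 0L || nrow(js) == 0L)
    stop("invalid reference: no V or J segments for chain ", chain)
  if (chain == "beta" && nrow(ds) == 0L)
    stop("invalid reference: beta chain requires D segments")
  with_seed(seed, {
    v <- as.list(vs[sample.int(nrow(vs), 1L), ])
    j <- as.list(js[sample.int(nrow(js), 1L), ])
    d <- if (chain == "beta") as.list(ds[sample.int(nrow(ds), 1L), ]) else NULL
    t_v <- sample(0:trim_max, 1L)
    t_j <- sample(0:trim_max, 1L)
    n1 <- if (ins_max > 0L) sample(0:ins_max, 1L) else 0L
    ins1 <- if (n1 > 0L) random_dna(n1) else ""
    mid <- ins1
    if (!is.null(d)) {
      core <- substr(d$sequence, d$rss_position + 1L,
                     d$rss_position + D_CORE_LEN)
      n2 <- if (ins_max > 0L) sample(0:ins_max, 1L) else 0L
      ins2 <- if (n2 > 0L) random_dna(n2) else ""
      mid <- paste0(ins1, core, ins2)
    }
    v_part <- substr(v$sequence, 1L, v$rss_position - t_v)
    j_part <- substr(j$sequence, j$rss_position + 1L + t_j, nchar(j$sequence))
    assembled <- paste0(v_part, mid, j_part)
    cb <- canonical_boundaries(assembled, v, j,
                               v_used0 = nchar(v_part),
                               j_first0 = nchar(v_part) + nchar(mid) + 1L,
                               j_trim0 = t_j)
    cdr3 <- if (cb$j_first - 1L >= cb$v_used + 1L)
      substr(assembled, cb$v_used + 1L, cb$j_first - 1L) else ""
    d_name <- NA_character_
    if (!is.null(d) && nrow(ds) > 0L) {
      hits <- vapply(seq_len(nrow(ds)), function(k) {
        core_k <- substr(ds$sequence[k], ds$rss_position[k] + 1L,
                         ds$rss_position[k] + D_CORE_LEN)
        grepl(core_k, cdr3, fixed = TRUE)
      }, logical(1))
      if (sum(hits) == 1L) d_name <- ds$name[hits]
    }
    pr <- assess_productivity(v, cdr3, j, v_used = cb$v_used,
                              j_trim = cb$j_trim)
    list(sequence = assembled, v_name = v$name, d_name = d_name,
         j_name = j$name, cdr3_nt = cdr3, productive = pr$productive,
         v_used = cb$v_used, j_trim = cb$j_trim)
  })
}
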
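# CDR3 extraction, productivity assessment, degenerate-UMI deduplication
# and repertoire construction.

#' Open-reading-frame productivity of a V-CDR3-J cassette
#'
#' The cassette is productive if the V reading frame is continued through
#' the junction into the J segment's annotated frame (junction length
#' preserves frame) and no stop codon occurs in that single ORF across the
#' assembled V-CDR3-J sequence. `v_used` and `j_trim` describe how much of
#' each germline coding region the junction retained; defaults correspond
#' to untrimmed segments.
#'
#' @param v,j germline segment records (rows of
#'   [make_germline_reference()]) with `coding_frame` annotations.
#' @param cdr3_nt junction nucleotides (may be `""`).
#' @param v_used number of V coding bases retained (default: all,
#'   `v$rss_position`).
#' @param j_trim number of J coding bases trimmed from the RSS end
#'   (default 0).
#' @return list with logical `productive` and `reason` (`NA`,
#'   `"out-of-frame"`, or `"stop"`).
#' @export
assess_productivity <- function(v, cdr3_nt, j, v_used = NULL, j_trim = 0L) {
  if (is.na(v$coding_frame) || is.na(j$coding_frame))
    stop("configuration error: segment lacks a coding_frame annotation")
  if (is.null(v_used)) v_used <- v$rss_position
  in_frame <- (v_used + nchar(cdr3_nt)) %% 3L ==
    (j$coding_frame + j_trim) %% 3L
  if (!in_frame)
    return(list(productive = FALSE, reason = "out-of-frame"))
  cassette <- paste0(substr(v$sequence, 1L, v_used), cdr3_nt,
                     substr(j$sequence, j$rss_position + j_trim + 1L,
                            nchar(j$sequence)))
  n <- nchar(cassette)
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(cassette, starts, starts + 2L)
  if (any(codons %in% stop_codons))
    return(list(productive = FALSE, reason = "stop"))
  list(productive = TRUE, reason = NA_character_)
}

#' Extract the CDR3 of one V+J tag conformation on a read
#'
#' Walks from each tag toward its predicted RSS cleavage point along the
#' read, comparing base-by-base to germline: the CDR3 boundary is the
#' predicted cleavage position, or the first divergence from germline if
#' divergence occurs before it (the signature of exonuclease trimming).
#' The junction is the read sequence between the V and J boundaries; it
#' may be empty but is rejected as `incoherent-junction` if the boundaries
#' cross.
#'
#' @param read_seq read sequence in the orientation of the conformation.
#' @param v_hit,j_hit single rows of a [scan_tags()] result (coding-flank V
#'   and J hits on this read/orientation).
#' @param segments germline reference.
#' @return list with `ok`, and on success `cdr3_nt`, `v_used`, `j_trim`,
#'   `d_name`, `category`; on failure `reason`.
#' @export
call_cdr3 <- function(read_seq, v_hit, j_hit, segments) {
  v <- get_segment(segments, v_hit$element)
  j <- get_segment(segments, j_hit$element)
  gap <- TAG_RSS_OFFSET
  if (v_hit$flank != j_hit$flank)
    return(list(ok = FALSE, reason = "mixed-flank-conformation"))
  category <- v_hit$flank
  if (category != "coding")
    return(call_signal_junction(read_seq, v_hit, j_hit, v, j))
  # V: tag ends 15 bp before cleavage; germline gap = v[rss-14 .. rss]
  v_rss <- v$rss_position
  if (v_hit$end + gap > nchar(read_seq) || j_hit$start - gap < 1L)
    return(list(ok = FALSE, reason = "junction-outside-read"))
  matched_v <- 0L
  while (matched_v < gap &&
         substr(read_seq, v_hit$end + matched_v + 1L,
                v_hit$end + matched_v + 1L) ==
         substr(v$sequence, v_rss - gap + matched_v + 1L,
                v_rss - gap + matched_v + 1L))
    matched_v <- matched_v + 1L
  v_bound <- v_hit$end + matched_v       # last read position matching V
  v_used <- v_rss - gap + matched_v
  # J: tag starts 15 bp after cleavage; germline gap = j[rss+1 .. rss+15]
  j_rss <- j$rss_position
  matched_j <- 0L
  while (matched_j < gap &&
         j_hit$start - matched_j - 1L > v_bound &&
         substr(read_seq, j_hit$start - matched_j - 1L,
                j_hit$start - matched_j - 1L) ==
         substr(j$sequence, j_rss + gap - matched_j,
                j_rss + gap - matched_j))
    matched_j <- matched_j + 1L
  j_first <- j_hit$start - matched_j     # first read position matching J
  j_trim <- gap - matched_j
  if (j_first <= v_bound)
    return(list(ok = FALSE, reason = "incoherent-junction"))
  cdr3 <- if (j_first - 1L >= v_bound + 1L)
    substr(read_seq, v_bound + 1L, j_first - 1L) else ""
  # D identification (beta coding joints): exact core substring of the CDR3
  d_name <- NA_character_
  ds <- segments[segments$locus == v$locus & segments$segment_class == "D", ]
  if (nrow(ds) > 0L && nchar(cdr3) >= D_CORE_LEN) {
    hits <- vapply(seq_len(nrow(ds)), function(k) {
      core <- substr(ds$sequence[k], ds$rss_position[k] + 1L,
                     ds$rss_position[k] + D_CORE_LEN)
      grepl(core, cdr3, fixed = TRUE)
    }, logical(1))
    if (sum(hits) == 1L) d_name <- ds$name[hits]
  }
  list(ok = TRUE, cdr3_nt = cdr3, v_used = v_used, j_trim = j_trim,
       d_name = d_name, category = "coding")
}

# signal-joint junction: J signal tag precedes V signal tag; boundaries
# walked toward the respective cleavage points
call_signal_junction <- function(read_seq, v_hit, j_hit, v, j) {
  gap <- TAG_RSS_OFFSET
  if (j_hit$end + gap > nchar(read_seq) || v_hit$start - gap < 1L)
    return(list(ok = FALSE, reason = "junction-outside-read"))
  matched_j <- 0L
  while (matched_j < gap &&
         substr(read_seq, j_hit$end + matched_j + 1L,
                j_hit$end + matched_j + 1L) ==
         substr(j$sequence, j$rss_position - gap + matched_j + 1L,
                j$rss_position - gap + matched_j + 1L))
    matched_j <- matched_j + 1L
  j_bound <- j_hit$end + matched_j
  matched_v <- 0L
  while (matched_v < gap &&
         v_hit$start - matched_v - 1L > j_bound &&
         substr(read_seq, v_hit$start - matched_v - 1L,
                v_hit$start - matched_v - 1L) ==
         substr(v$sequence, v$rss_position + gap - matched_v,
                v$rss_position + gap - matched_v))
    matched_v <- matched_v + 1L
  v_first <- v_hit$start - matched_v
  if (v_first <= j_bound)
    return(list(ok = FALSE, reason = "incoherent-junction"))
  cdr3 <- if (v_first - 1L >= j_bound + 1L)
    substr(read_seq, j_bound + 1L, v_first - 1L) else ""
  list(ok = TRUE, cdr3_nt = cdr3, v_used = NA_integer_, j_trim = NA_integer_,
       d_name = NA_character_, category = "signal")
}

# find the unique V+J conformation among one read's hits (one orientation)
find_conformation <- function(hits) {
  confs <- list()
  vh <- hits[hits$class == "V" & !hits$ambiguous, , drop = FALSE]
  jh <- hits[hits$class == "J" & !hits$ambiguous, , drop = FALSE]
  if (nrow(vh) > 0L && nrow(jh) > 0L) {
    for (a in seq_len(nrow(vh))) {
      for (b in seq_len(nrow(jh))) {
        if (vh$locus[a] != jh$locus[b]) next
        if (vh$flank[a] != jh$flank[b]) next
        if (vh$flank[a] == "coding" && vh$end[a] < jh$start[b])
          confs[[length(confs) + 1L]] <- list(v = vh[a, ], j = jh[b, ])
        if (vh$flank[a] == "signal" && jh$end[b] < vh$start[a])
          confs[[length(confs) + 1L]] <- list(v = vh[a, ], j = jh[b, ])
      }
    }
  }
  confs
}

#' Call junctions for a set of demultiplexed single-end reads
#'
#' Scans each read on both strands, requires exactly one
#' recombination-compatible V+J tag conformation across both orientations,
#' and extracts its CDR3 and productivity.
#'
#' @param se single-end tibble from [demultiplex_and_parse_umi()].
#' @param lib tag library.
#' @param segments germline reference.
#' @return list with `calls` (tibble: `read_id`, `mate`, `sample_id`,
#'   `umi12`, `locus`, `v_call`, `d_call`, `j_call`, `junction`,
#'   `category`, `productive`) and `n_no_conformation`, `n_rejected`.
#' @export
call_junctions <- function(se, lib, segments) {
  hits <- scan_tags(se$seq, lib)
  calls <- list()
  n_nc <- 0L; n_rej <- 0L
  called_reads <- logical(nrow(se))
  for (r in unique(hits$read)) {
    rh <- hits[hits$read == r, , drop = FALSE]
    confs <- c(find_conformation(rh[rh$strand == "+", , drop = FALSE]),
               find_conformation(rh[rh$strand == "-", , drop = FALSE]))
    if (length(confs) != 1L) { n_nc <- n_nc + 1L; next }
    cf <- confs[[1]]
    oriented <- if (cf$v$strand == "+") se$seq[r] else revcomp(se$seq[r])
    res <- call_cdr3(oriented, cf$v, cf$j, segments)
    if (!res$ok) { n_rej <- n_rej + 1L; next }
    v <- get_segment(segments, cf$v$element)
    j <- get_segment(segments, cf$j$element)
    productive <- if (res$category == "coding")
      assess_productivity(v, res$cdr3_nt, j, res$v_used, res$j_trim)$productive
    else FALSE
    called_reads[r] <- TRUE
    calls[[length(calls) + 1L]] <- tibble::tibble(
      read_id = se$read_id[r], mate = se$mate[r],
      sample_id = se$sample_id[r], umi12 = se$umi12[r],
      locus = cf$v$locus, v_call = cf$v$element, d_call = res$d_name,
      j_call = cf$j$element, junction = res$cdr3_nt,
      category = res$category, productive = productive)
  }
  out <- dplyr::bind_rows(calls)
  list(calls = out,
       n_no_conformation = nrow(se) - sum(called_reads) - n_rej,
       n_rejected = n_rej)
}

#' Deduplicate PCR copies by degenerate fragment-UMI matching
#'
#' Clusters 12 bp UMIs by single-linkage over the "within Hamming distance
#' 2" graph (union-find over all pairs), so the cluster count equals the
#' number of connected components -- the inferred number of original
#' molecules. Identical UMIs never split, and adding copies of an existing
#' UMI never changes the count.
#'
#' @param umis character vector of 12-base UMIs (one entry per read/call of
#'   one clonotype in one sample).
#' @param max_mismatch merge threshold (default 2).
#' @return list with `n_molecules` and integer `cluster` assignment per
#'   input UMI.
#' @export
dedup_umis <- function(umis, max_mismatch = 2L) {
  if (any(nchar(umis) != 12L)) stop("UMIs must be 12 bases")
  uniq <- unique(umis)
  n <- length(uniq)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    mat <- do.call(rbind, lapply(uniq, utf8ToInt))
    for (i in seq_len(n - 1L)) {
      for (k in seq(i + 1L, n)) {
        if (sum(mat[i, ] != mat[k, ]) <= max_mismatch) {
          ri <- find(i); rk <- find(k)
          if (ri != rk) parent[rk] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  list(n_molecules = length(unique(comp)), cluster = comp[match(umis, uniq)])
}

#' Build a per-sample repertoire from junction calls
#'
#' Keeps productive coding-joint calls only, excludes any delta-locus rows,
#' groups by the clonotype key (V, CDR3, J, and D where called) and counts
#' molecules by degenerate UMI deduplication.
#'
#' @param calls tibble from [call_junctions()] (one sample).
#' @return tibble with `v_call`, `d_call`, `j_call`, `junction`,
#'   `productive`, `duplicate_count`; attributes `sample_id` and
#'   `n_delta_excluded`.
#' @export
build_repertoire <- function(calls) {
  if (nrow(calls) == 0L)
    stop("no calls supplied")
  if (length(unique(calls$sample_id)) != 1L)
    stop("mixed sample ids in one repertoire")
  n_delta <- sum(calls$locus == "TRD")
  keep <- calls$category == "coding" & calls$productive & calls$locus != "TRD"
  cc <- calls[keep, , drop = FALSE]
  key <- paste(cc$v_call, cc$junction, cc$j_call,
               ifelse(is.na(cc$d_call), "", cc$d_call), sep = "|")
  out <- lapply(unique(key), function(k) {
    rows <- cc[key == k, , drop = FALSE]
    tibble::tibble(v_call = rows$v_call[1], d_call = rows$d_call[1],
                   j_call = rows$j_call[1], junction = rows$junction[1],
                   productive = TRUE,
                   duplicate_count = dedup_umis(rows$umi12)$n_molecules)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "sample_id") <- calls$sample_id[1]
  attr(out, "n_delta_excluded") <- n_delta
  out
}

#' Full read-pair to repertoire pipeline for one library
#'
#' Chains QC filtering, demultiplexing/UMI parsing, tag scanning, junction
#' calling and repertoire construction, with pair-level accounting: every
#' input pair lands in exactly one bin.
#'
#' @param reads read-pair tibble (as produced by [simulate_reads()] or
#'   [read_fastq()]).
#' @param layout an [adapter_layout()].
#' @param lib a [derive_tag_library()] tag library.
#' @param segments the germline reference.
#' @return list with `repertoires` (named list of [build_repertoire()]
#'   tibbles per sample), `calls`, and `report` (bins: `qc_fail`,
#'   `validation_fail`, `undetermined`, `no_call`, `called`; they sum to
#'   the input pair count).
#' @export
call_reads <- function(reads, layout, lib, segments) {
  n_input <- nrow(reads)
  q <- qc_filter(reads)
  qc_fail <- sum(!q$qc_pass)
  dm <- demultiplex_and_parse_umi(q[q$qc_pass, , drop = FALSE], layout)
  cj <- call_junctions(dm$se, lib, segments)
  calls <- cj$calls
  called_pairs <- unique(calls$read_id)
  n_called <- length(called_pairs)
  n_no_call <- dm$report$n_assigned - n_called
  repertoires <- list()
  if (nrow(calls) > 0L) {
    for (sid in unique(calls$sample_id)) {
      repertoires[[sid]] <-
        build_repertoire(calls[calls$sample_id == sid, , drop = FALSE])
    }
  }
  report <- list(
    n_input = n_input,
    bins = c(qc_fail = qc_fail,
             validation_fail = dm$report$n_validation_discarded,
             undetermined = dm$report$n_undetermined,
             no_call = n_no_call,
             called = n_called))
  list(repertoires = repertoires, calls = calls, report = report)
}

#' Write a repertoire as an AIRR-style rearrangement TSV
#'
#' @param repertoire a [build_repertoire()] tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(repertoire, path) {
  df <- data.frame(
    sequence_id = sprintf("%s.%d", attr(repertoire, "sample_id") %||% "s",
                          seq_len(nrow(repertoire))),
    v_call = repertoire$v_call,
    d_call = ifelse(is.na(repertoire$d_call), "", repertoire$d_call),
    j_call = repertoire$j_call,
    junction = repertoire$junction,
    productive = ifelse(repertoire$productive, "T", "F"),
    duplicate_count = repertoire$duplicate_count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rearrangement TSV back as a clonotype count vector
#'
#' @param path TSV written by [write_rearrangements()] (or any table with a
#'   `duplicate_count` column).
#' @param sample_id sample id for the resulting vector.
#' @return a [clonotype_vector()].
#' @export
read_rearrangements <- function(path, sample_id = basename(path)) {
  df <- utils::read.delim(path)
  clonotype_vector(df$duplicate_count, sample_id)
}
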
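# Read-pair quality control and demultiplexing with fragment-UMI parsing.

#' Quality and length filter for read pairs
#'
#' A pair passes only if every base of both mates has Phred quality
#' strictly above 20 and each mate is at least 250 bp. (A 2x250 protocol
#' cannot produce reads strictly longer than 250 bp, so the length rule is
#' interpreted as `>= 250`.)
#'
#' @param reads tibble with columns `read_id`, `mate1`, `mate2`, `qual1`,
#'   `qual2` (Sanger Phred+33 qualities).
#' @param min_phred exclusive quality threshold (default 20).
#' @param min_len minimum mate length (default 250).
#' @return the input with logical column `qc_pass` and character column
#'   `qc_reason` (`NA` for passing pairs; `"length"` or `"quality"`
#'   otherwise).
#' @export
qc_filter <- function(reads, min_phred = 20L, min_len = 250L) {
  min_q <- function(qual) {
    vapply(qual, function(q) {
      v <- utf8ToInt(q) - 33L
      if (length(v) == 0L || any(v < 0L | v > 93L))
        stop("malformed FASTQ quality string")
      min(v)
    }, integer(1), USE.NAMES = FALSE)
  }
  len_ok <- nchar(reads$mate1) >= min_len & nchar(reads$mate2) >= min_len
  qual_ok <- min_q(reads$qual1) > min_phred & min_q(reads$qual2) > min_phred
  reads$qc_pass <- len_ok & qual_ok
  reads$qc_reason <- ifelse(reads$qc_pass, NA_character_,
                            ifelse(!len_ok, "length", "quality"))
  reads
}

#' Demultiplex read pairs and parse the fragment UMI
#'
#' Validates the 4 bp validation barcode on both mates, extracts the 6 bp
#' UMI from each mate and concatenates them (mate-1 UMI first) into the
#' fragment-specific 12 bp UMI, looks up the 4 bp library ID, trims the
#' 14 bp adapter prefix, and collapses the pair into two single-end reads
#' (one per mate) annotated with the shared fragment UMI.
#'
#' @param reads QC-passing pairs (tibble as in [qc_filter()]).
#' @param layout an [adapter_layout()].
#' @return list with
#'   * `se`: tibble of single-end reads (`read_id`, `mate`, `seq`,
#'     `sample_id`, `umi12`), excluding discarded and undetermined pairs;
#'   * `report`: counts of input / assigned / validation-discarded /
#'     undetermined pairs and per-sample assignments.
#' @export
demultiplex_and_parse_umi <- function(reads, layout) {
  stopifnot(inherits(layout, "adapter_layout"))
  vlen <- layout$validation_barcode_len
  ulen <- layout$umi_len
  llen <- layout$library_id_len
  val1 <- substr(reads$mate1, 1L, vlen)
  val2 <- substr(reads$mate2, 1L, vlen)
  umi1 <- substr(reads$mate1, vlen + 1L, vlen + ulen)
  umi2 <- substr(reads$mate2, vlen + 1L, vlen + ulen)
  lib1 <- substr(reads$mate1, vlen + ulen + 1L, vlen + ulen + llen)
  lib2 <- substr(reads$mate2, vlen + ulen + 1L, vlen + ulen + llen)
  valid <- val1 == layout$validation_barcode & val2 == layout$validation_barcode
  sample1 <- unname(layout$library_id_map[lib1])
  known <- valid & !is.na(sample1) & lib1 == lib2
  prefix <- vlen + ulen + llen
  keep <- which(known)
  se <- tibble::tibble(
    read_id = rep(reads$read_id[keep], each = 2L),
    mate = rep(1:2, times = length(keep)),
    seq = as.vector(rbind(
      substr(reads$mate1[keep], prefix + 1L, nchar(reads$mate1[keep])),
      substr(reads$mate2[keep], prefix + 1L, nchar(reads$mate2[keep])))),
    sample_id = rep(sample1[keep], each = 2L),
    umi12 = rep(paste0(umi1[keep], umi2[keep]), each = 2L))
  report <- list(
    n_input = nrow(reads),
    n_assigned = sum(known),
    n_validation_discarded = sum(!valid),
    n_undetermined = sum(valid & !known),
    per_sample = table(sample1[keep]))
  list(se = se, report = report)
}
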
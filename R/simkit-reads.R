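# Simulation of UMI-tagged paired-end reads from a sequence-level
# repertoire, emulating the custom adapter layout: each mate begins with a
# 4 bp validation barcode, a 6 bp random unique molecular identifier (UMI),
# and a 4 bp library ID barcode; the two 6 bp UMIs concatenate to a
# fragment-specific 12 bp UMI. PCR duplicates share their molecule's UMI up
# to a bounded number of substitutions, exercising the degenerate
# deduplication rule downstream.

READ_LEN <- 250L
ADAPTER_PREFIX_LEN <- 14L  # 4 validation + 6 UMI + 4 library ID

#' Adapter layout description
#'
#' @param validation_barcode expected 4-mer at the start of every mate.
#' @param library_id_map named character vector: 4 bp library ID -> sample
#'   id. Library IDs must be pairwise Hamming distance >= 2 so a single
#'   sequencing error cannot silently reassign a read.
#' @return list of class `adapter_layout`.
#' @export
adapter_layout <- function(validation_barcode = "TGAC",
                           library_id_map = c(AAGG = "sample")) {
  if (nchar(validation_barcode) != 4L)
    stop("validation barcode must be 4 bp")
  ids <- names(library_id_map)
  if (is.null(ids) || any(nchar(ids) != 4L))
    stop("library IDs must be 4 bp")
  if (length(ids) > 1L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (k in seq(i + 1L, length(ids))) {
        if (hamming(ids[i], ids[k]) < 2L)
          stop("library IDs must be pairwise Hamming distance >= 2")
      }
    }
  }
  structure(list(validation_barcode_len = 4L, umi_len = 6L,
                 library_id_len = 4L,
                 validation_barcode = validation_barcode,
                 library_id_map = library_id_map),
            class = "adapter_layout")
}

#' Read-simulation settings
#'
#' @param pcr_duplication_mean expected number of extra PCR copies per
#'   molecule (Poisson).
#' @param error_rate per-base substitution probability, in `[0, 0.05]`.
#' @param umi_error_max maximum substitutions injected into a PCR copy's
#'   12 bp UMI (`<= 2`, so the degenerate dedup rule can recover molecules).
#' @param fragment_length_range sonication fragment size interval (bp).
#' @param seed integer seed.
#' @return list of class `read_sim_spec`.
#' @export
read_sim_spec <- function(pcr_duplication_mean = 1, error_rate = 0,
                          umi_error_max = 2L,
                          fragment_length_range = c(250L, 350L),
                          seed = NULL) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must be in [0, 0.05]")
  if (umi_error_max < 0L || umi_error_max > 2L)
    stop("umi_error_max must be in 0..2 for the dedup rule to recover molecules")
  structure(list(pcr_duplication_mean = pcr_duplication_mean,
                 error_rate = error_rate,
                 umi_error_max = as.integer(umi_error_max),
                 fragment_length_range = as.integer(fragment_length_range),
                 seed = seed),
            class = "read_sim_spec")
}

#' Simulate UMI-tagged paired-end reads from a repertoire truth table
#'
#' Every molecule of every clonotype becomes a sonication fragment (the
#' assembled junction sequence padded with random flanking bases into the
#' configured size range) with a fresh 12 bp fragment UMI (6 bp per mate).
#' PCR copies are drawn per molecule; copies carry the molecule's UMI with
#' at most `umi_error_max` substitutions. Mate 1 reads the fragment 5' end,
#' mate 2 the reverse complement of its 3' end; both are exactly 250 bp
#' (fragments shorter than the insert are padded through). Substitution
#' errors are injected uniformly at `error_rate`. The truth mapping read ->
#' molecule -> clonotype is returned alongside.
#'
#' @param repertoire a sequence-level [simulate_repertoire()] result (its
#'   `table` must be present).
#' @param rspec a [read_sim_spec()].
#' @param layout an [adapter_layout()].
#' @param sample_id sample whose library ID barcode is used (must appear in
#'   `layout$library_id_map`).
#' @return list with `reads` (tibble: `read_id`, `mate1`, `mate2`, `qual1`,
#'   `qual2`) and `truth` (tibble: `read_id`, `molecule_id`, `clonotype`,
#'   `umi12`, `fragment`).
#' @export
simulate_reads <- function(repertoire, rspec = read_sim_spec(),
                           layout = adapter_layout(), sample_id = NULL) {
  stopifnot(inherits(repertoire, "sim_repertoire"))
  if (is.null(repertoire$table))
    stop("repertoire has no sequence-level table; simulate with a germline reference")
  if (is.null(sample_id)) sample_id <- repertoire$sample_id
  lib_ids <- names(layout$library_id_map)[layout$library_id_map == sample_id]
  if (length(lib_ids) != 1L)
    stop("sample_id must map to exactly one library ID in the layout")
  insert_len <- READ_LEN - ADAPTER_PREFIX_LEN
  if (ADAPTER_PREFIX_LEN >= READ_LEN)
    stop("adapter layout longer than read")
  tab <- repertoire$table
  with_seed(rspec$seed, {
    reads <- list(); truth <- list(); mol_counter <- 0L
    for (ci in seq_len(nrow(tab))) {
      clono <- paste(tab$v_call[ci], tab$junction[ci], tab$j_call[ci],
                     sep = "|")
      cassette <- tab$sequence[ci]
      lc <- nchar(cassette)
      for (mol in seq_len(tab$duplicate_count[ci])) {
        mol_counter <- mol_counter + 1L
        fr <- rspec$fragment_length_range
        L <- sample(seq(max(fr[1], lc), max(fr[2], lc)), 1L)
        p1 <- sample.int(L - lc + 1L, 1L) - 1L
        fragment <- paste0(random_dna(p1), cassette,
                           random_dna(L - lc - p1))
        umi12 <- random_dna(12L)
        n_copies <- 1L + stats::rpois(1L, rspec$pcr_duplication_mean)
        for (cp in seq_len(n_copies)) {
          u <- if (cp == 1L) umi12 else
            mutate_bases(umi12, sample(0:rspec$umi_error_max, 1L))
          m1 <- paste0(layout$validation_barcode, substr(u, 1L, 6L), lib_ids,
                       substr(fragment, 1L, insert_len))
          m2 <- paste0(layout$validation_barcode, substr(u, 7L, 12L), lib_ids,
                       substr(revcomp(fragment), 1L, insert_len))
          if (rspec$error_rate > 0) {
            m1 <- mutate_bases(m1, stats::rbinom(1L, nchar(m1), rspec$error_rate))
            m2 <- mutate_bases(m2, stats::rbinom(1L, nchar(m2), rspec$error_rate))
          }
          rid <- sprintf("%s:mol%06d:c%d", sample_id, mol_counter, cp)
          reads[[length(reads) + 1L]] <- tibble::tibble(
            read_id = rid, mate1 = m1, mate2 = m2,
            qual1 = strrep("I", nchar(m1)), qual2 = strrep("I", nchar(m2)))
          truth[[length(truth) + 1L]] <- tibble::tibble(
            read_id = rid, molecule_id = mol_counter, clonotype = clono,
            umi12 = umi12, fragment = fragment)
        }
      }
    }
    list(reads = dplyr::bind_rows(reads), truth = dplyr::bind_rows(truth))
  })
}

#' Write simulated read pairs as a pair of FASTQ files
#'
#' Sanger Phred+33 qualities; read ids suffixed `/1` and `/2`.
#'
#' @param reads the `reads` tibble from [simulate_reads()].
#' @param prefix output path prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("mate", m)]])
    names(seqs) <- paste0(reads$read_id, "/", m)
    q <- Biostrings::PhredQuality(reads[[paste0("qual", m)]])
    qs <- Biostrings::QualityScaledDNAStringSet(seqs, q)
    Biostrings::writeQualityScaledXStringSet(qs, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ read-pair back into the internal tibble form
#'
#' @param path_r1,path_r2 FASTQ files for mates 1 and 2.
#' @return tibble with `read_id`, `mate1`, `mate2`, `qual1`, `qual2`.
#' @export
read_fastq <- function(path_r1, path_r2) {
  # Biostrings warns that the FASTQ id line's metadata columns are dropped
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path_r1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path_r2))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  tibble::tibble(
    read_id = sub("/1$", "", names(r1)),
    mate1 = unname(as.character(r1)), mate2 = unname(as.character(r2)),
    qual1 = unname(as.character(Biostrings::quality(r1))),
    qual2 = unname(as.character(Biostrings::quality(r2))))
}
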
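# Read QC, demultiplexing, tag scanning, CDR3 calling, productivity and
# UMI deduplication.

make_pair <- function(mate1, mate2, q1 = NULL, q2 = NULL, id = "r1") {
  tibble::tibble(read_id = id, mate1 = mate1, mate2 = mate2,
                 qual1 = q1 %||% strrep("I", nchar(mate1)),
                 qual2 = q2 %||% strrep("I", nchar(mate2)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("QC filter enforces strict quality and length rules", {
  good <- strrep("A", 250)
  r <- make_pair(good, good)
  expect_true(qc_filter(r)$qc_pass)
  # one base at exactly Q20 fails (rule is strictly greater than 20)
  q20 <- paste0(strrep("I", 249), rawToChar(as.raw(20 + 33)))
  r2 <- qc_filter(make_pair(good, good, q2 = q20))
  expect_false(r2$qc_pass)
  expect_equal(r2$qc_reason, "quality")
  # a Q21 base passes
  q21 <- paste0(strrep("I", 249), rawToChar(as.raw(21 + 33)))
  expect_true(qc_filter(make_pair(good, good, q2 = q21))$qc_pass)
  r3 <- qc_filter(make_pair(strrep("A", 200), good))
  expect_false(r3$qc_pass)
  expect_equal(r3$qc_reason, "length")
  expect_error(qc_filter(make_pair(good, good, q1 = strrep(" ", 250))),
               "malformed")
})

test_that("demultiplexing concatenates mate UMIs and bins failures", {
  lay <- adapter_layout(validation_barcode = "TGAC",
                        library_id_map = c(AAGG = "S1", CCTT = "S2"))
  pad <- strrep("G", 236)
  ok <- make_pair(paste0("TGAC", "AAAAAA", "AAGG", pad),
                  paste0("TGAC", "CCCCCC", "AAGG", pad))
  badval <- make_pair(paste0("TTTT", "AAAAAA", "AAGG", pad),
                      paste0("TGAC", "CCCCCC", "AAGG", pad), id = "r2")
  unk <- make_pair(paste0("TGAC", "AAAAAA", "GGGG", pad),
                   paste0("TGAC", "CCCCCC", "GGGG", pad), id = "r3")
  dm <- demultiplex_and_parse_umi(dplyr::bind_rows(ok, badval, unk), lay)
  expect_equal(dm$report$n_input, 3)
  expect_equal(dm$report$n_assigned, 1)
  expect_equal(dm$report$n_validation_discarded, 1)
  expect_equal(dm$report$n_undetermined, 1)
  expect_equal(nrow(dm$se), 2)  # two single-end reads from the one pair
  expect_equal(unique(dm$se$umi12), "AAAAAACCCCCC")
  expect_equal(unique(dm$se$sample_id), "S1")
  expect_equal(unique(dm$se$seq), pad)
})

test_that("error-free demultiplexing assigns every pair correctly", {
  segs <- trg_segments()
  lay <- adapter_layout(library_id_map = c(AAGG = "S1", CCTT = "S2"))
  r1 <- simulate_reads(
    simulate_repertoire(repertoire_spec(10, 20, 0, seed = 1), segs,
                        "gamma", "S1"),
    read_sim_spec(pcr_duplication_mean = 0, seed = 2), lay)
  r2 <- simulate_reads(
    simulate_repertoire(repertoire_spec(10, 20, 0, seed = 3), segs,
                        "gamma", "S2"),
    read_sim_spec(pcr_duplication_mean = 0, seed = 4), lay)
  dm <- demultiplex_and_parse_umi(dplyr::bind_rows(r1$reads, r2$reads), lay)
  expect_equal(dm$report$n_assigned, 40)
  got <- dm$se$sample_id[match(c(r1$reads$read_id, r2$reads$read_id),
                               dm$se$read_id)]
  expect_equal(got, rep(c("S1", "S2"), each = 20))
})

test_that("tag scanning finds conformations and flags lone hits", {
  segs <- trg_segments()
  lib <- derive_tag_library(segs)
  rc <- simulate_recombination(segs, "gamma", seed = 11)
  hits <- scan_tags(rc$sequence, lib)
  fwd <- hits[hits$strand == "+", ]
  expect_true(any(fwd$class == "V" & fwd$element == rc$v_name))
  expect_true(any(fwd$class == "J" & fwd$element == rc$j_name))
  confs <- tcrdiv:::find_conformation(fwd)
  expect_length(confs, 1)
  # a read containing only V sequence yields no conformation
  v <- tcrdiv:::get_segment(segs, rc$v_name)
  vonly <- substr(v$sequence, 1, v$rss_position)
  hits_v <- scan_tags(vonly, lib)
  expect_length(tcrdiv:::find_conformation(
    hits_v[hits_v$strand == "+", ]), 0)
  # reverse-complemented reads are found on the minus strand
  hits_rc <- scan_tags(tcrdiv:::revcomp(rc$sequence), lib)
  expect_true(any(hits_rc$strand == "-" & hits_rc$element == rc$v_name))
})

test_that("rtags are resolved through alt-tags at the divergence point", {
  segs <- trg_segments()
  # force two V segments to share their coding tag region
  i1 <- which(segs$segment_class == "V")[1]
  i2 <- which(segs$segment_class == "V")[2]
  r <- segs$rss_position[i1]
  shared <- substr(segs$sequence[i1], r - 34, r - 15)
  substr(segs$sequence[i2], r - 34, r - 15) <- shared
  lib <- derive_tag_library(segs)
  vrows <- lib$element %in% segs$name[c(i1, i2)] & lib$flank == "coding"
  expect_true(all(lib$is_rtag[vrows]))
  expect_true(all(!is.na(lib$alt_tag[vrows])))
  expect_true(all(lib$alt_offset[vrows] < 0))  # away from the RSS
  # reads drawn from each element resolve to it
  set.seed(99)
  src <- rep(c(i1, i2), each = 50)
  reads <- vapply(src, function(i)
    paste0(tcrdiv:::random_dna(20), substr(segs$sequence[i], 1, r)),
    character(1))
  hits <- scan_tags(reads, lib)
  hits <- hits[hits$strand == "+" & hits$flank == "coding" &
                 hits$class == "V", ]
  expect_equal(nrow(hits), 100)
  expect_false(any(hits$ambiguous))
  expect_true(all(hits$via_rtag))
  expect_equal(hits$element[order(hits$read)], segs$name[src])
  # a read carrying the rtag but neither alt-tag region is ambiguous
  # (N padding cannot match any alt-tag base)
  bare <- paste0(strrep("N", 30), shared, strrep("N", 30))
  hits <- scan_tags(bare, lib)
  amb <- hits[hits$strand == "+" & hits$class == "V", ]
  expect_true(all(amb$ambiguous))
})

test_that("allelic variant tags map to their parent element", {
  segs <- trg_segments()
  lib <- derive_tag_library(segs)
  v1 <- segs$name[segs$segment_class == "V"][1]
  variant <- tcrdiv:::mutate_bases(lib$tag[lib$element == v1 &
                                             lib$flank == "coding"], 1)
  lib2 <- add_tag_variant(lib, v1, "coding", variant)
  hits <- scan_tags(paste0("ACGT", variant, "ACGT"), lib2)
  expect_true(any(hits$element == v1 & hits$strand == "+"))
})

test_that("called CDR3s match simulation truth, including divergence cases", {
  segs <- trb_segments()
  lib <- derive_tag_library(segs)
  set.seed(77)
  rcs <- lapply(1:200, function(i)
    simulate_recombination(segs, "beta", seed = 5000 + i,
                           trim_max = 6, ins_max = 9))
  reads <- vapply(rcs, function(rc)
    paste0(tcrdiv:::random_dna(10), rc$sequence, tcrdiv:::random_dna(10)),
    character(1))
  hits <- scan_tags(reads, lib)
  n_checked <- 0
  for (i in seq_along(rcs)) {
    rh <- hits[hits$read == i & hits$strand == "+", ]
    confs <- tcrdiv:::find_conformation(rh)
    if (length(confs) != 1) next
    res <- call_cdr3(reads[i], confs[[1]]$v, confs[[1]]$j, segments = segs)
    expect_true(res$ok)
    expect_identical(res$cdr3_nt, rcs[[i]]$cdr3_nt,
                     info = sprintf("draw %d", i))
    expect_identical(res$d_name, rcs[[i]]$d_name)
    expect_equal(res$v_used, rcs[[i]]$v_used)
    expect_equal(res$j_trim, rcs[[i]]$j_trim)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 150)
})

test_that("productivity follows the single-ORF frame and stop rules", {
  segs <- trg_segments()
  v <- tcrdiv:::get_segment(segs, segs$name[segs$segment_class == "V"][1])
  j <- tcrdiv:::get_segment(segs, segs$name[segs$segment_class == "J"][1])
  # frame-preserving junction of As, no stop possible
  k <- (j$coding_frame - v$rss_position) %% 3
  good <- strrep("A", k + 3)
  expect_true(assess_productivity(v, good, j)$productive)
  shift <- strrep("A", k + 4)
  res <- assess_productivity(v, shift, j)
  expect_false(res$productive)
  expect_equal(res$reason, "out-of-frame")
  # place TAA at a codon boundary of the cassette
  off <- (3 - (v$rss_position %% 3)) %% 3
  stopj <- paste0(strrep("C", off), "TAA",
                  strrep("A", (k - off) %% 3 + 3))
  res2 <- assess_productivity(v, stopj, j)
  expect_false(res2$productive)
  expect_equal(res2$reason, "stop")
  v_na <- v; v_na$coding_frame <- NA_integer_
  expect_error(assess_productivity(v_na, "", j), "configuration error")
})

test_that("degenerate UMI dedup equals connected components", {
  expect_equal(dedup_umis(c("AAAAAAAAAAAA", "AAAAAAAAAATT"))$n_molecules, 1)
  expect_equal(dedup_umis(c("AAAAAAAAAAAA", "TTTTTTTTTTTT"))$n_molecules, 2)
  expect_error(dedup_umis("ACGT"), "12 bases")
  set.seed(42)
  for (i in 1:50) {
    # families of perturbed UMIs induce merges and occasional chains
    n_seed <- sample(1:3, 1)
    base <- tcrdiv:::random_dna(12, n_seed)
    fam <- unlist(lapply(base, function(b) {
      c(b, vapply(seq_len(sample(0:3, 1)),
                  function(z) tcrdiv:::mutate_bases(b, sample(1:2, 1)),
                  character(1)))
    }))
    fam <- fam[seq_len(min(8, length(fam)))]
    expect_equal(dedup_umis(fam)$n_molecules, bf_umi_components(fam),
                 info = paste(fam, collapse = ","))
  }
  # PCR duplicates with identical UMIs never change the molecule count
  u <- c("ACGTACGTACGT", "ACGTACGTACTT", "GGGGGGGGGGGG")
  expect_equal(dedup_umis(c(u, u, u))$n_molecules, dedup_umis(u)$n_molecules)
})

test_that("repertoires are productive coding joints without delta rows", {
  calls <- tibble::tibble(
    read_id = sprintf("r%d", 1:6), mate = 1L, sample_id = "S1",
    umi12 = c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG",
              "TTTTTTTTTTTT", "ACACACACACAC", "AGAGAGAGAGAG"),
    locus = c(rep("TRG", 4), "TRG", "TRD"),
    v_call = c(rep("TRGV1", 4), "TRGV2", "TRDV1"),
    d_call = NA_character_,
    j_call = "TRGJ1",
    junction = c(rep("AAA", 4), "CCC", "GGG"),
    category = "coding", productive = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  rep <- build_repertoire(calls)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$duplicate_count[rep$junction == "AAA"], 3)
  expect_equal(rep$duplicate_count[rep$junction == "CCC"], 1)
  expect_equal(attr(rep, "n_delta_excluded"), 1)
  calls$sample_id[2] <- "S2"
  expect_error(build_repertoire(calls), "mixed sample ids")
})

test_that("signal-joint conformations are called but kept out of repertoires", {
  segs <- trg_segments()
  lib <- derive_tag_library(segs)
  v <- tcrdiv:::get_segment(segs, segs$name[segs$segment_class == "V"][1])
  j <- tcrdiv:::get_segment(segs, segs$name[segs$segment_class == "J"][1])
  # signal joint: J signal flank followed by V signal flank
  sj <- paste0(substr(j$sequence, 1, j$rss_position),
               substr(v$sequence, v$rss_position + 1, nchar(v$sequence)))
  hits <- scan_tags(sj, lib)
  confs <- tcrdiv:::find_conformation(hits[hits$strand == "+", ])
  expect_length(confs, 1)
  res <- call_cdr3(sj, confs[[1]]$v, confs[[1]]$j, segments = segs)
  expect_true(res$ok)
  expect_equal(res$category, "signal")
  expect_identical(res$cdr3_nt, "")
})

test_that("error-free round trip recovers at least 99% of truth counts", {
  segs <- trb_segments()
  lib <- derive_tag_library(segs)
  rep <- simulate_repertoire(repertoire_spec(50, 110, 0.2, seed = 21),
                             segs, "beta", "S1")
  lay <- adapter_layout(library_id_map = c(AAGG = "S1"))
  rs <- simulate_reads(rep, read_sim_spec(pcr_duplication_mean = 1,
                                          error_rate = 0, umi_error_max = 2,
                                          seed = 22), lay)
  res <- call_reads(rs$reads, lay, lib, segs)
  expect_equal(sum(res$report$bins), res$report$n_input)
  truth <- rep$table
  called <- res$repertoires[["S1"]]
  tkey <- paste(truth$v_call, truth$junction, truth$j_call,
                ifelse(is.na(truth$d_call), "", truth$d_call), sep = "|")
  ckey <- paste(called$v_call, called$junction, called$j_call,
                ifelse(is.na(called$d_call), "", called$d_call), sep = "|")
  m <- match(tkey, ckey)
  exact <- !is.na(m) & called$duplicate_count[m] == truth$duplicate_count
  expect_gte(mean(exact), 0.99)
  expect_equal(sum(called$duplicate_count), sum(truth$duplicate_count))
})

test_that("read-pair accounting conserves every input pair", {
  segs <- trg_segments()
  lib <- derive_tag_library(segs)
  rep <- simulate_repertoire(repertoire_spec(15, 30, 0, seed = 31),
                             segs, "gamma", "S1")
  lay <- adapter_layout(library_id_map = c(AAGG = "S1"))
  rs <- simulate_reads(rep, read_sim_spec(pcr_duplication_mean = 0,
                                          seed = 32), lay)
  reads <- rs$reads
  # corrupt pair 1's validation barcode, truncate pair 2, degrade pair 3
  substr(reads$mate1[1], 1, 4) <- "GGGG"
  reads$mate2[2] <- substr(reads$mate2[2], 1, 100)
  reads$qual2[2] <- substr(reads$qual2[2], 1, 100)
  substr(reads$qual1[3], 50, 50) <- "!"
  res <- call_reads(reads, lay, lib, segs)
  bins <- res$report$bins
  expect_equal(sum(bins), nrow(reads))
  expect_equal(unname(bins["qc_fail"]), 2)
  expect_equal(unname(bins["validation_fail"]), 1)
  expect_equal(unname(bins["called"]), nrow(reads) - 3)
})
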
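# Synthetic germline, recombination, repertoire and read simulation.

test_that("germline references respect locus rules and are deterministic", {
  trg <- make_germline_reference(2, 0, 2, "TRG", seed = 1)
  expect_equal(nrow(trg), 4)
  expect_false(any(trg$segment_class == "D"))
  expect_true(all(grepl("^[ACGT]+$", trg$sequence)))
  expect_true(all(trg$rss_position >= 0 &
                    trg$rss_position <= nchar(trg$sequence)))
  expect_identical(make_germline_reference(2, 0, 2, "TRG", seed = 1), trg)
  expect_error(make_germline_reference(0, 0, 2, "TRG", seed = 1),
               "invalid reference")
  expect_error(make_germline_reference(2, 1, 2, "TRA", seed = 1),
               "no D segments")
  expect_error(make_germline_reference(2, 0, 2, "TRB", seed = 1),
               "requires at least one D")
})

test_that("every segment carries a 20-mer unique across the reference", {
  segs <- trb_segments()
  expect_equal(nrow(segs), 14)
  all_kmers <- lapply(segs$sequence, function(s) {
    n <- nchar(s)
    unique(substring(s, 1:(n - 19), 20:n))
  })
  for (i in seq_len(nrow(segs))) {
    others <- unlist(all_kmers[-i])
    expect_true(any(!(all_kmers[[i]] %in% others)),
                info = segs$name[i])
  }
})

test_that("zero-edit recombination concatenates the reference junctions", {
  trg <- trg_segments()
  rc <- simulate_recombination(trg, "gamma", seed = 3, trim_max = 0,
                               ins_max = 0)
  v <- tcrdiv:::get_segment(trg, rc$v_name)
  j <- tcrdiv:::get_segment(trg, rc$j_name)
  expect_identical(rc$cdr3_nt, "")
  expect_identical(rc$sequence,
                   paste0(substr(v$sequence, 1, v$rss_position),
                          substr(j$sequence, j$rss_position + 1,
                                 nchar(j$sequence))))
  expect_true(is.na(rc$d_name))
  trb <- trb_segments()
  rcb <- simulate_recombination(trb, "beta", seed = 3, trim_max = 0,
                                ins_max = 0)
  d <- tcrdiv:::get_segment(trb, rcb$d_name)
  expect_identical(rcb$cdr3_nt,
                   substr(d$sequence, d$rss_position + 1,
                          d$rss_position + tcrdiv:::D_CORE_LEN))
  expect_error(simulate_recombination(trg, "beta"), "invalid reference")
})

test_that("truth productivity agrees with an independent translation check", {
  segs <- trb_segments()
  for (i in 1:300) {
    rc <- simulate_recombination(segs, "beta", seed = 1000 + i)
    v <- tcrdiv:::get_segment(segs, rc$v_name)
    j <- tcrdiv:::get_segment(segs, rc$j_name)
    cassette <- paste0(substr(v$sequence, 1, rc$v_used), rc$cdr3_nt,
                       substr(j$sequence, j$rss_position + rc$j_trim + 1,
                              nchar(j$sequence)))
    in_frame <- (rc$v_used + nchar(rc$cdr3_nt)) %% 3 ==
      (j$coding_frame + rc$j_trim) %% 3
    aa <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(substr(cassette, 1,
                                   3 * (nchar(cassette) %/% 3))))))
    expect_identical(rc$productive, in_frame && !grepl("*", aa, fixed = TRUE),
                     info = sprintf("draw %d", i))
  }
})

test_that("clone-size structure follows the specified mixture", {
  # no expansion: all singletons, richness equals depth
  r0 <- simulate_repertoire(repertoire_spec(100, 250, 0, seed = 1))
  expect_true(all(r0$counts$counts == 1))
  expect_equal(length(r0$counts$counts), 250)
  # full expansion with an extreme tail: one clone dominates
  r1 <- simulate_repertoire(
    repertoire_spec(3, 1000, 1, expansion_shape = 1e-6, seed = 2))
  expect_gt(max(r1$counts$counts) / r1$counts$depth, 0.9)
  # exact depth always
  r2 <- simulate_repertoire(repertoire_spec(500, 5000, 0.1, seed = 3))
  expect_equal(r2$counts$depth, 5000)
  expect_error(repertoire_spec(600, 500), "infeasible")
})

test_that("expanded clone sizes fit the shifted-geometric law", {
  spec <- repertoire_spec(2000, 20000, 0.25, expansion_shape = 0.2, seed = 3)
  rep <- simulate_repertoire(spec)
  sizes <- rep$counts$counts[rep$counts$counts >= 2]
  expect_equal(length(sizes), 500)
  # chi-squared GOF against P(S = k) = q (1-q)^(k-2), k >= 2
  q <- 0.2
  kmax <- max(sizes)
  probs <- q * (1 - q)^(0:(kmax - 2))
  bins <- c(2:9, Inf)  # pool the tail
  obs <- vapply(seq_len(length(bins) - 1), function(b)
    sum(sizes >= bins[b] & sizes < bins[b + 1]), numeric(1))
  pexp <- vapply(seq_len(length(bins) - 1), function(b) {
    ks <- 2:max(sizes)
    sum(probs[ks - 1][ks >= bins[b] & ks < bins[b + 1]])
  }, numeric(1))
  pexp <- pexp / sum(pexp)
  gof <- suppressWarnings(stats::chisq.test(obs, p = pexp))
  expect_gt(gof$p.value, 0.001)
})

test_that("cohorts have the requested layout, depths and determinism", {
  cs <- cohort_spec(groups = c(A = 5, B = 5), base_expansion = 0.05,
                    effect_delta = 0.2, effect_groups = "B",
                    depth_range = c(300, 1500), seed = 9)
  co <- simulate_cohort(cs)
  expect_equal(nrow(co), 10)
  expect_equal(as.integer(table(co$group)), c(5L, 5L))
  expect_true(all(co$depth >= 300 & co$depth <= 1500))
  expect_equal(unique(co$expansion_fraction[co$group == "A"]), 0.05)
  expect_equal(unique(co$expansion_fraction[co$group == "B"]), 0.25)
  expect_true(all(vapply(co$repertoire, function(r) r$counts$depth,
                         numeric(1)) == co$depth))
  co2 <- simulate_cohort(cs)
  expect_identical(cohort_counts(co), cohort_counts(co2))
})

test_that("read simulation is lossless and deterministic without noise", {
  segs <- trg_segments()
  rep <- simulate_repertoire(repertoire_spec(20, 40, 0.2, seed = 4),
                             segs, "gamma", "S1")
  lay <- adapter_layout(library_id_map = c(AAGG = "S1"))
  rs <- simulate_reads(rep, read_sim_spec(pcr_duplication_mean = 0,
                                          error_rate = 0, seed = 5), lay)
  expect_equal(nrow(rs$reads), sum(rep$table$duplicate_count))
  expect_equal(length(unique(rs$truth$molecule_id)),
               sum(rep$table$duplicate_count))
  expect_true(all(nchar(rs$reads$mate1) == 250))
  expect_true(all(nchar(rs$reads$mate2) == 250))
  rs2 <- simulate_reads(rep, read_sim_spec(pcr_duplication_mean = 0,
                                           error_rate = 0, seed = 5), lay)
  expect_identical(rs$reads, rs2$reads)
  # FASTQ round trip is byte-faithful
  pre <- file.path(tempdir(), "simreads")
  write_fastq(rs$reads, pre)
  back <- read_fastq(paste0(pre, "_R1.fastq"), paste0(pre, "_R2.fastq"))
  expect_equal(back$mate1, rs$reads$mate1)
  expect_equal(back$qual2, rs$reads$qual2)
})

test_that("injected substitution errors match the configured rate", {
  segs <- trg_segments()
  rep <- simulate_repertoire(repertoire_spec(30, 120, 0.2, seed = 6),
                             segs, "gamma", "S1")
  lay <- adapter_layout(library_id_map = c(AAGG = "S1"))
  rs <- simulate_reads(rep, read_sim_spec(pcr_duplication_mean = 0,
                                          error_rate = 0.01, seed = 8), lay)
  expected1 <- paste0("TGAC", substr(rs$truth$umi12, 1, 6), "AAGG",
                      substr(rs$truth$fragment, 1, 236))
  mism <- sum(mapply(tcrdiv:::hamming, rs$reads$mate1, expected1))
  n_bases <- 250 * nrow(rs$reads)
  expect_gt(n_bases, 1e4)
  ci <- stats::binom.test(mism, n_bases, 0.01)$conf.int
  expect_true(ci[1] <= 0.01 && 0.01 <= ci[2])
})
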
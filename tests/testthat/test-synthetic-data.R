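test_that("toy references are seeded-deterministic with the requested GC", {
  r1 <- make_toy_reference(100000, gc = 0.5, seed = 1)
  r2 <- make_toy_reference(100000, gc = 0.5, seed = 1)
  expect_identical(r1, r2)
  gc_obs <- sum(strsplit(r1$seq, "")[[1]] %in% c("G", "C")) / r1$length
  expect_gt(gc_obs, 0.48)
  expect_lt(gc_obs, 0.52)
  at_only <- make_toy_reference(2000, gc = 0, seed = 2)
  expect_false(grepl("[GC]", at_only$seq))
  expect_error(make_toy_reference(500), "1000")
  expect_error(make_toy_reference(10000, gc = 1.5), "fraction")
})

test_that("inject_svs places the requested SVs with exact length bookkeeping", {
  ref <- make_toy_reference(100000, seed = 7)
  inj <- inject_svs(ref, sv_spec(
    n_del = 3, n_ins = 2, n_inv = 1, n_dup = 1,
    seed = 5
  ))
  expect_equal(nrow(inj$truth), 7L)
  expect_equal(
    sort(table(inj$truth$sv_type)),
    sort(table(c(rep("DEL", 3), rep("INS", 2), "INV", "DUP")))
  )
  del_len <- sum(inj$truth$svlen[inj$truth$sv_type == "DEL"])
  ins_len <- sum(inj$truth$svlen[inj$truth$sv_type == "INS"])
  dup_len <- sum(inj$truth$svlen[inj$truth$sv_type == "DUP"])
  expect_equal(
    sum(inj$altered$length),
    sum(ref$length) - del_len + ins_len + dup_len
  )
  # one DEL of known size: simple arithmetic
  inj1 <- inject_svs(ref, sv_spec(
    n_del = 1, n_ins = 0, n_inv = 0, n_dup = 0,
    len_range = c(500L, 500L), seed = 9
  ))
  expect_equal(sum(inj1$altered$length), 100000L - 500L)
  expect_equal(nrow(inj1$truth), 1L)
  # all SV lengths respect the >= 50 bp definition
  expect_true(all(inj$truth$svlen >= 50L))
  expect_error(sv_spec(len_range = c(40L, 100L)), "50")
})

test_that("inversions are in-place reverse complements", {
  ref <- make_toy_reference(50000, seed = 3)
  inj <- inject_svs(ref, sv_spec(
    n_del = 0, n_ins = 0, n_inv = 1, n_dup = 0,
    seed = 4
  ))
  t <- inj$truth
  orig_seg <- substr(ref$seq, t$pos, t$end)
  alt_seg <- substr(inj$altered$seq, t$pos, t$end)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", orig_seg), "")[[1]]),
    collapse = ""
  )
  expect_identical(alt_seg, rc)
})

test_that("truth applied to the original reference rebuilds the altered one", {
  ref <- make_toy_reference(100000, n_contigs = 2, seed = 11)
  inj <- inject_svs(ref, sv_spec(n_del = 2, n_ins = 2, n_inv = 1, n_dup = 1,
    n_tra = 1, seed = 12
  ))
  rebuilt <- oracle_rebuild_reference(ref, inj$truth)
  expect_identical(unname(rebuilt[inj$altered$contig]), inj$altered$seq)
})

test_that("translocations need two contigs", {
  ref <- make_toy_reference(50000, n_contigs = 1, seed = 1)
  expect_error(
    inject_svs(ref, sv_spec(n_tra = 1, seed = 1)),
    "2 contigs"
  )
})

test_that("read simulation hits the coverage target and is exact when noiseless", {
  ref <- make_toy_reference(100000, seed = 21)
  reads <- simulate_reads(ref, coverage = 10, seed = 22)
  total <- sum(reads$length)
  expect_gt(total, 0.9e6)
  expect_lt(total, 1.1e6)
  expect_identical(reads, simulate_reads(ref, coverage = 10, seed = 22))
  r0 <- simulate_reads(ref,
    coverage = 0.3, sub_rate = 0, ins_rate = 0,
    del_rate = 0, seed = 23
  )
  for (i in seq_len(nrow(r0))) {
    seg <- substr(ref$seq, r0$start[i], r0$end[i])
    if (r0$strand[i] == "-") {
      seg <- paste(rev(strsplit(chartr("ACGT", "TGCA", seg), "")[[1]]),
        collapse = ""
      )
    }
    expect_identical(r0$seq[i], seg)
  }
  expect_error(simulate_reads(ref, coverage = 0), "positive")
  expect_error(
    simulate_reads(ref, coverage = 1, sub_rate = 0.2, ins_rate = 0.2),
    "0.3"
  )
})

test_that("synthetic alignments are internally consistent and labelled by the rule", {
  syn <- synth_alignments(400, informative_fraction = 0.05, seed = 31)
  aln <- syn$alignments
  # CIGAR read length equals the stored read length for every record
  implied <- vapply(aln$cigar, function(cg) {
    ops <- parse_cigar(cg)
    sum(ops$length[ops$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
  expect_equal(implied, aln$seq_len)
  # MD is consistent with the CIGAR (the parser validates while walking)
  expect_silent(invisible(count_edit_ops(aln)))
  # labels follow the stated generative rule exactly
  prim <- dplyr::filter(aln, bitwAnd(flag, 0x900L) == 0L)
  feats <- extract_features(prim)
  rule <- as.integer(
    feats$softclip_left + feats$softclip_right > 200 | feats$longest_del_run > 40
  )
  expect_equal(rule, syn$labels$label[match(feats$read_name, syn$labels$read_name)])
})

test_that("informative fraction concentrates near its binomial expectation", {
  syn <- synth_alignments(10000, informative_fraction = 0.01, seed = 97)
  pos <- sum(syn$labels$label)
  expect_gte(pos, 50L)
  expect_lte(pos, 150L)
})

test_that("synth_vcf_pair noiseless limits behave exactly", {
  ref <- make_toy_reference(80000, seed = 41)
  truth <- inject_svs(ref, sv_spec(n_del = 3, n_ins = 2, n_inv = 1, seed = 42))$truth
  clean <- synth_vcf_pair(truth, jitter_a = 0, jitter_b = 0, seed = 43)
  merged <- merge_calls(clean$calls_a, clean$calls_b)
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(sort(merged$pos), sort(truth$pos))
  # total dropout of one caller leaves the other caller's calls
  only_b <- synth_vcf_pair(truth, dropout_a = 1, seed = 44)
  merged_b <- merge_calls(only_b$calls_a, only_b$calls_b)
  expect_equal(nrow(merged_b), nrow(only_b$calls_b))
  expect_true(all(merged_b$callers == "callerB"))
})
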
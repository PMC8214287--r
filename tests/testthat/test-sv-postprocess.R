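write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
    '##INFO=<ID=RNAMES,Number=.,Type=String,Description="r">',
    '##INFO=<ID=RE,Number=1,Type=Integer,Description="n">',
    '##INFO=<ID=MATEID,Number=1,Type=String,Description="m">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  writeLines(c(hdr, lines), path)
  path
}

test_that("parse_sv_vcf reads calls, read names, and count fallbacks", {
  path <- write_mini_vcf(c(
    "chr1\t1000\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500;SVLEN=-500;RNAMES=r1,r2",
    "chr1\t3000\tsv2\tN\t<INS>\t.\tPASS\tSVTYPE=INS;SVLEN=80;RE=7",
    "chr2\t500\tsv3\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=900;SVLEN=401"
  ))
  calls <- parse_sv_vcf(path, "callerA")
  expect_equal(nrow(calls), 3L)
  del <- calls[calls$id == "sv1", ]
  expect_equal(del$sv_type, "DEL")
  expect_equal(del$pos, 1000L)
  expect_equal(del$end, 1500L)
  expect_equal(del$svlen, 500L) # stored absolute
  expect_equal(del$support_reads[[1]], c("r1", "r2"))
  ins <- calls[calls$id == "sv2", ]
  expect_equal(ins$support_count, 7L)
  expect_equal(ins$support_reads[[1]], character())
  expect_equal(ins$end, ins$pos)
  # record without SVTYPE skipped with warning
  path2 <- write_mini_vcf("chr1\t10\tx\tN\tT\t.\tPASS\tEND=20")
  expect_warning(c2 <- parse_sv_vcf(path2, "c"), "SVTYPE")
  expect_equal(nrow(c2), 0L)
  # empty body parses to an empty call set
  path3 <- write_mini_vcf(character())
  expect_equal(nrow(parse_sv_vcf(path3, "c")), 0L)
})

test_that("breakend mate pairs collapse to a single TRA call", {
  path <- write_mini_vcf(c(
    "chr1\t5000\tbnd1\tN\tN[chr2:8000[\t.\tPASS\tSVTYPE=BND;RNAMES=r1,r2;MATEID=bnd2",
    "chr2\t8000\tbnd2\tN\t]chr1:5000]N\t.\tPASS\tSVTYPE=BND;RNAMES=r2,r3;MATEID=bnd1"
  ))
  calls <- parse_sv_vcf(path, "callerA")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$sv_type, "TRA")
  expect_equal(calls$chrom, "chr1")
  expect_equal(calls$pos, 5000L)
  expect_equal(calls$chrom2, "chr2")
  expect_equal(calls$pos2, 8000L)
  expect_setequal(calls$support_reads[[1]], c("r1", "r2", "r3"))
})

test_that("unique support counts distinct read names with count fallback", {
  calls <- tibble::tibble(
    id = c("a", "b", "c"), caller = "x", sv_type = "DEL", chrom = "chr1",
    pos = c(1L, 2L, 3L), end = c(10L, 20L, 30L),
    chrom2 = NA_character_, pos2 = NA_integer_, svlen = 10L,
    support_reads = list(c("r1", "r2", "r1"), character(), "r1"),
    support_count = c(3L, 7L, 1L)
  )
  u <- unique_support(calls)
  expect_equal(u$support_unique, c(2L, 7L, 1L))
})

test_that("minimum support is half the coverage, rounded up", {
  expect_identical(min_support_threshold(10), 5L)
  expect_identical(min_support_threshold(8), 4L)
  expect_identical(min_support_threshold(9), 5L)
  expect_identical(min_support_threshold(1), 1L)
  expect_error(min_support_threshold(0), "positive")
  expect_error(min_support_threshold(-3), "positive")
})

test_that("filter_min_support retains exactly the calls at or above threshold", {
  calls <- tibble::tibble(
    id = letters[1:3], caller = "x", sv_type = "DEL", chrom = "chr1",
    pos = c(100L, 200L, 300L), end = c(150L, 250L, 350L),
    chrom2 = NA_character_, pos2 = NA_integer_, svlen = 50L,
    support_reads = list(character(), character(), character()),
    support_count = c(5L, 4L, 6L)
  )
  kept <- filter_min_support(calls, 5L)
  expect_equal(kept$id, c("a", "c"))
  expect_equal(nrow(filter_min_support(calls, 1L)), 3L)
  expect_equal(nrow(filter_min_support(calls[0, ], 5L)), 0L)
  # idempotent and monotone
  expect_equal(filter_min_support(kept, 5L)$id, kept$id)
  expect_lte(nrow(filter_min_support(calls, 6L)), nrow(kept))
  expect_error(filter_min_support(calls, 0L), ">= 1")
})

mk_call <- function(id, caller, type, chrom, pos, end, reads,
                    chrom2 = NA_character_, pos2 = NA_integer_) {
  tibble::tibble(
    id = id, caller = caller, sv_type = type, chrom = chrom,
    pos = as.integer(pos), end = as.integer(end), chrom2 = chrom2,
    pos2 = as.integer(pos2), svlen = abs(as.integer(end - pos)) + 1L,
    support_reads = list(reads), support_count = length(reads)
  )
}

test_that("merge_calls unifies same-type calls within the window", {
  a <- mk_call("a1", "callerA", "DEL", "chr1", 1000, 1500, c("r1", "r2", "r3"))
  b <- mk_call("b1", "callerB", "DEL", "chr1", 1030, 1530, c("r4", "r5"))
  m <- merge_calls(a, b, window = 50L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$pos, 1000L) # the better-supported call's coordinates
  expect_equal(m$callers, "callerA,callerB")
  # distance exactly the window never merges (strict inequality)
  b2 <- mk_call("b1", "callerB", "DEL", "chr1", 1050, 1550, c("r4", "r5"))
  expect_equal(nrow(merge_calls(a, b2, window = 50L)), 2L)
  # type mismatch never merges
  b3 <- mk_call("b1", "callerB", "INS", "chr1", 1000, 1000, c("r4", "r5"))
  expect_equal(nrow(merge_calls(a, b3, window = 50L)), 2L)
  # both breakpoints must sit inside the window
  b4 <- mk_call("b1", "callerB", "DEL", "chr1", 1010, 1900, c("r4", "r5"))
  expect_equal(nrow(merge_calls(a, b4, window = 50L)), 2L)
  # commutative up to ordering
  m1 <- merge_calls(a, b, window = 50L)
  m2 <- merge_calls(b, a, window = 50L)
  expect_equal(m1$pos, m2$pos)
  expect_equal(m1$callers, m2$callers)
  expect_error(merge_calls(a, b, window = -1), "non-negative")
})

test_that("each call joins at most one unification and output size is bounded", {
  a <- dplyr::bind_rows(
    mk_call("a1", "callerA", "DEL", "chr1", 1000, 1500, c("r1", "r2")),
    mk_call("a2", "callerA", "DEL", "chr1", 1040, 1540, c("r3"))
  )
  b <- mk_call("b1", "callerB", "DEL", "chr1", 1020, 1520, c("r4", "r5", "r6"))
  m <- merge_calls(a, b, window = 50L)
  # b1 pairs with exactly one of a1/a2; the other survives
  expect_equal(nrow(m), 2L)
  expect_lte(nrow(m), nrow(a) + nrow(b))
})

test_that("two copies of one call set deduplicate to the original set", {
  ref <- make_toy_reference(60000, seed = 2)
  truth <- inject_svs(ref, sv_spec(n_del = 2, n_ins = 2, n_inv = 1, seed = 3))$truth
  pair <- synth_vcf_pair(truth, jitter_a = 0, jitter_b = 0, seed = 4)
  copy_a <- pair$calls_a
  copy_b <- dplyr::mutate(copy_a, caller = "callerB")
  # same physical reads listed by both copies, plus aligner-duplicated names
  copy_b$support_reads <- lapply(copy_a$support_reads, function(r) c(r, r[1]))
  merged <- merge_calls(copy_a, copy_b, window = 50L)
  expect_equal(nrow(merged), nrow(copy_a))
  key <- function(x) {
    dplyr::arrange(
      x[, c("sv_type", "chrom", "pos", "end")],
      .data$chrom, .data$pos
    )
  }
  expect_equal(key(merged), key(copy_a))
  expect_equal(
    unique_support(merged)$support_unique,
    unique_support(dplyr::arrange(copy_a, chrom, pos))$support_unique
  )
})

test_that("match_to_truth applies the strict breakpoint tolerance", {
  truth <- tibble::tibble(
    sv_id = "t1", sv_type = "DEL", chrom = "chr1", pos = 1000L, end = 1500L,
    svlen = 501L, chrom2 = NA_character_, pos2 = NA_integer_
  )
  near <- mk_call("c1", "callerA", "DEL", "chr1", 1009, 1509, c("r1"))
  ev <- match_to_truth(near, truth, tol = 10L)
  expect_equal(glance(ev)$recall, 1)
  expect_equal(glance(ev)$fdr, 0)
  # distance exactly 10 is not a match
  at <- mk_call("c1", "callerA", "DEL", "chr1", 1010, 1510, c("r1"))
  ev2 <- match_to_truth(at, truth, tol = 10L)
  expect_equal(glance(ev2)$recall, 0)
  expect_equal(glance(ev2)$fdr, 1)
  expect_equal(glance(ev2)$tp + glance(ev2)$fn, nrow(truth))
  # exact calls give recall 1, fdr 0; accounting identities hold
  exact <- mk_call("c1", "callerA", "DEL", "chr1", 1000, 1500, c("r1"))
  ev3 <- match_to_truth(exact, truth, tol = 10L)
  expect_equal(glance(ev3)$recall, 1)
  expect_equal(glance(ev3)$tp + glance(ev3)$fp, 1L)
  # no calls: FDR defined as 0
  ev4 <- match_to_truth(exact[0, ], truth, tol = 10L)
  expect_equal(glance(ev4)$fdr, 0)
  expect_equal(glance(ev4)$recall, 0)
})

test_that("written VCFs round-trip through the parser", {
  a <- mk_call("a1", "callerA", "DEL", "chr1", 1000, 1500, c("r1", "r2"))
  b <- mk_call("b1", "callerA", "TRA", "chr1", 2000, NA, c("r3", "r4"),
    chrom2 = "chr2", pos2 = 700
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(dplyr::bind_rows(a, b), path, contigs = c(chr1 = 10000L, chr2 = 10000L))
  back <- parse_sv_vcf(path, "callerA")
  expect_equal(nrow(back), 2L)
  expect_equal(back$sv_type, c("DEL", "TRA"))
  expect_equal(back$support_reads[[1]], c("r1", "r2"))
  expect_equal(back$chrom2[2], "chr2")
  expect_equal(back$pos2[2], 700L)
})
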
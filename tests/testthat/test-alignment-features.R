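test_that("parse_cigar tokenizes, keeps order, and rejects malformed input", {
  expect_equal(parse_cigar("50M"), tibble::tibble(op = "M", length = 50L))
  expect_equal(
    parse_cigar("5S10M2I8M3D10M4S"),
    tibble::tibble(
      op = c("S", "M", "I", "M", "D", "M", "S"),
      length = c(5L, 10L, 2L, 8L, 3L, 10L, 4L)
    )
  )
  expect_equal(nrow(parse_cigar("*")), 0L)
  expect_error(parse_cigar("10M5"), "position")
  expect_error(parse_cigar("M10"), "position 1")
  expect_error(parse_cigar("10M-5I"), "position")
  expect_error(parse_cigar(NA_character_))
})

test_that("count_edit_ops matches hand-derived CIGAR/MD counts", {
  expect_equal(
    count_edit_ops(alignment_record("5S10M2I8M3D10M4S", MD = "18^ACG10"))[-1],
    tibble::tibble(ins_bases = 2L, del_bases = 3L, mismatch_bases = 0L)
  )
  expect_equal(
    count_edit_ops(alignment_record("50M", MD = "50"))[-1],
    tibble::tibble(ins_bases = 0L, del_bases = 0L, mismatch_bases = 0L)
  )
  # MD walk places two substitutions
  expect_equal(
    count_edit_ops(alignment_record("120M5I130M", MD = "10A9C229"))[-1],
    tibble::tibble(ins_bases = 5L, del_bases = 0L, mismatch_bases = 2L)
  )
  # =/X CIGARs carry mismatches without MD
  expect_equal(
    count_edit_ops(alignment_record("10=2X38="))[-1],
    tibble::tibble(ins_bases = 0L, del_bases = 0L, mismatch_bases = 2L)
  )
  # NM-only fallback: mismatches = NM - ins - del
  expect_equal(
    count_edit_ops(alignment_record("20M2I20M1D20M", NM = 7L))$mismatch_bases,
    4L
  )
})

test_that("count_edit_ops handles unmapped records and bad MD", {
  expect_warning(
    res <- count_edit_ops(alignment_record("*", flag = 4L, seq_len = 100L)),
    "Unmapped"
  )
  expect_equal(unlist(res[-1]), c(ins_bases = 0L, del_bases = 0L, mismatch_bases = 0L))
  expect_error(
    count_edit_ops(alignment_record("50M", MD = "20^AC28")),
    "inconsistent"
  )
  expect_error(
    count_edit_ops(alignment_record("50M", MD = "49")),
    "aligned"
  )
})

test_that("longest_run measures maximal runs in bases, with one-match joins", {
  rec <- alignment_record("4M1D1M2D5M")
  expect_equal(longest_run(rec, "del")$longest_run, 2L)
  expect_equal(longest_run(rec, "del", allow_one_match = TRUE)$longest_run, 3L)
  expect_equal(longest_run(alignment_record("50M"), "ins")$longest_run, 0L)
  # two matches in between do not join
  rec2 <- alignment_record("4M1D2M2D5M")
  expect_equal(longest_run(rec2, "del", allow_one_match = TRUE)$longest_run, 2L)
  # chains join repeatedly across single matches
  rec3 <- alignment_record("3M2D1M2D1M2D9M")
  expect_equal(longest_run(rec3, "del", allow_one_match = TRUE)$longest_run, 6L)
  # mismatch runs come from the MD tag
  rec4 <- alignment_record("20M", MD = "5AA0T12")
  expect_equal(longest_run(rec4, "mismatch")$longest_run, 3L)
})

test_that("softclip_ends reads clip lengths off the CIGAR ends", {
  expect_equal(
    unlist(softclip_ends(alignment_record("5S10M2I8M3D10M4S"))[-1]),
    c(softclip_left = 5L, softclip_right = 4L)
  )
  expect_equal(
    unlist(softclip_ends(alignment_record("50M"))[-1]),
    c(softclip_left = 0L, softclip_right = 0L)
  )
  expect_equal(
    unlist(softclip_ends(alignment_record("7S43M"))[-1]),
    c(softclip_left = 7L, softclip_right = 0L)
  )
  # hard clips are ignored
  expect_equal(
    unlist(softclip_ends(alignment_record("10H5S35M"))[-1]),
    c(softclip_left = 5L, softclip_right = 0L)
  )
})

test_that("bin_top_counts charges events to read-coordinate bins", {
  res <- bin_top_counts(alignment_record("120M5I130M", MD = "10A9C229"))
  expect_equal(unlist(res[-1], use.names = FALSE), c(5L, 2L, 0L, 0L))
  res2 <- bin_top_counts(alignment_record("50M", MD = "50"))
  expect_equal(unlist(res2[-1], use.names = FALSE), c(0L, 0L, 0L, 0L))
  expect_error(bin_top_counts(alignment_record("50M"), bin_size = 0), "positive")
  expect_error(bin_top_counts(alignment_record("50M"), k = 0), "positive")
})

test_that("extract_features fills the 21-slot schema with documented defaults", {
  rec <- alignment_record("50M",
    MD = "50", NM = 0L, AS = 90L, s1 = 100L,
    s2 = 0L, cm = 12L
  )
  fv <- extract_features(rec)
  expect_equal(attr(fv, "schema_version"), "lrsv-1")
  expect_equal(names(fv), c("read_name", lrsv_feature_names()))
  expect_equal(
    unname(unlist(fv[-1])),
    c(100, 0, 12, 0, 90, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 50)
  )
  # missing optional tags default to 0
  fv2 <- extract_features(alignment_record("50M", MD = "50"))
  expect_equal(unname(unlist(fv2[, c("s1", "s2", "cm", "AS")])), c(0, 0, 0, 0))
  # NM falls back to ins + del + mismatch
  fv3 <- extract_features(alignment_record("20M2I20M1D10M", MD = "15G24^A10"))
  expect_equal(fv3$NM, 2 + 1 + 1)
})

test_that("features are location-independent and tag-order independent", {
  a <- alignment_record("10S30M5I20M3D40M2S",
    MD = "20T29^GCA40", NM = 9L,
    AS = 80L, s1 = 90L, pos = 100L, rname = "chr1"
  )
  b <- dplyr::mutate(a, pos = 999999L, rname = "chrX", mapq = 13L)
  expect_equal(extract_features(a)[-1], extract_features(b)[-1])
})

test_that("features come from the primary record only", {
  primary <- alignment_record("100M", MD = "100", read_name = "r1", NM = 0L)
  supp <- alignment_record("60S40M",
    MD = "40", read_name = "r1", flag = 2048L,
    NM = 0L
  )
  fv <- extract_features(dplyr::bind_rows(primary, supp))
  expect_equal(nrow(fv), 1L)
  expect_equal(fv$softclip_left, 0L)
  expect_equal(fv$read_length, 100L)
})

test_that("is_split follows the SAM supplementary convention", {
  expect_false(is_split(alignment_record("50M"))$split)
  expect_true(is_split(alignment_record("50M", SA = "chr1,1,+,50M,60,0;"))$split)
  two <- dplyr::bind_rows(
    alignment_record("50M", read_name = "r"),
    alignment_record("20S30M", read_name = "r", flag = 2048L)
  )
  expect_true(is_split(two)$split)
  # secondary alone is not split
  sec <- dplyr::bind_rows(
    alignment_record("50M", read_name = "r"),
    alignment_record("50M", read_name = "r", flag = 256L)
  )
  expect_false(is_split(sec)$split)
})

test_that("bin totals sum to the total edit bases for every record", {
  syn <- synth_alignments(150, informative_fraction = 0.1, seed = 41)
  prim <- dplyr::filter(syn$alignments, bitwAnd(flag, 0x900L) == 0L)
  counts <- count_edit_ops(prim)
  all_bins <- bin_top_counts(prim, k = 200L) # k larger than any bin count
  bin_sums <- rowSums(as.matrix(all_bins[-1]))
  expect_equal(
    bin_sums,
    counts$ins_bases + counts$del_bases + counts$mismatch_bases
  )
})

test_that("feature tables round-trip through TSV", {
  syn <- synth_alignments(30, seed = 8)
  fv <- extract_features(syn$alignments)
  fv$label <- syn$labels$label[match(fv$read_name, syn$labels$read_name)]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(fv, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(fv))
  expect_error(
    read_feature_table(write_feature_table(fv[, 1:3], path)),
    "missing column"
  )
})
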
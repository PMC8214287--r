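#' Read alignments from a SAM (or BAM) file into a tibble
#'
#' SAM text is parsed directly; BAM goes through Rsamtools. One row per
#' alignment record, with the aligner tags the downstream feature and
#' unification stages use (`s1`, `s2`, `cm`, `NM`, `AS`, `SA`, `MD`) lifted
#' into columns and any remaining tags kept verbatim in the `other_tags`
#' list-column. The header lines are attached as the `"header"` attribute.
#'
#' @param path Path to a `.sam` (text) or `.bam` file.
#' @return Alignment tibble with columns `read_name`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `rnext`, `pnext`, `tlen`, `seq`, `qual`, `seq_len`,
#'   tag columns, and `other_tags`.
#' @export
read_sam <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(.read_bam(path))
  }
  lines <- readLines(path)
  is_header <- startsWith(lines, "@")
  header <- lines[is_header]
  body <- lines[!is_header & nzchar(lines)]
  known_int <- c("s1", "s2", "cm", "NM", "AS")
  known_chr <- c("SA", "MD")
  if (length(body) == 0L) {
    out <- tibble::tibble(
      read_name = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      rnext = character(), pnext = integer(), tlen = integer(),
      seq = character(), qual = character(), seq_len = integer(),
      s1 = integer(), s2 = integer(), cm = integer(), NM = integer(),
      AS = integer(), SA = character(), MD = character(),
      other_tags = list()
    )
    attr(out, "header") <- header
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    rlang::abort(sprintf(
      "Malformed SAM record at body line %d: fewer than 11 fields.",
      which(nf < 11L)[1]
    ))
  }
  fx <- function(i) vapply(fields, `[[`, character(1), i)
  seq_field <- fx(10)
  cigar_field <- fx(6)
  tag_sets <- lapply(fields, function(f) if (length(f) > 11L) f[-(1:11)] else character())
  tagval <- function(tags, name) {
    hit <- tags[startsWith(tags, paste0(name, ":"))]
    if (length(hit) == 0L) NA_character_ else sub("^..:.:", "", hit[1])
  }
  out <- tibble::tibble(
    read_name = fx(1),
    flag = as.integer(fx(2)),
    rname = fx(3),
    pos = as.integer(fx(4)),
    mapq = as.integer(fx(5)),
    cigar = cigar_field,
    rnext = fx(7),
    pnext = as.integer(fx(8)),
    tlen = as.integer(fx(9)),
    seq = seq_field,
    qual = fx(11)
  )
  out$seq_len <- ifelse(
    seq_field != "*", nchar(seq_field),
    vapply(cigar_field, function(cg) {
      if (cg == "*") 0L else .cigar_read_len(parse_cigar(cg))
    }, integer(1), USE.NAMES = FALSE)
  )
  for (tg in known_int) {
    out[[tg]] <- as.integer(vapply(tag_sets, tagval, character(1), name = tg))
  }
  for (tg in known_chr) {
    out[[tg]] <- vapply(tag_sets, tagval, character(1), name = tg)
  }
  known <- c(known_int, known_chr)
  out$other_tags <- lapply(tag_sets, function(tags) {
    tags[!substr(tags, 1L, 2L) %in% known]
  })
  attr(out, "header") <- header
  out
}

.read_bam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    rlang::abort("Reading BAM requires the Rsamtools package.")
  }
  tags <- c("s1", "s2", "cm", "NM", "AS", "SA", "MD")
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm", "mpos",
             "isize", "seq", "qual"),
    tag = tags
  )
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  seq_chr <- as.character(res$seq)
  out <- tibble::tibble(
    read_name = res$qname,
    flag = as.integer(res$flag),
    rname = ifelse(is.na(res$rname), "*", as.character(res$rname)),
    pos = ifelse(is.na(res$pos), 0L, res$pos),
    mapq = as.integer(res$mapq),
    cigar = ifelse(is.na(res$cigar), "*", res$cigar),
    rnext = ifelse(is.na(res$mrnm), "*", as.character(res$mrnm)),
    pnext = ifelse(is.na(res$mpos), 0L, res$mpos),
    tlen = ifelse(is.na(res$isize), 0L, res$isize),
    seq = ifelse(nzchar(seq_chr), seq_chr, "*"),
    qual = as.character(res$qual)
  )
  out$seq_len <- nchar(seq_chr)
  for (tg in c("s1", "s2", "cm", "NM", "AS")) {
    v <- res$tag[[tg]]
    out[[tg]] <- if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  }
  for (tg in c("SA", "MD")) {
    v <- res$tag[[tg]]
    out[[tg]] <- if (is.null(v)) rep(NA_character_, n) else as.character(v)
  }
  out$other_tags <- rep(list(character()), n)
  hdr <- Rsamtools::scanBamHeader(path)[[1]]
  attr(out, "header") <- unname(vapply(
    seq_along(hdr$targets),
    function(i) sprintf("@SQ\tSN:%s\tLN:%d", names(hdr$targets)[i], hdr$targets[i]),
    character(1)
  ))
  out
}

#' Write an alignment tibble as SAM text
#'
#' @param aln Alignment tibble as produced by [read_sam()],
#'   [synth_alignments()], or [merge_alignments()].
#' @param path Output path.
#' @param header Header lines; defaults to the tibble's `"header"` attribute.
#'   When the tibble carries a `source` column (added by [harmonize_tags()]),
#'   it is emitted as an `sr:Z:` provenance tag.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, header = attr(aln, "header")) {
  if (is.null(header)) header <- character()
  known_int <- c("s1", "s2", "cm", "NM", "AS")
  known_chr <- c("SA", "MD")
  n <- nrow(aln)
  col_or <- function(name, default) {
    if (name %in% names(aln)) aln[[name]] else rep(default, n)
  }
  seqs <- col_or("seq", "*")
  quals <- col_or("qual", "*")
  lines <- character(n)
  src <- col_or("source", NA_character_)
  other <- if ("other_tags" %in% names(aln)) aln$other_tags else rep(list(character()), n)
  for (i in seq_len(n)) {
    tags <- character()
    for (tg in known_int) {
      v <- col_or(tg, NA_integer_)[i]
      if (!is.na(v)) tags <- c(tags, sprintf("%s:i:%d", tg, as.integer(v)))
    }
    for (tg in known_chr) {
      v <- col_or(tg, NA_character_)[i]
      if (!is.na(v)) tags <- c(tags, sprintf("%s:Z:%s", tg, v))
    }
    tags <- c(tags, other[[i]])
    if (!is.na(src[i])) tags <- c(tags, sprintf("sr:Z:%s", src[i]))
    lines[i] <- paste(c(
      aln$read_name[i], aln$flag[i], aln$rname[i], aln$pos[i], aln$mapq[i],
      aln$cigar[i], col_or("rnext", "*")[i], col_or("pnext", 0L)[i],
      col_or("tlen", 0L)[i], seqs[i], quals[i], tags
    ), collapse = "\t")
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Extract FASTQ records by read name
#'
#' Streams `fastq_in` in a single pass and writes exactly the records whose
#' name — the token before the first whitespace, without the leading `@` —
#' is in `names`, preserving input order.
#'
#' @param fastq_in Input FASTQ path.
#' @param names Character vector (or set) of read names to keep.
#' @param fastq_out Output FASTQ path.
#' @param chunk_records Records read per chunk while streaming.
#' @return Number of records written.
#' @export
extract_reads_by_name <- function(fastq_in, names, fastq_out,
                                  chunk_records = 10000L) {
  names <- unique(as.character(names))
  con_in <- file(fastq_in, open = "r")
  on.exit(close(con_in), add = TRUE)
  con_out <- file(fastq_out, open = "w")
  on.exit(close(con_out), add = TRUE)
  written <- 0L
  record_idx <- 0L
  repeat {
    lines <- readLines(con_in, n = 4L * chunk_records)
    if (length(lines) == 0L) break
    if (length(lines) %% 4L != 0L) {
      rlang::abort(sprintf(
        "Malformed FASTQ: truncated record at record %d.",
        record_idx + length(lines) %/% 4L + 1L
      ))
    }
    hdr <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad) > 0L) {
      rlang::abort(sprintf(
        "Malformed FASTQ record at record %d.", record_idx + bad[1]
      ))
    }
    nm <- sub("^@", "", sub("\\s.*$", "", hdr))
    keep <- nm %in% names
    if (any(keep)) {
      idx <- rep((which(keep) - 1L) * 4L, each = 4L) + 1:4
      writeLines(lines[idx], con_out)
      written <- written + sum(keep)
    }
    record_idx <- record_idx + length(hdr)
  }
  written
}
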
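#' Select the read subset to re-align with the accurate aligner
#'
#' The accurate (SV-aware) aligner only sees the union of (a) reads the
#' classifier flagged as informative and (b) reads the fast aligner itself
#' split — the fast aligner splits some reads wrongly, especially across
#' translocations, so its split reads are re-aligned regardless of the
#' classifier. A read in both groups is attributed to the split set.
#'
#' @param labels Tibble with `read_name` and a 0/1 label column (`label` or
#'   `informative`), as returned by [classify_reads()] or [label_reads()].
#' @param split_names Character vector of read names the fast aligner split.
#' @return Tibble with `read_name` and `provenance`
#'   (`"classifier_positive"` or `"split_by_fast_aligner"`), one row per read.
#' @export
select_for_realignment <- function(labels, split_names = character()) {
  lab_col <- intersect(c("label", "informative"), names(labels))
  if (is.data.frame(labels) && length(lab_col) == 0L) {
    rlang::abort("`labels` must have a `label` or `informative` column.")
  }
  positives <- labels$read_name[!is.na(labels[[lab_col[1]]]) &
    labels[[lab_col[1]]] == 1L]
  split_names <- unique(as.character(split_names))
  dplyr::bind_rows(
    tibble::tibble(read_name = split_names, provenance = "split_by_fast_aligner"),
    tibble::tibble(
      read_name = setdiff(unique(positives), split_names),
      provenance = "classifier_positive"
    )
  ) |>
    dplyr::arrange(.data$read_name)
}

#' Harmonize aligner-specific SAM tags to a shared vocabulary
#'
#' Different long-read aligners emit different optional tags, and mixing their
#' records in one SAM breaks SAM-to-BAM conversion. Harmonization keeps a
#' configured allow-list of standard tags, drops every source-specific tag
#' (e.g. the fast aligner's `s1`/`s2`/`cm` chaining scores), and records the
#' originating aligner in a `source` column (emitted as an `sr:Z:` tag by
#' [write_sam()]). Mandatory SAM fields are untouched.
#'
#' @param aln Alignment tibble.
#' @param source `"fast_aligner"` or `"accurate_aligner"`.
#' @param allow Tags retained in the output vocabulary.
#' @return The harmonized alignment tibble.
#' @export
harmonize_tags <- function(aln, source = c("fast_aligner", "accurate_aligner"),
                           allow = c("NM", "AS", "SA", "MD")) {
  source <- match.arg(source)
  known <- c("s1", "s2", "cm", "NM", "AS", "SA", "MD")
  for (tg in setdiff(known, allow)) {
    if (tg %in% names(aln)) {
      aln[[tg]] <- if (tg %in% c("SA", "MD")) NA_character_ else NA_integer_
    }
  }
  if ("other_tags" %in% names(aln)) {
    aln$other_tags <- lapply(aln$other_tags, function(tags) {
      tags[substr(tags, 1L, 2L) %in% allow]
    })
  }
  aln$source <- rep(source, nrow(aln))
  aln
}

.parse_sq <- function(header) {
  sq <- header[startsWith(header, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  tibble::tibble(sn = sn, ln = ln)
}

#' Merge two aligners' alignment streams into one harmonized stream
#'
#' Both inputs must be aligned to the same reference: the `@SQ` (name, length)
#' pairs of the two headers have to agree, or the merge refuses. Records from
#' both streams are tag-harmonized (see [harmonize_tags()]) and concatenated
#' — no record is dropped or deduplicated; a read aligned by both aligners is
#' deliberately represented twice and resolved downstream by unique
#' supporting-read counting. `@PG` lines are concatenated and a new `@PG`
#' entry for this tool is appended.
#'
#' @param aln_a,aln_b Alignment tibbles carrying `"header"` attributes (from
#'   [read_sam()] or [synth_alignments()]).
#' @param source_a,source_b Provenance labels for the two streams.
#' @param allow Tag allow-list passed to [harmonize_tags()].
#' @return Merged alignment tibble with a merged `"header"` attribute.
#' @export
merge_alignments <- function(aln_a, aln_b,
                             source_a = "fast_aligner",
                             source_b = "accurate_aligner",
                             allow = c("NM", "AS", "SA", "MD")) {
  hdr_a <- attr(aln_a, "header") %||% character()
  hdr_b <- attr(aln_b, "header") %||% character()
  sq_a <- .parse_sq(hdr_a)
  sq_b <- .parse_sq(hdr_b)
  if (nrow(sq_a) > 0L && nrow(sq_b) > 0L) {
    a_key <- paste(sq_a$sn, sq_a$ln)
    b_key <- paste(sq_b$sn, sq_b$ln)
    if (!setequal(a_key, b_key)) {
      off <- c(setdiff(a_key, b_key), setdiff(b_key, a_key))
      rlang::abort(sprintf(
        "Reference-incompatible inputs: @SQ entries differ (%s).",
        paste(off, collapse = "; ")
      ))
    }
  }
  ha <- harmonize_tags(aln_a, source_a, allow = allow)
  hb <- harmonize_tags(aln_b, source_b, allow = allow)
  merged <- dplyr::bind_rows(ha, hb)
  hd <- hdr_a[startsWith(hdr_a, "@HD")]
  if (length(hd) == 0L) hd <- "@HD\tVN:1.6"
  pg <- c(
    hdr_a[startsWith(hdr_a, "@PG")], hdr_b[startsWith(hdr_b, "@PG")],
    sprintf("@PG\tID:lrsv\tPN:lrsv\tVN:%s",
            as.character(utils::packageVersion("lrsv")))
  )
  attr(merged, "header") <- c(hd[1], hdr_a[startsWith(hdr_a, "@SQ")], pg)
  merged
}
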
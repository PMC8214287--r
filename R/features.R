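#' Ordered feature schema for informative-read classification
#'
#' The per-read feature vector is a fixed, ordered 21-slot schema frozen under
#' `schema_version` `"lrsv-1"`: the five aligner tag scores (`s1`, `s2`, `cm`,
#' `NM`, `AS`), total inserted/deleted/mismatched bases, the longest
#' single-kind edit run with and without a one-match gap (per kind), soft-clip
#' lengths at both read ends, the four largest 100-bp-bin edit totals, and the
#' read length. All features are location-independent: none depends on the
#' mapping position or reference name.
#'
#' @return Character vector of the 21 feature column names, in schema order.
#' @export
lrsv_feature_names <- function() {
  c(
    "s1", "s2", "cm", "NM", "AS",
    "ins_bases", "del_bases", "mismatch_bases",
    "longest_del_run", "longest_ins_run", "longest_mismatch_run",
    "longest_del_run_gap1", "longest_ins_run_gap1", "longest_mismatch_run_gap1",
    "softclip_left", "softclip_right",
    "bin_top1", "bin_top2", "bin_top3", "bin_top4",
    "read_length"
  )
}

#' @rdname lrsv_feature_names
#' @export
lrsv_feature_schema <- function() "lrsv-1"

#' Build a one-row alignment-record tibble
#'
#' Convenience constructor for a single SAM-like alignment record in the
#' tibble layout the feature functions consume (`read_sam()` and
#' `synth_alignments()` produce the same layout).
#'
#' @param cigar CIGAR string.
#' @param read_name Read name.
#' @param flag SAM flag (integer bitfield).
#' @param rname,pos,mapq Mapping fields (1-based `pos`).
#' @param MD,SA Optional string tags (`NA` when absent).
#' @param NM,AS,s1,s2,cm Optional integer tags (`NA` when absent).
#' @param seq_len Read length in bases; defaults to the length implied by the
#'   read-consuming CIGAR ops.
#' @return A one-row tibble of alignment-record columns.
#' @examples
#' alignment_record("5S10M2I8M3D10M4S", MD = "18^ACG10")
#' @export
alignment_record <- function(cigar, read_name = "read1", flag = 0L,
                             rname = "chr1", pos = 1L, mapq = 60L,
                             MD = NA_character_, NM = NA_integer_,
                             AS = NA_integer_, s1 = NA_integer_,
                             s2 = NA_integer_, cm = NA_integer_,
                             SA = NA_character_, seq_len = NULL) {
  if (is.null(seq_len)) {
    seq_len <- if (cigar == "*") 0L else .cigar_read_len(parse_cigar(cigar))
  }
  tibble::tibble(
    read_name = read_name, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
    seq_len = as.integer(seq_len),
    s1 = as.integer(s1), s2 = as.integer(s2), cm = as.integer(cm),
    NM = as.integer(NM), AS = as.integer(AS),
    SA = as.character(SA), MD = as.character(MD)
  )
}

.aln_col <- function(aln, name, default) {
  if (name %in% names(aln)) aln[[name]] else rep(default, nrow(aln))
}

.is_unmapped <- function(flag, cigar) {
  bitwAnd(as.integer(flag), 4L) != 0L | cigar == "*"
}

# All positional edit features for one record, from its column-level events.
.rec_edit_stats <- function(cigar, md, nm, read_len, bin_size = 100L, k = 4L) {
  ev <- .alignment_events(cigar, md)
  mismatch_known <- attr(ev, "mismatch_known")
  ins_bases <- sum(ev$len[ev$state == "ins"])
  del_bases <- sum(ev$len[ev$state == "del"])
  mismatch_bases <- if (mismatch_known) {
    sum(ev$len[ev$state == "mismatch"])
  } else if (!is.na(nm)) {
    max(0L, as.integer(nm) - ins_bases - del_bases)
  } else {
    0L
  }
  runs <- lapply(c(del = "del", ins = "ins", mismatch = "mismatch"), function(kind) {
    c(
      plain = .longest_state_run(ev, kind, allow_one_match = FALSE),
      gap1 = .longest_state_run(ev, kind, allow_one_match = TRUE)
    )
  })
  bins <- .bin_totals(ev, read_len = read_len, bin_size = bin_size)
  top <- sort(bins, decreasing = TRUE)
  top <- c(top, integer(k))[seq_len(k)]
  list(
    ins_bases = ins_bases, del_bases = del_bases, mismatch_bases = mismatch_bases,
    longest_del_run = runs$del[["plain"]], longest_ins_run = runs$ins[["plain"]],
    longest_mismatch_run = runs$mismatch[["plain"]],
    longest_del_run_gap1 = runs$del[["gap1"]], longest_ins_run_gap1 = runs$ins[["gap1"]],
    longest_mismatch_run_gap1 = runs$mismatch[["gap1"]],
    bin_top = as.integer(top)
  )
}

# Longest run of one state over the event table; with allow_one_match, runs
# separated by exactly one matched base are joined (the match adds 0).
.longest_state_run <- function(ev, state, allow_one_match = FALSE) {
  st <- ev$state
  ln <- ev$len
  if (!allow_one_match) {
    hits <- ln[st == state]
    return(if (length(hits)) max(hits) else 0L)
  }
  best <- 0L
  cur <- 0L
  n <- length(st)
  i <- 1L
  while (i <= n) {
    if (st[i] == state) {
      cur <- cur + ln[i]
      best <- max(best, cur)
    } else if (st[i] == "match" && ln[i] == 1L && i < n && st[i + 1L] == state) {
      # bridge: contributes nothing, run continues
    } else {
      cur <- 0L
    }
    i <- i + 1L
  }
  best
}

# Per-bin edit totals over read coordinates. Inserted and mismatched bases are
# charged per base to the bin of their read offset; a deletion consumes no
# read bases, so its full length is charged to the bin of the read offset at
# which it occurs (clamped into the read for end deletions).
.bin_totals <- function(ev, read_len, bin_size = 100L) {
  if (bin_size <= 0L) rlang::abort("`bin_size` must be positive.")
  nbins <- max(1L, ceiling(read_len / bin_size))
  totals <- numeric(nbins)
  for (i in seq_len(nrow(ev))) {
    s <- ev$state[i]
    if (s == "ins" || s == "mismatch") {
      offs <- seq.int(ev$start[i], length.out = ev$len[i])
      idx <- pmin(offs %/% bin_size + 1L, nbins)
      tb <- tabulate(idx, nbins)
      totals <- totals + tb
    } else if (s == "del") {
      idx <- min(max(ev$start[i], 0L), max(read_len - 1L, 0L)) %/% bin_size + 1L
      idx <- min(idx, nbins)
      totals[idx] <- totals[idx] + ev$len[i]
    }
  }
  as.integer(totals)
}

.warn_unmapped <- function(read_name) {
  rlang::warn(sprintf(
    "Unmapped record(s) (%s): edit features are defined empty (all zero).",
    paste(utils::head(read_name, 3L), collapse = ", ")
  ))
}

#' Count inserted, deleted, and mismatched bases per alignment record
#'
#' Insertions and deletions come from the CIGAR; mismatches from `=`/`X` CIGAR
#' ops when present, else from walking the MD tag, else recovered as
#' `max(0, NM - ins - del)` when only `NM` is available.
#'
#' @param aln Alignment tibble (columns `cigar`, optionally `read_name`,
#'   `flag`, `MD`, `NM`).
#' @return Tibble with one row per record: `read_name`, `ins_bases`,
#'   `del_bases`, `mismatch_bases`.
#' @examples
#' count_edit_ops(alignment_record("5S10M2I8M3D10M4S", MD = "18^ACG10"))
#' @export
count_edit_ops <- function(aln) {
  stopifnot(is.data.frame(aln), "cigar" %in% names(aln))
  read_name <- .aln_col(aln, "read_name", NA_character_)
  flag <- .aln_col(aln, "flag", 0L)
  md <- .aln_col(aln, "MD", NA_character_)
  nm <- .aln_col(aln, "NM", NA_integer_)
  unmapped <- .is_unmapped(flag, aln$cigar)
  if (any(unmapped)) .warn_unmapped(read_name[unmapped])
  rows <- purrr::pmap(
    list(aln$cigar, md, nm, unmapped),
    function(cg, m, n, um) {
      if (um) {
        return(c(ins_bases = 0L, del_bases = 0L, mismatch_bases = 0L))
      }
      ev <- .alignment_events(cg, m)
      ins <- sum(ev$len[ev$state == "ins"])
      del <- sum(ev$len[ev$state == "del"])
      mm <- if (attr(ev, "mismatch_known")) {
        sum(ev$len[ev$state == "mismatch"])
      } else if (!is.na(n)) max(0L, as.integer(n) - ins - del) else 0L
      c(ins_bases = ins, del_bases = del, mismatch_bases = mm)
    }
  )
  dplyr::bind_cols(
    tibble::tibble(read_name = read_name),
    tibble::as_tibble(do.call(rbind, rows))
  )
}

#' Longest single-kind edit run per alignment record
#'
#' The longest run of consecutive bases of one edit kind (insertion, deletion,
#' or mismatch) along the alignment, measured in bases. With
#' `allow_one_match = TRUE`, two runs separated by exactly one matched base
#' are joined; the bridging match contributes nothing to the run value.
#'
#' @inheritParams count_edit_ops
#' @param kind One of `"ins"`, `"del"`, `"mismatch"`.
#' @param allow_one_match Join runs across a single matched base.
#' @return Tibble with `read_name` and `longest_run` (bases).
#' @examples
#' longest_run(alignment_record("4M1D1M2D5M"), kind = "del")
#' longest_run(alignment_record("4M1D1M2D5M"), kind = "del", allow_one_match = TRUE)
#' @export
longest_run <- function(aln, kind = c("ins", "del", "mismatch"),
                        allow_one_match = FALSE) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(aln), "cigar" %in% names(aln))
  read_name <- .aln_col(aln, "read_name", NA_character_)
  flag <- .aln_col(aln, "flag", 0L)
  md <- .aln_col(aln, "MD", NA_character_)
  unmapped <- .is_unmapped(flag, aln$cigar)
  if (any(unmapped)) .warn_unmapped(read_name[unmapped])
  vals <- purrr::pmap_int(
    list(aln$cigar, md, unmapped),
    function(cg, m, um) {
      if (um) return(0L)
      as.integer(.longest_state_run(.alignment_events(cg, m), kind, allow_one_match))
    }
  )
  tibble::tibble(read_name = read_name, longest_run = vals)
}

#' Soft-clip lengths at the two read ends
#'
#' @inheritParams count_edit_ops
#' @return Tibble with `read_name`, `softclip_left`, `softclip_right`
#'   (bases; 0 where absent; hard clips are ignored).
#' @examples
#' softclip_ends(alignment_record("5S10M2I8M3D10M4S"))
#' @export
softclip_ends <- function(aln) {
  stopifnot(is.data.frame(aln), "cigar" %in% names(aln))
  read_name <- .aln_col(aln, "read_name", NA_character_)
  vals <- purrr::map(aln$cigar, function(cg) {
    if (cg == "*") return(c(0L, 0L))
    ops <- parse_cigar(cg)
    ops <- ops[ops$op != "H", , drop = FALSE]
    n <- nrow(ops)
    left <- if (n > 0L && ops$op[1] == "S") ops$length[1] else 0L
    right <- if (n > 1L && ops$op[n] == "S") ops$length[n] else 0L
    c(left, right)
  })
  tibble::tibble(
    read_name = read_name,
    softclip_left = purrr::map_int(vals, 1L),
    softclip_right = purrr::map_int(vals, 2L)
  )
}

#' Largest binned edit totals per alignment record
#'
#' The read is partitioned into consecutive `bin_size`-bp bins over read
#' coordinates; every inserted, deleted, and mismatched base is charged to a
#' bin (deletion runs to the bin of the read offset where they occur), and the
#' `k` largest bin totals are returned in descending order, zero-padded when
#' the read has fewer than `k` bins.
#'
#' @inheritParams count_edit_ops
#' @param bin_size Bin width in read bases (default 100).
#' @param k Number of top bins to report (default 4).
#' @return Tibble with `read_name` and `bin_top1` ... `bin_top<k>`.
#' @examples
#' bin_top_counts(alignment_record("120M5I130M", MD = "10A9C229"))
#' @export
bin_top_counts <- function(aln, bin_size = 100L, k = 4L) {
  if (bin_size <= 0L || k <= 0L) {
    rlang::abort("`bin_size` and `k` must be positive integers.")
  }
  stopifnot(is.data.frame(aln), "cigar" %in% names(aln))
  read_name <- .aln_col(aln, "read_name", NA_character_)
  flag <- .aln_col(aln, "flag", 0L)
  md <- .aln_col(aln, "MD", NA_character_)
  seq_len_col <- .aln_col(aln, "seq_len", NA_integer_)
  unmapped <- .is_unmapped(flag, aln$cigar)
  if (any(unmapped)) .warn_unmapped(read_name[unmapped])
  rows <- purrr::pmap(
    list(aln$cigar, md, seq_len_col, unmapped),
    function(cg, m, sl, um) {
      if (um) return(integer(k))
      if (is.na(sl)) sl <- .cigar_read_len(parse_cigar(cg))
      ev <- .alignment_events(cg, m)
      top <- sort(.bin_totals(ev, read_len = sl, bin_size = bin_size), decreasing = TRUE)
      c(top, integer(k))[seq_len(k)]
    }
  )
  out <- tibble::as_tibble(do.call(rbind, rows), .name_repair = "minimal")
  names(out) <- paste0("bin_top", seq_len(k))
  dplyr::bind_cols(tibble::tibble(read_name = read_name), out)
}

#' Extract the per-read feature vector for informative-read classification
#'
#' Computes the 21-slot ordered feature schema (see [lrsv_feature_names()])
#' for every read in an alignment tibble. Features come from the primary
#' record only (secondary/supplementary records inform [is_split()] but not
#' the vector); missing optional tags (`s1`, `s2`, `cm`, `AS`) default to 0,
#' and `NM` falls back to `ins + del + mismatch` when absent. All features are
#' location-independent.
#'
#' @param aln Alignment tibble, possibly several records per read.
#' @param bin_size,k Binning parameters passed through to the bin features.
#' @return Tibble with `read_name` plus the 21 feature columns, carrying a
#'   `schema_version` attribute.
#' @examples
#' extract_features(alignment_record("50M", MD = "50", NM = 0L, AS = 90L, s1 = 100L))
#' @export
extract_features <- function(aln, bin_size = 100L, k = 4L) {
  stopifnot(is.data.frame(aln), all(c("read_name", "cigar") %in% names(aln)))
  if (nrow(aln) == 0L) rlang::abort("`aln` has no records.")
  flag <- .aln_col(aln, "flag", 0L)
  aln$flag <- as.integer(flag)
  for (col in c("s1", "s2", "cm", "NM", "AS")) {
    aln[[col]] <- as.integer(.aln_col(aln, col, NA_integer_))
  }
  aln$MD <- as.character(.aln_col(aln, "MD", NA_character_))
  aln$seq_len <- as.integer(.aln_col(aln, "seq_len", NA_integer_))

  primary <- aln |>
    dplyr::filter(bitwAnd(.data$flag, 0x900L) == 0L) |>
    dplyr::distinct(.data$read_name, .keep_all = TRUE)
  missing <- setdiff(unique(aln$read_name), primary$read_name)
  if (length(missing) > 0L) {
    rlang::warn(sprintf(
      "%d read(s) have no primary record and were dropped from the feature table.",
      length(missing)
    ))
  }
  if (nrow(primary) == 0L) rlang::abort("No primary alignment records in `aln`.")

  rows <- purrr::pmap(
    list(primary$cigar, primary$MD, primary$NM, primary$seq_len, primary$flag),
    function(cg, md, nm, sl, fl) {
      if (.is_unmapped(fl, cg)) {
        return(c(
          ins_bases = 0L, del_bases = 0L, mismatch_bases = 0L,
          longest_del_run = 0L, longest_ins_run = 0L, longest_mismatch_run = 0L,
          longest_del_run_gap1 = 0L, longest_ins_run_gap1 = 0L,
          longest_mismatch_run_gap1 = 0L, softclip_left = 0L, softclip_right = 0L,
          stats::setNames(integer(k), paste0("bin_top", seq_len(k))),
          read_length = if (is.na(sl)) 0L else sl
        ))
      }
      if (is.na(sl)) sl <- .cigar_read_len(parse_cigar(cg))
      st <- .rec_edit_stats(cg, md, nm, sl, bin_size = bin_size, k = k)
      ops <- parse_cigar(cg)
      ops_noH <- ops[ops$op != "H", , drop = FALSE]
      n <- nrow(ops_noH)
      scl <- if (n > 0L && ops_noH$op[1] == "S") ops_noH$length[1] else 0L
      scr <- if (n > 1L && ops_noH$op[n] == "S") ops_noH$length[n] else 0L
      c(
        ins_bases = st$ins_bases, del_bases = st$del_bases,
        mismatch_bases = st$mismatch_bases,
        longest_del_run = st$longest_del_run, longest_ins_run = st$longest_ins_run,
        longest_mismatch_run = st$longest_mismatch_run,
        longest_del_run_gap1 = st$longest_del_run_gap1,
        longest_ins_run_gap1 = st$longest_ins_run_gap1,
        longest_mismatch_run_gap1 = st$longest_mismatch_run_gap1,
        softclip_left = scl, softclip_right = scr,
        stats::setNames(st$bin_top, paste0("bin_top", seq_len(k))),
        read_length = sl
      )
    }
  )
  pos_feats <- tibble::as_tibble(do.call(rbind, rows))
  out <- tibble::tibble(
    read_name = primary$read_name,
    s1 = dplyr::coalesce(primary$s1, 0L),
    s2 = dplyr::coalesce(primary$s2, 0L),
    cm = dplyr::coalesce(primary$cm, 0L),
    NM = primary$NM,
    AS = dplyr::coalesce(primary$AS, 0L)
  ) |>
    dplyr::bind_cols(pos_feats) |>
    dplyr::mutate(NM = dplyr::coalesce(
      .data$NM,
      .data$ins_bases + .data$del_bases + .data$mismatch_bases
    )) |>
    dplyr::select(dplyr::all_of(c("read_name", lrsv_feature_names())))
  attr(out, "schema_version") <- lrsv_feature_schema()
  out
}

#' Flag split reads
#'
#' A read is split when any of its alignment records carries the supplementary
#' flag (bit 2048) or an `SA` tag — the SAM convention for chimeric/split
#' alignments. Secondary records (bit 256) alone do not make a read split.
#'
#' @param aln Alignment tibble, possibly several records per read.
#' @return Tibble with `read_name` and logical `split`.
#' @export
is_split <- function(aln) {
  stopifnot(is.data.frame(aln), all(c("read_name") %in% names(aln)))
  flag <- as.integer(.aln_col(aln, "flag", 0L))
  sa <- as.character(.aln_col(aln, "SA", NA_character_))
  tibble::tibble(
    read_name = aln$read_name,
    rec_split = bitwAnd(flag, 2048L) != 0L | !is.na(sa)
  ) |>
    dplyr::summarise(split = any(.data$rec_split), .by = "read_name")
}

#' Write / read a feature table as tab-separated text
#'
#' The on-disk form is a TSV with a header row: `read_name`, the 21 feature
#' columns in schema order, and optionally a `label` column.
#'
#' @param features Feature tibble from [extract_features()], optionally with a
#'   `label` column.
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature tibble.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- tibble::as_tibble(utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  ))
  need <- c("read_name", lrsv_feature_names())
  miss <- setdiff(need, names(out))
  if (length(miss) > 0L) {
    rlang::abort(sprintf(
      "Feature table at '%s' is missing column(s): %s.", path,
      paste(miss, collapse = ", ")
    ))
  }
  attr(out, "schema_version") <- lrsv_feature_schema()
  out
}
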
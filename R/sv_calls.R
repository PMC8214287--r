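#' Parse a structural-variant VCF into a call tibble
#'
#' Reads a caller's VCF 4.x (via vcfR) into one row per SV call. Supporting
#' read names are taken from the INFO key long-read callers use
#' (`RNAMES` by default, configurable); when only a support count is present
#' (`SUPPORT`/`RE`), the name set is empty and the count is kept. Breakend
#' (`BND`) mate pairs representing one translocation are collapsed to a
#' single `TRA` call; records without `SVTYPE` are skipped with a warning.
#'
#' @param path VCF path.
#' @param caller_id Identifier recorded in the `caller` column.
#' @param rnames_key INFO key holding comma-separated supporting read names.
#' @param count_keys INFO keys tried, in order, for a support count when no
#'   read names are present.
#' @return Tibble with columns `id`, `caller`, `sv_type`, `chrom`, `pos`,
#'   `end`, `chrom2`, `pos2`, `svlen`, `support_reads` (list), `support_count`.
#' @export
parse_sv_vcf <- function(path, caller_id,
                         rnames_key = "RNAMES",
                         count_keys = c("SUPPORT", "RE")) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || length(fix) == 0L) {
    return(.empty_sv_calls())
  }
  if (!is.matrix(fix)) {
    # single-record VCFs come back as a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0L) {
    return(.empty_sv_calls())
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    suppressWarnings(vcfR::extract.info(vcf, element = key))
  }
  svtype <- info_get("SVTYPE")
  if (any(is.na(svtype))) {
    rlang::warn(sprintf(
      "%d record(s) without SVTYPE skipped in '%s'.", sum(is.na(svtype)), path
    ))
  }
  end_raw <- info_get("END")
  svlen_raw <- info_get("SVLEN")
  chr2 <- info_get("CHR2")
  pos2_raw <- info_get("POS2")
  rn <- info_get(rnames_key)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (any(is.na(pos) & !is.na(svtype))) {
    rlang::abort(sprintf("Unparseable POS in '%s'.", path))
  }
  counts <- rep(NA_integer_, nrow(fix))
  for (k in count_keys) {
    v <- suppressWarnings(as.integer(info_get(k)))
    counts <- dplyr::coalesce(counts, v)
  }
  reads <- lapply(rn, function(x) {
    if (is.na(x)) character() else strsplit(x, ",", fixed = TRUE)[[1]]
  })
  svlen <- abs(suppressWarnings(as.integer(svlen_raw)))
  end <- suppressWarnings(as.integer(end_raw))

  calls <- tibble::tibble(
    id = fix$ID,
    caller = caller_id,
    sv_type = svtype,
    chrom = fix$CHROM,
    pos = pos,
    end = end,
    chrom2 = as.character(chr2),
    pos2 = suppressWarnings(as.integer(pos2_raw)),
    svlen = svlen,
    alt = fix$ALT,
    support_reads = reads,
    support_count = dplyr::coalesce(
      counts,
      vapply(reads, function(r) {
        if (length(r)) length(unique(r)) else NA_integer_
      }, integer(1))
    )
  ) |>
    dplyr::filter(!is.na(.data$sv_type))

  bnd <- calls$sv_type == "BND"
  if (any(bnd)) {
    calls <- dplyr::bind_rows(
      .collapse_breakends(calls[bnd, , drop = FALSE]),
      calls[!bnd, , drop = FALSE]
    )
  }
  calls |>
    dplyr::mutate(
      end = dplyr::case_when(
        .data$sv_type == "TRA" ~ NA_integer_,
        .data$sv_type == "INS" ~ .data$pos,
        !is.na(.data$end) ~ .data$end,
        !is.na(.data$svlen) ~ .data$pos + .data$svlen - 1L,
        TRUE ~ .data$pos
      ),
      pos2 = dplyr::if_else(
        .data$sv_type == "TRA" & is.na(.data$pos2), .data$end, .data$pos2
      )
    ) |>
    dplyr::select(-"alt") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

.empty_sv_calls <- function() {
  tibble::tibble(
    id = character(), caller = character(), sv_type = character(),
    chrom = character(), pos = integer(), end = integer(),
    chrom2 = character(), pos2 = integer(), svlen = integer(),
    support_reads = list(), support_count = integer()
  )
}

# Collapse BND mate pairs into single TRA calls. Mates are recognized by
# reciprocal (chrom, pos) <-> ALT coordinates; unpaired breakends become
# single-ended TRA calls at their own coordinates.
.collapse_breakends <- function(bnd) {
  mate <- stringr::str_match(bnd$alt, "[\\[\\]]([^:\\[\\]]+):([0-9]+)[\\[\\]]")
  bnd$m_chrom <- mate[, 2L]
  bnd$m_pos <- as.integer(mate[, 3L])
  used <- logical(nrow(bnd))
  out <- list()
  for (i in seq_len(nrow(bnd))) {
    if (used[i]) next
    j <- which(!used & seq_len(nrow(bnd)) != i &
      bnd$chrom == bnd$m_chrom[i] & bnd$pos == bnd$m_pos[i] &
      bnd$m_chrom == bnd$chrom[i] & bnd$m_pos == bnd$pos[i])
    used[i] <- TRUE
    row <- bnd[i, , drop = FALSE]
    if (length(j) > 0L) {
      j <- j[1L]
      used[j] <- TRUE
      # keep the lexicographically smaller end as the first breakpoint
      first_i <- (bnd$chrom[i] < bnd$chrom[j]) ||
        (bnd$chrom[i] == bnd$chrom[j] && bnd$pos[i] <= bnd$pos[j])
      a <- if (first_i) i else j
      b <- if (first_i) j else i
      row <- bnd[a, , drop = FALSE]
      row$chrom2 <- bnd$chrom[b]
      row$pos2 <- bnd$pos[b]
      both <- unique(c(bnd$support_reads[[a]], bnd$support_reads[[b]]))
      if (length(both)) {
        row$support_reads <- list(both)
        row$support_count <- length(both)
      } else {
        row$support_count <- max(bnd$support_count[c(a, b)], na.rm = TRUE)
      }
    } else {
      row$chrom2 <- bnd$m_chrom[i]
      row$pos2 <- bnd$m_pos[i]
    }
    row$sv_type <- "TRA"
    out[[length(out) + 1L]] <- row
  }
  dplyr::bind_rows(out) |> dplyr::select(-"m_chrom", -"m_pos")
}

#' Count unique supporting reads per call
#'
#' Merging two aligners' alignments makes one physical read able to support
#' an SV twice (once per aligner), so raw support counts double-count; the
#' filterable quantity is the number of distinct supporting read names. Calls
#' without names fall back to the caller's reported count.
#'
#' @param calls SV call tibble.
#' @return `calls` with a `support_unique` integer column.
#' @export
unique_support <- function(calls) {
  calls$support_unique <- purrr::map2_int(
    calls$support_reads, calls$support_count,
    function(r, n) {
      if (length(r) > 0L) length(unique(r)) else if (is.na(n)) 0L else n
    }
  )
  calls
}

#' Minimum supporting reads implied by sequencing coverage
#'
#' The default minimum support for an SV call is half the mean coverage —
#' at 10x coverage an SV must be supported by at least 5 reads. Odd coverage
#' rounds up (conservative against false positives).
#'
#' @param coverage Mean sequencing coverage (fold, > 0).
#' @return Integer minimum supporting-read count, `ceiling(coverage / 2)`.
#' @examples
#' min_support_threshold(10)
#' @export
min_support_threshold <- function(coverage) {
  if (!is.numeric(coverage) || length(coverage) != 1L || is.na(coverage) ||
    coverage <= 0) {
    rlang::abort("`coverage` must be a single positive number.")
  }
  as.integer(ceiling(coverage / 2))
}

#' Drop calls below the minimum unique support
#'
#' @param calls SV call tibble.
#' @param min_support Minimum unique supporting reads (>= 1), e.g. from
#'   [min_support_threshold()].
#' @return The retained calls (with `support_unique` populated).
#' @export
filter_min_support <- function(calls, min_support) {
  if (!is.numeric(min_support) || min_support < 1) {
    rlang::abort("`min_support` must be >= 1.")
  }
  unique_support(calls) |>
    dplyr::filter(.data$support_unique >= min_support)
}

.pair_distance <- function(type, pos_a, end_a, pos2_a, pos_b, end_b, pos2_b) {
  d1 <- abs(pos_a - pos_b)
  if (type == "TRA") {
    d2 <- if (!is.na(pos2_a) && !is.na(pos2_b)) abs(pos2_a - pos2_b) else 0L
  } else {
    d2 <- if (!is.na(end_a) && !is.na(end_b)) abs(end_a - end_b) else 0L
  }
  max(d1, d2)
}

#' Merge two SV callers' call sets, removing cross-caller redundancy
#'
#' Two calls of the same type on the same chromosome(s) whose breakpoints
#' differ by less than `window` bases (both `pos` and `end`; for
#' translocations, both breakpoints on their respective chromosomes) describe
#' the same event; each such pair is unified into the member with the larger
#' unique supporting-read count. Matching is greedy by descending unique
#' support (ties: named support before count-only, then caller id, then
#' position) and each call participates in at most one unification; unmatched
#' calls pass through unchanged.
#'
#' @param calls_a,calls_b Call tibbles from the two callers (e.g.
#'   [parse_sv_vcf()] output).
#' @param window Breakpoint-distance window in bases (default 50; merging
#'   requires distance strictly less than `window`).
#' @return Merged call tibble with a `callers` column; when both members of a
#'   unified pair carry read names, the names are unioned.
#' @export
merge_calls <- function(calls_a, calls_b, window = 50L) {
  if (!is.numeric(window) || window < 0) {
    rlang::abort("`window` must be a non-negative number.")
  }
  all_calls <- dplyr::bind_rows(calls_a, calls_b) |> unique_support()
  if (nrow(all_calls) == 0L) {
    out <- .empty_sv_calls()
    out$support_unique <- integer()
    out$callers <- character()
    return(out)
  }
  all_calls$has_names <- lengths(all_calls$support_reads) > 0L
  ord <- order(
    -all_calls$support_unique, -all_calls$has_names,
    all_calls$caller, all_calls$chrom, all_calls$pos
  )
  consumed <- logical(nrow(all_calls))
  keep <- list()
  for (i in ord) {
    if (consumed[i]) next
    consumed[i] <- TRUE
    row <- all_calls[i, , drop = FALSE]
    cand <- which(!consumed &
      all_calls$caller != row$caller &
      all_calls$sv_type == row$sv_type &
      all_calls$chrom == row$chrom &
      (is.na(all_calls$chrom2) == is.na(row$chrom2)) &
      (is.na(row$chrom2) | all_calls$chrom2 == row$chrom2))
    if (length(cand) > 0L) {
      dists <- vapply(cand, function(j) {
        .pair_distance(
          row$sv_type, row$pos, row$end, row$pos2,
          all_calls$pos[j], all_calls$end[j], all_calls$pos2[j]
        )
      }, numeric(1))
      ok <- cand[dists < window]
      if (length(ok) > 0L) {
        j <- ok[which.min(dists[dists < window])]
        consumed[j] <- TRUE
        row$callers <- paste(sort(unique(c(row$caller, all_calls$caller[j]))),
          collapse = ","
        )
        if (row$has_names && all_calls$has_names[j]) {
          u <- unique(c(row$support_reads[[1]], all_calls$support_reads[[j]]))
          row$support_reads <- list(u)
          row$support_count <- length(u)
          row$support_unique <- length(u)
        }
        keep[[length(keep) + 1L]] <- row
        next
      }
    }
    row$callers <- row$caller
    keep[[length(keep) + 1L]] <- row
  }
  dplyr::bind_rows(keep) |>
    dplyr::select(-"has_names") |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Score SV calls against a truth set
#'
#' A call is a true positive when an unmatched truth record of the same type
#' (and chromosome) lies within `tol` bases of its breakpoint(s) — strictly
#' less than `tol`, checked on both coordinates for two-breakpoint types.
#' Matching is greedy (descending support, nearest truth first) and
#' one-to-one. Sensitivity (recall) is TP / |truth|; FDR is FP / |calls|
#' (defined 0 when there are no calls).
#'
#' @param calls SV call tibble.
#' @param truth Truth tibble (e.g. from [inject_svs()]): columns `sv_type`,
#'   `chrom`, `pos`, and `end` / `chrom2`, `pos2` where applicable.
#' @param tol Breakpoint tolerance in bases (default 10).
#' @return An `sv_eval` object: summary statistics, per-type recall, and the
#'   TP/FP/FN record tibbles. Use [glance()] / [tidy()] to extract tibbles.
#' @export
match_to_truth <- function(calls, truth, tol = 10L) {
  if (!is.numeric(tol) || tol < 0) rlang::abort("`tol` must be >= 0.")
  calls <- unique_support(calls)
  n_calls <- nrow(calls)
  n_truth <- nrow(truth)
  truth_end <- if ("end" %in% names(truth)) truth$end else rep(NA_integer_, n_truth)
  truth_pos2 <- if ("pos2" %in% names(truth)) truth$pos2 else rep(NA_integer_, n_truth)
  truth_chrom2 <- if ("chrom2" %in% names(truth)) truth$chrom2 else rep(NA_character_, n_truth)
  matched_truth <- logical(n_truth)
  matched_call <- logical(n_calls)
  truth_of_call <- rep(NA_integer_, n_calls)
  ord <- if (n_calls > 0L) order(-calls$support_unique, calls$chrom, calls$pos) else integer()
  for (i in ord) {
    cand <- which(!matched_truth &
      truth$sv_type == calls$sv_type[i] &
      truth$chrom == calls$chrom[i])
    if (calls$sv_type[i] == "TRA") {
      cand <- cand[is.na(truth_chrom2[cand]) | is.na(calls$chrom2[i]) |
        truth_chrom2[cand] == calls$chrom2[i]]
    }
    if (length(cand) == 0L) next
    dists <- vapply(cand, function(j) {
      .pair_distance(
        calls$sv_type[i], calls$pos[i], calls$end[i], calls$pos2[i],
        truth$pos[j], truth_end[j], truth_pos2[j]
      )
    }, numeric(1))
    ok <- dists < tol
    if (!any(ok)) next
    j <- cand[ok][which.min(dists[ok])]
    matched_truth[j] <- TRUE
    matched_call[i] <- TRUE
    truth_of_call[i] <- j
  }
  tp <- calls[matched_call, , drop = FALSE]
  fp <- calls[!matched_call, , drop = FALSE]
  fn <- truth[!matched_truth, , drop = FALSE]
  recall <- if (n_truth > 0L) sum(matched_call) / n_truth else NA_real_
  fdr <- if (n_calls > 0L) nrow(fp) / n_calls else 0
  per_type <- truth |>
    dplyr::mutate(matched = matched_truth) |>
    dplyr::summarise(
      n_truth = dplyr::n(),
      n_detected = sum(.data$matched),
      recall = mean(.data$matched),
      .by = "sv_type"
    )
  structure(
    list(
      summary = tibble::tibble(
        n_truth = n_truth, n_calls = n_calls,
        tp = nrow(tp), fp = nrow(fp), fn = nrow(fn),
        recall = recall, fdr = fdr, tol = tol
      ),
      per_type = per_type,
      tp = tp, fp = fp, fn = fn
    ),
    class = "sv_eval"
  )
}

#' @export
print.sv_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<sv_eval> %d calls vs %d truth SVs (tol < %d bp): recall %.3f, FDR %.3f\n",
    s$n_calls, s$n_truth, s$tol, s$recall, s$fdr
  ))
  print(x$per_type)
  invisible(x)
}

#' @param x An `sv_eval` object.
#' @param ... Unused.
#' @rdname match_to_truth
#' @export
glance.sv_eval <- function(x, ...) x$summary

#' @rdname match_to_truth
#' @export
tidy.sv_eval <- function(x, ...) x$per_type

#' Plot per-type recall of an SV evaluation
#'
#' @param object An `sv_eval` object from [match_to_truth()].
#' @param ... Unused.
#' @return A ggplot bar chart of per-type recall.
#' @export
autoplot.sv_eval <- function(object, ...) {
  ggplot2::ggplot(
    object$per_type,
    ggplot2::aes(.data$sv_type, .data$recall)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "SV type", y = "Recall",
      title = sprintf(
        "Recall %.3f, FDR %.3f (breakpoint tolerance < %d bp)",
        object$summary$recall, object$summary$fdr, object$summary$tol
      )
    ) +
    ggplot2::theme_minimal()
}

#' Write an SV call tibble as a VCF
#'
#' Emits VCF 4.2 with `SVTYPE`, `END` (or `CHR2`/`POS2` for translocations),
#' `SVLEN`, `SUPPORT` (unique count), `CALLERS`, and `RNAMES` when read names
#' are available.
#'
#' @param calls SV call tibble.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path, contigs = NULL) {
  calls <- unique_support(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lrsv",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of the variant">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Chromosome of the second breakpoint">',
    '##INFO=<ID=POS2,Number=1,Type=Integer,Description="Position of the second breakpoint">',
    '##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description="Number of unique supporting reads">',
    '##INFO=<ID=CALLERS,Number=.,Type=String,Description="Callers reporting this variant">',
    '##INFO=<ID=RNAMES,Number=.,Type=String,Description="Names of supporting reads">'
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
      as.integer(contigs)
    ))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(calls))
  callers_col <- if ("callers" %in% names(calls)) calls$callers else calls$caller
  for (i in seq_len(nrow(calls))) {
    info <- c(sprintf("SVTYPE=%s", calls$sv_type[i]))
    if (calls$sv_type[i] == "TRA") {
      info <- c(info,
        sprintf("CHR2=%s", calls$chrom2[i]),
        sprintf("POS2=%d", calls$pos2[i])
      )
    } else if (!is.na(calls$end[i])) {
      info <- c(info, sprintf("END=%d", calls$end[i]))
    }
    if (!is.na(calls$svlen[i])) {
      info <- c(info, sprintf("SVLEN=%d", calls$svlen[i]))
    }
    info <- c(info, sprintf("SUPPORT=%d", calls$support_unique[i]))
    if (!is.null(callers_col) && !is.na(callers_col[i])) {
      info <- c(info, sprintf("CALLERS=%s", callers_col[i]))
    }
    if (length(calls$support_reads[[i]]) > 0L) {
      info <- c(info, sprintf(
        "RNAMES=%s",
        paste(unique(calls$support_reads[[i]]), collapse = ",")
      ))
    }
    id <- if ("id" %in% names(calls) && !is.na(calls$id[i])) calls$id[i] else sprintf("lrsv_%d", i)
    rows[i] <- paste(
      calls$chrom[i], calls$pos[i], id, "N",
      sprintf("<%s>", calls$sv_type[i]), ".", "PASS",
      paste(info, collapse = ";"),
      sep = "\t"
    )
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
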
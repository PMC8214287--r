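.BASES <- c("A", "C", "G", "T")

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
    collapse = ""
  ))
}

.rand_bases <- function(n, gc = 0.5) {
  paste(sample(.BASES, n,
    replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  ), collapse = "")
}

#' Generate a toy reference genome
#'
#' Seeded i.i.d. sequence with a requested GC fraction; deterministic per
#' seed. One or more contigs are returned as a tibble so the reference can be
#' piped into [inject_svs()] and [simulate_reads()].
#'
#' @param length Total length in bases (>= 1000), split evenly over contigs.
#' @param gc GC fraction in `[0, 1]`.
#' @param n_contigs Number of contigs (>= 2 required for translocations).
#' @param seed Integer seed.
#' @param fasta_path Optional path: when given, the reference is also written
#'   as FASTA.
#' @return Tibble with columns `contig`, `length`, `seq`.
#' @export
make_toy_reference <- function(length, gc = 0.5, n_contigs = 1L, seed = 1L,
                               fasta_path = NULL) {
  if (length < 1000L) rlang::abort("`length` must be at least 1000 bases.")
  if (!is.numeric(gc) || is.na(gc) || gc < 0 || gc > 1) {
    rlang::abort("`gc` must be a fraction in [0, 1].")
  }
  per <- rep(length %/% n_contigs, n_contigs)
  per[1] <- per[1] + length %% n_contigs
  ref <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      contig = sprintf("contig%d", seq_len(n_contigs)),
      length = as.integer(per),
      seq = vapply(per, .rand_bases, character(1), gc = gc)
    )
  })
  if (!is.null(fasta_path)) write_reference_fasta(ref, fasta_path)
  ref
}

#' @rdname make_toy_reference
#' @param reference Reference tibble.
#' @param path FASTA output path.
#' @export
write_reference_fasta <- function(reference, path, width = 70L) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(reference))) {
    writeLines(sprintf(">%s", reference$contig[i]), con)
    s <- reference$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname make_toy_reference
#' @param width Line width for FASTA output.
#' @export
read_reference_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- which(startsWith(lines, ">"))
  stopifnot(length(hdr) > 0L)
  ends <- c(hdr[-1L] - 1L, length(lines))
  tibble::tibble(
    contig = sub("\\s.*$", "", sub("^>", "", lines[hdr])),
    seq = vapply(seq_along(hdr), function(i) {
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")
    }, character(1))
  ) |>
    dplyr::mutate(length = nchar(.data$seq), .before = "seq")
}

#' Specify the structural variants to inject
#'
#' Per-type counts and a shared length range for the five SV classes. SVs are
#' by definition at least 50 bp, so the length range must start at 50 or
#' above. Translocations swap segments between two contigs and therefore
#' require a multi-contig reference.
#'
#' @param n_del,n_ins,n_inv,n_dup,n_tra Counts per SV type.
#' @param len_range Two-element integer range of SV lengths in bases
#'   (minimum >= 50).
#' @param min_gap Minimum distance in bases between injected SVs.
#' @param seed Integer seed for placement.
#' @return An `sv_spec` list.
#' @export
sv_spec <- function(n_del = 3L, n_ins = 3L, n_inv = 2L, n_dup = 2L,
                    n_tra = 0L, len_range = c(60L, 2000L), min_gap = 500L,
                    seed = 1L) {
  counts <- c(DEL = n_del, INS = n_ins, INV = n_inv, DUP = n_dup, TRA = n_tra)
  if (any(counts < 0L)) rlang::abort("SV counts must be >= 0.")
  if (len_range[1] < 50L) {
    rlang::abort("Structural variants are >= 50 bp: `len_range` must start at 50 or more.")
  }
  if (min_gap < 0L) rlang::abort("`min_gap` must be >= 0.")
  structure(
    list(
      counts = counts, len_range = as.integer(len_range),
      min_gap = as.integer(min_gap), seed = as.integer(seed)
    ),
    class = "sv_spec"
  )
}

# uniform draw from [lo, hi] that is safe for degenerate ranges
.sample_len <- function(lo, hi) {
  if (lo >= hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# reserve a non-overlapping interval of `len` (+gap padding) on some contig
.place_interval <- function(occupied, contig_lengths, len, gap, contig = NULL,
                            max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    ctg <- if (is.null(contig)) {
      sample(names(contig_lengths), 1L, prob = contig_lengths)
    } else {
      contig
    }
    clen <- contig_lengths[[ctg]]
    if (clen < len + 2L * gap + 2L) next
    start <- sample.int(clen - len - 1L, 1L) + 1L
    end <- start + len - 1L
    occ <- occupied[[ctg]]
    clash <- !is.null(occ) && any(start - gap <= occ$end & end + gap >= occ$start)
    if (!clash) {
      return(list(contig = ctg, start = start, end = end))
    }
  }
  NULL
}

#' Inject structural variants into a reference
#'
#' Places non-overlapping DEL/INS/INV/DUP/TRA events on the reference and
#' applies them: deletions remove bases, insertions add random bases,
#' inversions reverse-complement in place, duplications insert a tandem copy,
#' and translocations swap two segments between two contigs. The truth table
#' records each event with exact 1-based breakpoints on the ORIGINAL
#' reference coordinates (with the inserted sequence for INS, so the altered
#' reference is fully reconstructible from original + truth).
#'
#' @param reference Reference tibble from [make_toy_reference()].
#' @param spec An [sv_spec()].
#' @param vcf_path,fasta_path Optional output paths for the truth VCF and the
#'   altered FASTA.
#' @return List with `altered` (reference tibble) and `truth` (tibble with
#'   `sv_id`, `sv_type`, `chrom`, `pos`, `end`, `svlen`, `chrom2`, `pos2`,
#'   `end2`, `ins_seq`).
#' @export
inject_svs <- function(reference, spec, vcf_path = NULL, fasta_path = NULL) {
  counts <- spec$counts
  if (counts[["TRA"]] > 0L && nrow(reference) < 2L) {
    rlang::abort("Translocations require a reference with at least 2 contigs.")
  }
  contig_lengths <- stats::setNames(reference$length, reference$contig)
  truth <- withr::with_seed(spec$seed, {
    occupied <- stats::setNames(
      vector("list", nrow(reference)), reference$contig
    )
    reserve <- function(p) {
      occupied[[p$contig]] <<- dplyr::bind_rows(
        occupied[[p$contig]], tibble::tibble(start = p$start, end = p$end)
      )
    }
    rows <- list()
    type_seq <- sample(rep(names(counts), counts))
    for (k in seq_along(type_seq)) {
      ty <- type_seq[k]
      len <- .sample_len(spec$len_range[1], spec$len_range[2])
      p <- .place_interval(occupied, contig_lengths, len, spec$min_gap)
      if (is.null(p)) {
        rlang::abort(sprintf(
          "Cannot place a %d bp %s without overlap: reference too small for the spec.",
          len, ty
        ))
      }
      reserve(p)
      row <- tibble::tibble(
        sv_id = sprintf("truth_%s_%d", ty, k), sv_type = ty,
        chrom = p$contig, pos = p$start, end = p$end, svlen = len,
        chrom2 = NA_character_, pos2 = NA_integer_, end2 = NA_integer_,
        ins_seq = NA_character_
      )
      if (ty == "INS") {
        # inserted after `pos`; event occupies no reference span
        row$end <- p$start
        row$ins_seq <- .rand_bases(len)
      } else if (ty == "TRA") {
        len2 <- .sample_len(spec$len_range[1], spec$len_range[2])
        other <- setdiff(reference$contig, p$contig)
        p2 <- .place_interval(occupied, contig_lengths, len2, spec$min_gap,
          contig = sample(other, 1L)
        )
        if (is.null(p2)) {
          rlang::abort("Cannot place the second translocation segment.")
        }
        reserve(p2)
        row$chrom2 <- p2$contig
        row$pos2 <- p2$start
        row$end2 <- p2$end
      }
      rows[[length(rows) + 1L]] <- row
    }
    dplyr::bind_rows(rows)
  })
  if (is.null(truth) || nrow(truth) == 0L) {
    truth <- tibble::tibble(
      sv_id = character(), sv_type = character(), chrom = character(),
      pos = integer(), end = integer(), svlen = integer(),
      chrom2 = character(), pos2 = integer(), end2 = integer(),
      ins_seq = character()
    )
  }
  truth <- dplyr::arrange(truth, .data$chrom, .data$pos)
  altered <- apply_svs(reference, truth)
  if (!is.null(vcf_path)) write_truth_vcf(truth, vcf_path, reference)
  if (!is.null(fasta_path)) write_reference_fasta(altered, fasta_path)
  list(altered = altered, truth = truth)
}

#' Apply a truth table of structural variants to a reference
#'
#' Reconstructs the altered reference from the original sequences plus the
#' truth coordinates (and inserted sequences). Events must be non-overlapping
#' on original coordinates.
#'
#' @param reference Original reference tibble.
#' @param truth Truth tibble as produced by [inject_svs()].
#' @return Altered reference tibble.
#' @export
apply_svs <- function(reference, truth) {
  seqs <- stats::setNames(reference$seq, reference$contig)
  edits <- list() # per contig: tibble(start, end, repl); end = start-1 inserts
  add_edit <- function(ctg, start, end, repl) {
    edits[[ctg]] <<- dplyr::bind_rows(
      edits[[ctg]],
      tibble::tibble(start = start, end = end, repl = repl)
    )
  }
  for (i in seq_len(nrow(truth))) {
    ty <- truth$sv_type[i]
    ctg <- truth$chrom[i]
    pos <- truth$pos[i]
    end <- truth$end[i]
    seg <- substr(seqs[[ctg]], pos, end)
    if (ty == "DEL") {
      add_edit(ctg, pos, end, "")
    } else if (ty == "INS") {
      add_edit(ctg, pos + 1L, pos, truth$ins_seq[i])
    } else if (ty == "INV") {
      add_edit(ctg, pos, end, .revcomp(seg))
    } else if (ty == "DUP") {
      add_edit(ctg, end + 1L, end, seg)
    } else if (ty == "TRA") {
      ctg2 <- truth$chrom2[i]
      seg2 <- substr(seqs[[ctg2]], truth$pos2[i], truth$end2[i])
      add_edit(ctg, pos, end, seg2)
      add_edit(ctg2, truth$pos2[i], truth$end2[i], seg)
    } else {
      rlang::abort(sprintf("Unknown SV type '%s'.", ty))
    }
  }
  out <- reference
  for (ctg in names(edits)) {
    ed <- dplyr::arrange(edits[[ctg]], dplyr::desc(.data$start))
    s <- seqs[[ctg]]
    for (j in seq_len(nrow(ed))) {
      s <- paste0(
        substr(s, 1L, ed$start[j] - 1L), ed$repl[j],
        substr(s, ed$end[j] + 1L, nchar(s))
      )
    }
    out$seq[out$contig == ctg] <- s
  }
  out$length <- nchar(out$seq)
  out
}

#' Write a truth table as a VCF
#'
#' @param truth Truth tibble from [inject_svs()].
#' @param path Output path.
#' @param reference Optional reference tibble for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path, reference = NULL) {
  calls <- truth |>
    dplyr::mutate(
      id = .data$sv_id, caller = "truth",
      support_count = NA_integer_
    )
  calls$support_reads <- rep(list(character()), nrow(calls))
  contigs <- if (!is.null(reference)) {
    stats::setNames(reference$length, reference$contig)
  } else {
    NULL
  }
  write_sv_vcf(calls, path, contigs = contigs)
}

#' Simulate PacBio-like long reads from a reference
#'
#' Uniform start positions, truncated-normal read lengths, and independent
#' per-base substitution/insertion/deletion errors at the given rates
#' (long-read CLR error profiles run to roughly 15% total error). Read names
#' encode the true origin interval and strand
#' (`read<i>_<contig>_<start>_<end>_<strand>`) so downstream checks can
#' recover the truth. Reads are emitted until total bases reach
#' `coverage x reference length`; deterministic per seed.
#'
#' @param reference Reference tibble.
#' @param coverage Target mean coverage (fold, > 0).
#' @param mean_length,sd_length,min_length Read-length model in bases.
#' @param sub_rate,ins_rate,del_rate Per-base error fractions
#'   (sum <= 0.3).
#' @param seed Integer seed.
#' @param fastq_path Optional FASTQ output path.
#' @return Tibble with `read_name`, `contig`, `start`, `end`, `strand`,
#'   `length`, `seq`.
#' @export
simulate_reads <- function(reference, coverage = 10, mean_length = 8000,
                           sd_length = 1500, min_length = 200,
                           sub_rate = 0.05, ins_rate = 0.05, del_rate = 0.05,
                           seed = 1L, fastq_path = NULL) {
  if (coverage <= 0) rlang::abort("`coverage` must be positive.")
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || sum(rates) > 0.3) {
    rlang::abort("Error rates must be >= 0 and sum to at most 0.3.")
  }
  if (mean_length >= sum(reference$length)) {
    rlang::abort("`mean_length` must be smaller than the reference length.")
  }
  total_len <- sum(reference$length)
  target <- coverage * total_len
  reads <- withr::with_seed(as.integer(seed), {
    out <- list()
    emitted <- 0
    i <- 0L
    while (emitted < target) {
      i <- i + 1L
      ci <- sample.int(nrow(reference), 1L, prob = reference$length)
      clen <- reference$length[ci]
      rl <- max(min_length, round(stats::rnorm(1L, mean_length, sd_length)))
      start <- sample.int(clen, 1L)
      end <- min(start + rl - 1L, clen)
      raw <- substr(reference$seq[ci], start, end)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") raw <- .revcomp(raw)
      seq <- .apply_read_errors(raw, sub_rate, ins_rate, del_rate)
      emitted <- emitted + nchar(seq)
      out[[i]] <- tibble::tibble(
        read_name = sprintf(
          "read%05d_%s_%d_%d_%s", i, reference$contig[ci], start, end, strand
        ),
        contig = reference$contig[ci], start = start, end = end,
        strand = strand, length = nchar(seq), seq = seq
      )
    }
    dplyr::bind_rows(out)
  })
  if (!is.null(fastq_path)) {
    lines <- as.vector(rbind(
      paste0("@", reads$read_name),
      reads$seq,
      "+",
      strrep("I", reads$length)
    ))
    writeLines(lines, fastq_path)
  }
  reads
}

.apply_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- stats::runif(n)
  is_del <- u < del_rate
  is_sub <- !is_del & u < del_rate + sub_rate
  is_ins <- !is_del & !is_sub & u < del_rate + sub_rate + ins_rate
  if (any(is_sub)) {
    # substitute with a uniformly chosen different base
    orig <- chars[is_sub]
    repl <- vapply(orig, function(b) sample(setdiff(.BASES, b), 1L),
      character(1), USE.NAMES = FALSE
    )
    chars[is_sub] <- repl
  }
  piece <- ifelse(is_del, "", chars)
  if (any(is_ins)) {
    piece[is_ins] <- paste0(
      piece[is_ins], sample(.BASES, sum(is_ins), replace = TRUE)
    )
  }
  paste(piece, collapse = "")
}

# --- synthetic alignment records with known informative labels -------------

# Build CIGAR + MD (+ derived counts) from an alignment plan: parallel
# vectors of segment types in {S, M, X, I, D} and lengths, alignment order.
.plan_to_record <- function(type, len) {
  # merge adjacent same-type segments first (keeps CIGAR and MD consistent)
  if (length(type) > 1L) {
    keep <- c(TRUE, type[-1L] != type[-length(type)])
    grp <- cumsum(keep)
    len <- as.integer(rowsum(len, grp))
    type <- type[keep]
  }
  # CIGAR: X folds into M (aligner M-style output)
  cig_op <- ifelse(type == "X", "M", type)
  keep <- c(TRUE, cig_op[-1L] != cig_op[-length(cig_op)])
  grp <- cumsum(keep)
  cigar <- paste0(as.integer(rowsum(len, grp)), cig_op[keep], collapse = "")
  # MD walk over M/X/D
  md <- vector("list", length(type) + 1L)
  runlen <- 0L
  for (i in seq_along(type)) {
    ty <- type[i]
    if (ty == "M") {
      runlen <- runlen + len[i]
    } else if (ty == "X") {
      bases <- sample(.BASES, len[i], replace = TRUE)
      md[[i]] <- paste0(
        c(runlen, rep(0L, len[i] - 1L)), bases,
        collapse = ""
      )
      runlen <- 0L
    } else if (ty == "D") {
      md[[i]] <- paste0(runlen, "^", .rand_bases(len[i]))
      runlen <- 0L
    }
  }
  md[[length(type) + 1L]] <- as.character(runlen)
  list(
    cigar = cigar, md = paste(unlist(md), collapse = ""),
    seq_len = sum(len[type %in% c("S", "M", "X", "I")]),
    nm = sum(len[type %in% c("X", "I", "D")])
  )
}

# Random middle section: small edits separated by match blocks of at least
# 3 bases (so one-match-gap joining cannot chain background edits).
# Returns list(type, len) vectors.
.random_middle_plan <- function(aligned_read_bases, n_ins, n_del, n_mm,
                                max_edit_len) {
  ev_type <- c(rep("I", n_ins), rep("D", n_del), rep("X", n_mm))
  ev_len <- c(
    sample.int(max_edit_len, n_ins, replace = TRUE),
    sample.int(max_edit_len, n_del, replace = TRUE),
    rep(1L, n_mm)
  )
  if (length(ev_type) > 1L) {
    perm <- sample.int(length(ev_type))
    ev_type <- ev_type[perm]
    ev_len <- ev_len[perm]
  }
  min_match <- 3L
  read_bases <- function(ty, ln) sum(ln[ty %in% c("I", "X")])
  # too many edits for the span: drop events until they fit
  while (length(ev_type) > 0L &&
    aligned_read_bases - read_bases(ev_type, ev_len) <
      (length(ev_type) + 1L) * min_match) {
    ev_type <- ev_type[-length(ev_type)]
    ev_len <- ev_len[-length(ev_len)]
  }
  ne <- length(ev_type)
  match_total <- aligned_read_bases - read_bases(ev_type, ev_len)
  # random composition of match_total into ne + 1 parts, each >= min_match
  extra <- match_total - (ne + 1L) * min_match
  cuts <- if (ne > 0L) {
    sort(sample.int(extra + 1L, ne, replace = TRUE) - 1L)
  } else {
    integer()
  }
  parts <- diff(c(0L, cuts, extra)) + min_match
  type <- character(2L * ne + 1L)
  len <- integer(2L * ne + 1L)
  odd <- seq(1L, 2L * ne + 1L, by = 2L)
  type[odd] <- "M"
  len[odd] <- parts
  if (ne > 0L) {
    even <- seq(2L, 2L * ne, by = 2L)
    type[even] <- ev_type
    len[even] <- ev_len
  }
  list(type = type, len = len)
}

#' Generate synthetic alignment records with known informative labels
#'
#' Emulates a fast aligner's SAM output without running one: each read gets a
#' primary record with mutually consistent CIGAR, MD, NM, and read length,
#' plus plausible chaining-score tags (`s1`, `s2`, `cm`, `AS`). A configured
#' fraction of reads is generated "informative" under a stated generative
#' rule — informative reads carry a large soft-clip (total > 200 bases) or a
#' long deletion run (> 40 bases), the alignment footprints of a missed SV
#' breakpoint — while background reads carry only small scattered edits well
#' inside those margins. A further fraction is emitted as split (supplementary
#' record + `SA` tag), mirroring reads the fast aligner itself splits.
#'
#' @param n Number of reads.
#' @param informative_fraction Fraction of informative reads (default 1%).
#' @param split_fraction Fraction of split reads (default 0.5%).
#' @param mean_length,sd_length Read-length model (bases).
#' @param seed Integer seed.
#' @return List with `alignments` (alignment tibble with a `"header"`
#'   attribute) and `labels` (tibble `read_name`, `label`, `split`).
#' @export
synth_alignments <- function(n, informative_fraction = 0.01,
                             split_fraction = 0.005,
                             mean_length = 8000, sd_length = 1500,
                             seed = 1L) {
  withr::with_seed(as.integer(seed), {
    name <- sprintf("synth%06d", seq_len(n))
    rl <- pmax(1500L, as.integer(round(stats::rnorm(n, mean_length, sd_length))))
    informative <- stats::runif(n) < informative_fraction
    split <- !informative & stats::runif(n) < split_fraction
    cigar <- md <- character(n)
    seq_len_v <- nm_v <- integer(n)
    pos <- sample.int(9e6, n, replace = TRUE)
    flag <- ifelse(split, 0L, sample(c(0L, 16L), n, replace = TRUE))
    for (i in seq_len(n)) {
      # background clip sizes; informative reads may get a breakpoint clip
      scl <- sample.int(60L, 1L) - 1L
      scr <- sample.int(60L, 1L) - 1L
      big_del <- 0L
      if (informative[i]) {
        mode <- sample(c("clip", "del", "both"), 1L)
        if (mode %in% c("clip", "both")) {
          big <- sample(260:800, 1L)
          if (stats::runif(1L) < 0.5) scl <- big else scr <- big
        }
        if (mode %in% c("del", "both")) {
          big_del <- sample(60:300, 1L)
        }
      }
      aligned <- rl[i] - scl - scr
      middle <- .random_middle_plan(
        aligned_read_bases = aligned,
        n_ins = stats::rpois(1L, 3), n_del = stats::rpois(1L, 3),
        n_mm = stats::rpois(1L, 6), max_edit_len = 8L
      )
      if (big_del > 0L) {
        # place the long deletion run after a match segment
        m_idx <- which(middle$type == "M")
        at <- m_idx[sample.int(length(m_idx), 1L)]
        middle$type <- append(middle$type, "D", after = at)
        middle$len <- append(middle$len, big_del, after = at)
      }
      type <- c(if (scl > 0L) "S", middle$type, if (scr > 0L) "S")
      len <- c(if (scl > 0L) scl, middle$len, if (scr > 0L) scr)
      rec <- .plan_to_record(type, len)
      cigar[i] <- rec$cigar
      md[i] <- rec$md
      seq_len_v[i] <- rec$seq_len
      nm_v[i] <- rec$nm
    }
    s1 <- as.integer(round(0.9 * seq_len_v + stats::rnorm(n, 0, 50)))
    aln <- tibble::tibble(
      read_name = name, flag = flag, rname = "chr1", pos = pos, mapq = 60L,
      cigar = cigar, rnext = "*", pnext = 0L, tlen = 0L,
      seq = "*", qual = "*", seq_len = seq_len_v,
      s1 = s1,
      s2 = as.integer(pmax(0, round(stats::rnorm(n, 80, 30)))),
      cm = as.integer(round(seq_len_v / 50)),
      NM = nm_v, AS = as.integer(s1 - nm_v),
      SA = ifelse(split, "chr1,9500000,+,100S900M,60,5;", NA_character_),
      MD = md
    )
    aln$other_tags <- rep(list(character()), n)
    if (any(split)) {
      sup <- aln[split, , drop = FALSE]
      sup$flag <- 2048L
      sup$pos <- sup$pos + 5000L
      sup$cigar <- sprintf("%dS%dM", sup$seq_len - 900L, 900L)
      sup$s1 <- NA_integer_
      sup$s2 <- NA_integer_
      sup$cm <- NA_integer_
      sup$NM <- 0L
      sup$AS <- 800L
      sup$SA <- NA_character_
      sup$MD <- "900"
      aln <- dplyr::bind_rows(aln, sup) |> dplyr::arrange(.data$read_name, .data$flag)
    }
    attr(aln, "header") <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:10000000")
    list(
      alignments = aln,
      labels = tibble::tibble(
        read_name = name, label = as.integer(informative), split = split
      )
    )
  })
}

#' Generate a pair of caller VCFs with a known merge outcome
#'
#' Each simulated caller reports the truth set with seeded breakpoint jitter,
#' per-call dropout, and supporting-read names drawn from a simple support
#' model. The expected post-merge call set is computed analytically from the
#' construction (which truth events survive in which caller, and which caller
#' wins on support) and returned for assertion.
#'
#' @param truth Truth tibble from [inject_svs()].
#' @param jitter_a,jitter_b Maximum absolute breakpoint shift per caller
#'   (bases; shifts are drawn uniformly from `-jitter..jitter`). Keep below
#'   half the merge window so intended merges stay inside it.
#' @param dropout_a,dropout_b Per-call dropout probability per caller.
#' @param mean_support Mean of the (>= 1) Poisson support-count model.
#' @param seed Integer seed.
#' @param vcf_a_path,vcf_b_path Optional VCF output paths.
#' @return List with `calls_a`, `calls_b` (call tibbles), and `expected`
#'   (tibble of the analytically expected merged set: `sv_id`, `sv_type`,
#'   `winner_caller`, `n_callers`).
#' @export
synth_vcf_pair <- function(truth, jitter_a = 5L, jitter_b = 5L,
                           dropout_a = 0, dropout_b = 0, mean_support = 6,
                           seed = 1L, vcf_a_path = NULL, vcf_b_path = NULL) {
  jit <- function(x, j) {
    if (j == 0L) x else x + sample(seq(-j, j), length(x), replace = TRUE)
  }
  withr::with_seed(as.integer(seed), {
    make_caller <- function(caller, jitter, dropout) {
      kept <- truth[stats::runif(nrow(truth)) >= dropout, , drop = FALSE]
      if (nrow(kept) == 0L) {
        out <- .empty_sv_calls()
        out$sv_id <- character()
        return(out)
      }
      support_n <- 1L + stats::rpois(nrow(kept), mean_support - 1)
      tibble::tibble(
        id = sprintf("%s_%s", caller, kept$sv_id),
        sv_id = kept$sv_id,
        caller = caller,
        sv_type = kept$sv_type,
        chrom = kept$chrom,
        pos = pmax(1L, jit(kept$pos, jitter)),
        end = dplyr::if_else(
          kept$sv_type == "TRA", NA_integer_,
          pmax(1L, jit(kept$end, jitter))
        ),
        chrom2 = kept$chrom2,
        pos2 = dplyr::if_else(
          is.na(kept$pos2), NA_integer_, pmax(1L, jit(kept$pos2, jitter))
        ),
        svlen = kept$svlen,
        support_reads = lapply(support_n, function(k) {
          sample(sprintf("simread%05d", 1:2000), k)
        }),
        support_count = support_n
      )
    }
    calls_a <- make_caller("callerA", as.integer(jitter_a), dropout_a)
    calls_b <- make_caller("callerB", as.integer(jitter_b), dropout_b)
  })
  expected <- dplyr::bind_rows(calls_a, calls_b) |>
    unique_support() |>
    dplyr::summarise(
      sv_type = .data$sv_type[1],
      n_callers = dplyr::n(),
      winner_caller = .data$caller[order(
        -.data$support_unique, .data$caller
      )][1],
      support_unique = max(.data$support_unique),
      .by = "sv_id"
    )
  if (!is.null(vcf_a_path)) {
    write_sv_vcf(dplyr::select(calls_a, -"sv_id"), vcf_a_path)
  }
  if (!is.null(vcf_b_path)) {
    write_sv_vcf(dplyr::select(calls_b, -"sv_id"), vcf_b_path)
  }
  list(calls_a = calls_a, calls_b = calls_b, expected = expected)
}
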
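#' Parse a SAM CIGAR string
#'
#' Tokenizes a CIGAR string into its ordered sequence of operations. The
#' unmapped sentinel `"*"` yields a zero-row tibble.
#'
#' @param cigar A single CIGAR string (SAM grammar: `([0-9]+[MIDNSHP=X])+`
#'   or `"*"`).
#' @return A tibble with columns `op` (character, one of
#'   M, I, D, N, S, H, P, =, X) and `length` (integer), in original order.
#' @examples
#' parse_cigar("5S10M2I8M3D10M4S")
#' @export
parse_cigar <- function(cigar) {
  if (!is.character(cigar) || length(cigar) != 1L || is.na(cigar)) {
    rlang::abort("`cigar` must be a single non-NA character string.")
  }
  if (cigar == "*") {
    return(tibble::tibble(op = character(), length = integer()))
  }
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    rlang::abort(sprintf("Malformed CIGAR '%s': no valid token at position 1.", cigar))
  }
  lens <- attr(m, "match.length")
  # tokens must tile the whole string; report the first gap
  expected <- cumsum(c(1L, lens))
  starts <- c(as.integer(m), nchar(cigar) + 1L)
  bad <- which(starts != expected)
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "Malformed CIGAR '%s': unexpected character at position %d.",
      cigar, expected[bad[1]]
    ))
  }
  tok <- regmatches(cigar, list(m))[[1]]
  tibble::tibble(
    op = substr(tok, nchar(tok), nchar(tok)),
    length = as.integer(substr(tok, 1L, nchar(tok) - 1L))
  )
}

# Ops that consume read bases / reference bases (SAM spec)
.read_ops <- c("M", "I", "S", "=", "X")
.ref_ops <- c("M", "D", "N", "=", "X")
.aligned_ops <- c("M", "=", "X") # columns the MD tag walks over (plus ^-deletions)

# Parse an MD tag against a CIGAR op table.
# Returns 0-based read offsets of mismatched bases, validating deletion runs
# and the total aligned length against the CIGAR.
.md_mismatch_offsets <- function(ops, md) {
  tok <- regmatches(md, gregexpr("[0-9]+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  if (paste0(tok, collapse = "") != md) {
    rlang::abort(sprintf("Malformed MD tag '%s'.", md))
  }
  read_start <- cumsum(c(0L, ifelse(ops$op %in% .read_ops, ops$length, 0L)))
  aligned_idx <- which(ops$op %in% .aligned_ops)
  # read offset of every aligned column, in alignment order
  aligned_offsets <- unlist(lapply(aligned_idx, function(i) {
    seq.int(read_start[i], length.out = ops$length[i])
  }), use.names = FALSE)
  n_aligned <- length(aligned_offsets)
  cigar_dels <- ops$length[ops$op == "D"]

  p <- 0L # aligned columns consumed
  d <- 0L # deletion runs consumed
  mismatch_at <- integer()
  for (t in tok) {
    first <- substr(t, 1L, 1L)
    if (first >= "0" && first <= "9") {
      p <- p + as.integer(t)
    } else if (first == "^") {
      d <- d + 1L
      dlen <- nchar(t) - 1L
      if (d > length(cigar_dels) || cigar_dels[d] != dlen) {
        rlang::abort(sprintf(
          "MD tag '%s' inconsistent with CIGAR: deletion run %d has length %d in MD.",
          md, d, dlen
        ))
      }
    } else {
      p <- p + 1L
      if (p > n_aligned) {
        rlang::abort(sprintf("MD tag '%s' walks past the aligned length of the CIGAR.", md))
      }
      mismatch_at <- c(mismatch_at, aligned_offsets[p])
    }
  }
  if (p != n_aligned) {
    rlang::abort(sprintf(
      "MD tag '%s' covers %d aligned bases but the CIGAR has %d.", md, p, n_aligned
    ))
  }
  mismatch_at
}

# Split one aligned segment [start, start+len) into match/mismatch entries
# given the sorted mismatch offsets that fall inside it.
.split_aligned_segment <- function(start, len, mm) {
  if (length(mm) == 0L) {
    return(list(state = "match", len = len, start = start))
  }
  grp <- cumsum(c(1L, diff(mm) != 1L))
  runs_start <- tapply(mm, grp, min)
  runs_len <- tapply(mm, grp, length)
  st <- character()
  ln <- integer()
  be <- integer()
  cursor <- start
  for (g in seq_along(runs_start)) {
    if (runs_start[g] > cursor) {
      st <- c(st, "match"); ln <- c(ln, runs_start[g] - cursor); be <- c(be, cursor)
    }
    st <- c(st, "mismatch"); ln <- c(ln, runs_len[g]); be <- c(be, runs_start[g])
    cursor <- runs_start[g] + runs_len[g]
  }
  if (cursor < start + len) {
    st <- c(st, "match"); ln <- c(ln, start + len - cursor); be <- c(be, cursor)
  }
  list(state = st, len = as.integer(ln), start = as.integer(be))
}

# Column-level run-length view of one alignment record, in alignment order.
# States: clip, match, mismatch, ins, del, skip. `start` is the 0-based read
# offset of the entry's first read base (for del/skip: the next read base).
# attr "mismatch_known" says whether mismatch positions could be resolved
# (=/X ops or an MD tag); when FALSE, aligned columns are reported as match.
.alignment_events <- function(cigar, md = NA_character_) {
  ops <- if (is.data.frame(cigar)) cigar else parse_cigar(cigar)
  has_eqx <- any(ops$op %in% c("=", "X"))
  mm <- integer()
  mismatch_known <- TRUE
  if (!has_eqx) {
    if (!is.na(md)) {
      mm <- .md_mismatch_offsets(ops, md)
    } else {
      mismatch_known <- FALSE
    }
  }
  read_start <- cumsum(c(0L, ifelse(ops$op %in% .read_ops, ops$length, 0L)))

  st <- character(); ln <- integer(); be <- integer()
  push <- function(s, l, b) {
    st <<- c(st, s); ln <<- c(ln, as.integer(l)); be <<- c(be, as.integer(b))
  }
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; l <- ops$length[i]; b <- read_start[i]
    if (op == "S") {
      push("clip", l, b)
    } else if (op == "I") {
      push("ins", l, b)
    } else if (op == "D") {
      push("del", l, b)
    } else if (op == "N") {
      push("skip", l, b)
    } else if (op == "=") {
      push("match", l, b)
    } else if (op == "X") {
      push("mismatch", l, b)
    } else if (op == "M") {
      seg <- .split_aligned_segment(b, l, sort(mm[mm >= b & mm < b + l]))
      st <- c(st, seg$state); ln <- c(ln, seg$len); be <- c(be, seg$start)
    } # H, P carry no bases and break no runs of interest
  }
  # merge adjacent same-state entries so each run is a single row
  if (length(st) > 1L) {
    keep <- c(TRUE, st[-1L] != st[-length(st)])
    grp <- cumsum(keep)
    ln <- as.integer(tapply(ln, grp, sum))
    be <- as.integer(tapply(be, grp, min))
    st <- st[keep]
  }
  out <- tibble::tibble(state = st, len = ln, start = be)
  attr(out, "mismatch_known") <- mismatch_known
  out
}

# read length implied by a CIGAR (sum of read-consuming ops)
.cigar_read_len <- function(ops) {
  sum(ops$length[ops$op %in% .read_ops])
}
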
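# Independent brute-force oracles: everything here walks alignments base by
# base with explicit loops, sharing no code with the package internals.

# Tokenize a CIGAR by scanning characters one at a time.
oracle_cigar_tokens <- function(cigar) {
  ops <- character()
  lens <- integer()
  num <- ""
  for (ch in strsplit(cigar, "")[[1]]) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      ops <- c(ops, ch)
      lens <- c(lens, as.integer(num))
      num <- ""
    }
  }
  list(ops = ops, lens = lens)
}

# Expand an alignment into one entry per column: state in
# {clip, match, mismatch, ins, del, skip} plus the 0-based read offset the
# column sits at (for del/skip: the offset of the next read base).
oracle_columns <- function(cigar, md = NA_character_) {
  tok <- oracle_cigar_tokens(cigar)
  n_cols <- sum(tok$lens[tok$ops != "H" & tok$ops != "P"])
  state <- character(n_cols)
  read_off <- integer(n_cols)
  col <- 0L
  off <- 0L
  for (i in seq_along(tok$ops)) {
    op <- tok$ops[i]
    for (k in seq_len(tok$lens[i])) {
      if (op %in% c("M", "=", "X", "I", "S")) {
        col <- col + 1L
        state[col] <- switch(op,
          M = "match", "=" = "match", X = "mismatch", I = "ins", S = "clip"
        )
        read_off[col] <- off
        off <- off + 1L
      } else if (op %in% c("D", "N")) {
        col <- col + 1L
        state[col] <- if (op == "D") "del" else "skip"
        read_off[col] <- off
      }
      # H and P contribute no columns
    }
  }
  state <- state[seq_len(col)]
  read_off <- read_off[seq_len(col)]
  # overlay MD mismatches onto match columns (M-style CIGARs)
  if (!is.na(md) && !any(tok$ops %in% c("=", "X"))) {
    aligned_cols <- which(state %in% c("match", "mismatch"))
    ptr <- 0L
    i <- 1L
    chars <- strsplit(md, "")[[1]]
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch >= "0" && ch <= "9") {
        num <- ""
        while (i <= length(chars) && chars[i] >= "0" && chars[i] <= "9") {
          num <- paste0(num, chars[i])
          i <- i + 1L
        }
        ptr <- ptr + as.integer(num)
      } else if (ch == "^") {
        i <- i + 1L
        while (i <= length(chars) && chars[i] %in% LETTERS) i <- i + 1L
      } else {
        ptr <- ptr + 1L
        state[aligned_cols[ptr]] <- "mismatch"
        i <- i + 1L
      }
    }
  }
  data.frame(state = state, read_off = read_off)
}

oracle_counts <- function(cols) {
  c(
    ins = sum(cols$state == "ins"),
    del = sum(cols$state == "del"),
    mismatch = sum(cols$state == "mismatch")
  )
}

oracle_longest_run <- function(cols, kind, allow_one_match = FALSE) {
  st <- cols$state
  best <- 0L
  cur <- 0L
  i <- 1L
  n <- length(st)
  while (i <= n) {
    if (st[i] == kind) {
      cur <- cur + 1L
      if (cur > best) best <- cur
      i <- i + 1L
    } else if (allow_one_match && st[i] == "match" &&
      i > 1L && i < n && st[i - 1L] == kind &&
      st[i + 1L] == kind) {
      i <- i + 1L # single bridging match, contributes 0
    } else {
      cur <- 0L
      i <- i + 1L
    }
  }
  best
}

oracle_softclips <- function(cigar) {
  tok <- oracle_cigar_tokens(cigar)
  keep <- tok$ops != "H"
  ops <- tok$ops[keep]
  lens <- tok$lens[keep]
  left <- if (length(ops) > 0L && ops[1] == "S") lens[1] else 0L
  right <- if (length(ops) > 1L && ops[length(ops)] == "S") lens[length(ops)] else 0L
  c(left = left, right = right)
}

oracle_bin_tops <- function(cols, seq_len, bin_size = 100L, k = 4L) {
  states <- cols$state
  offs <- cols$read_off
  nbins <- max(1L, ceiling(seq_len / bin_size))
  totals <- integer(nbins)
  for (i in seq_along(states)) {
    st <- states[i]
    if (st %in% c("ins", "mismatch", "del")) {
      off <- offs[i]
      if (off > seq_len - 1L) off <- seq_len - 1L
      b <- off %/% bin_size + 1L
      if (b > nbins) b <- nbins
      totals[b] <- totals[b] + 1L
    }
  }
  sorted <- sort(totals, decreasing = TRUE)
  out <- integer(k)
  out[seq_len(min(k, length(sorted)))] <- sorted[seq_len(min(k, length(sorted)))]
  out
}

# Explicit-loop forward pass for an lrsv_mlp model on one feature vector.
oracle_forward <- function(model, x) {
  a <- (x - model$feature_means) / model$feature_sds
  n_layers <- length(model$weights)
  for (l in seq_len(n_layers)) {
    W <- model$weights[[l]]
    b <- model$biases[[l]]
    out <- numeric(ncol(W))
    for (j in seq_len(ncol(W))) {
      s <- b[j]
      for (i in seq_along(a)) {
        s <- s + a[i] * W[i, j]
      }
      out[j] <- if (l < n_layers) tanh(s) else 1 / (1 + exp(-s))
    }
    a <- out
  }
  a
}

# Reconstruct an altered contig by straightforward substring surgery over the
# truth table, independent of apply_svs().
oracle_rebuild_reference <- function(reference, truth) {
  seqs <- stats::setNames(reference$seq, reference$contig)
  orig <- seqs
  # collect (contig, start, end, replacement) edits, then apply right-to-left
  edits <- list()
  for (i in seq_len(nrow(truth))) {
    t <- truth[i, ]
    if (t$sv_type == "DEL") {
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom, s = t$pos, e = t$end, r = "")
    } else if (t$sv_type == "INS") {
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom, s = t$pos + 1L, e = t$pos, r = t$ins_seq)
    } else if (t$sv_type == "INV") {
      seg <- substr(orig[[t$chrom]], t$pos, t$end)
      rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seg), "")[[1]]), collapse = "")
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom, s = t$pos, e = t$end, r = rc)
    } else if (t$sv_type == "DUP") {
      seg <- substr(orig[[t$chrom]], t$pos, t$end)
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom, s = t$end + 1L, e = t$end, r = seg)
    } else if (t$sv_type == "TRA") {
      seg1 <- substr(orig[[t$chrom]], t$pos, t$end)
      seg2 <- substr(orig[[t$chrom2]], t$pos2, t$end2)
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom, s = t$pos, e = t$end, r = seg2)
      edits[[length(edits) + 1L]] <- list(ctg = t$chrom2, s = t$pos2, e = t$end2, r = seg1)
    }
  }
  for (ctg in names(seqs)) {
    mine <- Filter(function(e) e$ctg == ctg, edits)
    if (length(mine) == 0L) next
    ord <- order(vapply(mine, `[[`, numeric(1), "s"), decreasing = TRUE)
    s <- seqs[[ctg]]
    for (e in mine[ord]) {
      s <- paste0(substr(s, 1L, e$s - 1L), e$r, substr(s, e$e + 1L, nchar(s)))
    }
    seqs[[ctg]] <- s
  }
  seqs
}
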
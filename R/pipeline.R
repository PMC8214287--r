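#' Configure a structural-variant pipeline run
#'
#' Collects paths, thresholds, and external-binary locations for
#' [run_sv_pipeline()]. The pipeline has two modes: full mode invokes the
#' external aligners/callers through the adapters, while bespoke-only mode
#' consumes pre-computed SAM and VCF inputs and exercises only the stages this
#' package implements (feature extraction, classification, read selection,
#' tag harmonization and merging, support filtering and call merging).
#' Exactly one of `coverage` / `min_support` must be given; with `coverage`,
#' the minimum support defaults to [min_support_threshold()].
#'
#' @param work_dir Writable working directory for stage outputs.
#' @param reads_fastq,reference_fasta Raw input paths (full mode; optional in
#'   bespoke mode).
#' @param fast_sam,accurate_sam Pre-computed alignments from the fast and
#'   accurate aligners (bespoke mode).
#' @param vcf_a,vcf_b Pre-computed caller VCFs (bespoke mode).
#' @param model,model_file Informative-read model (an `lrsv_mlp` or a path
#'   for [load_model()]); without one, selection falls back to split reads
#'   only.
#' @param coverage,min_support Sequencing coverage or an explicit minimum
#'   unique-support count (exactly one).
#' @param merge_window Cross-caller breakpoint merge window (bases).
#' @param classifier_threshold Probability cutoff for the classifier.
#' @param truth_vcf,tolerance Optional truth VCF and breakpoint tolerance:
#'   when given, the final call set is scored with [match_to_truth()].
#' @param binaries Named list of external binary names/paths.
#' @param threads Threads passed to external tools.
#' @param seed Integer seed recorded with the run.
#' @param force Recompute stage outputs even when present in `work_dir`.
#' @return An `lrsv_config` list.
#' @export
pipeline_config <- function(work_dir,
                            reads_fastq = NULL, reference_fasta = NULL,
                            fast_sam = NULL, accurate_sam = NULL,
                            vcf_a = NULL, vcf_b = NULL,
                            model = NULL, model_file = NULL,
                            coverage = NULL, min_support = NULL,
                            merge_window = 50L, classifier_threshold = 0.5,
                            truth_vcf = NULL, tolerance = 10L,
                            binaries = list(
                              fast_aligner = "minimap2",
                              accurate_aligner = "ngmlr",
                              caller_a = "sniffles",
                              caller_b = "svim",
                              samtools = "samtools"
                            ),
                            threads = 1L, seed = 1L, force = FALSE) {
  if (is.null(coverage) == is.null(min_support)) {
    rlang::abort("Set exactly one of `coverage` or `min_support`.")
  }
  if (merge_window < 0) rlang::abort("`merge_window` must be >= 0.")
  dir.create(work_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(work_dir, 2L) != 0L) {
    rlang::abort(sprintf("Work dir '%s' is not writable.", work_dir))
  }
  structure(
    list(
      work_dir = work_dir, reads_fastq = reads_fastq,
      reference_fasta = reference_fasta, fast_sam = fast_sam,
      accurate_sam = accurate_sam, vcf_a = vcf_a, vcf_b = vcf_b,
      model = model, model_file = model_file,
      coverage = coverage,
      min_support = if (is.null(min_support)) {
        min_support_threshold(coverage)
      } else {
        as.integer(min_support)
      },
      merge_window = as.integer(merge_window),
      classifier_threshold = classifier_threshold,
      truth_vcf = truth_vcf, tolerance = as.integer(tolerance),
      binaries = binaries, threads = as.integer(threads),
      seed = as.integer(seed), force = isTRUE(force)
    ),
    class = "lrsv_config"
  )
}

.require_binary <- function(binaries, role, stage) {
  bin <- binaries[[role]]
  path <- Sys.which(bin %||% "")
  if (is.null(bin) || !nzchar(path)) {
    rlang::abort(
      sprintf(
        paste0(
          "Stage '%s' needs the external binary '%s' (%s), which is not on ",
          "PATH. Install it, point `binaries$%s` at it, or run in ",
          "bespoke-only mode by supplying the stage's input file directly."
        ),
        stage, bin %||% role, role, role
      ),
      class = "lrsv_capability_error"
    )
  }
  unname(path)
}

.run_tool <- function(bin, args, stage) {
  out <- suppressWarnings(system2(bin, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    rlang::abort(sprintf(
      "Stage '%s': %s exited with status %d:\n%s",
      stage, bin, status, paste(utils::tail(out, 20L), collapse = "\n")
    ))
  }
  invisible(out)
}

#' External-tool adapters
#'
#' Thin subprocess wrappers with pinned, documented argument templates: the
#' fast aligner is asked for SAM output with MD tags; the callers are asked to
#' report supporting read names. A missing binary raises a capability error
#' (class `lrsv_capability_error`) naming the stage, never a crash. Outputs
#' are validated non-empty and an existing output is reused unless
#' `force = TRUE` (idempotent overwrite policy).
#'
#' @param config An `lrsv_config`.
#' @param out Output path.
#' @return The output path, invisibly.
#' @name adapters
NULL

.adapter <- function(config, role, stage, out, args_fun) {
  if (file.exists(out) && file.size(out) > 0L && !config$force) {
    return(invisible(out))
  }
  bin <- .require_binary(config$binaries, role, stage)
  .run_tool(bin, args_fun(bin), stage)
  if (!file.exists(out) || file.size(out) == 0L) {
    rlang::abort(sprintf("Stage '%s' produced no output at '%s'.", stage, out))
  }
  invisible(out)
}

#' @rdname adapters
#' @export
run_fast_aligner <- function(config, out) {
  .adapter(config, "fast_aligner", "fast_alignment", out, function(bin) {
    c(
      "-a", "--MD", "-x", "map-pb", "-t", config$threads,
      config$reference_fasta, config$reads_fastq, "-o", out
    )
  })
}

#' @rdname adapters
#' @param reads_fastq FASTQ of the selected read subset.
#' @export
run_accurate_aligner <- function(config, reads_fastq, out) {
  .adapter(config, "accurate_aligner", "accurate_alignment", out, function(bin) {
    c(
      "-r", config$reference_fasta, "-q", reads_fastq, "-o", out,
      "-x", "pacbio", "-t", config$threads
    )
  })
}

#' @rdname adapters
#' @param bam Sorted BAM of the merged alignments.
#' @export
run_caller_a <- function(config, bam, out) {
  .adapter(config, "caller_a", "sv_calling_a", out, function(bin) {
    c("--input", bam, "--vcf", out, "--output-rnames")
  })
}

#' @rdname adapters
#' @export
run_caller_b <- function(config, bam, out) {
  .adapter(config, "caller_b", "sv_calling_b", out, function(bin) {
    c(
      "alignment", "--read_names", file.path(config$work_dir, "caller_b"),
      bam, config$reference_fasta
    )
  })
}

#' @rdname adapters
#' @param sam Input SAM path.
#' @export
sam_to_sorted_bam <- function(config, sam, out) {
  if (file.exists(out) && file.size(out) > 0L && !config$force) {
    return(invisible(out))
  }
  bin <- .require_binary(config$binaries, "samtools", "bam_conversion")
  .run_tool(bin, c("sort", "-o", out, sam), "bam_conversion")
  .run_tool(bin, c("index", out), "bam_conversion")
  invisible(out)
}

#' Run the structural-variant pipeline
#'
#' Executes the six stages end-to-end: (1) fast alignment of all reads,
#' (2) per-read feature extraction and informative-read classification,
#' (3) selection (classifier positives plus fast-aligner split reads) and
#' accurate alignment of the selected subset, (4) tag harmonization and
#' merging of the two alignment streams, (5) SV calling with two callers, and
#' (6) unique-support filtering plus cross-caller call merging into the final
#' VCF. Stages whose inputs are supplied in the config are not recomputed, so
#' the bespoke stages run with no external binaries at all. A run report with
#' per-stage counts and wall-clock seconds is returned alongside the calls.
#'
#' @param config An [pipeline_config()] object.
#' @return An `lrsv_run` object: `calls` (final merged tibble), `report`
#'   (per-stage tibble), `selection`, `paths`, and optionally `evaluation`
#'   (an `sv_eval` against the configured truth).
#' @export
run_sv_pipeline <- function(config) {
  stopifnot(inherits(config, "lrsv_config"))
  wd <- config$work_dir
  report <- list()
  clock <- function(expr) {
    t0 <- Sys.time()
    val <- force(expr)
    list(val = val, secs = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  note <- function(stage, name, n_in, n_out, secs) {
    report[[length(report) + 1L]] <<- tibble::tibble(
      stage = stage, name = name, n_in = n_in, n_out = n_out,
      seconds = round(secs, 3)
    )
  }

  # stage 1: fast alignment
  s1 <- clock({
    if (!is.null(config$fast_sam)) {
      config$fast_sam
    } else {
      run_fast_aligner(config, file.path(wd, "fast_aligner.sam"))
      file.path(wd, "fast_aligner.sam")
    }
  })
  fast_sam <- s1$val
  fast_aln <- read_sam(fast_sam)
  note(1L, "fast_alignment", NA_integer_, nrow(fast_aln), s1$secs)

  # stage 2: features + classification
  s2 <- clock({
    feats <- extract_features(fast_aln)
    split_tbl <- is_split(fast_aln)
    model <- config$model
    if (is.null(model) && !is.null(config$model_file)) {
      model <- load_model(config$model_file)
    }
    cls <- if (!is.null(model)) {
      classify_reads(model, feats, threshold = config$classifier_threshold)
    } else {
      tibble::tibble(
        read_name = feats$read_name, prob = NA_real_, informative = 0L
      )
    }
    list(feats = feats, split = split_tbl, cls = cls)
  })
  n_reads <- nrow(s2$val$feats)
  note(2L, "classification", n_reads, sum(s2$val$cls$informative), s2$secs)

  # stage 3: read selection (+ accurate alignment)
  s3 <- clock({
    selection <- select_for_realignment(
      dplyr::rename(s2$val$cls, label = "informative"),
      s2$val$split$read_name[s2$val$split$split]
    )
    if (!is.null(config$reads_fastq) && nrow(selection) > 0L) {
      extract_reads_by_name(
        config$reads_fastq, selection$read_name,
        file.path(wd, "selected_reads.fastq")
      )
    }
    acc_sam <- config$accurate_sam
    if (is.null(acc_sam)) {
      acc_sam <- file.path(wd, "accurate_aligner.sam")
      run_accurate_aligner(config, file.path(wd, "selected_reads.fastq"), acc_sam)
    }
    list(selection = selection, acc_sam = acc_sam)
  })
  selection <- s3$val$selection
  note(3L, "selection_and_realignment", n_reads, nrow(selection), s3$secs)

  # stage 4: harmonize + merge alignments
  s4 <- clock({
    acc_aln <- read_sam(s3$val$acc_sam)
    merged <- merge_alignments(fast_aln, acc_aln)
    merged_sam <- file.path(wd, "merged.sam")
    write_sam(merged, merged_sam)
    bam <- NULL
    if (nzchar(Sys.which(config$binaries$samtools %||% ""))) {
      bam <- tryCatch(
        sam_to_sorted_bam(config, merged_sam, file.path(wd, "merged.bam")),
        error = function(e) NULL
      )
    }
    list(merged = merged, merged_sam = merged_sam, bam = bam)
  })
  note(4L, "harmonize_and_merge", nrow(fast_aln), nrow(s4$val$merged), s4$secs)

  # stage 5: SV calling
  s5 <- clock({
    vcf_a <- config$vcf_a
    vcf_b <- config$vcf_b
    if (is.null(vcf_a)) {
      vcf_a <- file.path(wd, "caller_a.vcf")
      run_caller_a(config, s4$val$bam, vcf_a)
    }
    if (is.null(vcf_b)) {
      vcf_b <- file.path(wd, "caller_b.vcf")
      run_caller_b(config, s4$val$bam, vcf_b)
    }
    list(
      calls_a = parse_sv_vcf(vcf_a, "callerA"),
      calls_b = parse_sv_vcf(vcf_b, "callerB")
    )
  })
  note(
    5L, "sv_calling", NA_integer_,
    nrow(s5$val$calls_a) + nrow(s5$val$calls_b), s5$secs
  )

  # stage 6: unique-support filter + cross-caller merge
  s6 <- clock({
    fa <- filter_min_support(s5$val$calls_a, config$min_support)
    fb <- filter_min_support(s5$val$calls_b, config$min_support)
    merged_calls <- merge_calls(fa, fb, window = config$merge_window)
    final_vcf <- file.path(wd, "final_merged.vcf")
    write_sv_vcf(merged_calls, final_vcf)
    list(calls = merged_calls, final_vcf = final_vcf)
  })
  note(
    6L, "filter_and_merge_calls",
    nrow(s5$val$calls_a) + nrow(s5$val$calls_b), nrow(s6$val$calls), s6$secs
  )

  evaluation <- NULL
  if (!is.null(config$truth_vcf)) {
    truth <- parse_sv_vcf(config$truth_vcf, "truth")
    evaluation <- match_to_truth(s6$val$calls, truth, tol = config$tolerance)
  }

  report_tbl <- dplyr::bind_rows(report)
  utils::write.table(
    report_tbl, file.path(wd, "run_report.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  structure(
    list(
      calls = s6$val$calls,
      report = report_tbl,
      selection = selection,
      evaluation = evaluation,
      paths = list(
        final_vcf = s6$val$final_vcf, merged_sam = s4$val$merged_sam,
        report = file.path(wd, "run_report.tsv")
      ),
      config = config
    ),
    class = "lrsv_run"
  )
}

#' @export
print.lrsv_run <- function(x, ...) {
  cat("<lrsv_run>\n")
  print(x$report)
  cat(sprintf(
    "final call set: %d SVs -> %s\n", nrow(x$calls), x$paths$final_vcf
  ))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}

#' Glance at a pipeline run
#'
#' @param x An `lrsv_run` object.
#' @param ... Unused.
#' @return One-row tibble: reads seen, reads selected, final call count,
#'   total seconds, and recall/FDR when a truth set was configured.
#' @export
glance.lrsv_run <- function(x, ...) {
  out <- tibble::tibble(
    n_reads = x$report$n_in[x$report$name == "classification"],
    n_selected = nrow(x$selection),
    n_calls = nrow(x$calls),
    min_support = x$config$min_support,
    merge_window = x$config$merge_window,
    seconds = sum(x$report$seconds)
  )
  if (!is.null(x$evaluation)) {
    out$recall <- x$evaluation$summary$recall
    out$fdr <- x$evaluation$summary$fdr
  }
  out
}
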
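# Build a complete bespoke-mode fixture set: fast-aligner SAM, accurate-
# aligner SAM for the selected reads, caller VCF pair, truth VCF, model.
make_dry_run_fixture <- function(wd, n_reads = 300L, seed = 2L) {
  syn <- synth_alignments(n_reads,
    informative_fraction = 0.05,
    split_fraction = 0.02, seed = seed
  )
  fast_sam <- file.path(wd, "fast.sam")
  write_sam(syn$alignments, fast_sam)
  feats <- extract_features(syn$alignments)
  tr <- dplyr::inner_join(feats, syn$labels[, c("read_name", "label")],
    by = "read_name"
  )
  model <- train_informative_classifier(tr, epochs = 150L, seed = seed)
  # accurate aligner output: records for informative + split reads only,
  # without the fast aligner's chaining-score tags
  sel <- syn$labels$read_name[syn$labels$label == 1L | syn$labels$split]
  acc <- dplyr::filter(syn$alignments, read_name %in% sel)
  acc$s1 <- NA_integer_
  acc$s2 <- NA_integer_
  acc$cm <- NA_integer_
  attr(acc, "header") <- attr(syn$alignments, "header")
  acc_sam <- file.path(wd, "accurate.sam")
  write_sam(acc, acc_sam)
  ref <- make_toy_reference(100000, n_contigs = 2, seed = seed)
  inj <- inject_svs(ref, sv_spec(n_tra = 1, seed = seed + 1L))
  pair <- synth_vcf_pair(inj$truth,
    seed = seed + 2L,
    vcf_a_path = file.path(wd, "caller_a.vcf"),
    vcf_b_path = file.path(wd, "caller_b.vcf")
  )
  truth_vcf <- file.path(wd, "truth.vcf")
  write_truth_vcf(inj$truth, truth_vcf, ref)
  list(
    fast_sam = fast_sam, acc_sam = acc_sam, model = model,
    vcf_a = file.path(wd, "caller_a.vcf"),
    vcf_b = file.path(wd, "caller_b.vcf"),
    truth_vcf = truth_vcf, labels = syn$labels, pair = pair
  )
}
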
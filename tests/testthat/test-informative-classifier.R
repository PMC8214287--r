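make_labelled_features <- function(n, frac = 0.05, seed = 11) {
  syn <- synth_alignments(n, informative_fraction = frac, seed = seed)
  feats <- extract_features(syn$alignments)
  dplyr::inner_join(feats, syn$labels[, c("read_name", "label")],
    by = "read_name"
  )
}

test_that("label_reads applies the split-based labeling rule", {
  mk <- function(name, split) {
    if (split) {
      dplyr::bind_rows(
        alignment_record("50M", read_name = name, SA = "chr1,1,+,50M,60,0;"),
        alignment_record("25S25M", read_name = name, flag = 2048L)
      )
    } else {
      alignment_record("50M", read_name = name)
    }
  }
  fast <- dplyr::bind_rows(mk("r1", FALSE), mk("r2", FALSE), mk("r3", TRUE))
  acc <- dplyr::bind_rows(mk("r1", TRUE), mk("r2", FALSE), mk("r3", FALSE))
  labs <- label_reads(fast, acc)
  expect_equal(labs$label[labs$read_name == "r1"], 1L) # split only by accurate
  expect_equal(labs$label[labs$read_name == "r2"], 0L) # split by neither
  expect_true(is.na(labs$label[labs$read_name == "r3"])) # split by fast: excluded
  expect_equal(labs$reason[labs$read_name == "r3"], "split_by_fast_aligner")
  # reads absent from one output are excluded with a reason
  fast2 <- dplyr::bind_rows(fast, mk("r4", FALSE))
  expect_message(labs2 <- label_reads(fast2, acc), "excluded")
  expect_equal(labs2$reason[labs2$read_name == "r4"], "missing_from_one_aligner")
  expect_error(label_reads(mk("a", FALSE), mk("b", FALSE)), "shared")
})

test_that("forward pass is sigmoid(0) = 0.5 for an all-zero network", {
  fv <- extract_features(alignment_record("50M", MD = "50"))
  m <- structure(
    list(
      version = "lrsv-mlp-1",
      layer_dims = c(21L, 18L, 30L, 18L, 11L, 5L, 1L),
      weights = lapply(1:6, function(l) {
        dims <- c(21L, 18L, 30L, 18L, 11L, 5L, 1L)
        matrix(0, dims[l], dims[l + 1L])
      }),
      biases = lapply(c(18L, 30L, 18L, 11L, 5L, 1L), numeric),
      feature_names = lrsv_feature_names(),
      feature_means = numeric(21L), feature_sds = rep(1, 21L),
      schema_version = "lrsv-1", threshold = 0.5
    ),
    class = "lrsv_mlp"
  )
  expect_equal(forward_mlp(m, fv), 0.5)
  expect_identical(forward_mlp(m, fv), forward_mlp(m, fv))
})

test_that("forward pass matches the explicit-loop oracle within 1e-9", {
  tr <- make_labelled_features(120, frac = 0.2, seed = 3)
  model <- train_informative_classifier(tr, epochs = 30L, seed = 5)
  X <- as.matrix(tr[, model$feature_names])
  probs <- forward_mlp(model, tr)
  for (i in seq_len(20L)) {
    expect_equal(probs[i], oracle_forward(model, X[i, ]), tolerance = 1e-9)
  }
})

test_that("training is seeded-deterministic and learns separable data", {
  tr <- make_labelled_features(600, frac = 0.1, seed = 21)
  m1 <- train_informative_classifier(tr, epochs = 150L, seed = 9)
  m2 <- train_informative_classifier(tr, epochs = 150L, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_gt(m1$metrics$accuracy, 0.99)
  # degenerate inputs refuse cleanly
  one_class <- dplyr::filter(tr, label == 0)
  expect_error(train_informative_classifier(one_class), "both classes")
  bad <- tr
  bad$s1[1] <- Inf
  expect_error(train_informative_classifier(bad), "Non-finite")
})

test_that("classification threshold is inclusive and monotone", {
  tr <- make_labelled_features(300, frac = 0.1, seed = 13)
  m <- train_informative_classifier(tr, epochs = 60L, seed = 2)
  p <- classify_reads(m, tr)
  expect_true(all(p$informative[p$prob >= m$threshold] == 1L))
  expect_true(all(p$informative[p$prob < m$threshold] == 0L))
  # exactly-at-threshold classifies positive
  p_at <- classify_reads(m, tr, threshold = p$prob[1])
  expect_equal(p_at$informative[1], 1L)
  # lowering the threshold never shrinks the selected set
  lo <- classify_reads(m, tr, threshold = 0.2)
  hi <- classify_reads(m, tr, threshold = 0.8)
  expect_true(all(hi$informative <= lo$informative))
  # output is row-wise: permuting the input permutes the output identically
  perm <- sample(nrow(tr))
  expect_equal(classify_reads(m, tr[perm, ])$prob, p$prob[perm])
  expect_error(classify_reads(m, tr, threshold = 1.5), "0, 1")
})

test_that("model serialization round-trips bit-for-bit and refuses bad files", {
  tr <- make_labelled_features(200, frac = 0.15, seed = 31)
  m <- train_informative_classifier(tr, epochs = 40L, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(forward_mlp(m, tr), forward_mlp(m2, tr))
  # truncated file: load error, not a crash
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 100), trunc_path)
  expect_error(load_model(trunc_path), "Cannot read|Unsupported")
  # version refusal
  bad <- jsonlite::fromJSON(readLines(path))
  bad$version <- "lrsv-mlp-99"
  bad_path <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(bad, auto_unbox = TRUE), bad_path)
  expect_error(load_model(bad_path), "version")
  # schema mismatch at classify time
  expect_error(classify_reads(m2, tr[, 1:5]), "schema")
})
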
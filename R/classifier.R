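#' Label reads for informative-read training from paired aligner outputs
#'
#' The positive class ("informative") is a read the fast aligner did not
#' split but the accurate aligner did: exactly the reads whose accurate
#' alignment contributes split-read SV evidence the fast aligner misses.
#' Reads split by the fast aligner are excluded — they are forwarded to the
#' accurate aligner anyway, so the classifier never needs to decide them.
#' Reads absent from either aligner's output are excluded with a logged count.
#'
#' @param fast_aln,accurate_aln Alignment tibbles from the two aligners
#'   (several records per read allowed).
#' @return Tibble with `read_name`, `label` (1 = informative, 0 = not,
#'   `NA` = excluded), and `reason` for exclusions.
#' @export
label_reads <- function(fast_aln, accurate_aln) {
  split_fast <- is_split(fast_aln)
  split_acc <- is_split(accurate_aln)
  common <- intersect(split_fast$read_name, split_acc$read_name)
  if (length(common) == 0L) {
    rlang::abort("No reads shared between the two aligners' outputs; nothing to label.")
  }
  only <- setdiff(
    union(split_fast$read_name, split_acc$read_name), common
  )
  if (length(only) > 0L) {
    rlang::inform(sprintf(
      "%d read(s) absent from one aligner's output were excluded from labeling.",
      length(only)
    ))
  }
  labs <- tibble::tibble(read_name = common) |>
    dplyr::left_join(
      dplyr::rename(split_fast, split_fast = "split"), by = "read_name"
    ) |>
    dplyr::left_join(
      dplyr::rename(split_acc, split_accurate = "split"), by = "read_name"
    ) |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$split_fast ~ NA_integer_,
        .data$split_accurate ~ 1L,
        TRUE ~ 0L
      ),
      reason = dplyr::if_else(.data$split_fast, "split_by_fast_aligner",
        NA_character_
      )
    ) |>
    dplyr::select("read_name", "label", "reason")
  dplyr::bind_rows(
    labs,
    tibble::tibble(
      read_name = only, label = NA_integer_,
      reason = "missing_from_one_aligner"
    )
  )
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.mlp_feature_matrix <- function(model, features) {
  if (is.matrix(features)) {
    if (ncol(features) != length(model$feature_names)) {
      rlang::abort(sprintf(
        "Feature matrix has %d columns; model expects %d.",
        ncol(features), length(model$feature_names)
      ))
    }
    return(features)
  }
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss) > 0L) {
    rlang::abort(sprintf(
      "Feature schema mismatch: missing column(s) %s (model schema '%s').",
      paste(miss, collapse = ", "), model$schema_version
    ))
  }
  as.matrix(features[, model$feature_names, drop = FALSE])
}

.mlp_forward_all <- function(weights, biases, X) {
  L <- length(weights)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% weights[[l]]
    Z <- sweep(Z, 2L, biases[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else .sigmoid(Z)
  }
  A
}

#' Forward pass of the informative-read network
#'
#' Standardizes the input with the model's stored per-feature mean/sd and
#' propagates it through the tanh hidden layers and the sigmoid output unit.
#' Deterministic for a fixed model.
#'
#' @param model An `lrsv_mlp` model.
#' @param features Feature tibble (schema-checked against the model) or a
#'   numeric matrix already in model feature order.
#' @return Numeric vector of probabilities in (0, 1), one per row.
#' @export
forward_mlp <- function(model, features) {
  X <- .mlp_feature_matrix(model, features)
  if (any(!is.finite(X))) rlang::abort("Non-finite feature values.")
  Xs <- sweep(sweep(X, 2L, model$feature_means, "-"), 2L, model$feature_sds, "/")
  A <- .mlp_forward_all(model$weights, model$biases, Xs)
  as.numeric(A[[length(A)]])
}

#' Train the informative-read classifier
#'
#' Fits the fixed fully-connected architecture — five tanh hidden layers of
#' 18, 30, 18, 11, and 5 units and one sigmoid output — on a labelled feature
#' table. Because informative reads are rare (well under 1% of reads in
#' typical long-read data), the binary cross-entropy loss is weighted by
#' inverse class frequency by default; features are z-scored with parameters
#' stored in the model; optimization is full-batch Adam with early stopping
#' on a stratified validation split. Training is reproducible given `seed`.
#'
#' @param features Feature tibble (e.g. from [extract_features()]); columns
#'   beyond `read_name` and the label are taken as features in order.
#' @param label_col Name of the 0/1 label column in `features`.
#' @param hidden Hidden-layer widths; the default is the fixed architecture.
#' @param epochs Maximum training epochs.
#' @param learning_rate Adam step size.
#' @param class_weights `"balanced"` (inverse-frequency) or `"none"`.
#' @param val_fraction Fraction held out (stratified) for early stopping;
#'   0 disables early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param threshold Decision threshold stored in the model (ties classify
#'   as informative).
#' @param seed Integer seed controlling initialization and the split.
#' @return An object of class `lrsv_mlp`.
#' @export
train_informative_classifier <- function(features, label_col = "label",
                                         hidden = c(18L, 30L, 18L, 11L, 5L),
                                         epochs = 400L, learning_rate = 0.01,
                                         class_weights = c("balanced", "none"),
                                         val_fraction = 0.15, patience = 30L,
                                         threshold = 0.5, seed = 1L) {
  class_weights <- match.arg(class_weights)
  if (!label_col %in% names(features)) {
    rlang::abort(sprintf("No label column '%s' in `features`.", label_col))
  }
  y <- as.numeric(features[[label_col]])
  keep <- !is.na(y)
  features <- features[keep, , drop = FALSE]
  y <- y[keep]
  if (!all(y %in% c(0, 1))) rlang::abort("Labels must be 0/1.")
  if (length(unique(y)) < 2L) {
    rlang::abort("Training data must contain both classes.")
  }
  feature_names <- setdiff(names(features), c("read_name", label_col))
  feature_names <- feature_names[vapply(
    features[feature_names], is.numeric, logical(1)
  )]
  X <- as.matrix(features[, feature_names, drop = FALSE])
  if (any(!is.finite(X))) rlang::abort("Non-finite feature values.")
  schema <- attr(features, "schema_version")
  if (is.null(schema)) {
    schema <- if (identical(feature_names, lrsv_feature_names())) {
      lrsv_feature_schema()
    } else {
      "custom"
    }
  }
  n <- nrow(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd_, "/")

  dims <- c(ncol(X), as.integer(hidden), 1L)
  L <- length(dims) - 1L

  withr::with_seed(as.integer(seed), {
    weights <- biases <- vector("list", L)
    for (l in seq_len(L)) {
      s <- 1 / sqrt(dims[l])
      weights[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1L], -s, s),
        nrow = dims[l]
      )
      biases[[l]] <- numeric(dims[l + 1L])
    }
    # stratified validation split
    val_idx <- integer()
    if (val_fraction > 0) {
      for (cls in c(0, 1)) {
        idx <- which(y == cls)
        n_val <- floor(length(idx) * val_fraction)
        if (n_val >= 1L && length(idx) - n_val >= 1L) {
          val_idx <- c(val_idx, sample(idx, n_val))
        }
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    w_cls <- if (class_weights == "balanced") {
      c(`0` = n / (2 * sum(y == 0)), `1` = n / (2 * sum(y == 1)))
    } else {
      c(`0` = 1, `1` = 1)
    }
    wv <- unname(w_cls[as.character(y)])

    Xtr <- Xs[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    wtr <- wv[tr_idx]
    Xval <- Xs[val_idx, , drop = FALSE]
    yval <- y[val_idx]
    wval <- wv[val_idx]
    eps <- 1e-12
    wloss <- function(p, yy, ww) {
      -mean(ww * (yy * log(p + eps) + (1 - yy) * log(1 - p + eps)))
    }

    mW <- vW <- lapply(weights, function(w) w * 0)
    mB <- vB <- lapply(biases, function(b) b * 0)
    b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
    best <- list(loss = Inf, weights = weights, biases = biases, epoch = 0L)
    hist_epoch <- integer(); hist_train <- numeric(); hist_val <- numeric()
    stall <- 0L
    ntr <- nrow(Xtr)

    for (ep in seq_len(epochs)) {
      A <- .mlp_forward_all(weights, biases, Xtr)
      p <- as.numeric(A[[L + 1L]])
      train_loss <- wloss(p, ytr, wtr)
      delta <- matrix((p - ytr) * wtr / ntr, ncol = 1L)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta)
        gB <- colSums(delta)
        if (l > 1L) {
          delta <- (delta %*% t(weights[[l]])) * (1 - A[[l]]^2)
        }
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
        mB[[l]] <- b1 * mB[[l]] + (1 - b1) * gB
        vB[[l]] <- b2 * vB[[l]] + (1 - b2) * gB^2
        mhW <- mW[[l]] / (1 - b1^ep); vhW <- vW[[l]] / (1 - b2^ep)
        mhB <- mB[[l]] / (1 - b1^ep); vhB <- vB[[l]] / (1 - b2^ep)
        weights[[l]] <- weights[[l]] - learning_rate * mhW / (sqrt(vhW) + aeps)
        biases[[l]] <- biases[[l]] - learning_rate * mhB / (sqrt(vhB) + aeps)
      }
      if (length(val_idx) > 0L) {
        Av <- .mlp_forward_all(weights, biases, Xval)
        val_loss <- wloss(as.numeric(Av[[L + 1L]]), yval, wval)
      } else {
        val_loss <- NA_real_
      }
      hist_epoch <- c(hist_epoch, ep)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      monitor <- if (is.na(val_loss)) train_loss else val_loss
      if (monitor < best$loss - 1e-9) {
        best <- list(loss = monitor, weights = weights, biases = biases, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (length(val_idx) > 0L && stall >= patience) break
      }
    }
  })

  model <- structure(
    list(
      version = "lrsv-mlp-1",
      layer_dims = dims,
      weights = best$weights,
      biases = best$biases,
      hidden_activation = "tanh",
      output_activation = "sigmoid",
      feature_names = feature_names,
      feature_means = unname(mu),
      feature_sds = unname(sd_),
      schema_version = schema,
      threshold = threshold,
      seed = as.integer(seed),
      history = tibble::tibble(
        epoch = hist_epoch, train_loss = hist_train, val_loss = hist_val
      ),
      best_epoch = best$epoch
    ),
    class = "lrsv_mlp"
  )
  p_all <- forward_mlp(model, X)
  pred <- as.integer(p_all >= threshold)
  model$metrics <- tibble::tibble(
    n = n,
    n_positive = sum(y == 1),
    final_train_loss = hist_train[length(hist_train)],
    best_monitor_loss = best$loss,
    accuracy = mean(pred == y),
    accuracy_positive = mean(pred[y == 1] == 1),
    accuracy_negative = mean(pred[y == 0] == 0)
  )
  model
}

#' Classify reads as informative or not
#'
#' Applies [forward_mlp()] and thresholds at the model's stored cutoff;
#' probabilities exactly at the threshold classify as informative (a missed
#' informative read costs sensitivity, a false positive only costs
#' re-alignment time). Output order follows the input and the decision for a
#' read does not depend on the other rows.
#'
#' @param model An `lrsv_mlp` model.
#' @param features Feature tibble.
#' @param threshold Optional override of the model threshold.
#' @return Tibble with `read_name` (when present), `prob`, and `informative`
#'   (0/1).
#' @export
classify_reads <- function(model, features, threshold = model$threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    rlang::abort("`threshold` must be in (0, 1).")
  }
  p <- forward_mlp(model, features)
  out <- tibble::tibble(prob = p, informative = as.integer(p >= threshold))
  if (is.data.frame(features) && "read_name" %in% names(features)) {
    out <- dplyr::bind_cols(
      tibble::tibble(read_name = features$read_name), out
    )
  }
  out
}

#' Save / load an informative-read model
#'
#' The on-disk form is versioned JSON: layer dimensions, row-major weight
#' arrays, bias vectors, the standardization parameters, the feature schema,
#' and the decision threshold, written at full double precision so a reloaded
#' model reproduces forward outputs bit-for-bit.
#'
#' @param model An `lrsv_mlp` model.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lrsv_mlp"))
  payload <- list(
    version = model$version,
    layer_dims = model$layer_dims,
    hidden_activation = model$hidden_activation,
    output_activation = model$output_activation,
    # row-major serialization: weights[[l]] has dim (dims[l], dims[l+1])
    weights = lapply(model$weights, function(w) as.numeric(t(w))),
    biases = lapply(model$biases, as.numeric),
    feature_names = model$feature_names,
    feature_means = model$feature_means,
    feature_sds = model$feature_sds,
    schema_version = model$schema_version,
    threshold = model$threshold
  )
  writeLines(
    jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE),
    path
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(readLines(path, warn = FALSE)),
    error = function(e) {
      rlang::abort(sprintf("Cannot read model file '%s': %s", path, conditionMessage(e)))
    }
  )
  if (!identical(payload$version, "lrsv-mlp-1")) {
    rlang::abort(sprintf(
      "Unsupported model version '%s' (expected 'lrsv-mlp-1').",
      paste(payload$version, collapse = ",")
    ))
  }
  dims <- as.integer(payload$layer_dims)
  L <- length(dims) - 1L
  weights <- vector("list", L)
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(as.numeric(payload$weights[[l]]),
      nrow = dims[l], ncol = dims[l + 1L], byrow = TRUE
    )
  }
  structure(
    list(
      version = payload$version,
      layer_dims = dims,
      weights = weights,
      biases = lapply(payload$biases, as.numeric),
      hidden_activation = payload$hidden_activation,
      output_activation = payload$output_activation,
      feature_names = as.character(payload$feature_names),
      feature_means = as.numeric(payload$feature_means),
      feature_sds = as.numeric(payload$feature_sds),
      schema_version = payload$schema_version,
      threshold = as.numeric(payload$threshold),
      history = NULL
    ),
    class = "lrsv_mlp"
  )
}

#' @export
print.lrsv_mlp <- function(x, ...) {
  cat(sprintf(
    "<lrsv_mlp> %s network: %s (tanh hidden, sigmoid output)\n",
    x$schema_version, paste(x$layer_dims, collapse = "-")
  ))
  cat(sprintf("  threshold %.3f, %d features\n", x$threshold, x$layer_dims[1]))
  if (!is.null(x$metrics)) {
    cat(sprintf(
      "  trained on n = %d (%d positive); per-class accuracy %.3f / %.3f\n",
      x$metrics$n, x$metrics$n_positive,
      x$metrics$accuracy_negative, x$metrics$accuracy_positive
    ))
  }
  invisible(x)
}

#' Tidy an informative-read model
#'
#' @param x An `lrsv_mlp` model.
#' @param ... Unused.
#' @return One row per layer: widths, parameter counts, weight norms.
#' @export
tidy.lrsv_mlp <- function(x, ...) {
  L <- length(x$weights)
  tibble::tibble(
    layer = seq_len(L),
    input_dim = x$layer_dims[-length(x$layer_dims)],
    output_dim = x$layer_dims[-1L],
    activation = c(rep(x$hidden_activation, L - 1L), x$output_activation),
    n_parameters = purrr::map2_int(
      x$layer_dims[-length(x$layer_dims)], x$layer_dims[-1L],
      ~ .x * .y + .y
    ),
    weight_norm = purrr::map_dbl(x$weights, ~ sqrt(sum(.x^2)))
  )
}

#' Glance at an informative-read model
#'
#' @param x An `lrsv_mlp` model.
#' @param ... Unused.
#' @return One-row tibble of training summary statistics.
#' @export
glance.lrsv_mlp <- function(x, ...) {
  base <- tibble::tibble(
    n_features = x$layer_dims[1],
    n_layers = length(x$weights),
    threshold = x$threshold,
    schema_version = x$schema_version
  )
  if (is.null(x$metrics)) base else dplyr::bind_cols(base, x$metrics)
}

#' Plot the training history of an informative-read model
#'
#' @param object An `lrsv_mlp` model with a training history.
#' @param ... Unused.
#' @return A ggplot of train/validation loss by epoch.
#' @export
autoplot.lrsv_mlp <- function(object, ...) {
  if (is.null(object$history)) {
    rlang::abort("Model carries no training history (loaded from disk?).")
  }
  df <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss"),
      names_to = "series", values_to = "loss"
    ) |>
    dplyr::filter(!is.na(.data$loss))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Epoch", y = "Weighted cross-entropy", colour = NULL,
      title = "Informative-read classifier training"
    ) +
    ggplot2::theme_minimal()
}
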
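# Training of the PRDIS-specific classifiers: feature-matrix assembly,
# SMOTE class rebalancing and the two small neural networks.

#' Training configuration for a specific predictor
#'
#' Defaults mirror the classic perceptron-style setup used to build
#' the published predictors: learning rate `L = 0.3`, momentum
#' `M = 0.2`, `N = 500` training epochs, no validation split
#' (`V = 0`, so the early-stopping patience `E` is inert and retained
#' only for completeness), seed `S = 0`, and two hidden nodes when a
#' hidden layer is used.
#'
#' @param architecture `"no_hidden"` (single sigmoid output unit) or
#'   `"hidden_2"` (one hidden layer of sigmoid units).
#' @param learning_rate,momentum,epochs SGD hyperparameters.
#' @param validation_fraction Fraction held out for early stopping
#'   (0 disables; the default).
#' @param seed Seed for weight initialisation and presentation order.
#' @param early_stop_patience Retained for completeness; unused while
#'   `validation_fraction == 0`.
#' @param hidden_nodes Hidden-layer width (2 for `"hidden_2"`).
#' @param feature_set `"scores_only"` or `"scores_plus_bio"`.
#' @param decision_threshold Score cutoff for calling pathogenic
#'   (ties are pathogenic).
#' @param smote_k Number of nearest minority neighbours for SMOTE.
#' @return A `training_config` object.
#' @export
training_config <- function(architecture = c("no_hidden", "hidden_2"),
                            learning_rate = 0.3, momentum = 0.2,
                            epochs = 500L, validation_fraction = 0,
                            seed = 0L, early_stop_patience = 20L,
                            hidden_nodes = 2L,
                            feature_set = c("scores_only", "scores_plus_bio"),
                            decision_threshold = 0.5, smote_k = 5L) {
  architecture <- match.arg(architecture)
  feature_set <- match.arg(feature_set)
  stopifnot(learning_rate > 0, epochs >= 1,
            decision_threshold > 0, decision_threshold < 1)
  structure(list(architecture = architecture,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience),
                 hidden_nodes = if (architecture == "hidden_2") as.integer(hidden_nodes) else 0L,
                 feature_set = feature_set,
                 decision_threshold = decision_threshold,
                 smote_k = as.integer(smote_k)),
            class = "training_config")
}

#' Build the numeric feature matrix for a predictor combination
#'
#' Columns are the combination predictors' outputs in the given order
#' — numeric scores for score-mode predictors, 1/0 encoded binary
#' calls for categorical ones — optionally followed by the three
#' biological features (`blosum62`, `entropy`, `pssm_nat`).  Labels
#' are 1 = pathogenic, 0 = neutral, `NA` = unlabeled.
#'
#' PRDIS construction guarantees output from every combination
#' predictor, so a missing score here is an invariant violation and an
#' error.
#'
#' @param records A variant table (typically the PRDIS rows).
#' @param combination Predictor names.
#' @param feature_set `"scores_only"` or `"scores_plus_bio"`.
#' @param specs Binarisation registry (used to encode categorical
#'   predictors).
#' @return `list(x = matrix, y = numeric labels)`.
#' @export
build_feature_matrix <- function(records, combination,
                                 feature_set = c("scores_only",
                                                 "scores_plus_bio"),
                                 specs = default_predictor_specs()) {
  feature_set <- match.arg(feature_set)
  validate_variant_table(records)
  n <- nrow(records)
  cols <- list()
  for (p in combination) {
    if (!p %in% names(records)) stop("no column for predictor: ", p)
    spec <- specs[[p]]
    if (is.null(spec)) stop("no predictor spec registered for: ", p)
    v <- if (spec$mode == "score_threshold") {
      raw <- suppressWarnings(as.numeric(records[[p]]))
      if (any(is.na(raw) & !is.na(records[[p]]))) {
        # categorical fallback: encode the binarised call
        calls <- binarize(records[[p]], spec)
        ifelse(calls == "pathogenic", 1, 0)
      } else {
        raw
      }
    } else {
      calls <- binarize(records[[p]], spec)
      ifelse(is.na(calls), NA_real_, ifelse(calls == "pathogenic", 1, 0))
    }
    if (n > 0 && anyNA(v)) {
      stop("missing ", p, " output in row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "),
           " (PRDIS rows must have full output)")
    }
    cols[[p]] <- v
  }
  if (feature_set == "scores_plus_bio") {
    for (f in c("blosum62", "entropy", "pssm_nat")) {
      v <- records[[f]]
      if (n > 0 && anyNA(v)) {
        stop("biological feature '", f, "' missing in row(s) ",
             paste(utils::head(which(is.na(v)), 5), collapse = ", "))
      }
      cols[[f]] <- as.numeric(v)
    }
  }
  x <- if (n == 0) {
    matrix(numeric(0), nrow = 0, ncol = length(cols),
           dimnames = list(NULL, names(cols)))
  } else {
    matrix(unlist(cols, use.names = FALSE), nrow = n,
           dimnames = list(NULL, names(cols)))
  }
  y <- ifelse(records$label == "pathogenic", 1,
              ifelse(records$label == "neutral", 0, NA_real_))
  list(x = x, y = y)
}

#' SMOTE oversampling to class parity
#'
#' Synthetic minority rows are added until the two classes are equal in
#' size.  Each synthetic row is `x + u * (x_nn - x)` with `u ~ U[0,1]`,
#' where `x` is a minority row and `x_nn` one of its `k` nearest
#' minority neighbours (Euclidean distance).  Majority rows are never
#' touched.  Reproducible under a fixed seed.
#'
#' @param x Numeric feature matrix.
#' @param y Binary labels (0/1), both classes present.
#' @param k Number of nearest neighbours; clamped (with a warning) to
#'   the minority size minus one.
#' @param seed RNG seed.
#' @return `list(x, y)` with synthetic minority rows appended, and the
#'   number of synthetic rows in `attr(, "n_synthetic")`.
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 0L) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  classes <- sort(unique(y))
  if (length(classes) != 2) stop("SMOTE needs exactly two classes present")
  n1 <- sum(y == classes[2]); n0 <- sum(y == classes[1])
  minority <- if (n1 < n0) classes[2] else classes[1]
  n_min <- min(n0, n1)
  n_new <- abs(n0 - n1)
  if (n_new == 0) {
    out <- list(x = x, y = y)
    attr(out, "n_synthetic") <- 0L
    return(out)
  }
  if (n_min == 1 && n_new > 0 && k >= 1) {
    # lone minority point: no neighbours, duplicate it
    xm <- x[y == minority, , drop = FALSE]
    synth <- xm[rep(1, n_new), , drop = FALSE]
  } else {
    if (k > n_min - 1) {
      warning("k = ", k, " larger than minority size - 1; clamped to ",
              n_min - 1)
      k <- n_min - 1L
    }
    xm <- x[y == minority, , drop = FALSE]
    d <- as.matrix(stats::dist(xm))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
    nn <- matrix(nn, nrow = k)  # k x n_min
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
    set.seed(seed)
    base_i <- rep_len(seq_len(n_min), n_new)[sample.int(n_new)]
    pick <- nn[cbind(sample.int(k, n_new, replace = TRUE), base_i)]
    u <- runif(n_new)
    synth <- xm[base_i, , drop = FALSE] +
      u * (xm[pick, , drop = FALSE] - xm[base_i, , drop = FALSE])
  }
  out <- list(x = rbind(x, synth), y = c(y, rep(minority, n_new)))
  attr(out, "n_synthetic") <- n_new
  out
}

# per-column affine map onto [-1, 1] fitted on the training matrix
.fit_normalization <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  center <- (hi + lo) / 2
  halfrange <- (hi - lo) / 2
  halfrange[halfrange == 0] <- 1  # constant column maps to 0
  list(center = center, halfrange = halfrange)
}

.apply_normalization <- function(x, norm) {
  sweep(sweep(x, 2, norm$center, "-"), 2, norm$halfrange, "/")
}

#' Train a PRDIS-specific neural network
#'
#' Fits a feed-forward network with sigmoid units — either a direct
#' input-to-output unit (`no_hidden`) or one hidden layer
#' (`hidden_2`) — by per-instance stochastic gradient descent on
#' squared error with momentum.  Inputs are affinely normalised to
#' \[-1, 1\] per feature (parameters stored with the model).  Training
#' is deterministic under a fixed seed.
#'
#' @param x Numeric feature matrix (typically SMOTE-balanced).
#' @param y Binary labels, 1 = pathogenic, 0 = neutral.
#' @param config A [training_config()].
#' @param combination,feature_set,specs Optional provenance stored with
#'   the model so that [predict.specific_model()] can accept variant
#'   tables directly.
#' @return A `specific_model` object.
#' @export
train_specific_model <- function(x, y, config = training_config(),
                                 combination = colnames(x),
                                 feature_set = config$feature_set,
                                 specs = default_predictor_specs()) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- colnames(x)[apply(x, 2, function(v) any(!is.finite(v)))]
    stop("non-finite feature values in column(s): ",
         paste(bad, collapse = ", "))
  }
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least two rows of each class")
  }
  norm <- .fit_normalization(x)
  z <- .apply_normalization(x, norm)
  hidden <- if (config$architecture == "hidden_2") config$hidden_nodes else 0L
  weights <- .mlp_train_cpp(z, as.numeric(y), hidden,
                            config$learning_rate, config$momentum,
                            config$epochs, config$seed)
  structure(list(weights = weights, normalization = norm,
                 feature_names = colnames(x), config = config,
                 combination = combination, feature_set = feature_set,
                 specs = specs),
            class = "specific_model")
}

#' Predict with a specific model
#'
#' @param object A `specific_model`.
#' @param newdata Either a numeric matrix with the model's feature
#'   columns or a variant table (the feature matrix is then rebuilt
#'   with the model's stored combination and feature set).
#' @param type `"response"` for scores in \[0, 1\], `"call"` for
#'   pathogenic/neutral calls (score at or above the decision
#'   threshold is pathogenic), `"both"` for a data.frame of both.
#' @param ... Unused.
#' @return Numeric scores, character calls, or a data.frame.
#' @export
predict.specific_model <- function(object, newdata,
                                   type = c("response", "call", "both"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    fm <- build_feature_matrix(newdata, object$combination,
                               object$feature_set, object$specs)
    x <- fm$x
  } else {
    x <- as.matrix(newdata)
    if (!is.null(colnames(x)) && all(object$feature_names %in% colnames(x))) {
      x <- x[, object$feature_names, drop = FALSE]
    }
  }
  if (ncol(x) != length(object$feature_names)) {
    stop("newdata has ", ncol(x), " feature columns; model expects ",
         length(object$feature_names))
  }
  z <- .apply_normalization(x, object$normalization)
  w <- object$weights
  score <- if (is.null(w$W1)) {
    plogis(drop(z %*% w$w) + w$b)
  } else {
    h <- plogis(sweep(z %*% t(w$W1), 2, w$b1, "+"))
    plogis(drop(h %*% w$w2) + w$b2)
  }
  call <- ifelse(score >= object$config$decision_threshold,
                 "pathogenic", "neutral")
  switch(type,
         response = score,
         call = call,
         both = data.frame(score = score, call = call,
                           stringsAsFactors = FALSE))
}

#' @export
print.specific_model <- function(x, ...) {
  cat("PRDIS-specific predictor (", x$config$architecture, ", ",
      x$feature_set, ")\n", sep = "")
  cat("  inputs:", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a specific model to JSON
#'
#' @param model A `specific_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_specific_model <- function(model, path) {
  stopifnot(inherits(model, "specific_model"))
  payload <- list(
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.vector(w)) else w
    }),
    normalization = model$normalization,
    feature_names = model$feature_names,
    combination = model$combination,
    feature_set = model$feature_set,
    config = unclass(model$config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a specific model written by [write_specific_model()]
#'
#' The binarisation registry is not serialised; supply it (defaults to
#' the shipped registry).
#'
#' @param path JSON file.
#' @param specs Binarisation registry.
#' @return A `specific_model`.
#' @export
read_specific_model <- function(path, specs = default_predictor_specs()) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(p$weights, function(w) {
    if (is.list(w) && !is.null(w$dim)) {
      matrix(w$data, nrow = w$dim[1], ncol = w$dim[2])
    } else {
      unlist(w)
    }
  })
  cfg <- do.call(training_config, as.list(p$config))
  structure(list(weights = weights,
                 normalization = lapply(p$normalization, unlist),
                 feature_names = p$feature_names,
                 config = cfg, combination = p$combination,
                 feature_set = p$feature_set, specs = specs),
            class = "specific_model")
}
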
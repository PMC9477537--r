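MODEL_FORMAT_VERSION <- 1L
FEATURE_ORDER <- c(paste0("bg_", seq(10, 100, by = 10), "kb"), "bg_chrom")

# Logistic regression over log-transformed enrichment ratios. Perfectly
# separable training data drives the coefficients to the boundary; the
# fitted probabilities are still what we want, so convergence chatter is
# silenced.
fit_enrichment_model <- function(enrich, y) {
  Z <- log(enrich)
  colnames(Z) <- FEATURE_ORDER
  df <- data.frame(y = y, Z)
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(maxit = 100)))
  list(coef = stats::coef(fit))
}

predict_enrichment <- function(model, enrich) {
  Z <- cbind(1, log(enrich))
  co <- model$coef
  co[is.na(co)] <- 0
  as.numeric(stats::plogis(Z %*% co))
}

# 13-column combiner input: shape score, enrichment score, then the 11
# log-transformed enrichment measurements.
combiner_input <- function(shape_score, enrich_score, enrich) {
  cbind(shape_score, enrich_score, log(enrich))
}

#' Train the wide-and-deep peak-scoring model
#'
#' Three stages, each deterministic given `seed`:
#' 1. the convolutional *shape model* is fit on the 2000-point signal
#'    windows alone (binary cross-entropy, early stopping on a held-out
#'    20% split);
#' 2. the logistic-regression *enrichment model* is fit on the 11 local
#'    enrichment measurements (log-transformed) alone;
#' 3. with both frozen, the *combiner* multilayer perceptron is fit on the
#'    13-input vector (shape score, enrichment score, 11 measurements) and
#'    its sigmoid output is the Peak Score.
#'
#' The staging keeps the shape and enrichment components independently
#' usable classifiers rather than features co-adapted to the combiner.
#'
#' @param features A [extract_features()] bundle for the labeled regions.
#' @param labels Character vector in `{"peak", "noise"}`, one per region.
#' @param seed Integer seed controlling initialization, splits and batch
#'   order.
#' @param epochs,batch,lr Training-loop controls shared by both networks.
#' @return A list of class `peak_model` with components `shape`,
#'   `enrichment`, `combiner` and the frozen architecture descriptor.
#' @export
train_peak_model <- function(features, labels, seed = 1L,
                             epochs = 150L, batch = 32L, lr = 1e-3) {
  stopifnot(inherits(features, "feature_bundles"))
  y <- as.integer(labels == "peak")
  if (length(y) != nrow(features$signal))
    stop("labels must match the number of feature rows")
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("training requires at least two examples of each class")

  shape_best <- train_net(
    with_seed(seed, shape_init_params()),
    shape_forward, shape_backward,
    features$signal, y, seed = seed,
    epochs = epochs, batch = batch, lr = lr)
  shape <- list(params = shape_best$params, arch = SHAPE_ARCH)

  enrichment <- fit_enrichment_model(features$enrich, y)

  ss <- shape_forward(shape$params, features$signal)
  es <- predict_enrichment(enrichment, features$enrich)
  Xc <- combiner_input(ss, es, features$enrich)
  comb_best <- train_net(
    with_seed(seed + 1L, mlp_init_params(ncol(Xc))),
    mlp_forward, function(p, cache, yy) mlp_backward(p, cache, yy),
    Xc, y, seed = seed + 1L,
    epochs = epochs, batch = batch, lr = 1e-2)
  combiner <- list(params = comb_best$params, hidden = 8L)

  structure(list(shape = shape, enrichment = enrichment,
                 combiner = combiner,
                 feature_order = FEATURE_ORDER,
                 epsilon = PSEUDOCOUNT,
                 signal_window = SIGNAL_WINDOW_BP,
                 version = MODEL_FORMAT_VERSION),
            class = "peak_model")
}

#' @export
print.peak_model <- function(x, ...) {
  cat("peak_model: CNN shape score + logistic enrichment score +",
      "MLP Peak Score\n")
  cat("  signal window:", x$signal_window, "bp;",
      length(x$feature_order), "enrichment features\n")
  invisible(x)
}

#' Score regions with a trained model
#'
#' @param model A [train_peak_model()] result.
#' @param features A [extract_features()] bundle.
#' @return A data frame with one row per region: `shape_score`,
#'   `enrichment_score`, `peak_score`, all in `[0, 1]`.
#' @export
score_features <- function(model, features) {
  stopifnot(inherits(model, "peak_model"),
            inherits(features, "feature_bundles"))
  if (ncol(features$enrich) != length(model$feature_order))
    stop("feature dimensionality does not match the model")
  if (ncol(features$signal) != model$signal_window)
    stop("signal window length does not match the model")
  n <- nrow(features$signal)
  if (n == 0L)
    return(data.frame(shape_score = numeric(0),
                      enrichment_score = numeric(0),
                      peak_score = numeric(0)))
  ss <- shape_forward(model$shape$params, features$signal,
                      arch = model$shape$arch)
  es <- predict_enrichment(model$enrichment, features$enrich)
  ps <- mlp_forward(model$combiner$params,
                    combiner_input(ss, es, features$enrich))
  data.frame(shape_score = ss, enrichment_score = es, peak_score = ps)
}

# ---- serialization ---------------------------------------------------------
# Plain-text bundle: <dir>/model.json holds the descriptor (version,
# architecture, feature order, epsilon, parameter shapes) and
# <dir>/weights.txt holds all parameters, one value per line in declared
# order, printed with 17 significant digits so doubles round-trip exactly.

model_param_blocks <- function(model) {
  list(shape = model$shape$params, enrichment = list(coef = model$enrichment$coef),
       combiner = model$combiner$params)
}

#' Save / load a trained model bundle
#'
#' The on-disk format is a directory with a JSON descriptor and a flat
#' text weights file; loading reproduces bit-identical scores.
#'
#' @param model A `peak_model`.
#' @param path Directory to write (created if needed) / read.
#' @return `load_model()` returns the `peak_model`; `save_model()` its
#'   path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "peak_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  blocks <- model_param_blocks(model)
  shapes <- lapply(blocks, function(bl) lapply(bl, function(p) dim(p) %||% length(p)))
  desc <- list(format = "peakshaper-model",
               version = model$version,
               signal_window = model$signal_window,
               epsilon = model$epsilon,
               feature_order = model$feature_order,
               shape_arch = model$shape$arch,
               combiner_hidden = model$combiner$hidden,
               param_shapes = shapes)
  jsonlite::write_json(desc, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  vals <- unlist(lapply(blocks, function(bl) lapply(bl, as.numeric)),
                 use.names = FALSE)
  writeLines(sprintf("%.17g", vals), file.path(path, "weights.txt"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_model
#' @export
load_model <- function(path) {
  desc_path <- file.path(path, "model.json")
  w_path <- file.path(path, "weights.txt")
  if (!file.exists(desc_path) || !file.exists(w_path))
    stop("not a model bundle: missing model.json or weights.txt in ", path)
  desc <- tryCatch(jsonlite::read_json(desc_path, simplifyVector = TRUE),
                   error = function(e) stop("corrupt model descriptor: ",
                                            conditionMessage(e)))
  if (!identical(desc$format, "peakshaper-model") ||
      !identical(as.integer(desc$version), MODEL_FORMAT_VERSION))
    stop("model bundle version/descriptor mismatch")
  if (!identical(as.character(desc$feature_order), FEATURE_ORDER))
    stop("model bundle was trained with a different feature ordering")
  vals <- as.numeric(readLines(w_path))
  if (anyNA(vals)) stop("corrupt weights file")
  shapes <- desc$param_shapes
  blocks <- list(); pos <- 0L
  for (blk in names(shapes)) {
    blocks[[blk]] <- list()
    for (pn in names(shapes[[blk]])) {
      sh <- as.integer(shapes[[blk]][[pn]])
      n <- prod(sh)
      if (pos + n > length(vals)) stop("corrupt weights file: too short")
      v <- vals[(pos + 1L):(pos + n)]
      blocks[[blk]][[pn]] <- if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
      pos <- pos + n
    }
  }
  if (pos != length(vals)) stop("corrupt weights file: trailing values")
  arch <- lapply(desc$shape_arch, as.integer)
  enr_coef <- blocks$enrichment$coef
  names(enr_coef) <- c("(Intercept)", FEATURE_ORDER)
  structure(list(shape = list(params = blocks$shape, arch = arch),
                 enrichment = list(coef = enr_coef),
                 combiner = list(params = blocks$combiner,
                                 hidden = as.integer(desc$combiner_hidden)),
                 feature_order = as.character(desc$feature_order),
                 epsilon = desc$epsilon,
                 signal_window = as.integer(desc$signal_window),
                 version = as.integer(desc$version)),
            class = "peak_model")
}
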
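#' Classifier architecture specification
#'
#' Describes the two-branch CNN used to classify artificial image objects
#' (AIOs): a modified-VGG convolutional branch of exactly six 3x3
#' convolutional stages plus one 1x1 convolutional stage, an optional
#' embedding branch over the 256 integer pixel intensities, concatenation of
#' the two branches, and exactly four fully connected layers.  Filter
#' counts, pooling placement, embedding dimension and dense widths are free
#' parameters; the 6+1 convolutional stages and 4 dense layers are fixed
#' structural invariants.
#'
#' @param input_shape For the 2D architecture, `c(channels, height, width)`
#'   of the AIOs; for the 1D architecture, `c(length, channels)` of the gene
#'   sequence.
#' @param n_classes Number of classes; 2 gives a single sigmoid output,
#'   K >= 3 a K-way softmax.
#' @param conv_filters Integer vector of length 6: filters of the six 3x3
#'   convolutional stages.
#' @param conv1x1_filters Filters of the final 1x1 convolutional stage.
#' @param kernel_size Side of the square (2D) or length of the 1D
#'   convolution kernel for the six main stages.
#' @param pool_after Indices (among stages 1..6) after which a max-pooling
#'   step halves the spatial resolution.
#' @param dense_units Widths of the first three fully connected layers; the
#'   fourth is the output layer.
#' @param embed_dim Dimension of the intensity-embedding branch; the branch
#'   embeds the integer pixel values 0..255 and average-pools them over the
#'   image.
#' @param use_embedding Set `FALSE` to drop the embedding branch.
#' @param l2 L2 kernel-regularizer strength applied to all weight matrices.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(input_shape, n_classes = 2,
                       conv_filters = rep(4L, 6),
                       conv1x1_filters = 4,
                       kernel_size = 3,
                       pool_after = 1L,
                       pool_type = c("avg", "max"),
                       dense_units = c(256, 128, 64),
                       embed_dim = 8,
                       use_embedding = TRUE,
                       l2 = 5e-3) {
  if (length(conv_filters) != 6L)
    stop("the convolutional branch has exactly six main stages; ",
         "`conv_filters` must have length 6")
  if (length(dense_units) != 3L)
    stop("the head has exactly four fully connected layers; ",
         "`dense_units` must name the first three widths")
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  pool_type <- match.arg(pool_type)
  structure(list(input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 conv1x1_filters = as.integer(conv1x1_filters),
                 kernel_size = as.integer(kernel_size),
                 pool_after = as.integer(pool_after),
                 pool_type = pool_type,
                 dense_units = as.integer(dense_units),
                 embed_dim = as.integer(embed_dim),
                 use_embedding = isTRUE(use_embedding),
                 l2 = as.numeric(l2)),
            class = "model_spec")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate.
#' @param epsilon Adam stability constant.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param validation_split Fraction of the training set held out to monitor
#'   validation loss (0 disables monitoring and early stopping).
#' @param patience Early-stopping patience in epochs, used only when
#'   `validation_split > 0`.
#' @param l2 Optional override of the model's kernel-regularizer strength.
#' @param seed RNG seed controlling shuffling (and recorded with the run).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, epsilon = 1e-7,
                         batch_size = 96, epochs = 12,
                         validation_split = 0, patience = 3,
                         l2 = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, epsilon > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_split = validation_split,
                 patience = as.integer(patience),
                 l2 = l2, seed = as.integer(seed)),
            class = "train_config")
}

build_classifier <- function(spec, seed, arch) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  if (arch == "2d") {
    if (length(spec$input_shape) != 3L)
      stop("2D input shape must be c(channels, height, width)")
    h <- spec$input_shape[2L]; w <- spec$input_shape[3L]
    cin <- spec$input_shape[1L]
    kh <- spec$kernel_size; kw <- spec$kernel_size
    ph <- 2L; pw <- 2L
  } else {
    if (length(spec$input_shape) != 2L)
      stop("1D input shape must be c(length, channels)")
    h <- spec$input_shape[1L]; w <- 1L
    cin <- spec$input_shape[2L]
    kh <- spec$kernel_size; kw <- 1L
    ph <- 2L; pw <- 1L
  }
  model <- new.env(parent = emptyenv())
  model$arch <- arch
  model$spec <- spec
  model$seed <- as.integer(seed)
  model$n_classes <- spec$n_classes
  model$input_dim <- c(h, w, cin)
  stack <- list()
  cc <- cin
  for (i in seq_len(6L)) {
    stack[[length(stack) + 1L]] <- nn_conv_layer(kh, kw, cc, spec$conv_filters[i])
    cc <- spec$conv_filters[i]
    if (i %in% spec$pool_after) {
      if (h %% ph != 0L || w %% pw != 0L)
        stop("input too small for the configured pooling schedule at stage ", i)
      stack[[length(stack) + 1L]] <-
        nn_pool_layer(ph, pw, if (is.null(spec$pool_type)) "max"
                              else spec$pool_type)
      h <- h %/% ph; w <- w %/% pw
    }
  }
  stack[[length(stack) + 1L]] <- nn_conv_layer(1L, 1L, cc, spec$conv1x1_filters)
  cc <- spec$conv1x1_filters
  model$stack <- stack
  model$conv_out_dim <- c(h, w, cc)
  flat <- h * w * cc
  model$embed <- if (spec$use_embedding) nn_embed_layer(256L, spec$embed_dim)
  din <- flat + if (spec$use_embedding) spec$embed_dim else 0L
  out <- if (spec$n_classes == 2L) 1L else spec$n_classes
  dense <- list()
  for (u in spec$dense_units) {
    dense[[length(dense) + 1L]] <- nn_dense_layer(din, u, "relu")
    din <- u
  }
  dense[[length(dense) + 1L]] <- nn_dense_layer(din, out, "linear")
  model$dense <- dense
  model$trained <- FALSE
  class(model) <- c("aio_model", class(model))
  model
}

#' Build the two-branch 2D CNN classifier
#'
#' Constructs the image classifier: six 3x3 convolutional stages, one 1x1
#' convolutional stage, an intensity-embedding branch, concatenation, and
#' four fully connected layers ending in a sigmoid (binary) or softmax
#' (multiclass) output.  Identical `(spec, seed)` yield identical initial
#' parameters.
#'
#' @param spec A [model_spec()] with a `c(channels, height, width)` input
#'   shape.
#' @param seed Integer seed fixing the parameter initialization.
#' @return An `aio_model` handle.
#' @export
build_2d_classifier <- function(spec, seed = 1L) build_classifier(spec, seed, "2d")

#' Build the 1D CNN classifier
#'
#' Same two-branch design as [build_2d_classifier()], but the convolutional
#' stages use 1D kernels over the gene sequence (genes ordered linearly
#' along chromosomes), so the input is a length-L intensity sequence rather
#' than an image.
#'
#' @param spec A [model_spec()] with a `c(length, channels)` input shape.
#' @param seed Integer seed fixing the parameter initialization.
#' @return An `aio_model` handle.
#' @export
build_1d_classifier <- function(spec, seed = 1L) build_classifier(spec, seed, "1d")

# Coerce the accepted input containers to the internal (N, H, W, C) array.
as_input_array <- function(model, x) {
  if (inherits(x, "aio_stack")) x <- x$tensors
  if (inherits(x, "scaled_matrix")) x <- x$values
  if (is.matrix(x)) {
    if (model$arch != "1d")
      stop("a plain samples x genes matrix is only accepted by the 1D ",
           "architecture; build AIOs for the 2D model")
    dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  } else if (length(dim(x)) == 3L && model$arch == "1d") {
    d <- dim(x)
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  }
  if (length(dim(x)) != 4L)
    stop("expected a 4D (N, H, W, C) array, an aio_stack, or (for the 1D ",
         "architecture) a samples x genes matrix")
  got <- dim(x)[-1L]
  want <- model$input_dim
  if (!all(got == want))
    stop(sprintf("input shape mismatch: model expects (H,W,C)=(%s), got (%s)",
                 paste(want, collapse = ","), paste(got, collapse = ",")))
  storage.mode(x) <- "double"
  x
}

check_labels <- function(labels, n_classes, n) {
  if (length(labels) != n)
    stop("length of labels (", length(labels), ") != number of samples (", n, ")")
  if (anyNA(labels)) stop("labels must be non-missing for all training samples")
  labels <- as.integer(labels)
  dom <- 0:(if (n_classes == 2L) 1L else n_classes - 1L)
  if (!all(labels %in% dom))
    stop("labels must lie in {", paste(dom, collapse = ","), "}")
  if (length(unique(labels)) < 2L)
    stop("degenerate labels: at least 2 classes must be present in training data")
  labels
}

sub_counts <- function(counts, idx) {
  if (is.null(counts)) NULL else counts[idx, , drop = FALSE]
}

model_counts <- function(model, x) {
  if (is.null(model$embed)) return(NULL)
  n <- dim(x)[1L]
  p <- length(x) %/% n
  xi <- as.integer(round(x))
  dim(xi) <- c(n, p)
  intensity_counts(xi, n, p, 256L)
}

#' Train a classifier
#'
#' Minibatch Adam training with fixed-seed shuffling.  With
#' `validation_split > 0` a held-out fraction monitors validation loss and
#' training stops early after `patience` epochs without improvement.
#'
#' @param model An `aio_model` from [build_2d_classifier()] or
#'   [build_1d_classifier()].
#' @param x AIO tensors: an `aio_stack`, a 4D `(N, H, W, C)` array, or (1D
#'   architecture) a samples x genes intensity matrix.
#' @param labels Integer class labels, `0/1` (binary) or `0..K-1`; no
#'   missing values.
#' @param cfg A [train_config()].
#' @return A list with `model` (the trained handle, updated in place) and
#'   `history`, a data frame of per-epoch training (and validation) loss.
#' @export
train_model <- function(model, x, labels, cfg = train_config()) {
  stopifnot(inherits(model, "aio_model"), inherits(cfg, "train_config"))
  x <- as_input_array(model, x)
  n <- dim(x)[1L]
  y <- check_labels(labels, model$n_classes, n)
  counts <- model_counts(model, x)
  l2 <- if (is.null(cfg$l2)) model$spec$l2 else cfg$l2
  set.seed(cfg$seed)
  nn_adam_init(model)
  val_idx <- integer(0)
  if (cfg$validation_split > 0) {
    nv <- max(1L, floor(cfg$validation_split * n))
    val_idx <- sample.int(n, nv)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf; stale <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      xb <- x[idx, , , , drop = FALSE]
      logits <- nn_forward(model, xb, sub_counts(counts, idx),
                           training = TRUE)
      lg <- nn_loss_grad(logits, y[idx], model$n_classes)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss); try a lower learning rate")
      nn_backward(model, lg$grad)
      nn_adam_step(model, cfg$learning_rate, 0.9, 0.999, cfg$epsilon, l2)
      ep_loss <- ep_loss + lg$loss * length(idx); nb <- nb + length(idx)
    }
    vl <- NA_real_
    if (length(val_idx)) {
      vlog <- nn_forward(model, x[val_idx, , , , drop = FALSE],
                         sub_counts(counts, val_idx), training = FALSE)
      vl <- nn_loss_grad(vlog, y[val_idx], model$n_classes)$loss
      if (vl < best_val - 1e-6) { best_val <- vl; stale <- 0L }
      else stale <- stale + 1L
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   val_loss = vl))
    if (length(val_idx) && stale >= cfg$patience) break
  }
  model$trained <- TRUE
  model$cfg <- cfg
  invisible(list(model = model, history = hist))
}

#' Predict class probabilities and calls
#'
#' @param model A trained `aio_model`.
#' @param x AIO tensors (same containers as [train_model()]).
#' @param sample_ids Optional sample identifiers; taken from an `aio_stack`
#'   when available.
#' @param threshold Binary decision threshold; the call is 1 iff
#'   `prob > threshold` (strict), so a probability of exactly 0.5 yields
#'   call 0 under the default.  Multiclass calls are the argmax with ties
#'   broken toward the lowest class index.
#' @return A `prediction_set` data frame: `sample_id`, probability
#'   column(s), and `call`.
#' @export
predict_proba <- function(model, x, sample_ids = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "aio_model"))
  if (is.null(sample_ids) && inherits(x, "aio_stack")) sample_ids <- x$sample_ids
  x <- as_input_array(model, x)
  n <- dim(x)[1L]
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  counts <- model_counts(model, x)
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 128))
  out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    idx <- chunks[[i]]
    logits <- nn_forward(model, x[idx, , , , drop = FALSE],
                         sub_counts(counts, idx), training = FALSE)
    out[[i]] <- nn_probs(logits, model$n_classes)
  }
  if (model$n_classes == 2L) {
    p <- unlist(out)
    res <- data.frame(sample_id = sample_ids, prob = p,
                      call = as.integer(p > threshold),
                      stringsAsFactors = FALSE)
  } else {
    p <- do.call(rbind, out)
    colnames(p) <- paste0("prob_", seq_len(ncol(p)) - 1L)
    res <- data.frame(sample_id = sample_ids, p,
                      call = max.col(p, ties.method = "first") - 1L,
                      stringsAsFactors = FALSE)
  }
  class(res) <- c("prediction_set", class(res))
  res
}

#' Repeat a run with perturbed configurations
#'
#' Runs a user-supplied evaluation function under `n_runs` slightly
#' different training configurations (by default, consecutive seeds) and
#' reports per-run metrics plus their mean and standard deviation, the
#' mean +- sd convention used throughout the package's reports.
#'
#' @param run_fn Function taking a [train_config()] and returning a named
#'   numeric vector of metrics.
#' @param base_cfg The base [train_config()].
#' @param n_runs Number of runs (>= 1).
#' @param perturbations Optional list (length `n_runs`) of named lists of
#'   `train_config` overrides per run, e.g.
#'   `list(list(seed = 2), list(learning_rate = 2e-3))`.  Default: run i
#'   uses `seed = base_cfg$seed + i - 1`.
#' @return A `run_ensemble`: `runs` (per-run metric rows), `summary`
#'   (mean and sd per metric), and `configs`.
#' @export
repeated_runs <- function(run_fn, base_cfg = train_config(), n_runs = 5,
                          perturbations = NULL) {
  stopifnot(n_runs >= 1)
  if (is.null(perturbations))
    perturbations <- lapply(seq_len(n_runs) - 1L,
                            function(i) list(seed = base_cfg$seed + i))
  if (length(perturbations) != n_runs)
    stop("`perturbations` must have one entry per run")
  cfgs <- lapply(perturbations, function(p) {
    cfg <- utils::modifyList(base_cfg, p)
    class(cfg) <- "train_config"
    cfg
  })
  if (n_runs > 1L && length(unique(lapply(cfgs, unclass))) == 1L)
    warning("all run configurations are identical; repeated runs will coincide")
  rows <- lapply(cfgs, run_fn)
  runs <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  runs <- cbind(run = seq_len(n_runs), seed = vapply(cfgs, `[[`, 1L, "seed"),
                runs)
  metr <- setdiff(names(runs), c("run", "seed"))
  summ <- data.frame(metric = metr,
                     mean = vapply(metr, function(m) mean(runs[[m]]), 0),
                     sd = vapply(metr, function(m) stats::sd(runs[[m]]), 0),
                     row.names = NULL)
  structure(list(runs = runs, summary = summ, configs = cfgs),
            class = "run_ensemble")
}

#' @export
print.run_ensemble <- function(x, ...) {
  cat("Run ensemble over", nrow(x$runs), "runs\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %.4f +- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the architecture spec, training configuration, seed and all
#' weights; `load_model()` rebuilds the handle so predictions reproduce
#' exactly.
#'
#' @param model An `aio_model`.
#' @param path File path for the serialized model.
#' @return `save_model()` returns `path` invisibly; `load_model()` returns
#'   the rebuilt `aio_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "aio_model"))
  snap <- list(arch = model$arch, spec = model$spec, seed = model$seed,
               cfg = model$cfg, trained = model$trained,
               stack_w = lapply(model$stack, function(l)
                 if (l$type == "conv") list(W = l$W, b = l$b)),
               embed_w = if (!is.null(model$embed)) model$embed$W,
               dense_w = lapply(model$dense, function(l) list(W = l$W, b = l$b)))
  saveRDS(snap, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  snap <- readRDS(path)
  model <- build_classifier(snap$spec, snap$seed, snap$arch)
  for (i in seq_along(model$stack))
    if (model$stack[[i]]$type == "conv") {
      model$stack[[i]]$W <- snap$stack_w[[i]]$W
      model$stack[[i]]$b <- snap$stack_w[[i]]$b
    }
  if (!is.null(model$embed)) model$embed$W <- snap$embed_w
  for (i in seq_along(model$dense)) {
    model$dense[[i]]$W <- snap$dense_w[[i]]$W
    model$dense[[i]]$b <- snap$dense_w[[i]]$b
  }
  model$cfg <- snap$cfg
  model$trained <- snap$trained
  model
}
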
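#' CNN classifier configuration
#'
#' Configuration of the convolutional CTC classifier. The \code{baseline3}
#' architecture has three hidden blocks, each a convolution, ReLU
#' excitation, and max-pooling layer; its first block is fixed at 32
#' convolution kernels of 5x5. Kernel counts double in the later blocks
#' (64, 128). The named large architectures (VGG16/19, ResNet18/50,
#' AlexNet) are instantiated per their published layer schedules at the
#' configured input size.
#'
#' @param architecture One of \code{"baseline3"}, \code{"vgg16"},
#'   \code{"vgg19"}, \code{"resnet18"}, \code{"resnet50"}, \code{"alexnet"}.
#' @param input_size Square input side in pixels; crops are resized to this.
#' @param channels_used Subset of \code{c("dapi", "cep8", "cd45")} stacked
#'   as input planes. All three are used by default because the CTC label
#'   depends on CD45 status as well as the CEP8 signal count.
#' @param learning_rate,batch_size,epochs Training scalars (Adam optimizer,
#'   binary cross-entropy loss).
#' @param seed Integer seed controlling weight initialization and batch
#'   shuffling.
#' @param transfer Whether this model was transfer-initialized.
#' @return An object of class \code{cnn_config}.
#' @export
cnn_config <- function(architecture = "baseline3", input_size = 64,
                       channels_used = c("dapi", "cep8", "cd45"),
                       learning_rate = 1e-3, batch_size = 32, epochs = 20,
                       seed = 1L, transfer = FALSE) {
  archs <- c("baseline3", "vgg16", "vgg19", "resnet18", "resnet50", "alexnet")
  if (!architecture %in% archs)
    stop("unknown architecture: ", architecture)
  stopifnot(input_size >= 16, length(channels_used) >= 1,
            all(channels_used %in% c("dapi", "cep8", "cd45")),
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(architecture = architecture,
                 input_size = as.integer(input_size),
                 channels_used = channels_used,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 transfer = isTRUE(transfer)),
            class = "cnn_config")
}

conv_out <- function(s, k, stride, pad) (s + 2 * pad - k) %/% stride + 1

# Returns list(layers, block_of, n_feature_layers). block_of assigns each
# top-level feature layer to a feature block (pool-delimited for sequential
# nets, one block per residual unit for ResNets).
build_layers <- function(config) {
  S <- config$input_size
  C <- length(config$channels_used)
  arch <- config$architecture
  layers <- list(); block <- integer(0); bi <- 1L
  push <- function(l) { layers[[length(layers) + 1]] <<- l; block <<- c(block, bi) }

  if (arch == "baseline3") {
    kernels <- c(32, 64, 128); ks <- c(5, 3, 3); cin <- C; s <- S
    for (i in 1:3) {
      push(L_conv(ks[i], ks[i], cin, kernels[i], 1L, (ks[i] - 1L) %/% 2L))
      push(L_relu())
      push(L_pool(2L))
      s <- conv_out(s, 2, 2, 0); cin <- kernels[i]; bi <- bi + 1L
    }
    head <- list(L_flatten(), L_dense(cin * s * s, 1L))
  } else if (arch %in% c("vgg16", "vgg19")) {
    sched <- if (arch == "vgg16") list(c(64, 64), c(128, 128), c(256, 256, 256),
                                       c(512, 512, 512), c(512, 512, 512))
             else list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                       c(512, 512, 512, 512), c(512, 512, 512, 512))
    cin <- C; s <- S
    for (blk in sched) {
      for (co in blk) {
        push(L_conv(3L, 3L, cin, co, 1L, 1L)); push(L_relu()); cin <- co
      }
      push(L_pool(2L)); s <- conv_out(s, 2, 2, 0); bi <- bi + 1L
      if (s < 1) stop("input_size too small for ", arch)
    }
    head <- list(L_flatten(), L_dense(cin * s * s, 4096L), L_relu(),
                 L_dense(4096L, 4096L), L_relu(), L_dense(4096L, 1L))
  } else if (arch == "alexnet") {
    s <- S
    push(L_conv(11L, 11L, C, 96L, 4L, 2L)); push(L_relu())
    s <- conv_out(s, 11, 4, 2)
    push(L_pool(3L, 2L)); s <- conv_out(s, 3, 2, 0); bi <- bi + 1L
    push(L_conv(5L, 5L, 96L, 256L, 1L, 2L)); push(L_relu())
    push(L_pool(3L, 2L)); s <- conv_out(s, 3, 2, 0); bi <- bi + 1L
    push(L_conv(3L, 3L, 256L, 384L, 1L, 1L)); push(L_relu())
    push(L_conv(3L, 3L, 384L, 384L, 1L, 1L)); push(L_relu())
    push(L_conv(3L, 3L, 384L, 256L, 1L, 1L)); push(L_relu())
    push(L_pool(3L, 2L)); s <- conv_out(s, 3, 2, 0); bi <- bi + 1L
    if (s < 1) stop("input_size too small for alexnet")
    head <- list(L_flatten(), L_dense(256L * s * s, 4096L), L_relu(),
                 L_dense(4096L, 4096L), L_relu(), L_dense(4096L, 1L))
  } else if (arch %in% c("resnet18", "resnet50")) {
    push(L_conv(7L, 7L, C, 64L, 2L, 3L)); push(L_bn(64L)); push(L_relu())
    push(L_pool(3L, 2L, 1L)); bi <- bi + 1L
    basic <- function(cin, cout, stride) {
      f <- list(L_conv(3L, 3L, cin, cout, stride, 1L), L_bn(cout), L_relu(),
                L_conv(3L, 3L, cout, cout, 1L, 1L), L_bn(cout))
      s <- if (stride != 1 || cin != cout)
        list(L_conv(1L, 1L, cin, cout, stride, 0L), L_bn(cout)) else NULL
      L_res(f, s)
    }
    bottleneck <- function(cin, mid, stride) {
      cout <- 4L * mid
      f <- list(L_conv(1L, 1L, cin, mid, stride, 0L), L_bn(mid), L_relu(),
                L_conv(3L, 3L, mid, mid, 1L, 1L), L_bn(mid), L_relu(),
                L_conv(1L, 1L, mid, cout, 1L, 0L), L_bn(cout))
      s <- if (stride != 1 || cin != cout)
        list(L_conv(1L, 1L, cin, cout, stride, 0L), L_bn(cout)) else NULL
      L_res(f, s)
    }
    if (arch == "resnet18") {
      counts <- c(2, 2, 2, 2); widths <- c(64, 128, 256, 512); cin <- 64L
      for (st in 1:4) for (b in seq_len(counts[st])) {
        stride <- if (st > 1 && b == 1) 2L else 1L
        push(basic(cin, widths[st], stride)); cin <- widths[st]; bi <- bi + 1L
      }
      head <- list(L_gap(), L_dense(512L, 1L))
    } else {
      counts <- c(3, 4, 6, 3); mids <- c(64, 128, 256, 512); cin <- 64L
      for (st in 1:4) for (b in seq_len(counts[st])) {
        stride <- if (st > 1 && b == 1) 2L else 1L
        push(bottleneck(cin, mids[st], stride)); cin <- 4L * mids[st]; bi <- bi + 1L
      }
      head <- list(L_gap(), L_dense(2048L, 1L))
    }
    if (S < 32) stop("input_size too small for ", arch)
  } else stop("unknown architecture: ", arch)

  n_feature <- length(layers)
  layers <- c(layers, head)
  list(layers = layers, block_of = block, n_feature_layers = n_feature)
}

#' Build an (untrained) CNN classifier
#'
#' Allocates and initializes the network described by the configuration.
#' Weights use He-normal initialization seeded from \code{config$seed}, so
#' two builds from the same config are identical.
#'
#' @param config A \code{\link{cnn_config}} object.
#' @return An object of class \code{ctc_cnn} with fields \code{config},
#'   \code{layers}, \code{trained}, \code{history}.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "cnn_config"))
  arch <- build_layers(config)
  set.seed(config$seed)
  arch$layers <- nn_init(arch$layers)
  structure(list(config = config, layers = arch$layers,
                 block_of = arch$block_of,
                 n_feature_layers = arch$n_feature_layers,
                 trained = FALSE, history = NULL),
            class = "ctc_cnn")
}

#' Number of trainable parameters
#' @param model A \code{ctc_cnn}.
#' @return Integer-valued count.
#' @export
n_params <- function(model) nn_param_count(model$layers)

#' Stack cell crops into a model input tensor
#'
#' Resizes the selected channels of each crop to the configured square input
#' size, scales intensities to \code{[0, 1]}, and stacks them into an array
#' of dim \code{(size, size, channels, n)}.
#'
#' @param crops List of \code{cell_crop} objects (each with \code{dapi},
#'   \code{cep8}, \code{cd45} matrices).
#' @param config A \code{\link{cnn_config}}.
#' @return 4-D numeric array.
#' @export
crops_to_tensor <- function(crops, config) {
  S <- config$input_size
  ch <- config$channels_used
  n <- length(crops)
  x <- array(0, dim = c(S, S, length(ch), n))
  for (i in seq_len(n)) {
    for (j in seq_along(ch)) {
      m <- crops[[i]][[ch[j]]]
      x[, , j, i] <- EBImage::imageData(
        EBImage::resize(EBImage::Image(m / 255), w = S, h = S))
    }
  }
  x
}

as_binary_labels <- function(y) {
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "CTC"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be binary (0/1 or CTC/non-CTC)")
  y
}

as_input_tensor <- function(x, config) {
  if (is.list(x) && !is.array(x)) x <- crops_to_tensor(x, config)
  stopifnot(length(dim(x)) == 4)
  x
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a CNN classifier
#'
#' Minimizes binary cross-entropy with the Adam optimizer. When validation
#' data are supplied, the per-epoch validation AUC is recorded in the
#' training history. Deterministic under a fixed config seed in
#' single-threaded BLAS mode.
#'
#' @param model A \code{ctc_cnn} from \code{\link{build_model}} or
#'   \code{\link{transfer_init}}.
#' @param x Input tensor (dim \code{(S, S, C, N)}) or a list of crops.
#' @param y Binary labels (0/1, logical, or \code{"CTC"}/\code{"non-CTC"}).
#' @param xval,yval Optional validation data.
#' @param epochs Overrides \code{config$epochs} when given.
#' @param verbose Print per-epoch loss.
#' @return The trained \code{ctc_cnn}, with \code{history} (a data frame of
#'   epoch, loss, val_auc).
#' @export
train_cnn <- function(model, x, y, xval = NULL, yval = NULL,
                      epochs = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "ctc_cnn"))
  cfg <- model$config
  epochs <- as.integer(epochs %||% cfg$epochs)
  if (epochs < 1) stop("epochs must be at least 1")
  x <- as_input_tensor(x, cfg)
  y <- as_binary_labels(y)
  n <- dim(x)[4]
  stopifnot(length(y) == n)
  if (length(unique(y)) < 2)
    stop("training input contains a single class")
  if (!is.null(xval)) {
    xval <- as_input_tensor(xval, cfg)
    yval <- as_binary_labels(yval)
  }

  layers <- model$layers
  state <- vector("list", length(layers))
  set.seed(cfg$seed + 1L)
  t <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0), val_auc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx]
      fw <- nn_forward(layers, xb, train = TRUE)
      logits <- as.numeric(fw$out)
      p <- sigmoid(logits)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      losses <- c(losses, -mean(yb * log(pc) + (1 - yb) * log(1 - pc)))
      dlogit <- matrix((p - yb) / length(yb), nrow = 1)
      bw <- nn_backward(layers, fw$caches, dlogit)
      t <- t + 1L
      upd <- nn_adam_step(layers, bw$grads, fw$caches, state, cfg$learning_rate, t)
      layers <- upd$layers
      state <- upd$state
    }
    val_auc <- NA_real_
    if (!is.null(xval)) {
      sc <- predict_scores(layers, xval, cfg$batch_size)
      val_auc <- if (length(unique(yval)) == 2) roc_auc(sc, yval)$auc else NA_real_
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(losses),
                                   val_auc = val_auc))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val_auc %s", ep, mean(losses),
                      ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
  }
  model$layers <- layers
  model$trained <- TRUE
  model$history <- rbind(model$history, hist)
  model
}

predict_scores <- function(layers, x, batch_size) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- nn_forward(layers, x[, , , idx, drop = FALSE], train = FALSE)
    out[idx] <- sigmoid(as.numeric(fw$out))
  }
  out
}

#' Predict CTC probability scores
#'
#' @param object A trained \code{ctc_cnn}.
#' @param newdata Input tensor or list of crops.
#' @param ... Unused.
#' @return Numeric scores in \code{[0, 1]}, one per crop; threshold at 0.5
#'   for hard labels.
#' @export
predict.ctc_cnn <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop("model is untrained")
  x <- as_input_tensor(newdata, object$config)
  predict_scores(object$layers, x, object$config$batch_size)
}

#' Describe a transfer-learning setup
#'
#' A domain is a feature space together with a marginal distribution over
#' it; a task is a label space with a prediction function. Transfer copies
#' the feature-extractor parameters learned on the source domain/task into
#' the target model. It is meaningful only when the two domains differ in
#' feature space or marginal distribution; a warning is issued otherwise.
#'
#' @param source_domain,target_domain Lists with elements
#'   \code{feature_space} and \code{marginal} (free-text descriptors).
#' @param source_task,target_task Optional label-space descriptors.
#' @param frozen_depth Number of leading feature blocks whose copied
#'   parameters are held fixed during fine-tuning.
#' @return An object of class \code{transfer_spec}.
#' @export
transfer_spec <- function(source_domain, target_domain,
                          source_task = "source", target_task = "ctc",
                          frozen_depth = 0L) {
  stopifnot(frozen_depth >= 0)
  if (identical(source_domain, target_domain))
    warning("source and target domains are identical; transfer adds nothing")
  structure(list(source_domain = source_domain, target_domain = target_domain,
                 source_task = source_task, target_task = target_task,
                 frozen_depth = as.integer(frozen_depth)),
            class = "transfer_spec")
}

#' Initialize a model from a pre-trained source network
#'
#' Copies the feature-block parameters of a trained source model into a
#' freshly built target model, optionally freezing the first
#' \code{frozen_depth} blocks against gradient updates. The classifier head
#' keeps its fresh initialization.
#'
#' @param target_config A \code{\link{cnn_config}} (same architecture and
#'   input size as the source).
#' @param source A trained \code{ctc_cnn}.
#' @param spec A \code{\link{transfer_spec}}.
#' @return An initialized, untrained \code{ctc_cnn} with
#'   \code{config$transfer = TRUE}.
#' @export
transfer_init <- function(target_config, source, spec) {
  stopifnot(inherits(source, "ctc_cnn"), inherits(spec, "transfer_spec"))
  if (target_config$architecture != source$config$architecture ||
      target_config$input_size != source$config$input_size ||
      !identical(target_config$channels_used, source$config$channels_used))
    stop("source feature blocks are incompatible with the target config")
  target_config$transfer <- TRUE
  model <- build_model(target_config)
  n_blocks <- max(model$block_of)
  if (spec$frozen_depth > n_blocks)
    stop("frozen_depth exceeds the ", n_blocks, " feature blocks")
  for (i in seq_len(model$n_feature_layers)) {
    model$layers[[i]] <- copy_layer_params(model$layers[[i]], source$layers[[i]])
    model$layers[[i]] <- set_frozen(model$layers[[i]],
                                    model$block_of[i] <= spec$frozen_depth)
  }
  model
}

copy_layer_params <- function(dst, src) {
  if (dst$type == "res") {
    for (j in seq_along(dst$f)) dst$f[[j]] <- copy_layer_params(dst$f[[j]], src$f[[j]])
    if (!is.null(dst$s))
      for (j in seq_along(dst$s)) dst$s[[j]] <- copy_layer_params(dst$s[[j]], src$s[[j]])
  } else if (!is.null(dst$params)) {
    for (nm in names(dst$params)) {
      if (!identical(dim(dst$params[[nm]]), dim(src$params[[nm]])) ||
          length(dst$params[[nm]]) != length(src$params[[nm]]))
        stop("incompatible parameter shapes during transfer")
      dst$params[[nm]] <- src$params[[nm]]
    }
    if (dst$type == "bn") {
      dst$running_mean <- src$running_mean
      dst$running_var <- src$running_var
    }
  }
  dst
}

set_frozen <- function(l, frozen) {
  if (l$type == "res") {
    for (j in seq_along(l$f)) l$f[[j]] <- set_frozen(l$f[[j]], frozen)
    if (!is.null(l$s))
      for (j in seq_along(l$s)) l$s[[j]] <- set_frozen(l$s[[j]], frozen)
  } else if (!is.null(l$params)) l$frozen <- frozen
  l
}

#' Parameter checksum of a model
#'
#' MD5 digest of the serialized parameter tensors; stable across save/load
#' round trips.
#'
#' @param model A \code{ctc_cnn}.
#' @param which \code{"all"}, \code{"features"} (layers before the head), or
#'   \code{"head"}.
#' @return Character MD5 string.
#' @export
model_checksum <- function(model, which = c("all", "features", "head")) {
  which <- match.arg(which)
  idx <- switch(which,
                all = seq_along(model$layers),
                features = seq_len(model$n_feature_layers),
                head = setdiff(seq_along(model$layers),
                               seq_len(model$n_feature_layers)))
  params <- nn_collect_params(model$layers[idx])
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(params, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Save / load a model checkpoint
#'
#' A single checkpoint file holding the parameters with the configuration
#' embedded as a YAML string.
#'
#' @param model A \code{ctc_cnn}.
#' @param path Checkpoint file path.
#' @return \code{load_model} returns the restored \code{ctc_cnn}.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$config_yaml <- yaml::as.yaml(unclass(model$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  obj$config <- structure(obj$config, class = "cnn_config")
  structure(obj, class = "ctc_cnn")
}
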
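#' Training configuration for the sweep classifier
#'
#' @param validation_fraction fraction of the training examples held out
#'   as a validation set for early stopping (default 0.10).
#' @param patience_epochs training stops after this many consecutive
#'   epochs without a validation-loss improvement (default 5).
#' @param min_loss_delta the smallest decrease in categorical
#'   cross-entropy that counts as an improvement (default 0.001).
#' @param max_epochs upper bound on training epochs.
#' @param batch_size minibatch size.
#' @param hidden sizes of the hidden layers.
#' @param learning_rate Adam step size.
#' @param augment_mirror also train on each example with its subwindow
#'   axis reversed; the class definitions are invariant under this
#'   reflection, so it doubles the effective training set. Validation
#'   examples are never augmented.
#' @param seed integer seed controlling initialization, the validation
#'   split and minibatch order.
#' @return a list of class \code{"training_config"}.
#' @export
training_config <- function(validation_fraction = 0.10,
                            patience_epochs = 5L, min_loss_delta = 0.001,
                            max_epochs = 120L, batch_size = 32L,
                            hidden = c(64L, 32L), learning_rate = 1e-3,
                            augment_mirror = TRUE, seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  if (patience_epochs < 1L) stop("patience_epochs must be >= 1")
  structure(list(validation_fraction = validation_fraction,
                 patience_epochs = as.integer(patience_epochs),
                 min_loss_delta = min_loss_delta,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 hidden = as.integer(hidden),
                 learning_rate = learning_rate,
                 augment_mirror = isTRUE(augment_mirror),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Early-stopping controller
#'
#' Stateful tracker of the validation loss: an epoch "improves" when its
#' loss is at least \code{min_delta} below the best loss seen so far.
#' After \code{patience} consecutive non-improving epochs the controller
#' reports that training should stop; the epoch with the best loss is
#' recorded so its weights can be restored.
#'
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_delta minimum decrease that counts as improvement.
#' @return a function \code{f(loss)} returning a list with
#'   \code{improved}, \code{stop}, \code{best_loss} and \code{best_epoch}.
#' @export
make_early_stopper <- function(patience, min_delta) {
  best <- Inf
  best_epoch <- 0L
  wait <- 0L
  epoch <- 0L
  function(loss) {
    epoch <<- epoch + 1L
    improved <- (best - loss) >= min_delta
    if (improved) {
      best <<- loss
      best_epoch <<- epoch
      wait <<- 0L
    } else {
      wait <<- wait + 1L
    }
    list(improved = improved, stop = wait >= patience,
         best_loss = best, best_epoch = best_epoch)
  }
}

# ---- network internals ----------------------------------------------------

.init_net <- function(d_in, hidden, n_out) {
  sizes <- c(d_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1L), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1L],
                                 sd = sqrt(2 / sizes[i])),
                    nrow = sizes[i]),
         b = rep(0, sizes[i + 1L]))
  })
}

.forward <- function(net, x) {
  acts <- vector("list", length(net) + 1L)
  acts[[1L]] <- x
  for (i in seq_along(net)) {
    z <- acts[[i]] %*% net[[i]]$W
    z <- sweep(z, 2L, net[[i]]$b, "+")
    acts[[i + 1L]] <- if (i < length(net)) pmax(z, 0) else z
  }
  logits <- acts[[length(acts)]]
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  list(probs = e / rowSums(e), acts = acts)
}

.xent <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), y_idx)], 1e-12)))
}

# one Adam minibatch step; returns updated net and optimizer state
.adam_step <- function(net, grads, state, lr, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (i in seq_along(net)) {
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- b1 * state$m[[i]][[p]] + (1 - b1) * g
      state$v[[i]][[p]] <- b2 * state$v[[i]][[p]] + (1 - b2) * g^2
      mhat <- state$m[[i]][[p]] / (1 - b1^t)
      vhat <- state$v[[i]][[p]] / (1 - b2^t)
      net[[i]][[p]] <- net[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

.backward <- function(net, fw, y_idx) {
  n <- nrow(fw$probs)
  delta <- fw$probs
  delta[cbind(seq_len(n), y_idx)] <- delta[cbind(seq_len(n), y_idx)] - 1
  delta <- delta / n
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    a <- fw$acts[[i]]
    grads[[i]] <- list(W = crossprod(a, delta), b = colSums(delta))
    if (i > 1L) {
      delta <- delta %*% t(net[[i]]$W)
      delta[fw$acts[[i]] <= 0] <- 0
    }
  }
  grads
}

# ---- public API -----------------------------------------------------------

#' Train the five-class sweep classifier
#'
#' Fits a small fully-connected softmax network on normalized feature
#' vectors by minimizing categorical cross-entropy with Adam. A seeded,
#' class-stratified validation split drives early stopping: training ends
#' when \code{patience_epochs} consecutive epochs each fail to lower the
#' validation loss by at least \code{min_loss_delta} (or at
#' \code{max_epochs}), and the weights from the best validation epoch are
#' restored.
#'
#' @param x numeric matrix, one row per example (feature vectors from
#'   \code{\link{feature_vector}}).
#' @param y factor of class labels with levels
#'   \code{\link{sweep_classes}()}; every class must be present.
#' @param config a \code{\link{training_config}}.
#' @return an object of class \code{"sweep_classifier"} with the fitted
#'   weights, feature standardization, class order and training history.
#' @export
train_classifier <- function(x, y, config = training_config()) {
  stopifnot(is.matrix(x), inherits(config, "training_config"))
  y <- factor(y, levels = sweep_classes())
  if (nrow(x) != length(y)) stop("x and y size mismatch")
  missing_cl <- setdiff(sweep_classes(), unique(as.character(y)))
  if (length(missing_cl))
    stop(sprintf("class(es) absent from the training set: %s",
                 paste(missing_cl, collapse = ", ")))

  set.seed(config$seed)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  y_idx <- as.integer(y)

  # stratified validation split
  val_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
    n_val <- max(1L, round(length(idx) * config$validation_fraction))
    sample(idx, n_val)
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_along(y), val_idx)

  xs_tr <- xs[tr_idx, , drop = FALSE]
  y_tr <- y_idx[tr_idx]
  if (config$augment_mirror && ncol(x) %% 12L == 0L) {
    xs_tr <- rbind(xs_tr, .mirror_subwindows(xs_tr))
    y_tr <- c(y_tr, y_tr)
  }

  net <- .init_net(ncol(x), config$hidden, length(sweep_classes()))
  zero_like <- lapply(net, function(l) list(W = l$W * 0, b = l$b * 0))
  state <- list(m = zero_like, v = zero_like)
  stopper <- make_early_stopper(config$patience_epochs,
                                config$min_loss_delta)
  best_net <- net
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  t_step <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(nrow(xs_tr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    for (b in batches) {
      fw <- .forward(net, xs_tr[b, , drop = FALSE])
      grads <- .backward(net, fw, y_tr[b])
      t_step <- t_step + 1L
      upd <- .adam_step(net, grads, state, config$learning_rate, t_step)
      net <- upd$net
      state <- upd$state
    }
    tr_loss <- .xent(.forward(net, xs_tr)$probs, y_tr)
    val_loss <- .xent(.forward(net, xs[val_idx, , drop = FALSE])$probs,
                      y_idx[val_idx])
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss,
                                         val_loss = val_loss))
    st <- stopper(val_loss)
    if (st$improved) best_net <- net
    if (st$stop) break
  }
  structure(list(net = best_net, center = ctr, scale = scl,
                 classes = sweep_classes(), config = config,
                 history = history,
                 n_features = ncol(x)),
            class = "sweep_classifier")
}

#' @exportS3Method base::print
print.sweep_classifier <- function(x, ...) {
  cat(sprintf("Sweep classifier: %d features -> [%s] -> %d classes; trained %d epochs (best val loss %.4f)\n",
              x$n_features, paste(x$config$hidden, collapse = ", "),
              length(x$classes), nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

#' Class-membership posteriors for feature vectors
#'
#' Softmax probabilities over the five classes; deterministic for a fixed
#' model and input.
#'
#' @param model a fitted \code{"sweep_classifier"}.
#' @param x a numeric feature-vector matrix (one row per window), a
#'   single feature vector, or a \code{"feature_matrix"}.
#' @param window_id identifiers for the rows.
#' @return data.frame of class \code{"class_posterior"}: \code{window_id},
#'   \code{p_hard}, \code{p_hard_linked}, \code{p_soft},
#'   \code{p_soft_linked}, \code{p_neutral} (each row sums to 1).
#' @export
predict_posterior <- function(model, x, window_id = NULL) {
  stopifnot(inherits(model, "sweep_classifier"))
  if (inherits(x, "feature_matrix")) x <- rbind(feature_vector(x))
  if (!is.matrix(x)) x <- rbind(x)
  if (ncol(x) != model$n_features)
    stop(sprintf("feature matrix has %d columns; model expects %d",
                 ncol(x), model$n_features))
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  probs <- .forward(model$net, xs)$probs
  if (is.null(window_id))
    window_id <- if (!is.null(rownames(x))) rownames(x)
    else sprintf("window_%d", seq_len(nrow(x)))
  out <- data.frame(window_id = window_id,
                    p_hard = probs[, 1L], p_hard_linked = probs[, 2L],
                    p_soft = probs[, 3L], p_soft_linked = probs[, 4L],
                    p_neutral = probs[, 5L],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("class_posterior", "data.frame")
  out
}

# reverse the subwindow axis within each statistic's block of columns
.mirror_subwindows <- function(x) {
  k <- ncol(x) %/% 12L
  idx <- as.vector(vapply(seq_len(12L) - 1L, function(s) s * k + k:1,
                          integer(k)))
  x[, idx, drop = FALSE]
}

# posterior columns in fixed class order
.posterior_matrix <- function(post) {
  as.matrix(post[, c("p_hard", "p_hard_linked", "p_soft",
                     "p_soft_linked", "p_neutral")])
}

# argmax class label per row
.posterior_argmax <- function(post) {
  sweep_classes()[max.col(.posterior_matrix(post), ties.method = "first")]
}

#' Save a fitted classifier to a directory
#'
#' Writes a JSON manifest (architecture, class order, seed, training
#' history, standardization) plus one TSV per weight matrix.
#'
#' @param model a \code{"sweep_classifier"}.
#' @param dir output directory (created if needed).
#' @export
save_classifier <- function(model, dir) {
  stopifnot(inherits(model, "sweep_classifier"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(type = "sweep_classifier",
                   n_features = model$n_features,
                   hidden = model$config$hidden,
                   classes = model$classes,
                   seed = model$config$seed,
                   config = unclass(model$config),
                   history = model$history,
                   n_layers = length(model$net))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  fmt <- function(m) {
    ch <- sprintf("%.17g", m)
    dim(ch) <- dim(m)
    ch
  }
  utils::write.table(t(sprintf("%.17g", model$center)),
                     file.path(dir, "center.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(t(sprintf("%.17g", model$scale)),
                     file.path(dir, "scale.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (i in seq_along(model$net)) {
    utils::write.table(fmt(model$net[[i]]$W),
                       file.path(dir, sprintf("W%d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(t(sprintf("%.17g", model$net[[i]]$b)),
                       file.path(dir, sprintf("b%d.tsv", i)),
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(dir)
}

#' Load a classifier saved by \code{\link{save_classifier}}
#' @param dir model directory.
#' @return a \code{"sweep_classifier"}.
#' @export
load_classifier <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  net <- lapply(seq_len(manifest$n_layers), function(i) {
    W <- as.matrix(utils::read.table(file.path(dir, sprintf("W%d.tsv", i)),
                                     sep = "\t"))
    dimnames(W) <- NULL
    b <- as.numeric(utils::read.table(file.path(dir, sprintf("b%d.tsv", i)),
                                      sep = "\t"))
    list(W = W, b = b)
  })
  cfg <- manifest$config
  config <- training_config(cfg$validation_fraction, cfg$patience_epochs,
                            cfg$min_loss_delta, cfg$max_epochs,
                            cfg$batch_size, cfg$hidden, cfg$learning_rate,
                            cfg$augment_mirror, cfg$seed)
  center <- as.numeric(utils::read.table(file.path(dir, "center.tsv"),
                                         sep = "\t"))
  scale <- as.numeric(utils::read.table(file.path(dir, "scale.tsv"),
                                        sep = "\t"))
  structure(list(net = net, center = center,
                 scale = scale, classes = manifest$classes,
                 config = config, history = manifest$history,
                 n_features = manifest$n_features),
            class = "sweep_classifier")
}
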
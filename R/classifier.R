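#' Build a sliding-window dataset from a labelled movie
#'
#' One window per valid center frame: a 25-frame stack (12 frames before,
#' the center, 12 after), labelled with the movement class of its center
#' frame. A movie of N frames yields N - 24 overlapping windows.
#'
#' Windows are not materialized; the dataset keeps per-frame pooled
#' features (a fixed average-pooling front end over row bands x column
#' bands) and assembles window features by pooling over time bands. This is
#' the desk-scale stand-in for a convolutional feature extractor: the
#' learned part of the classifier consumes the pooled features.
#'
#' @param stack numeric array rows x cols x N (N >= 25).
#' @param frame_labels movement class per frame (length N).
#' @param animal_id identifier carried into training splits.
#' @param depth window depth in frames (odd; default 25).
#' @param row_bands,col_bands,time_bands pooling grid.
#' @return object of class `window_dataset`: `centers` (0-based center
#'   frames), `labels`, `features` (matrix, one row per window),
#'   `animal_id`, `depth`.
#' @export
make_windows <- function(stack, frame_labels, animal_id = "A01",
                         depth = 25, row_bands = 7, col_bands = 6,
                         time_bands = 5) {
  stopifnot_data(length(dim(stack)) == 3, "stack must be 3-d")
  n <- dim(stack)[3]
  if (n < depth) {
    abort_ecdysim(sprintf("need at least %d frames, got %d", depth, n),
                  "ecdysim_insufficient_data")
  }
  stopifnot_data(length(frame_labels) == n, "labels must cover all frames")
  stopifnot_config(depth %% 2 == 1, "window depth must be odd")
  half <- (depth - 1L) %/% 2L

  frame_feats <- pool_frames(stack, row_bands, col_bands)   # n x (rb*cb)
  centers <- half:(n - half - 1L)                            # 0-based
  tb_idx <- split(seq_len(depth),
                  cut(seq_len(depth), time_bands, labels = FALSE))
  feats <- matrix(0, nrow = length(centers),
                  ncol = ncol(frame_feats) * time_bands)
  for (wi in seq_along(centers)) {
    rows <- (centers[wi] - half):(centers[wi] + half) + 1L
    fb <- vapply(tb_idx, function(ix)
      colMeans(frame_feats[rows[ix], , drop = FALSE]),
      numeric(ncol(frame_feats)))
    feats[wi, ] <- as.numeric(fb)
  }
  out <- list(centers = centers, labels = frame_labels[centers + 1L],
              features = feats, animal_id = animal_id, depth = depth)
  class(out) <- "window_dataset"
  out
}

pool_frames <- function(stack, row_bands, col_bands) {
  d <- dim(stack)
  rb <- cut(seq_len(d[1]), row_bands, labels = FALSE)
  cb <- cut(seq_len(d[2]), col_bands, labels = FALSE)
  out <- matrix(0, nrow = d[3], ncol = row_bands * col_bands)
  for (f in seq_len(d[3])) {
    fr <- stack[, , f]
    k <- 1L
    for (r in seq_len(row_bands)) {
      for (c in seq_len(col_bands)) {
        out[f, k] <- mean(fr[rb == r, cb == c])
        k <- k + 1L
      }
    }
  }
  out
}

#' Classifier configuration
#'
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience: training halts when the
#'   validation objective has not improved for this many consecutive
#'   epochs.
#' @param max_epochs upper bound on epochs.
#' @param hidden_units width of the single hidden layer (0 = multinomial
#'   softmax regression on the pooled features).
#' @param l2 weight decay.
#' @param seed integer seed for initialization.
#' @param classes the movement classes (fixed 9-class set by default).
#' @return list of class `classifier_config`.
#' @export
classifier_config <- function(learning_rate = 0.005, patience = 10,
                              max_epochs = 400, hidden_units = 0,
                              l2 = 1e-4, seed = 1,
                              classes = default_syllabary()$movement_classes) {
  stopifnot_config(learning_rate > 0, "learning rate must be > 0")
  stopifnot_config(patience >= 1, "patience must be >= 1")
  out <- list(learning_rate = learning_rate, patience = patience,
              max_epochs = max_epochs, hidden_units = hidden_units,
              l2 = l2, seed = seed, classes = classes)
  class(out) <- "classifier_config"
  out
}

#' Train the frame-wise movement classifier
#'
#' Gradient training (Adam) of a softmax classifier (optionally with one
#' tanh hidden layer) on window features, with categorical cross-entropy
#' loss and early stopping: training halts when validation loss fails to
#' improve for `patience` consecutive epochs, and the best-validation
#' weights are kept. The train/validation split is by animal.
#'
#' @param datasets a `window_dataset` or list of them (one per animal).
#' @param config a [classifier_config()].
#' @param val_animals animal ids held out for validation; default = the
#'   last animal.
#' @return object of class `movement_classifier`: weights, feature scaling,
#'   config, and `log` (per-epoch train/validation loss).
#' @export
train_classifier <- function(datasets, config = classifier_config(),
                             val_animals = NULL) {
  if (inherits(datasets, "window_dataset")) datasets <- list(datasets)
  ids <- vapply(datasets, function(d) d$animal_id, character(1))
  if (is.null(val_animals)) val_animals <- ids[length(ids)]
  x <- do.call(rbind, lapply(datasets, function(d) d$features))
  y <- unlist(lapply(datasets, function(d) d$labels))
  who <- rep(ids, vapply(datasets, function(d) length(d$labels), integer(1)))
  stopifnot_data(length(unique(y)) >= 2,
                 "degenerate training set: single class")
  classes <- config$classes
  stopifnot_data(all(y %in% classes), "labels outside the class set")

  is_val <- who %in% val_animals
  if (!any(is_val) || all(is_val)) {
    # fall back to a within-data split when only one animal is available
    set.seed(config$seed)
    is_val <- stats::runif(length(y)) < 0.2
  }
  mu <- colMeans(x[!is_val, , drop = FALSE])
  sg <- apply(x[!is_val, , drop = FALSE], 2, stats::sd)
  sg[sg == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
  yi <- match(y, classes)
  fit <- adam_softmax(xs[!is_val, , drop = FALSE], yi[!is_val],
                      xs[is_val, , drop = FALSE], yi[is_val],
                      k = length(classes), config = config)
  out <- list(weights = fit$weights, scaling = list(mu = mu, sd = sg),
              config = config, classes = classes, log = fit$log,
              stopped_epoch = fit$stopped_epoch,
              feature_dim = ncol(x))
  class(out) <- "movement_classifier"
  out
}

# Adam-trained softmax head (optional single hidden layer), categorical
# cross-entropy, patience-based early stopping on validation loss.
adam_softmax <- function(xtr, ytr, xva, yva, k, config) {
  set.seed(config$seed)
  p <- ncol(xtr)
  h <- config$hidden_units
  init <- function(n, m) matrix(stats::rnorm(n * m, 0, 0.1), n, m)
  if (h > 0) {
    par <- list(W1 = init(p, h), b1 = rep(0, h),
                W2 = init(h, k), b2 = rep(0, k))
  } else {
    par <- list(W2 = init(p, k), b2 = rep(0, k))
  }
  mstate <- lapply(par, function(w) w * 0)
  vstate <- lapply(par, function(w) w * 0)
  b1t <- 1; b2t <- 1
  ytr_onehot <- diag(k)[ytr, , drop = FALSE]

  forward <- function(par, x) {
    if (h > 0) {
      a1 <- tanh(sweep(x %*% par$W1, 2, par$b1, "+"))
      z <- sweep(a1 %*% par$W2, 2, par$b2, "+")
      list(a1 = a1, z = z)
    } else {
      list(a1 = NULL, z = sweep(x %*% par$W2, 2, par$b2, "+"))
    }
  }
  softmax <- function(z) {
    z <- z - apply(z, 1, max)
    e <- exp(z)
    e / rowSums(e)
  }
  ce_loss <- function(par, x, yidx) {
    pr <- softmax(forward(par, x)$z)
    -mean(log(pmax(pr[cbind(seq_along(yidx), yidx)], 1e-12)))
  }

  best <- list(loss = Inf, par = par, epoch = 0)
  bad <- 0
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (epoch in seq_len(config$max_epochs)) {
    fw <- forward(par, xtr)
    pr <- softmax(fw$z)
    dz <- (pr - ytr_onehot) / nrow(xtr)
    grad <- list()
    if (h > 0) {
      grad$W2 <- t(fw$a1) %*% dz + config$l2 * par$W2
      grad$b2 <- colSums(dz)
      da1 <- dz %*% t(par$W2) * (1 - fw$a1^2)
      grad$W1 <- t(xtr) %*% da1 + config$l2 * par$W1
      grad$b1 <- colSums(da1)
    } else {
      grad$W2 <- t(xtr) %*% dz + config$l2 * par$W2
      grad$b2 <- colSums(dz)
    }
    b1t <- b1t * 0.9; b2t <- b2t * 0.999
    for (nm in names(par)) {
      mstate[[nm]] <- 0.9 * mstate[[nm]] + 0.1 * grad[[nm]]
      vstate[[nm]] <- 0.999 * vstate[[nm]] + 0.001 * grad[[nm]]^2
      mhat <- mstate[[nm]] / (1 - b1t)
      vhat <- vstate[[nm]] / (1 - b2t)
      par[[nm]] <- par[[nm]] - config$learning_rate * mhat /
        (sqrt(vhat) + 1e-8)
    }
    tl <- ce_loss(par, xtr, ytr)
    vl <- if (nrow(xva) > 0) ce_loss(par, xva, yva) else tl
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl,
                                 val_loss = vl))
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, par = par, epoch = epoch)
      bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= config$patience) break
    }
  }
  list(weights = best$par, log = log, stopped_epoch = nrow(log))
}

#' Predict per-frame movement probabilities for a movie
#'
#' Applies the classifier to every valid 25-frame window; frames inside the
#' half-window margins (the first and last 12 frames) take the prediction
#' of the nearest valid window.
#'
#' @param model a `movement_classifier`.
#' @param stack movie array (>= window depth frames).
#' @param row_bands,col_bands,time_bands pooling grid; must match training.
#' @return list: `probs` (frames x classes matrix, rows sum to 1), `labels`
#'   (argmax class per frame), `max_prob`.
#' @export
predict_movements <- function(model, stack, row_bands = 7, col_bands = 6,
                              time_bands = 5) {
  n <- dim(stack)[3]
  ds <- make_windows(stack, frame_labels = rep(model$classes[1], n),
                     depth = 25, row_bands = row_bands,
                     col_bands = col_bands, time_bands = time_bands)
  stopifnot_data(ncol(ds$features) == model$feature_dim,
                 "feature dimension mismatch between model and input")
  xs <- sweep(sweep(ds$features, 2, model$scaling$mu), 2,
              model$scaling$sd, "/")
  par <- model$weights
  z <- if (!is.null(par$W1)) {
    a1 <- tanh(sweep(xs %*% par$W1, 2, par$b1, "+"))
    sweep(a1 %*% par$W2, 2, par$b2, "+")
  } else {
    sweep(xs %*% par$W2, 2, par$b2, "+")
  }
  z <- z - apply(z, 1, max)
  e <- exp(z)
  pr_win <- e / rowSums(e)

  half <- (ds$depth - 1L) %/% 2L
  probs <- matrix(0, nrow = n, ncol = length(model$classes),
                  dimnames = list(NULL, model$classes))
  nearest <- pmin(pmax(seq_len(n) - 1L, ds$centers[1]),
                  ds$centers[length(ds$centers)])
  probs[] <- pr_win[nearest - ds$centers[1] + 1L, ]
  labels <- model$classes[max.col(probs, ties.method = "first")]
  list(probs = probs, labels = labels,
       max_prob = probs[cbind(seq_len(n), max.col(probs, "first"))])
}

#' Evaluate frame-wise predictions against ground truth
#'
#' @param pred,truth character vectors of equal length (frame labels).
#' @param classes class set for the confusion matrix.
#' @param fps frames per second, for the duration table.
#' @return list: `accuracy`, `confusion` (truth x predicted counts),
#'   `per_class` (precision/recall/n per class), `durations` (per class:
#'   `n_runs`, `total_s`, `median_run_s` from contiguous predicted runs).
#' @export
evaluate_predictions <- function(pred, truth,
                                 classes = default_syllabary()$movement_classes,
                                 fps = 2) {
  stopifnot_data(length(pred) == length(truth),
                 "prediction/truth length mismatch")
  pf <- factor(pred, levels = classes)
  tf <- factor(truth, levels = classes)
  confusion <- table(truth = tf, predicted = pf)
  acc <- mean(pred == truth)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    data.frame(class = cl,
               n = sum(truth == cl),
               precision = if (sum(pred == cl) > 0) tp / sum(pred == cl)
                           else NA_real_,
               recall = if (sum(truth == cl) > 0) tp / sum(truth == cl)
                        else NA_real_)
  }))
  r <- rle(pred)
  durations <- do.call(rbind, lapply(classes, function(cl) {
    runs <- r$lengths[r$values == cl]
    data.frame(class = cl, n_runs = length(runs),
               total_s = sum(runs) / fps,
               median_run_s = if (length(runs) > 0) stats::median(runs) / fps
                              else NA_real_)
  }))
  list(accuracy = acc, confusion = confusion, per_class = per_class,
       durations = durations)
}
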
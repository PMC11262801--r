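#' Training configuration
#'
#' Optimisation settings shared by self-supervised pre-training and
#' supervised fine-tuning. All training in this package is seeded and
#' single-threaded, so a given configuration reproduces its run bit for
#' bit.
#'
#' @param epochs Number of passes over the training set.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of windows held out for validation and
#'   early stopping (0 disables the split).
#' @param patience Early-stopping patience in epochs (`NULL` = run all
#'   epochs; the best validation weights are restored either way).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, lr = 1e-3, batch_size = 64L,
                         val_fraction = 0.1, patience = NULL, seed = 0L) {
  stopifnot(epochs >= 1L, lr > 0, batch_size >= 1L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, patience = patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize an encoder/decoder model
#'
#' Builds the posture autoencoder: a dense encoder compressing a flattened
#' `L x S x 2` window into a `latent_dim`-dimensional code Z, and a decoder
#' expanding Z into the extended sequence of `(1 + 2 * context_windows) * L`
#' posture samples (past, present and future). Weights are
#' Xavier-initialised; an un-pretrained model of this kind is the baseline
#' arm of the transfer experiments.
#'
#' @param samples_per_window L, time samples per window.
#' @param spine_points S, spine points per sample.
#' @param latent_dim D, latent dimension (default 16).
#' @param hidden Integer vector of hidden layer widths of the encoder
#'   (head to bottleneck); the decoder mirrors it.
#' @param context_windows Past/future window-lengths reconstructed.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `encoder_model`.
#' @export
encoder_model <- function(samples_per_window = 20L, spine_points = 5L,
                          latent_dim = 16L, hidden = c(128L, 96L, 64L, 32L),
                          context_windows = 1L, seed = 0L) {
  d_in <- samples_per_window * spine_points * 2L
  d_out <- (1L + 2L * context_windows) * samples_per_window * spine_points * 2L
  nh <- length(hidden)
  nets <- withr::with_seed(seed, list(
    enc = mlp_init(c(d_in, hidden, latent_dim), c(rep("tanh", nh), "linear")),
    dec = mlp_init(c(latent_dim, rev(hidden), d_out),
                   c(rep("tanh", nh), "linear"))))
  structure(list(enc = nets$enc, dec = nets$dec,
                 samples_per_window = as.integer(samples_per_window),
                 spine_points = as.integer(spine_points),
                 latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden),
                 context_windows = as.integer(context_windows),
                 pretrained = FALSE, fine_tuned = FALSE,
                 seed = as.integer(seed), log = NULL),
            class = "encoder_model")
}

#' @export
print.encoder_model <- function(x, ...) {
  cat(sprintf(paste0("<encoder_model> in=%dx%dx2  D=%d  hidden=%s  context=%d",
                     "  pretrained=%s  fine_tuned=%s\n"),
              x$samples_per_window, x$spine_points, x$latent_dim,
              paste(x$hidden, collapse = "-"),
              x$context_windows, x$pretrained, x$fine_tuned))
  invisible(x)
}

model_input_dim <- function(model)
  model$samples_per_window * model$spine_points * 2L

model_output_dim <- function(model)
  (1L + 2L * model$context_windows) * model_input_dim(model)

# Coerce a window / array / matrix into an n x d_in design matrix.
as_encoder_input <- function(model, w) {
  d_in <- model_input_dim(model)
  X <- if (inherits(w, "posture_window")) matrix(as.vector(w$x), 1L)
       else if (is.list(w)) windows_matrix(w)
       else if (is.matrix(w)) w
       else matrix(as.vector(w), 1L)
  if (ncol(X) != d_in)
    stop(sprintf("window shape mismatch: model expects %d values (L=%d, S=%d), got %d",
                 d_in, model$samples_per_window, model$spine_points, ncol(X)))
  X
}

#' Encode posture windows into latent codes
#'
#' Deterministically maps a posture window (or a list of windows) through
#' the encoder to its low-dimensional latent representation Z.
#'
#' @param model An [encoder_model()].
#' @param w A `posture_window`, a list of them, or an `n x (L*S*2)` matrix.
#' @return A numeric vector of length D for a single window, otherwise an
#'   `n x D` matrix.
#' @export
encode <- function(model, w) {
  X <- as_encoder_input(model, w)
  Z <- mlp_forward(model$enc, X)$out
  if (nrow(Z) == 1L && (inherits(w, "posture_window") ||
                        (!is.matrix(w) && !is.list(w)))) drop(Z) else Z
}

#' Decode a latent code into an extended posture sequence
#'
#' Expands a latent code Z through the decoder into the extended sequence:
#' the middle L samples reconstruct the input window, the flanks predict
#' the `context_windows` past and future window-lengths.
#'
#' @param model An [encoder_model()].
#' @param z Numeric vector of length D (or `n x D` matrix).
#' @return A `(1 + 2 * context_windows) * L x S x 2` array (or a list of
#'   such arrays for a matrix input).
#' @export
decode <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, 1L)
  if (ncol(Z) != model$latent_dim)
    stop(sprintf("latent dimension mismatch: expected %d, got %d",
                 model$latent_dim, ncol(Z)))
  Y <- mlp_forward(model$dec, Z)$out
  Lext <- (1L + 2L * model$context_windows) * model$samples_per_window
  to_arr <- function(v) array(v, c(Lext, model$spine_points, 2L))
  if (nrow(Y) == 1L && !is.matrix(z)) to_arr(Y[1L, ])
  else lapply(seq_len(nrow(Y)), function(i) to_arr(Y[i, ]))
}

#' Pre-train the autoencoder on unlabelled windows
#'
#' Self-supervised training: minimizes the mean squared error between the
#' decoded extended sequence and the observed past/present/future postures
#' of each window. No labels are needed, which is what lets the encoder be
#' trained on large unannotated repositories before any tagging task.
#'
#' @param windows List of `posture_window` objects (with extended context,
#'   as produced by [extract_windows()]).
#' @param cfg A [train_config()].
#' @param model Optional model to continue training; a fresh
#'   Xavier-initialised model matching the window shape is created
#'   otherwise.
#' @param quiet Suppress the per-epoch progress line.
#' @return The trained `encoder_model`, with `pretrained = TRUE` and a
#'   training log (`data.frame` epoch/train/validation loss) in `$log`.
#' @export
pretrain <- function(windows, cfg = train_config(), model = NULL,
                     quiet = TRUE) {
  if (!length(windows)) stop("no windows to pre-train on")
  d <- dim(windows[[1]]$x)
  cw <- (dim(windows[[1]]$x_ext)[1] / d[1] - 1) / 2
  if (is.null(model))
    model <- encoder_model(samples_per_window = d[1], spine_points = d[2],
                           context_windows = as.integer(cw), seed = cfg$seed)
  X <- windows_matrix(windows)
  Y <- windows_matrix(windows, extended = TRUE)
  if (ncol(X) != model_input_dim(model) || ncol(Y) != model_output_dim(model))
    stop("window shape does not match model architecture")

  fit <- withr::with_seed(cfg$seed, train_autoencoder(model, X, Y, cfg, quiet))
  fit$model$pretrained <- TRUE
  fit$model$log <- fit$log
  fit$model
}

train_autoencoder <- function(model, X, Y, cfg, quiet = TRUE) {
  n <- nrow(X)
  n_val <- floor(cfg$val_fraction * n)
  val_idx <- if (n_val >= 1L) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  enc <- model$enc; dec <- model$dec
  st_e <- adam_init(enc); st_d <- adam_init(dec)
  best <- list(enc = enc, dec = dec, val = Inf, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  step <- 0L
  stall <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (b in batches) {
      fe <- mlp_forward(enc, X[b, , drop = FALSE])
      fd <- mlp_forward(dec, fe$out)
      R <- fd$out - Y[b, , drop = FALSE]
      loss <- mean(R^2)
      if (!is.finite(loss))
        stop(sprintf("non-finite loss at epoch %d; lower the learning rate", ep))
      ep_loss <- ep_loss + loss * length(b)
      dOut <- 2 * R / length(R)
      bd <- mlp_backward(dec, fd$cache, dOut)
      be <- mlp_backward(enc, fe$cache, bd$dX)
      step <- step + 1L
      up <- adam_step(dec, bd$grads, st_d, cfg$lr, step)
      dec <- up$net; st_d <- up$state
      up <- adam_step(enc, be$grads, st_e, cfg$lr, step)
      enc <- up$net; st_e <- up$state
    }
    ep_loss <- ep_loss / length(tr_idx)
    val_loss <- NA_real_
    if (length(val_idx)) {
      fv <- mlp_forward(dec, mlp_forward(enc, X[val_idx, , drop = FALSE])$out)
      val_loss <- mean((fv$out - Y[val_idx, , drop = FALSE])^2)
      if (val_loss < best$val) {
        best <- list(enc = enc, dec = dec, val = val_loss, epoch = ep)
        stall <- 0L
      } else stall <- stall + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                 val_loss = val_loss))
    if (!quiet)
      message(sprintf("epoch %d  train %.5f  val %.5f", ep, ep_loss, val_loss))
    if (!is.null(cfg$patience) && length(val_idx) && stall >= cfg$patience)
      break
  }
  if (length(val_idx)) { enc <- best$enc; dec <- best$dec }
  model$enc <- enc; model$dec <- dec
  list(model = model, log = log)
}

#' Mean reconstruction error of a model on windows
#'
#' @param model A trained [encoder_model()].
#' @param windows List of `posture_window` objects.
#' @return Mean squared error over all coordinates of the extended
#'   reconstruction target.
#' @export
reconstruction_mse <- function(model, windows) {
  X <- windows_matrix(windows)
  Y <- windows_matrix(windows, extended = TRUE)
  P <- mlp_forward(model$dec, mlp_forward(model$enc, X)$out)$out
  mean((P - Y)^2)
}

#' Constant-mean-posture baseline error
#'
#' The reference any autoencoder must beat: predict, for every test window,
#' the coordinate-wise mean extended sequence of the training windows.
#'
#' @param train_windows,test_windows Lists of `posture_window` objects.
#' @return Mean squared error of the constant predictor on the test set.
#' @export
constant_baseline_mse <- function(train_windows, test_windows) {
  Ytr <- windows_matrix(train_windows, extended = TRUE)
  Yte <- windows_matrix(test_windows, extended = TRUE)
  mu <- colMeans(Ytr)
  mean(sweep(Yte, 2L, mu)^2)
}

#' Export latent codes for tracks
#'
#' Runs the windowing and encoder over a set of tracks and writes one row
#' per valid window: `larva_id`, `t_center`, then `z_1 ... z_D`. This is
#' the continuous behavioural readout, usable for latent-space statistics
#' independently of any action dictionary.
#'
#' @param model A trained [encoder_model()].
#' @param tracks List of `larva_track` objects.
#' @param cfg A [windowing_config()] matching the model.
#' @param out Output CSV path.
#' @return Invisibly, the exported data frame.
#' @export
export_latents <- function(model, tracks, cfg, out) {
  rows <- list()
  for (trk in tracks) {
    wins <- extract_windows(trk, cfg)
    if (!length(wins)) next
    Z <- encode(model, wins)
    rows[[length(rows) + 1L]] <-
      data.frame(larva_id = vapply(wins, `[[`, integer(1), "larva_id"),
                 t_center = vapply(wins, `[[`, numeric(1), "t_center"),
                 Z)
  }
  D <- model$latent_dim
  if (!length(rows)) {
    df <- as.data.frame(matrix(numeric(0), 0L, 2L + D))
  } else df <- do.call(rbind, rows)
  names(df) <- c("larva_id", "t_center", paste0("z_", seq_len(D)))
  utils::write.csv(df, out, row.names = FALSE)
  invisible(df)
}

#' Save / load an encoder checkpoint
#'
#' A checkpoint directory holds a JSON architecture manifest, a JSON weight
#' store and the training log as CSV — all plain text.
#'
#' @param model An [encoder_model()].
#' @param dir Checkpoint directory (created if needed).
#' @return `save_model()`: invisibly, `dir`. `load_model()`: the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- model[c("samples_per_window", "spine_points", "latent_dim",
                      "hidden", "context_windows", "pretrained",
                      "fine_tuned", "seed")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(serialize_nets(list(enc = model$enc, dec = model$dec)),
                       file.path(dir, "weights.json"), digits = NA)
  if (!is.null(model$log))
    utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  model <- encoder_model(manifest$samples_per_window, manifest$spine_points,
                         manifest$latent_dim, manifest$hidden,
                         manifest$context_windows, manifest$seed)
  nets <- deserialize_nets(jsonlite::fromJSON(file.path(dir, "weights.json"),
                                              simplifyVector = FALSE))
  model$enc <- nets$enc; model$dec <- nets$dec
  model$pretrained <- isTRUE(manifest$pretrained)
  model$fine_tuned <- isTRUE(manifest$fine_tuned)
  logf <- file.path(dir, "training_log.csv")
  if (file.exists(logf)) model$log <- utils::read.csv(logf)
  model
}

serialize_nets <- function(nets) {
  lapply(nets, function(net) lapply(net, function(l)
    list(W = as.vector(l$W), dim = dim(l$W), b = l$b, act = l$act)))
}

deserialize_nets <- function(raw) {
  lapply(raw, function(net) lapply(net, function(l)
    list(W = matrix(unlist(l$W), unlist(l$dim)[1], unlist(l$dim)[2]),
         b = as.numeric(unlist(l$b)), act = l$act[[1]])))
}
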
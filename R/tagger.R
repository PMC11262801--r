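#' Train an action classifier over the encoder
#'
#' Adds a small classification head on top of the encoder's latent space
#' and trains it by weighted cross-entropy on labelled posture windows.
#' Unless `freeze_encoder` is set, the encoder weights are fine-tuned
#' jointly, letting the latent representation adapt to the tagging task.
#' Class imbalance is handled with inverse-frequency class weights.
#'
#' @param encoder An [encoder_model()] (pre-trained or Xavier-initialised).
#'   The encoder is copied; the argument is not modified.
#' @param windows List of labelled `posture_window` objects.
#' @param classes Character vector of class names, parallel to `windows`;
#'   entries must appear in `dictionary` (NA entries are dropped).
#' @param dictionary Action dictionary data frame ([action_dictionary()]).
#' @param cfg A [train_config()].
#' @param freeze_encoder Keep encoder weights fixed (head-only training).
#' @param encoder_lr_scale Learning-rate multiplier for the encoder during
#'   fine-tuning (default 0.1): the usual fine-tuning regime where the
#'   pre-trained representation is adapted gently while the head trains at
#'   full rate.
#' @param head_hidden Hidden width of the classification head.
#' @return An object of class `tagger_model`.
#' @export
train_tagger <- function(encoder, windows, classes,
                         dictionary = action_dictionary(),
                         cfg = train_config(), freeze_encoder = FALSE,
                         encoder_lr_scale = 0.1, head_hidden = 32L) {
  keep <- !is.na(classes)
  windows <- windows[keep]; classes <- classes[keep]
  if (!length(windows)) stop("empty labelled set")
  if (length(windows) != length(classes))
    stop("windows and classes must have equal length")
  y <- match(classes, dictionary$name)
  if (anyNA(y))
    stop(sprintf("labels not in dictionary: %s",
                 paste(unique(classes[is.na(y)]), collapse = ", ")))
  absent <- setdiff(dictionary$name, classes)
  if (length(absent))
    warning(sprintf("no examples for class(es): %s; training on present classes",
                    paste(absent, collapse = ", ")))

  C <- nrow(dictionary)
  X <- windows_matrix(windows)
  if (ncol(X) != model_input_dim(encoder))
    stop("window shape does not match encoder architecture")

  # inverse-frequency weights over the classes actually present
  freq <- tabulate(y, nbins = C)
  present <- freq > 0L
  w_class <- rep(0, C)
  w_class[present] <- length(y) / (sum(present) * freq[present])
  w <- w_class[y]

  D <- encoder$latent_dim
  model <- encoder
  head <- withr::with_seed(cfg$seed,
    if (head_hidden > 0L) mlp_init(c(D, head_hidden, C), c("tanh", "linear"))
    else mlp_init(c(D, C), "linear"))

  fit <- withr::with_seed(cfg$seed + 1L,
    train_classifier(model$enc, head, X, y, w, C, cfg, freeze_encoder,
                     encoder_lr_scale))
  model$enc <- fit$enc
  model$fine_tuned <- !freeze_encoder
  structure(list(encoder = model, head = fit$head, dictionary = dictionary,
                 freeze_encoder = freeze_encoder,
                 head_hidden = as.integer(head_hidden),
                 seed = cfg$seed, log = fit$log),
            class = "tagger_model")
}

train_classifier <- function(enc, head, X, y, w, C, cfg, freeze,
                             enc_lr_scale = 0.1) {
  n <- nrow(X)
  onehot <- matrix(0, n, C)
  onehot[cbind(seq_len(n), y)] <- 1
  st_h <- adam_init(head)
  st_e <- if (!freeze) adam_init(enc)
  Zfull <- if (freeze) mlp_forward(enc, X)$out
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    train_acc = numeric(0))
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0; ep_hit <- 0
    for (b in batches) {
      if (freeze) {
        Z <- Zfull[b, , drop = FALSE]
      } else {
        fe <- mlp_forward(enc, X[b, , drop = FALSE])
        Z <- fe$out
      }
      fh <- mlp_forward(head, Z)
      P <- softmax_rows(fh$out)
      wi <- w[b]
      ce <- -log(pmax(P[cbind(seq_along(b), y[b])], 1e-12))
      loss <- sum(wi * ce) / sum(wi)
      if (!is.finite(loss)) stop("non-finite classification loss")
      ep_loss <- ep_loss + loss * length(b)
      ep_hit <- ep_hit + sum(max.col(P, ties.method = "first") == y[b])
      dZ <- (P - onehot[b, , drop = FALSE]) * (wi / sum(wi))
      bh <- mlp_backward(head, fh$cache, dZ)
      step <- step + 1L
      up <- adam_step(head, bh$grads, st_h, cfg$lr, step)
      head <- up$net; st_h <- up$state
      if (!freeze) {
        be <- mlp_backward(enc, fe$cache, bh$dX)
        up <- adam_step(enc, be$grads, st_e, cfg$lr * enc_lr_scale, step)
        enc <- up$net; st_e <- up$state
      }
    }
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / n,
                                 train_acc = ep_hit / n))
  }
  list(enc = enc, head = head, log = log)
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model> %d classes (%s), encoder pretrained=%s, fine_tuned=%s\n",
              nrow(x$dictionary), paste(x$dictionary$name, collapse = ", "),
              x$encoder$pretrained, x$encoder$fine_tuned))
  invisible(x)
}

# Class probabilities for a window design matrix.
tagger_probs <- function(model, X) {
  Z <- mlp_forward(model$encoder$enc, X)$out
  softmax_rows(mlp_forward(model$head, Z)$out)
}

#' Predict per-timestep actions for a track
#'
#' Extracts the windows of a track, classifies each one, and maps every
#' window back to its centre timestep: one class-probability vector and one
#' argmax label per timestep. Timesteps whose window was invalidated by
#' preprocessing (e.g. tracking gaps) are reported untagged (`NA`), never
#' guessed. Ties in the probabilities resolve to the first class in
#' dictionary order. Inference is deterministic.
#'
#' Classification is window-local by design; no temporal smoothing is
#' applied unless `smooth` is set, in which case the argmax label sequence
#' is passed through a running majority filter of that many timesteps
#' (probabilities are left untouched).
#'
#' @param object A `tagger_model`.
#' @param track A [larva_track()].
#' @param cfg A [windowing_config()] matching the model.
#' @param smooth Odd window length (timesteps) of an optional majority
#'   filter over the label sequence; 0 (default) disables smoothing.
#' @param ... Unused.
#' @return An object of class `prediction`: fields `larva_id`, `t`,
#'   `probs` (`T x n_classes` matrix, NA rows where untagged) and `labels`
#'   (character, NA where untagged).
#' @export
predict.tagger_model <- function(object, track, cfg = windowing_config(),
                                 smooth = 0L, ...) {
  validate_track(track)
  wins <- extract_windows(track, cfg)
  Tn <- length(track$t)
  C <- nrow(object$dictionary)
  probs <- matrix(NA_real_, Tn, C,
                  dimnames = list(NULL, object$dictionary$name))
  labels <- rep(NA_character_, Tn)
  if (length(wins)) {
    X <- windows_matrix(wins)
    P <- tagger_probs(object, X)
    tc <- vapply(wins, `[[`, numeric(1), "t_center")
    idx <- match(round(tc, 9), round(track$t, 9))
    probs[idx, ] <- P
    labels[idx] <- object$dictionary$name[max.col(P, ties.method = "first")]
    if (smooth > 0L) labels <- majority_filter(labels, as.integer(smooth))
  }
  structure(list(larva_id = track$larva_id, t = track$t,
                 probs = probs, labels = labels),
            class = "prediction")
}

# Running majority vote over a label sequence; NA entries stay NA and do
# not vote. Ties keep the centre label.
majority_filter <- function(labels, k) {
  if (k %% 2L == 0L) k <- k + 1L
  half <- k %/% 2L
  out <- labels
  n <- length(labels)
  for (i in seq_len(n)) {
    if (is.na(labels[i])) next
    win <- labels[max(1L, i - half):min(n, i + half)]
    tab <- table(win[!is.na(win)])
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) out[i] <- top
  }
  out
}

#' @export
print.prediction <- function(x, ...) {
  tagged <- sum(!is.na(x$labels))
  cat(sprintf("<prediction> larva %d, %d/%d timesteps tagged\n",
              x$larva_id, tagged, length(x$t)))
  invisible(x)
}

#' Convert predictions into a label set
#'
#' Packs a list of per-track [predict.tagger_model()] results into a
#' [label_set()] with provenance `"predicted"`, ready for
#' [write_labels_json()]. Untagged timesteps become empty label lists.
#'
#' @param preds List of `prediction` objects.
#' @param dictionary Action dictionary data frame.
#' @return A [label_set()].
#' @export
predictions_to_labelset <- function(preds, dictionary = action_dictionary()) {
  assignments <- list(); tvecs <- list(); prov <- character()
  for (p in preds) {
    id <- as.character(p$larva_id)
    idx <- match(p$labels, dictionary$name)
    assignments[[id]] <- lapply(idx, function(i)
      if (is.na(i)) integer(0) else i)
    tvecs[[id]] <- p$t
    prov[id] <- "predicted"
  }
  label_set(dictionary, assignments, tvecs, prov)
}

#' Pre-training transfer experiment
#'
#' Quantifies what pre-training buys: for each training-set size and each
#' seed, a tagger is trained on a stratified subsample either from the
#' given pre-trained encoder or from a fresh Xavier-initialised encoder,
#' and scored by macro-F1 on a fixed held-out test set.
#'
#' @param pretrained A pre-trained [encoder_model()].
#' @param train_sizes Integer vector of windows per class to train on.
#' @param n_seeds Number of independent seeds per size and arm.
#' @param windows,classes Labelled training pool (windows + class names).
#' @param test_windows,test_classes Fixed held-out evaluation set.
#' @param dictionary Action dictionary data frame.
#' @param cfg A [train_config()]; its seed is offset per run.
#' @param ... Passed to [train_tagger()].
#' @return Tidy data frame with columns `size`, `pretrained`, `seed`,
#'   `macro_f1`.
#' @export
transfer_experiment <- function(pretrained, train_sizes, n_seeds,
                                windows, classes, test_windows, test_classes,
                                dictionary = action_dictionary(),
                                cfg = train_config(), ...) {
  keep <- !is.na(classes)
  windows <- windows[keep]; classes <- classes[keep]
  rows <- list()
  for (size in train_sizes) {
    for (seed in seq_len(n_seeds)) {
      sub <- withr::with_seed(cfg$seed + 1000L * seed + size,
                              stratified_subsample(classes, size))
      if (is.null(sub)) {
        warning(sprintf("size %d exceeds available windows per class; skipped",
                        size))
        next
      }
      for (arm in c(TRUE, FALSE)) {
        run_cfg <- cfg
        run_cfg$seed <- cfg$seed + 10000L * seed + size + as.integer(arm)
        enc <- if (arm) pretrained
               else encoder_model(pretrained$samples_per_window,
                                  pretrained$spine_points,
                                  pretrained$latent_dim, pretrained$hidden,
                                  pretrained$context_windows,
                                  seed = run_cfg$seed)
        tg <- suppressWarnings(
          train_tagger(enc, windows[sub], classes[sub], dictionary,
                       cfg = run_cfg, ...))
        P <- tagger_probs(tg, windows_matrix(test_windows))
        pred <- dictionary$name[max.col(P, ties.method = "first")]
        rows[[length(rows) + 1L]] <-
          data.frame(size = size, pretrained = arm, seed = seed,
                     macro_f1 = macro_f1(test_classes, pred, dictionary))
      }
    }
  }
  do.call(rbind, rows)
}

# Indices of a stratified subsample with `per_class` examples per observed
# class, or NULL if any class has fewer.
stratified_subsample <- function(classes, per_class) {
  idx <- integer(0)
  for (cl in unique(classes)) {
    pool <- which(classes == cl)
    if (length(pool) < per_class) return(NULL)
    idx <- c(idx, sample(pool, per_class))
  }
  sort(idx)
}

#' Save / load a tagger checkpoint
#'
#' A tagger checkpoint is an encoder checkpoint plus the head weights and a
#' dictionary manifest, all plain text.
#'
#' @param model A `tagger_model`.
#' @param dir Checkpoint directory.
#' @return `save_tagger()`: invisibly, `dir`. `load_tagger()`: the model.
#' @export
save_tagger <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_model(model$encoder, file.path(dir, "encoder"))
  jsonlite::write_json(serialize_nets(list(head = model$head)),
                       file.path(dir, "head.json"), digits = NA)
  jsonlite::write_json(list(names = model$dictionary$name,
                            colors = model$dictionary$color,
                            freeze_encoder = model$freeze_encoder,
                            head_hidden = model$head_hidden,
                            seed = model$seed),
                       file.path(dir, "dictionary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(dir) {
  encoder <- load_model(file.path(dir, "encoder"))
  head <- deserialize_nets(jsonlite::fromJSON(file.path(dir, "head.json"),
                                              simplifyVector = FALSE))$head
  man <- jsonlite::fromJSON(file.path(dir, "dictionary.json"))
  structure(list(encoder = encoder, head = head,
                 dictionary = data.frame(name = man$names, color = man$colors,
                                         stringsAsFactors = FALSE),
                 freeze_encoder = isTRUE(man$freeze_encoder),
                 head_hidden = as.integer(man$head_hidden),
                 seed = as.integer(man$seed), log = NULL),
            class = "tagger_model")
}
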
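# Fine-motor-impairment severity estimation from keystroke dynamics.
#
# A 1-D convolutional autoencoder (two conv layers, kernel 5, 16 filters,
# no pooling, "same" padding; mirrored decoder) is pretrained to reconstruct
# padded HT/FT sequences, then the encoder plus a two-layer dense head
# (temporal mean pool -> 50 hidden units -> linear output) is fine-tuned
# end-to-end per symptom (rigidity R, bradykinesia B, alternate finger
# tapping AFT) against 0-4 severity scores, with leave-one-subject-out
# cross-validation. Optimizer is RMSprop throughout.

#' Encoder architecture specification
#'
#' @param input_length Sequence length (default 100).
#' @param channels Input channels (2: hold times, flight times).
#' @param kernel_size Convolution kernel size (default 5).
#' @param filters Filters per convolutional layer (default 16).
#' @return An `encoder_spec` list.
#' @export
encoder_spec <- function(input_length = 100L, channels = 2L,
                         kernel_size = 5L, filters = 16L) {
  stopifnot(input_length > 0, channels > 0, kernel_size > 0, filters > 0)
  structure(list(input_length = as.integer(input_length),
                 channels = as.integer(channels),
                 kernel_size = as.integer(kernel_size),
                 filters = as.integer(filters)),
            class = "encoder_spec")
}

#' Training configuration
#'
#' Defaults follow the model-development protocol: unsupervised pretraining
#' for 50 epochs with mini-batches of 64 and an 80/20 train-test split;
#' supervised fine-tuning for 50 epochs with mini-batches of 32 and a
#' 50-unit hidden head; RMSprop with learning rate 1e-3 everywhere.
#'
#' @param pretrain_epochs,pretrain_batch Pretraining schedule.
#' @param finetune_epochs,finetune_batch Fine-tuning schedule.
#' @param lr RMSprop learning rate.
#' @param head_hidden Hidden units in the regression head.
#' @param val_fraction Held-out fraction during pretraining.
#' @param seed Integer seed; recorded in all outputs.
#' @return A `training_config` list.
#' @export
training_config <- function(pretrain_epochs = 50L, pretrain_batch = 64L,
                            finetune_epochs = 50L, finetune_batch = 32L,
                            lr = 1e-3, head_hidden = 50L,
                            val_fraction = 0.2, seed = 1L) {
  stopifnot(pretrain_epochs > 0, pretrain_batch > 0, finetune_epochs > 0,
            finetune_batch > 0, lr > 0, head_hidden > 0,
            val_fraction > 0, val_fraction < 1)
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 pretrain_batch = as.integer(pretrain_batch),
                 finetune_epochs = as.integer(finetune_epochs),
                 finetune_batch = as.integer(finetune_batch),
                 lr = lr, head_hidden = as.integer(head_hidden),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "training_config")
}

# arma::vec comes back from compiled code as an n x 1 matrix
tidy_params <- function(params) {
  lapply(params, function(p) { p$b <- as.numeric(p$b); p })
}

batch_cols <- function(samples, L) {
  as.vector(vapply(samples, function(b) ((b - 1L) * L + 1L):(b * L),
                   integer(L)))
}

ae_forward <- function(params, X, idx) {
  c1 <- conv_fwd(params$conv1, X, idx);  m1 <- c1$out > 0
  c2 <- conv_fwd(params$conv2, c1$out * m1, idx); m2 <- c2$out > 0
  c3 <- conv_fwd(params$conv3, c2$out * m2, idx); m3 <- c3$out > 0
  c4 <- conv_fwd(params$conv4, c3$out * m3, idx)
  list(xhat = c4$out, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
       m1 = m1, m2 = m2, m3 = m3)
}

ae_loss <- function(params, X, idx) {
  f <- ae_forward(params, X, idx)
  mean((f$xhat - X)^2)
}

#' Pretrain the convolutional autoencoder
#'
#' Unsupervised reconstruction training on padded dynamics series with mean
#' squared error loss; an internal train/validation split tracks held-out
#' reconstruction loss per epoch.
#'
#' @param series_list List of padded `dynamics_series` (>= some tens of
#'   sessions; the generator in this package provides arbitrarily many).
#' @param spec An [encoder_spec()].
#' @param cfg A [training_config()].
#' @return An `fmi_encoder`: encoder/decoder parameters, per-epoch training
#'   history, the spec, config and parameter count.
#' @export
pretrain_autoencoder <- function(series_list, spec = encoder_spec(),
                                 cfg = training_config()) {
  L <- spec$input_length
  X <- stack_dynamics(series_list, L)
  B_all <- length(series_list)
  set.seed(cfg$seed)
  nf <- spec$filters; K <- spec$kernel_size; ch <- spec$channels
  params <- list(conv1 = conv_init(ch, nf, K), conv2 = conv_init(nf, nf, K),
                 conv3 = conv_init(nf, nf, K), conv4 = conv_init(nf, ch, K))

  if (B_all < 5L) stop("pretraining needs at least a handful of sessions")
  n_val <- max(1L, round(cfg$val_fraction * B_all))
  val_ids <- sample(B_all, n_val)
  train_ids <- setdiff(seq_len(B_all), val_ids)

  orders <- t(vapply(seq_len(cfg$pretrain_epochs),
                     function(e) sample(train_ids), integer(length(train_ids))))
  fit <- .cpp_train_autoencoder(X, L, params, train_ids, val_ids,
                                cfg$pretrain_epochs, cfg$pretrain_batch,
                                cfg$lr, orders)
  params <- tidy_params(fit$params)
  history <- data.frame(epoch = seq_len(cfg$pretrain_epochs),
                        train_loss = as.numeric(fit$train_loss),
                        val_loss = as.numeric(fit$val_loss))
  structure(list(params = params, history = history, spec = spec, cfg = cfg,
                 n_parameters = sum(vapply(params, function(p)
                   length(p$W) + length(p$b), numeric(1)))),
            class = "fmi_encoder")
}

#' @export
print.fmi_encoder <- function(x, ...) {
  cat(sprintf("<fmi_encoder %d params, %d epochs, final val loss %.3g>\n",
              x$n_parameters, nrow(x$history),
              x$history$val_loss[nrow(x$history)]))
  invisible(x)
}

reg_forward <- function(params, X, idx, L, B) {
  c1 <- conv_fwd(params$conv1, X, idx); m1 <- c1$out > 0
  c2 <- conv_fwd(params$conv2, c1$out * m1, idx); m2 <- c2$out > 0
  p <- pool_fwd(c2$out * m2, L, B)
  h_pre <- dense_fwd(params$d1, p); mh <- h_pre > 0; h <- h_pre * mh
  y <- dense_fwd(params$d2, h)
  list(y = as.numeric(y), c1 = c1, c2 = c2, m1 = m1, m2 = m2,
       p = p, h = h, mh = mh)
}

train_regressor <- function(init_params, X, y, L, K, cfg, seed) {
  set.seed(seed)
  orders <- t(vapply(seq_len(cfg$finetune_epochs),
                     function(e) sample(length(y)), integer(length(y))))
  tidy_params(.cpp_train_regressor(X, y, L, init_params, cfg$finetune_epochs,
                                   cfg$finetune_batch, cfg$lr, orders))
}

# pure-R reference implementation of the same training loop; kept as an
# independent check of the compiled path
train_regressor_ref <- function(init_params, X, y, L, K, cfg, seed) {
  set.seed(seed)
  orders <- t(vapply(seq_len(cfg$finetune_epochs),
                     function(e) sample(length(y)), integer(length(y))))
  params <- init_params
  state <- rmsprop_state(params)
  B_all <- length(y)
  idx_cache <- list()
  for (epoch in seq_len(cfg$finetune_epochs)) {
    ord <- orders[epoch, ]
    for (start in seq(1L, B_all, by = cfg$finetune_batch)) {
      bs <- ord[start:min(start + cfg$finetune_batch - 1L, B_all)]
      B <- length(bs)
      key <- as.character(B)
      if (is.null(idx_cache[[key]])) idx_cache[[key]] <- conv_index(L, B, K)
      idx <- idx_cache[[key]]
      Xb <- X[, batch_cols(bs, L), drop = FALSE]
      f <- reg_forward(params, Xb, idx, L, B)
      dy <- matrix(2 * (f$y - y[bs]) / B, nrow = 1)
      if (!all(is.finite(dy))) stop("non-finite regression loss at epoch ", epoch)
      gd2 <- dense_bwd(params$d2, f$h, dy)
      gd1 <- dense_bwd(params$d1, f$p, gd2$dX * f$mh)
      da2 <- pool_bwd(gd1$dX, L, B) * f$m2
      g2 <- conv_bwd(params$conv2, f$c2, da2, idx)
      g1 <- conv_bwd(params$conv1, f$c1, g2$dX * f$m1, idx, need_dx = FALSE)
      upd <- rmsprop_step(params, list(g1, g2, gd1, gd2), state, lr = cfg$lr)
      params <- upd$params; state <- upd$state
    }
  }
  params
}

init_head <- function(encoder, cfg) {
  list(conv1 = encoder$params$conv1, conv2 = encoder$params$conv2,
       d1 = dense_init(encoder$spec$filters, cfg$head_hidden),
       d2 = dense_init(cfg$head_hidden, 1L))
}

fmi_symptoms <- c(R = "item22", AFT = "item23", B = "item31")

#' Fine-tune per-symptom severity regressors with LOSO validation
#'
#' For each symptom (R from UPDRS item 22, AFT from item 23, B from item
#' 31) the pretrained encoder plus a fresh dense head is fine-tuned
#' end-to-end on all subjects but one; the held-out subject's sessions are
#' predicted out-of-fold. Final models trained on all subjects are returned
#' for inference on new sessions.
#'
#' @param encoder An `fmi_encoder` from [pretrain_autoencoder()].
#' @param samples List of `severity_sample` objects (see
#'   [simulate_severity_dataset()]): each has a padded `dynamics` series, a
#'   `subject_id` and `scores = c(item22, item23, item31)` in 0-4.
#' @param cfg A [training_config()].
#' @return An `fmi_models` object: `models` (one per symptom), `loso`
#'   (out-of-fold predictions with truth), and `spearman` (per-symptom
#'   Spearman correlation between LOSO predictions and true scores).
#' @export
finetune_regressors <- function(encoder, samples, cfg = training_config()) {
  subjects <- vapply(samples, function(s) s$subject_id, character(1))
  if (length(unique(subjects)) < 3L) stop("need samples from >= 3 subjects")
  L <- encoder$spec$input_length; K <- encoder$spec$kernel_size
  X <- stack_dynamics(lapply(samples, `[[`, "dynamics"), L)
  scores <- do.call(rbind, lapply(samples, `[[`, "scores"))
  scores <- scores[, unname(fmi_symptoms), drop = FALSE]

  uniq <- unique(subjects)
  loso <- list()
  models <- list()
  for (sym in names(fmi_symptoms)) {
    y <- scores[, fmi_symptoms[[sym]]]
    for (f in seq_along(uniq)) {
      tr <- which(subjects != uniq[[f]])
      te <- which(subjects == uniq[[f]])
      seed_f <- cfg$seed + 1000L * match(sym, names(fmi_symptoms)) + f
      set.seed(seed_f)
      params <- train_regressor(init_head(encoder, cfg),
                                X[, batch_cols(tr, L), drop = FALSE],
                                y[tr], L, K, cfg, seed_f)
      idx_te <- conv_index(L, length(te), K)
      pred <- reg_forward(params, X[, batch_cols(te, L), drop = FALSE],
                          idx_te, L, length(te))$y
      loso[[length(loso) + 1L]] <- data.frame(
        subject_id = uniq[[f]], sample = te, symptom = sym,
        truth = y[te], pred = pmin(pmax(pred, 0), 4),
        stringsAsFactors = FALSE)
    }
    seed_full <- cfg$seed + 1000L * match(sym, names(fmi_symptoms))
    set.seed(seed_full)
    params <- train_regressor(init_head(encoder, cfg), X, y, L, K, cfg, seed_full)
    models[[sym]] <- list(params = params, symptom = sym,
                          spec = encoder$spec, cfg = cfg)
  }
  loso <- do.call(rbind, loso)
  rho <- vapply(split(loso, loso$symptom), function(d)
    suppressWarnings(stats::cor(d$truth, d$pred, method = "spearman")),
    numeric(1))
  structure(list(models = models, loso = loso,
                 spearman = rho[names(fmi_symptoms)],
                 spec = encoder$spec, cfg = cfg),
            class = "fmi_models")
}

#' @export
print.fmi_models <- function(x, ...) {
  cat("<fmi_models R/B/AFT; LOSO Spearman:",
      paste(sprintf("%s=%.2f", names(x$spearman), x$spearman), collapse = " "),
      ">\n")
  invisible(x)
}

#' Predict severity indices for one typing session
#'
#' @param models An `fmi_models` object.
#' @param series A `dynamics_series` padded to the models' input length.
#' @return An `fmi_indices` row: `session_id`, `subject_id`, `r_index`,
#'   `b_index`, `aft_index`, each clipped to `[0, 4]`.
#' @export
predict_indices <- function(models, series) {
  stopifnot(inherits(models, "fmi_models"))
  L <- models$spec$input_length
  if (is.null(series$padded_ht) || length(series$padded_ht) != L)
    stop(sprintf("series must be padded to length %d", L))
  X <- stack_dynamics(list(series), L)
  idx <- conv_index(L, 1L, models$spec$kernel_size)
  one <- function(m) {
    y <- reg_forward(m$params, X, idx, L, 1L)$y
    pmin(pmax(y, 0), 4)
  }
  structure(data.frame(session_id = series$session_id,
                       subject_id = series$subject_id,
                       r_index = one(models$models$R),
                       b_index = one(models$models$B),
                       aft_index = one(models$models$AFT),
                       stringsAsFactors = FALSE),
            class = c("fmi_indices", "data.frame"))
}

#' Aggregate session-level indices to one subject row
#'
#' Field-wise mean of the per-session R/B/AFT indices.
#'
#' @param indices data.frame of per-session index rows for one subject
#'   (rbind of [predict_indices()] outputs).
#' @return One-row data.frame: `subject_id`, `n_sessions`, `R`, `B`, `AFT`.
#' @export
aggregate_subject_indices <- function(indices) {
  if (nrow(indices) < 1L) stop("no session indices to aggregate")
  data.frame(subject_id = indices$subject_id[[1]],
             n_sessions = nrow(indices),
             R = mean(indices$r_index), B = mean(indices$b_index),
             AFT = mean(indices$aft_index), stringsAsFactors = FALSE)
}

#' Save or load fitted severity models
#'
#' Checkpoints are a single JSON archive embedding the architecture spec,
#' the training configuration (including the seed) and all weights written
#' at full double precision (15+ significant digits), so reloaded models
#' reproduce inference to near machine precision.
#'
#' @param models An `fmi_models` object.
#' @param path Path to a `.json` checkpoint.
#' @return `write_fmi_models` returns `path` invisibly; `read_fmi_models`
#'   returns an `fmi_models` object.
#' @export
write_fmi_models <- function(models, path) {
  stopifnot(inherits(models, "fmi_models"))
  payload <- list(
    format = "cogtype-fmi-models-v1",
    spec = unclass(models$spec), cfg = unclass(models$cfg),
    spearman = as.list(models$spearman),
    params = lapply(models$models, function(m) m$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fmi_models
#' @export
read_fmi_models <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "cogtype-fmi-models-v1"))
    stop("not a cogtype model checkpoint: ", path)
  spec <- do.call(encoder_spec, raw$spec[c("input_length", "channels",
                                           "kernel_size", "filters")])
  cfg <- do.call(training_config, raw$cfg)
  fix <- function(p) {
    for (nm in names(p)) {
      p[[nm]]$W <- as.matrix(p[[nm]]$W)
      p[[nm]]$b <- as.numeric(p[[nm]]$b)
      if (!is.null(p[[nm]]$c_in)) {
        p[[nm]]$c_in <- as.integer(p[[nm]]$c_in)
        p[[nm]]$K <- as.integer(p[[nm]]$K)
      }
    }
    p
  }
  models <- lapply(names(raw$params), function(sym)
    list(params = fix(raw$params[[sym]]), symptom = sym,
         spec = spec, cfg = cfg))
  names(models) <- names(raw$params)
  structure(list(models = models, loso = NULL,
                 spearman = unlist(raw$spearman), spec = spec, cfg = cfg),
            class = "fmi_models")
}

#' Per-subject FMI feature table from raw sessions
#'
#' Preprocesses sessions ([preprocess_sessions()]), predicts per-session
#' indices and averages them within subject.
#'
#' @param sessions List of [typing_session()] objects.
#' @param models An `fmi_models` object.
#' @inheritParams preprocess_sessions
#' @return data.frame with one row per subject: `subject_id`, `n_sessions`,
#'   `R`, `B`, `AFT`.
#' @export
fmi_feature_table <- function(sessions, models, min_presses = 40L,
                              ht_max = 0.700, ft_max = 3.0) {
  dyn <- preprocess_sessions(sessions, min_presses, ht_max, ft_max,
                             models$spec$input_length)
  if (length(dyn) == 0L) stop("no usable sessions after QC")
  rows <- do.call(rbind, lapply(dyn, function(d) predict_indices(models, d)))
  out <- do.call(rbind, lapply(split(rows, rows$subject_id),
                               aggregate_subject_indices))
  rownames(out) <- NULL
  out
}
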
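#' Training configuration
#'
#' Defaults follow the published training protocol: Adam with learning
#' rate 5e-5 and batch size 1; early stopping once the validation score
#' fails to improve by 1e-4 within the last 10 epochs, with the first 30
#' epochs always trained.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size samples per optimization step.
#' @param max_epochs hard cap on epochs.
#' @param warmup_epochs_no_stop epochs trained before early stopping may
#'   trigger.
#' @param patience_epochs early-stopping patience window.
#' @param min_improvement minimum validation-score improvement that
#'   resets the patience window.
#' @param optimizer only `"adam"` (beta1 = 0.9, beta2 = 0.999,
#'   eps = 1e-8).
#' @param seed integer seed for shuffling, augmentation and
#'   initialization.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 1L,
                         max_epochs = 200L, warmup_epochs_no_stop = 30L,
                         patience_epochs = 10L, min_improvement = 1e-4,
                         optimizer = "adam", seed = 0L) {
  optimizer <- match.arg(optimizer, "adam")
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (patience_epochs < 1L) stop("patience_epochs must be >= 1", call. = FALSE)
  if (warmup_epochs_no_stop < 0L) stop("warmup must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs_no_stop = as.integer(warmup_epochs_no_stop),
                 patience_epochs = as.integer(patience_epochs),
                 min_improvement = min_improvement,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' Class re-weighting factors for the segmentation loss
#'
#' The foreground (proximal femur) typically occupies a small fraction of
#' the image, biasing an unweighted loss towards background. The loss
#' therefore weights foreground errors by the background fraction
#' `N_b / N` and background errors by the foreground fraction `N_p / N`;
#' the weights sum to one.
#'
#' @param m a [label_mask()] (or 0/1 array).
#' @return named vector `c(w_fg, w_bg)`.
#' @export
class_weights <- function(m) {
  y <- if (inherits(m, "label_mask")) m$data else m
  n <- length(y)
  np <- sum(y == 1)
  nb <- n - np
  if (np == 0L || nb == 0L) {
    stop("class_weights: degenerate mask (single class)", call. = FALSE)
  }
  c(w_fg = nb / n, w_bg = np / n)
}

#' Class-re-weighted cross-entropy
#'
#' `CE = -(1/N) * sum_i [ w_fg * y_i * log p_i + w_bg * (1 - y_i) * log(1 - p_i) ]`
#' with `y_i` the foreground indicator and `p_i` the predicted foreground
#' probability, clipped to `[eps, 1 - eps]` for numerical safety. With
#' the weights of [class_weights()] (`w_fg = N_b/N`, `w_bg = N_p/N`) this
#' is the class-imbalance-corrected loss minimized during training.
#'
#' @param p a [probability_map()] or probability array.
#' @param m a [label_mask()] or 0/1 array of the same shape.
#' @param w weight pair `c(w_fg, w_bg)`; defaults to [class_weights()] of
#'   `m`.
#' @param eps clipping constant.
#' @return non-negative scalar loss.
#' @export
weighted_cross_entropy <- function(p, m, w = NULL, eps = 1e-7) {
  pd <- if (inherits(p, "probability_map")) p$data else p
  y <- if (inherits(m, "label_mask")) m$data else m
  if (!identical(dim(pd), dim(y))) {
    stop("weighted_cross_entropy: shape mismatch", call. = FALSE)
  }
  if (is.null(w)) w <- class_weights(y)
  pd <- pmin(pmax(pd, eps), 1 - eps)
  -mean(w[[1L]] * y * log(pd) + w[[2L]] * (1 - y) * log(1 - pd))
}

# loss and gradient w.r.t. the two-channel logits, fused with the softmax
wce_loss_grad <- function(logits, y, w, eps = 1e-7) {
  d <- length(dim(logits)) - 1L
  sp <- dim(logits)[seq_len(d)]
  p1 <- softmax2(logits)
  pc <- pmin(pmax(p1, eps), 1 - eps)
  n <- length(y)
  loss <- -sum(w[[1L]] * y * log(pc) + w[[2L]] * (1 - y) * log(1 - pc)) / n
  wi <- (w[[1L]] * y + w[[2L]] * (1 - y)) / n
  dz1 <- wi * (p1 - y)
  dlogits <- array(c(-dz1, dz1), c(sp, 2L))
  list(loss = loss, dlogits = dlogits, prob = p1)
}

#' Joint left-right flip augmentation
#'
#' With probability 0.5, reflects image and mask together along the
#' in-plane left-right axis (axis 1), emulating the left/right hip
#' laterality variation across subjects. Always applied jointly so the
#' pair stays consistent.
#'
#' @param image,mask arrays (or the package's volume/mask types) sharing
#'   a grid.
#' @param force `NULL` for a random draw, or `TRUE`/`FALSE` to force.
#' @return `list(image, mask, flipped)`.
#' @export
augment_flip <- function(image, mask, force = NULL) {
  flip <- if (is.null(force)) stats::runif(1) < 0.5 else isTRUE(force)
  if (flip) {
    image <- flip_x(image)
    mask <- flip_x(mask)
  }
  list(image = image, mask = mask, flipped = flip)
}

flip_x <- function(x) {
  if (inherits(x, c("image_volume", "label_mask", "probability_map"))) {
    x$data <- flip_x(x$data)
    return(x)
  }
  d <- dim(x)
  idx <- c(list(d[1L]:1), rep(list(quote(expr = )), length(d) - 1L))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Build three-consecutive-slice training samples from a volume
#'
#' One sample per interior slice `k` in `2..(nz-1)`: the input channels
#' are slices `(k-1, k, k+1)` and the target is the mask of the center
#' slice `k`. Edge slices are never sample centers.
#'
#' @param v an [image_volume()] (or 3D array).
#' @param m the paired [label_mask()] (or 3D array).
#' @return list of `list(x = nx*ny*3 array, y = nx*ny matrix, slice = k)`.
#' @export
make_2d_samples <- function(v, m) {
  img <- if (inherits(v, "image_volume")) v$data else v
  msk <- if (inherits(m, "label_mask")) m$data else m
  if (!identical(dim(img), dim(msk))) {
    stop("make_2d_samples: image/mask shape mismatch", call. = FALSE)
  }
  nz <- dim(img)[3L]
  if (nz < 3L) stop("make_2d_samples: need at least 3 slices", call. = FALSE)
  lapply(seq(2L, nz - 1L), function(k) {
    list(x = array(img[, , (k - 1L):(k + 1L)], c(dim(img)[1:2], 3L)),
         y = msk[, , k], slice = k)
  })
}

#' Stratified fold assignment for cross-validation
#'
#' Random, seed-reproducible partition into `k` disjoint, exhaustive
#' folds whose total sizes differ by at most one and whose per-stratum
#' counts per fold differ by at most one (stratified random sampling).
#'
#' @param subjects a cohort list (elements carrying `$stratum`), or an
#'   integer/factor vector of stratum labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param subject_ids optional ids; defaults to positions.
#' @return data.frame `(subject_id, stratum, fold)` with folds in
#'   `1..k`.
#' @export
stratified_folds <- function(subjects, k = 4L, seed = 0L,
                             subject_ids = NULL) {
  if (is.list(subjects)) {
    strata <- vapply(subjects, function(s) as.integer(s$stratum), integer(1L))
    if (is.null(subject_ids)) {
      subject_ids <- vapply(seq_along(subjects), function(i) {
        id <- subjects[[i]]$image$subject_id %||% ""
        if (nzchar(id)) id else sprintf("subj-%03d", i)
      }, character(1L))
    }
  } else {
    strata <- subjects
  }
  n <- length(strata)
  k <- as.integer(k)
  if (k < 2L) stop("stratified_folds: k must be >= 2", call. = FALSE)
  if (k > n) stop("stratified_folds: k exceeds the number of subjects",
                  call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- sprintf("subj-%03d", seq_len(n))
  fold <- integer(n)
  totals <- integer(k)
  with_seed(derive_seed(seed, "folds"), {
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      counts <- rep(length(idx) %/% k, k)
      extra <- length(idx) %% k
      if (extra > 0L) {
        # remainders go to the currently smallest folds (random tie-break)
        ord <- order(totals + stats::runif(k) * 1e-9)
        counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
      }
      pos <- 1L
      for (f in seq_len(k)) {
        if (counts[f] > 0L) {
          fold[idx[pos:(pos + counts[f] - 1L)]] <- f
          pos <- pos + counts[f]
        }
      }
      totals <- totals + counts
    }
  })
  data.frame(subject_id = subject_ids, stratum = strata, fold = fold,
             stringsAsFactors = FALSE)
}

normalize_intensities <- function(x) {
  s <- stats::sd(x)
  if (s == 0) s <- 1
  (x - mean(x)) / s
}

# convert a cohort subject into the network's training samples
subject_samples <- function(subject, spec) {
  img <- normalize_intensities(subject$image$data)
  msk <- subject$mask$data
  if (spec$dims == 3L) {
    list(list(x = array(img, c(dim(img), 1L)), y = msk,
              subject_id = subject$image$subject_id))
  } else {
    samples <- make_2d_samples(img, msk)
    lapply(samples, function(s) {
      s$subject_id <- subject$image$subject_id
      s
    })
  }
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_update <- function(params, state, grads, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (st$mW / c1) /
      (sqrt(st$vW / c2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (st$mb / c1) /
      (sqrt(st$vb / c2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train a segmentation network
#'
#' Adam optimization of the class-re-weighted cross-entropy with
#' left-right flip augmentation on the training set only. The validation
#' score driving early stopping is the mean foreground Dice coefficient
#' at threshold 0.5 over the validation subjects. After the warmup
#' epochs, training stops once the best validation score has not improved
#' by at least `min_improvement` within the last `patience_epochs`
#' epochs; the parameters of the best validation epoch are returned.
#'
#' @param train,val lists of subjects (`list(image, mask)`), disjoint by
#'   subject.
#' @param spec an [architecture_spec()].
#' @param cfg a [train_config()].
#' @param quiet suppress the per-epoch progress line.
#' @return `list(model, history)`; `history` carries the per-epoch train
#'   loss and validation score, the stop epoch and the stop reason.
#' @export
train_model <- function(train, val, spec, cfg = train_config(),
                        quiet = TRUE) {
  if (length(train) == 0L || length(val) == 0L) {
    stop("train_model: train and val must be nonempty", call. = FALSE)
  }
  tr_ids <- vapply(train, function(s) s$image$subject_id, character(1L))
  va_ids <- vapply(val, function(s) s$image$subject_id, character(1L))
  if (length(intersect(tr_ids, va_ids)) > 0L) {
    stop("train_model: train and val share subjects: ",
         paste(intersect(tr_ids, va_ids), collapse = ", "), call. = FALSE)
  }
  model <- build_network(spec, seed = derive_seed(cfg$seed, "init"))
  samples <- unlist(lapply(train, subject_samples, spec = spec),
                    recursive = FALSE)
  keep <- vapply(samples, function(s) {
    np <- sum(s$y == 1)
    np > 0L && np < length(s$y)
  }, logical(1L))
  if (any(!keep)) {
    warning(sum(!keep), " degenerate (single-class) training samples excluded",
            call. = FALSE)
  }
  samples <- samples[keep]
  if (length(samples) == 0L) {
    stop("train_model: no usable training samples", call. = FALSE)
  }
  weights <- lapply(samples, function(s) class_weights(s$y))

  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_score = numeric(0))
  best_score <- -Inf
  best_epoch <- 0L
  signif_epoch <- 0L
  best_params <- model$params
  stop_reason <- "max_epochs"
  stop_epoch <- cfg$max_epochs
  t_step <- 0L

  with_seed(derive_seed(cfg$seed, "train-loop"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(samples))
      epoch_loss <- 0
      for (i in ord) {
        s <- samples[[i]]
        aug <- augment_flip(s$x, s$y)
        fw <- net_forward(model, aug$image, tape = TRUE)
        lg <- wce_loss_grad(fw$logits, aug$mask, weights[[i]])
        if (!is.finite(lg$loss)) {
          stop(sprintf("train_model: non-finite loss at epoch %d (subject %s)",
                       epoch, s$subject_id), call. = FALSE)
        }
        epoch_loss <- epoch_loss + lg$loss
        grads <- net_backward(model, fw, lg$dlogits)
        t_step <- t_step + 1L
        upd <- adam_update(model$params, state, grads, cfg$learning_rate,
                           t_step)
        model$params <- upd$params
        state <- upd$state
      }
      val_score <- mean(vapply(val, function(s) {
        pm <- predict_volume(model, s$image)
        dsc(confusion(label_mask(pm$data > 0.5, s$mask$spacing),
                      s$mask))
      }, numeric(1L)))
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / length(samples),
                                  val_score = val_score))
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.5f  val DSC %.4f", epoch,
                        epoch_loss / length(samples), val_score))
      }
      significant <- val_score >= best_score + cfg$min_improvement
      if (val_score > best_score) {
        best_score <- val_score
        best_params <- model$params
        best_epoch <- epoch
      }
      if (significant) signif_epoch <- epoch
      anchor <- max(signif_epoch, cfg$warmup_epochs_no_stop)
      if (epoch - anchor >= cfg$patience_epochs) {
        stop_reason <- "early"
        stop_epoch <- epoch
        break
      }
      stop_epoch <- epoch
    }
  })
  model$params <- best_params
  list(model = model,
       history = list(epochs = history, stop_epoch = stop_epoch,
                      stop_reason = stop_reason, best_epoch = best_epoch,
                      best_score = best_score))
}

#' Stratified k-fold cross-validation
#'
#' Derives `k` models, each trained on `k - 1` folds and applied to the
#' held-out fold, so the validation predictions collectively cover every
#' subject exactly once.
#'
#' @param cohort list of subjects (`list(image, mask, stratum)`).
#' @param spec an [architecture_spec()].
#' @param cfg a [train_config()].
#' @param k number of folds.
#' @param quiet passed to [train_model()].
#' @return list with `folds` (the assignment) and per-fold
#'   `list(model, predictions, history)`, predictions being named
#'   [probability_map()]s of the fold's validation subjects.
#' @export
crossvalidate <- function(cohort, spec, cfg = train_config(), k = 4L,
                          quiet = TRUE) {
  if (length(cohort) < k) {
    stop("crossvalidate: cohort smaller than k", call. = FALSE)
  }
  fa <- stratified_folds(cohort, k = k, seed = cfg$seed)
  results <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- cohort[fa$fold != f]
    va <- cohort[fa$fold == f]
    fit <- tryCatch(train_model(tr, va, spec, cfg, quiet = quiet),
                    error = function(e) {
                      stop(sprintf("fold %d: %s", f, conditionMessage(e)),
                           call. = FALSE)
                    })
    preds <- lapply(va, function(s) predict_volume(fit$model, s$image))
    names(preds) <- vapply(va, function(s) s$image$subject_id, character(1L))
    results[[f]] <- list(model = fit$model, predictions = preds,
                         history = fit$history)
  }
  list(folds = fa, results = results)
}
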
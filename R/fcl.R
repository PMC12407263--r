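# Fully connected peak-segmentation model for 512-sample profiles.
#
# Architecture: input 512 -> hidden 256 (ReLU, dropout 0.5 in training)
# -> output 1 (logistic). The single output node yields a per-pixel
# probability by evaluating the network once per profile position on a
# circularly shifted copy of the (min-max normalized) profile centred on
# that position, with the window's first element replaced by the
# normalized position. Training minimizes binary cross entropy with Adam.

# Circular-shift index matrix: row p gives the 512 profile indices of the
# window centred on position p (element 257 is position p itself).
.shift_cache <- new.env(parent = emptyenv())
shift_index <- function() {
  if (is.null(.shift_cache$I)) {
    .shift_cache$I <- (outer(1:512 - 257L, 0:511, "+") %% 512L) + 1L
  }
  .shift_cache$I
}

# min-max normalization of a profile to [0,1]; constant profiles map to 0.
normalize_profile <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < .Machine$double.eps) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

# Input rows for positions `pos` of normalized profile `x`.
encode_positions <- function(x, pos) {
  I <- shift_index()
  X <- matrix(x[t(I[pos, , drop = FALSE])], length(pos), 512, byrow = TRUE)
  X[, 1] <- pos / 512
  X
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a fully connected peak-segmentation model
#'
#' Learns per-pixel probabilities that a profile position belongs to a
#' colored line. Labeled profiles are split 80/20 into training and
#' held-out sets; the model is trained with binary cross entropy, Adam
#' (learning rate \code{lr}), 100 epochs and a batch size of 10 profiles,
#' with dropout 0.5 on the hidden layer. Because adjacent shifted windows
#' are nearly identical, each epoch draws a label-stratified random subset
#' of \code{pixels_per_profile} positions per profile rather than all 512;
#' every profile is still visited every epoch. Training is deterministic
#' given \code{seed}.
#'
#' @param data a labeled profile set: list with \code{profiles} (n x 512
#'   matrix), \code{masks} (n x 512 0/1 matrix) and \code{variant}
#'   (see [generate_labeled_profiles()]).
#' @param variant \code{"two_peak"}, \code{"three_peak"} or
#'   \code{"pooled"}; must match the data's variant.
#' @param seed integer seed (split, initialization, dropout, sampling).
#' @param epochs,batch_size,lr,dropout,hidden training hyperparameters;
#'   the defaults are the package's fixed recipe.
#' @param pixels_per_profile positions sampled per profile per epoch.
#' @param test_fraction held-out fraction.
#' @return object of class \code{fcl_model}: weights, \code{variant},
#'   \code{threshold} (0.5), held-out \code{metrics} (pixelwise accuracy,
#'   precision, recall), and training metadata.
#' @export
train_fcl <- function(data, variant = c("two_peak", "three_peak", "pooled"),
                      seed = 1L, epochs = 100L, batch_size = 10L,
                      lr = 1e-3, dropout = 0.5, hidden = 256L,
                      pixels_per_profile = 48L, test_fraction = 0.2) {
  variant <- match.arg(variant)
  stopifnot(is.list(data), is.matrix(data$profiles), is.matrix(data$masks),
            ncol(data$profiles) == 512, ncol(data$masks) == 512,
            nrow(data$profiles) == nrow(data$masks))
  if (!is.null(data$variant) && !identical(data$variant, variant))
    stop_domain(sprintf(
      "data error: labeled profiles are of variant '%s', not '%s'",
      data$variant, variant))
  n <- nrow(data$profiles)
  if (n < 50) stop_domain("need at least 50 labeled profiles")

  X_all <- t(apply(data$profiles, 1, normalize_profile))
  Y_all <- data$masks

  with_seed(seed, {
    n_test <- max(1L, round(test_fraction * n))
    test_idx <- sort(sample.int(n, n_test))
    train_idx <- setdiff(seq_len(n), test_idx)

    W1 <- matrix(stats::rnorm(512 * hidden, 0, sqrt(2 / 512)), 512, hidden)
    b1 <- rep(0, hidden)
    w2 <- matrix(stats::rnorm(hidden, 0, sqrt(2 / hidden)), hidden, 1)
    b2 <- 0
    adam <- list(mW1 = W1 * 0, vW1 = W1 * 0, mb1 = b1 * 0, vb1 = b1 * 0,
                 mw2 = w2 * 0, vw2 = w2 * 0, mb2 = 0, vb2 = 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0
    keep <- 1 - dropout

    for (ep in seq_len(epochs)) {
      order_ep <- sample(train_idx)
      batches <- split(order_ep, ceiling(seq_along(order_ep) / batch_size))
      for (bi in batches) {
        # build the batch: uniform position sample per profile (uniform
        # keeps the pixelwise class prior intact, so the learned
        # probabilities stay calibrated against the 0.5 threshold)
        Xl <- vector("list", length(bi)); Yl <- vector("list", length(bi))
        for (j in seq_along(bi)) {
          pos <- sample.int(512L, pixels_per_profile)
          Xl[[j]] <- encode_positions(X_all[bi[j], ], pos)
          Yl[[j]] <- Y_all[bi[j], pos]
        }
        X <- do.call(rbind, Xl); y <- unlist(Yl)
        m <- nrow(X)

        A1 <- X %*% W1
        A1 <- sweep(A1, 2, b1, "+")
        H1 <- A1 * (A1 > 0)
        D <- matrix(stats::rbinom(m * hidden, 1, keep), m, hidden) / keep
        Hd <- H1 * D
        p <- sigmoid(Hd %*% w2 + b2)

        dz <- (p - y) / m                       # BCE + logistic gradient
        gw2 <- crossprod(Hd, dz)
        gb2 <- sum(dz)
        dH <- (dz %*% t(w2)) * D * (A1 > 0)
        gW1 <- crossprod(X, dH)
        gb1 <- colSums(dH)

        t_step <- t_step + 1
        upd <- function(m_, v_, g) {
          m_ <- beta1 * m_ + (1 - beta1) * g
          v_ <- beta2 * v_ + (1 - beta2) * g^2
          mh <- m_ / (1 - beta1^t_step); vh <- v_ / (1 - beta2^t_step)
          list(m = m_, v = v_, step = lr * mh / (sqrt(vh) + eps))
        }
        u <- upd(adam$mW1, adam$vW1, gW1)
        adam$mW1 <- u$m; adam$vW1 <- u$v; W1 <- W1 - u$step
        u <- upd(adam$mb1, adam$vb1, gb1)
        adam$mb1 <- u$m; adam$vb1 <- u$v; b1 <- b1 - u$step
        u <- upd(adam$mw2, adam$vw2, gw2)
        adam$mw2 <- u$m; adam$vw2 <- u$v; w2 <- w2 - u$step
        u <- upd(adam$mb2, adam$vb2, gb2)
        adam$mb2 <- u$m; adam$vb2 <- u$v; b2 <- b2 - u$step
      }
    }

    model <- structure(list(
      W1 = W1, b1 = b1, w2 = w2, b2 = b2,
      variant = variant, threshold = 0.5, seed = as.integer(seed),
      meta = list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                  lr = lr, dropout = dropout,
                  pixels_per_profile = pixels_per_profile,
                  encoding = "circular-shift window centred on pixel; first element replaced by normalized position",
                  normalization = "per-profile min-max to [0,1]",
                  n_train = length(train_idx), n_test = n_test)),
      class = "fcl_model")

    # held-out pixelwise metrics
    preds <- lapply(test_idx, function(i)
      fcl_probabilities(model, X_all[i, ]) >= model$threshold)
    pred <- as.integer(unlist(preds))
    truth <- as.integer(t(Y_all[test_idx, , drop = FALSE]))
    model$metrics <- evaluate_segmentation(pred, truth)
    model
  })
}

# Per-position probabilities for a normalized 512-profile.
fcl_probabilities <- function(model, x_norm) {
  X <- encode_positions(x_norm, 1:512)
  H <- X %*% model$W1
  H <- sweep(H, 2, model$b1, "+")
  H <- H * (H > 0)
  as.numeric(sigmoid(H %*% model$w2 + model$b2))
}

#' Per-pixel peak probabilities and binary mask for a profile
#'
#' Applies the trained model to every position of a length-512 profile.
#' Inference is deterministic (no dropout). The binary mask is
#' \code{probability >= threshold}; a probability of exactly 0.5 counts as
#' peak (the documented tie rule).
#'
#' @param model an \code{fcl_model} from [train_fcl()].
#' @param profile an [intensity_profile()] or numeric vector of length
#'   512.
#' @param threshold override of the model's binarization threshold.
#' @return list with \code{probabilities} (length 512 in \code{(0,1)})
#'   and \code{mask} (integer 0/1).
#' @export
predict_mask <- function(model, profile, threshold = model$threshold) {
  stopifnot(inherits(model, "fcl_model"))
  v <- if (inherits(profile, "intensity_profile")) profile$values else profile
  if (!is.numeric(v) || length(v) != 512)
    stop_domain("profile must have exactly 512 samples (contract error)")
  p <- fcl_probabilities(model, normalize_profile(v))
  list(probabilities = p, mask = as.integer(p >= threshold))
}

#' @export
predict.fcl_model <- function(object, newdata, ...) {
  predict_mask(object, newdata, ...)
}

#' @export
print.fcl_model <- function(x, ...) {
  cat(sprintf("FCL peak-segmentation model (%s): 512-256-1, threshold %.2f, seed %d\n",
              x$variant, x$threshold, x$seed))
  if (!is.null(x$metrics))
    cat(sprintf("  held-out pixelwise: accuracy %.3f, precision %.3f, recall %.3f (n_test = %d)\n",
                x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
                x$meta$n_test))
  invisible(x)
}

#' Pixelwise segmentation metrics
#'
#' Standard binary confusion-matrix metrics. When a denominator is zero
#' (no predicted positives for precision, no true positives for recall)
#' the metric is reported as 0.
#'
#' @param pred_mask,truth_mask equal-length 0/1 vectors.
#' @return list with \code{accuracy}, \code{precision}, \code{recall}.
#' @export
evaluate_segmentation <- function(pred_mask, truth_mask) {
  if (length(pred_mask) != length(truth_mask))
    stop_domain("prediction and truth masks must have equal length (contract error)")
  p <- as.integer(pred_mask); t_ <- as.integer(truth_mask)
  tp <- sum(p == 1 & t_ == 1); tn <- sum(p == 0 & t_ == 0)
  fp <- sum(p == 1 & t_ == 0); fn <- sum(p == 0 & t_ == 1)
  list(accuracy = (tp + tn) / length(p),
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' Serialize / restore an FCL model as portable text
#'
#' Weights are written as a single JSON file with a metadata header
#' (variant, seed, held-out metrics, training recipe), so models can be
#' shipped and audited without binary artifacts.
#'
#' @param model an \code{fcl_model}.
#' @param path file path.
#' @return \code{write_fcl} returns \code{path} invisibly;
#'   \code{read_fcl} returns the restored model.
#' @export
write_fcl <- function(model, path) {
  stopifnot(inherits(model, "fcl_model"))
  obj <- list(variant = model$variant, seed = model$seed,
              threshold = model$threshold, meta = model$meta,
              metrics = model$metrics,
              W1 = as.numeric(model$W1), b1 = model$b1,
              w2 = as.numeric(model$w2), b2 = model$b2,
              hidden = ncol(model$W1))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fcl
#' @export
read_fcl <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W1 = matrix(o$W1, 512, o$hidden), b1 = o$b1,
                 w2 = matrix(o$w2, o$hidden, 1), b2 = o$b2,
                 variant = o$variant, threshold = o$threshold,
                 seed = o$seed, meta = o$meta, metrics = o$metrics),
            class = "fcl_model")
}
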
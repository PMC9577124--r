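#' Specify the attention-MIL model architecture
#'
#' The scorer is encoder -> attention pooling -> decoder. The attention
#' head is a one-hidden-layer network (mish activation, batch
#' normalization) producing one logit per instance, softmax-normalized
#' into pooling weights; the decoder is a two-hidden-layer network (mish,
#' batchnorm) ending in a 2-class output. Batchnorm sits after the linear
#' map, before the activation.
#'
#' The default encoder is a small fixed-weight convolutional feature
#' extractor: two 3x3 convolution layers (mish, 2x2 mean pooling between
#' them) whose weights are drawn once from `seed` and then frozen; per-map
#' spatial mean and max form the instance feature vector. Only the
#' attention and decoder heads are trained.
#'
#' @param patch_px Side length of the input patches.
#' @param enc_filters Filter counts of the two convolution layers
#'   (feature width is `2 * enc_filters[2]`).
#' @param att_hidden Attention hidden width (the full-scale architecture
#'   uses 64; the desk-scale default is 16).
#' @param dec_hidden Decoder hidden widths (full-scale: `c(768, 16)`;
#'   desk-scale default `c(32, 16)`).
#' @param batchnorm Use batch normalization in the heads (default TRUE).
#' @param seed Integer seed that fixes the encoder weights and head
#'   initialisation.
#' @return A `model_spec` list.
#' @export
model_spec <- function(patch_px = 32, enc_filters = c(8, 16), att_hidden = 16,
                       dec_hidden = c(32, 16), batchnorm = TRUE, seed = 1) {
  structure(list(
    patch_px = as.integer(patch_px), enc_filters = as.integer(enc_filters),
    feat_width = 2L * as.integer(enc_filters[2]),
    att_hidden = as.integer(att_hidden), dec_hidden = as.integer(dec_hidden),
    batchnorm = isTRUE(batchnorm), seed = as.integer(seed)
  ), class = "model_spec")
}

mish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  x * tanh(sp)
}

mish_grad <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  t <- tanh(sp)
  t + x * (1 - t^2) * stats::plogis(x)
}

# valid 3x3 convolution of an HxWxCin array with weights [3,3,Cin,Cout]
conv3x3 <- function(x, w, b) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]; cout <- dim(w)[4]
  oh <- h - 2L; ow <- wd - 2L
  out <- array(rep(b, each = oh * ow), dim = c(oh, ow, cout))
  for (ci in seq_len(cin)) {
    xc <- x[, , ci]
    for (di in 0:2) for (dj in 0:2) {
      patch <- xc[(1 + di):(oh + di), (1 + dj):(ow + dj)]
      for (co in seq_len(cout)) {
        out[, , co] <- out[, , co] + patch * w[di + 1, dj + 1, ci, co]
      }
    }
  }
  out
}

meanpool2 <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L; cc <- dim(x)[3]
  out <- array(0, dim = c(h, w, cc))
  for (ci in seq_len(cc)) {
    m <- x[seq_len(2 * h), seq_len(2 * w), ci]
    out[, , ci] <- (m[seq(1, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(1, 2 * w, 2)] +
                    m[seq(1, 2 * h, 2), seq(2, 2 * w, 2)] +
                    m[seq(2, 2 * h, 2), seq(2, 2 * w, 2)]) / 4
  }
  out
}

init_encoder <- function(spec) {
  f1 <- spec$enc_filters[1]; f2 <- spec$enc_filters[2]
  with_seed(spec$seed, {
    list(
      w1 = array(stats::rnorm(3 * 3 * 3 * f1, sd = sqrt(2 / (9 * 3))), c(3, 3, 3, f1)),
      b1 = rep(0, f1),
      w2 = array(stats::rnorm(3 * 3 * f1 * f2, sd = sqrt(2 / (9 * f1))), c(3, 3, f1, f2)),
      b2 = rep(0, f2)
    )
  })
}

#' Initialise an untrained MIL model
#'
#' @param spec A [model_spec()].
#' @param head_seed Seed for the trainable head initialisation; the frozen
#'   encoder always comes from `spec$seed`, so models sharing a spec share
#'   features regardless of head initialisation.
#' @return A `mil_model` with frozen encoder weights and empty training
#'   history.
#' @export
init_mil_model <- function(spec, head_seed = spec$seed + 1L) {
  d <- spec$feat_width; ha <- spec$att_hidden
  h1 <- spec$dec_hidden[1]; h2 <- spec$dec_hidden[2]
  enc <- init_encoder(spec)
  params <- with_seed(head_seed, list(
    A_W1 = matrix(stats::rnorm(d * ha, sd = sqrt(2 / d)), d, ha),
    A_b1 = rep(0, ha), A_g = rep(1, ha), A_be = rep(0, ha),
    A_w2 = stats::rnorm(ha, sd = sqrt(1 / ha)), A_b2 = 0,
    D_W1 = matrix(stats::rnorm(d * h1, sd = sqrt(2 / d)), d, h1),
    D_b1 = rep(0, h1), D_g1 = rep(1, h1), D_be1 = rep(0, h1),
    D_W2 = matrix(stats::rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
    D_b2 = rep(0, h2), D_g2 = rep(1, h2), D_be2 = rep(0, h2),
    D_W3 = matrix(stats::rnorm(h2 * 2, sd = sqrt(2 / h2)), h2, 2),
    D_b3 = rep(0, 2)
  ))
  bn <- list(
    A_mu = rep(0, ha), A_var = rep(1, ha),
    D1_mu = rep(0, h1), D1_var = rep(1, h1),
    D2_mu = rep(0, h2), D2_var = rep(1, h2)
  )
  structure(list(spec = spec, encoder = enc, params = params, bn = bn,
                 history = numeric(0)), class = "mil_model")
}

#' Encode the instances of a bag into feature vectors
#'
#' Runs the frozen convolutional encoder on every patch: one fixed-width
#' feature vector per instance, deterministic for a given model.
#'
#' @param bag An `instance_bag` from [make_instances()], or a plain list
#'   of PxPx3 arrays.
#' @param model A `mil_model`.
#' @return An n x feat_width matrix, one row per instance.
#' @export
encode_instances <- function(bag, model) {
  patches <- if (inherits(bag, "instance_bag")) bag$patches else bag
  if (length(patches) == 0) stop("empty bag: nothing to encode")
  p <- model$spec$patch_px
  feats <- matrix(0, length(patches), model$spec$feat_width)
  for (i in seq_along(patches)) {
    x <- patches[[i]]
    if (dim(x)[1] != p || dim(x)[2] != p) {
      stop(sprintf("patch %d is %dx%d but the encoder expects %dx%d",
                   i, dim(x)[1], dim(x)[2], p, p))
    }
    a1 <- mish(conv3x3(x, model$encoder$w1, model$encoder$b1))
    a1 <- meanpool2(a1)
    a2 <- mish(conv3x3(a1, model$encoder$w2, model$encoder$b2))
    f2 <- dim(a2)[3]
    feats[i, ] <- c(
      vapply(seq_len(f2), function(c) mean(a2[, , c]), numeric(1)),
      vapply(seq_len(f2), function(c) max(a2[, , c]), numeric(1))
    )
  }
  feats
}

bn_eps <- 1e-5

bn_forward <- function(x, g, be, running_mu, running_var, training, momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    running_mu <- (1 - momentum) * running_mu + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mu; v <- running_var
  }
  xc <- sweep(x, 2, mu)
  inv <- 1 / sqrt(v + bn_eps)
  xhat <- sweep(xc, 2, inv, "*")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, be, "+")
  list(out = out, xhat = xhat, inv = inv, xc = xc, mu = mu, v = v,
       running_mu = running_mu, running_var = running_var)
}

bn_backward <- function(dout, cache, g) {
  n <- nrow(dout)
  dg <- colSums(dout * cache$xhat)
  dbe <- colSums(dout)
  dxhat <- sweep(dout, 2, g, "*")
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  dx <- sweep(
    dxhat - matrix(sum_dxhat / n, n, ncol(dout), byrow = TRUE) -
      sweep(cache$xhat, 2, sum_dxhat_xhat / n, "*"),
    2, cache$inv, "*")
  list(dx = dx, dg = dg, dbe = dbe)
}

#' Attention pooling of instance features
#'
#' Computes one attention logit per instance through the attention head,
#' softmax-normalizes the logits into weights summing to one, and returns
#' the weight-weighted sum of the features as the bag embedding. Weights
#' are permutation-equivariant; the embedding is permutation-invariant.
#'
#' @param features n x d matrix of instance features.
#' @param model A `mil_model` (inference mode: running batchnorm
#'   statistics are used).
#' @return A list with `embedding` (length-d vector) and `weights`
#'   (length-n, summing to 1).
#' @export
attention_pool <- function(features, model) {
  if (!is.matrix(features) || nrow(features) == 0) stop("need >= 1 feature vector")
  p <- model$params
  s1 <- sweep(features %*% p$A_W1, 2, p$A_b1, "+")
  if (model$spec$batchnorm) {
    s1 <- bn_forward(s1, p$A_g, p$A_be, model$bn$A_mu, model$bn$A_var, FALSE)$out
  }
  h <- mish(s1)
  logits <- drop(h %*% p$A_w2) + p$A_b2
  w <- exp(logits - max(logits))
  w <- w / sum(w)
  list(embedding = drop(crossprod(features, w)), weights = w)
}

decoder_forward <- function(z, model, training = FALSE) {
  p <- model$params
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  d1 <- sweep(z %*% p$D_W1, 2, p$D_b1, "+")
  if (model$spec$batchnorm) {
    d1 <- bn_forward(d1, p$D_g1, p$D_be1, model$bn$D1_mu, model$bn$D1_var, training)$out
  }
  u1 <- mish(d1)
  d2 <- sweep(u1 %*% p$D_W2, 2, p$D_b2, "+")
  if (model$spec$batchnorm) {
    d2 <- bn_forward(d2, p$D_g2, p$D_be2, model$bn$D2_mu, model$bn$D2_var, training)$out
  }
  u2 <- mish(d2)
  logits <- sweep(u2 %*% p$D_W3, 2, p$D_b3, "+")
  pr <- exp(logits - apply(logits, 1, max))
  pr / rowSums(pr)
}

#' Score pre-encoded bags with a MIL model
#'
#' @param model A `mil_model`.
#' @param features_list List of n_i x d feature matrices (from
#'   [encode_instances()]).
#' @return A tibble with `score` (probability of the high-risk class) and
#'   a list-column `attention` of per-instance weights.
#' @export
predict_bags <- function(model, features_list) {
  res <- purrr::map(features_list, function(f) attention_pool(f, model))
  z <- do.call(rbind, purrr::map(res, "embedding"))
  pr <- decoder_forward(z, model, training = FALSE)
  tibble::tibble(score = pr[, 2], attention = purrr::map(res, "weights"))
}

# ---- training ----------------------------------------------------------

# forward + analytic gradients of mean cross-entropy over a batch of bags.
# Returns loss, gradient list (same names as params), and updated BN state.
mil_loss_grad <- function(model, feats, labels, training = TRUE) {
  p <- model$params
  spec <- model$spec
  bn <- model$bn
  B <- length(feats)
  use_bn <- spec$batchnorm

  att_caches <- vector("list", B)
  Z <- matrix(0, B, spec$feat_width)
  for (b in seq_len(B)) {
    X <- feats[[b]]
    s1 <- sweep(X %*% p$A_W1, 2, p$A_b1, "+")
    if (use_bn) {
      cache <- bn_forward(s1, p$A_g, p$A_be, bn$A_mu, bn$A_var, training)
      bn$A_mu <- cache$running_mu; bn$A_var <- cache$running_var
      s1n <- cache$out
    } else cache <- NULL
    h_in <- if (use_bn) s1n else s1
    H <- mish(h_in)
    logits <- drop(H %*% p$A_w2) + p$A_b2
    a <- exp(logits - max(logits)); a <- a / sum(a)
    Z[b, ] <- drop(crossprod(X, a))
    att_caches[[b]] <- list(X = X, s1 = s1, bn = cache, h_in = h_in, H = H, a = a)
  }

  d1 <- sweep(Z %*% p$D_W1, 2, p$D_b1, "+")
  if (use_bn) {
    c1 <- bn_forward(d1, p$D_g1, p$D_be1, bn$D1_mu, bn$D1_var, training)
    bn$D1_mu <- c1$running_mu; bn$D1_var <- c1$running_var
    d1n <- c1$out
  }
  u1_in <- if (use_bn) d1n else d1
  U1 <- mish(u1_in)
  d2 <- sweep(U1 %*% p$D_W2, 2, p$D_b2, "+")
  if (use_bn) {
    c2 <- bn_forward(d2, p$D_g2, p$D_be2, bn$D2_mu, bn$D2_var, training)
    bn$D2_mu <- c2$running_mu; bn$D2_var <- c2$running_var
    d2n <- c2$out
  }
  u2_in <- if (use_bn) d2n else d2
  U2 <- mish(u2_in)
  L <- sweep(U2 %*% p$D_W3, 2, p$D_b3, "+")
  Lmax <- apply(L, 1, max)
  pr <- exp(L - Lmax); pr <- pr / rowSums(pr)
  y1 <- labels + 1L
  loss <- -mean(log(pmax(pr[cbind(seq_len(B), y1)], 1e-12)))

  # ---- backward ----
  g <- purrr::map(p, function(x) x * 0)
  dL <- pr
  dL[cbind(seq_len(B), y1)] <- dL[cbind(seq_len(B), y1)] - 1
  dL <- dL / B
  g$D_W3 <- crossprod(U2, dL)
  g$D_b3 <- colSums(dL)
  dU2 <- dL %*% t(p$D_W3)
  dd2n <- dU2 * mish_grad(u2_in)
  if (use_bn) {
    bb <- bn_backward(dd2n, c2, p$D_g2)
    g$D_g2 <- bb$dg; g$D_be2 <- bb$dbe
    dd2 <- bb$dx
  } else dd2 <- dd2n
  g$D_W2 <- crossprod(U1, dd2)
  g$D_b2 <- colSums(dd2)
  dU1 <- dd2 %*% t(p$D_W2)
  dd1n <- dU1 * mish_grad(u1_in)
  if (use_bn) {
    bb <- bn_backward(dd1n, c1, p$D_g1)
    g$D_g1 <- bb$dg; g$D_be1 <- bb$dbe
    dd1 <- bb$dx
  } else dd1 <- dd1n
  g$D_W1 <- crossprod(Z, dd1)
  g$D_b1 <- colSums(dd1)
  dZ <- dd1 %*% t(p$D_W1)

  for (b in seq_len(B)) {
    cc <- att_caches[[b]]
    dz <- dZ[b, ]
    da <- drop(cc$X %*% dz)
    ds <- cc$a * (da - sum(cc$a * da))
    g$A_w2 <- g$A_w2 + drop(crossprod(cc$H, ds))
    g$A_b2 <- g$A_b2 + sum(ds)
    dH <- outer(ds, p$A_w2)
    ds1n <- dH * mish_grad(cc$h_in)
    if (use_bn) {
      bb <- bn_backward(ds1n, cc$bn, p$A_g)
      g$A_g <- g$A_g + bb$dg; g$A_be <- g$A_be + bb$dbe
      ds1 <- bb$dx
    } else ds1 <- ds1n
    g$A_W1 <- g$A_W1 + crossprod(cc$X, ds1)
    g$A_b1 <- g$A_b1 + colSums(ds1)
  }

  list(loss = loss, grads = g, bn = bn, prob = pr[, 2])
}

#' Train the attention-MIL heads on labelled bags
#'
#' Minimises binary cross-entropy with Adam over the attention and decoder
#' parameters; the encoder stays frozen. Bags are presented in shuffled
#' mini-batches; an optional `draft_fun` supplies the index set of bags to
#' use each epoch (the hook used for TMA-balanced drafting).
#'
#' @param model A `mil_model` (or a [model_spec()], which is initialised).
#' @param features_list List of n_i x d instance-feature matrices.
#' @param labels Integer/logical vector: 1/TRUE = high risk.
#' @param epochs Number of passes (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Bags per mini-batch (default 8).
#' @param draft_fun Optional `function(epoch)` returning the indices of
#'   the bags to train on that epoch; default uses all bags.
#' @param verbose Print the per-epoch loss.
#' @return The trained `mil_model`, with per-epoch mean loss in `$history`.
#' @export
train_mil <- function(model, features_list, labels, epochs = 30, lr = 1e-3,
                      batch_size = 8, draft_fun = NULL, verbose = FALSE) {
  if (inherits(model, "model_spec")) model <- init_mil_model(model)
  labels <- as.integer(as_pos(labels))
  if (length(labels) != length(features_list)) stop("labels/bags length mismatch")

  adam_m <- purrr::map(model$params, function(x) x * 0)
  adam_v <- purrr::map(model$params, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0

  for (ep in seq_len(epochs)) {
    idx <- if (is.null(draft_fun)) seq_along(features_list) else draft_fun(ep)
    if (length(unique(labels[idx])) < 2) {
      stop("epoch draft contains a single class; cannot train")
    }
    if (length(idx) > 1) idx <- sample(idx)
    ep_losses <- c()
    for (start in seq(1, length(idx), by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1, length(idx))]
      res <- mil_loss_grad(model, features_list[take], labels[take], training = TRUE)
      model$bn <- res$bn
      step <- step + 1
      for (nm in names(model$params)) {
        gr <- res$grads[[nm]]
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      ep_losses <- c(ep_losses, res$loss)
    }
    model$history <- c(model$history, mean(ep_losses))
    if (verbose) message(sprintf("epoch %d: loss %.4f", ep, mean(ep_losses)))
  }
  model
}

#' Combine per-scale scores into the ensemble risk score
#'
#' Linear ensemble on the probability scale with weights 0.25, 0.25, 0.5
#' for the scale 1.0, 0.25 and 0.5 models respectively.
#'
#' @param s1,s025,s05 Scores from the scale-1.0, scale-0.25 and scale-0.5
#'   models (vectors recycle).
#' @param weights Ensemble weights in that order (must be positive; they
#'   are used as given, not renormalized).
#' @return The combined score.
#' @export
pcai_ensemble <- function(s1, s025, s05, weights = c(0.25, 0.25, 0.5)) {
  if (length(weights) != 3 || any(weights <= 0)) stop("need 3 positive weights")
  weights[1] * s1 + weights[2] * s025 + weights[3] * s05
}

#' Score one spot image with the three-scale ensemble
#'
#' Runs preprocessing, instance creation, encoding, attention pooling and
#' decoding per scale, then combines the per-scale probabilities with the
#' ensemble weights. A spot where any scale yields no instances is marked
#' unassessable (all scores `NA`) with the reason recorded.
#'
#' @param image HxWx3 linear RGB array.
#' @param models Named list of trained `mil_model`s: `s1`, `s025`, `s05`.
#' @param scales Named list of [scale_spec()]s matching `models`.
#' @param weights Ensemble weights (scale 1.0, 0.25, 0.5).
#' @param offset Optional fixed grid offset for reproducibility.
#' @return A one-row tibble: `s_scale1`, `s_scale025`, `s_scale05`,
#'   `pcai`, `assessable`, `reason`, and a list-column `attention` of
#'   per-scale attention weights.
#' @export
predict_spot <- function(image, models, scales, weights = c(0.25, 0.25, 0.5),
                         offset = c(0L, 0L)) {
  stopifnot(all(c("s1", "s025", "s05") %in% names(models)),
            all(c("s1", "s025", "s05") %in% names(scales)))
  scores <- c(s1 = NA_real_, s025 = NA_real_, s05 = NA_real_)
  atts <- list()
  for (nm in c("s1", "s025", "s05")) {
    bag <- tryCatch(make_instances(image, scales[[nm]], offset = offset),
                    error = function(e) e)
    if (inherits(bag, "error")) {
      return(tibble::tibble(
        s_scale1 = NA_real_, s_scale025 = NA_real_, s_scale05 = NA_real_,
        pcai = NA_real_, assessable = FALSE,
        reason = paste0("scale ", nm, ": ", conditionMessage(bag)),
        attention = list(NULL)
      ))
    }
    f <- encode_instances(bag, models[[nm]])
    pred <- predict_bags(models[[nm]], list(f))
    scores[nm] <- pred$score[1]
    atts[[nm]] <- pred$attention[[1]]
  }
  tibble::tibble(
    s_scale1 = scores[["s1"]], s_scale025 = scores[["s025"]],
    s_scale05 = scores[["s05"]],
    pcai = pcai_ensemble(scores[["s1"]], scores[["s025"]], scores[["s05"]], weights),
    assessable = TRUE, reason = NA_character_, attention = list(atts)
  )
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model> %d-px patches, %d features, attention %d, decoder %s%s\n",
              x$spec$patch_px, x$spec$feat_width, x$spec$att_hidden,
              paste(x$spec$dec_hidden, collapse = "/"),
              if (length(x$history)) sprintf("; trained %d epochs (final loss %.3f)",
                                             length(x$history),
                                             x$history[length(x$history)]) else ""))
  invisible(x)
}

#' @export
glance.mil_model <- function(x, ...) {
  tibble::tibble(
    epochs = length(x$history),
    final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_,
    feat_width = x$spec$feat_width, att_hidden = x$spec$att_hidden
  )
}
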
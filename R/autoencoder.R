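#' Model configuration for the deconvolution autoencoder
#'
#' The encoder is a five-layer fully connected net with progressively
#' decreasing widths `(N, 512, 256, 128, 64, 2)`, CELU activations on the
#' hidden layers and dropout after each hidden activation during training. The
#' two latent units represent the healthy and tumor mixing fractions. The
#' decoder is a symmetric stack of five bias-free linear layers
#' `(2, 64, 128, 256, 512, N)` whose effective weight matrix, squashed through
#' a sigmoid, is the learned two-population methylation atlas.
#'
#' For small feature sets the hidden widths are capped at `n_features` so the
#' net stays well-formed; a warning is issued when `n_features < 64`.
#'
#' @param n_features number of CpG features N (model input width).
#' @param hidden_widths encoder hidden-layer widths. Default
#'   `c(512, 256, 128, 64)`.
#' @param latent_dim latent width; fixed at 2 (healthy, tumor).
#' @param dropout dropout rate on encoder hidden layers, in `[0, 1)`.
#'   Default 0.5.
#' @param lr Adam learning rate. Default 1e-4.
#' @param batch_size mini-batch size. Default 128.
#' @param epochs training epochs. Default 256.
#' @param seed integer seed controlling initialization, dropout and batch
#'   shuffling. Default 1.
#' @param loss_weights named weights for the four loss terms `comp`, `recon`,
#'   `methy_h`, `methy_t`. Default 1 each.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_features, hidden_widths = c(512, 256, 128, 64),
                         latent_dim = 2, dropout = 0.5, lr = 1e-4,
                         batch_size = 128, epochs = 256, seed = 1,
                         loss_weights = c(comp = 1, recon = 1,
                                          methy_h = 1, methy_t = 1)) {
  if (latent_dim != 2) stop2("latent_dim is fixed at 2 (healthy, tumor)")
  if (n_features < latent_dim) stop2("n_features must be >= the latent dimension")
  if (dropout < 0 || dropout >= 1) stop2("dropout must lie in [0, 1)")
  if (any(diff(hidden_widths) >= 0)) stop2("hidden_widths must be strictly decreasing")
  widths <- hidden_widths
  if (n_features < min(hidden_widths)) {
    warn2("n_features (", n_features, ") is smaller than the narrowest hidden ",
          "layer; hidden widths are capped at n_features")
    widths <- pmin(hidden_widths, n_features)
  }
  need <- c("comp", "recon", "methy_h", "methy_t")
  if (!all(need %in% names(loss_weights))) {
    stop2("loss_weights must name: ", paste(need, collapse = ", "))
  }
  structure(list(n_features = as.integer(n_features), hidden_widths = widths,
                 latent_dim = 2L, dropout = dropout, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 seed = as.integer(seed), loss_weights = loss_weights[need]),
            class = "model_config")
}

# uniform(-1/sqrt(fan_in), 1/sqrt(fan_in)) init, the standard for affine layers
init_layer <- function(n_in, n_out, bias = TRUE) {
  b <- 1 / sqrt(n_in)
  w <- matrix(stats::runif(n_in * n_out, -b, b), n_in, n_out)
  if (bias) list(w = w, b = stats::runif(n_out, -b, b)) else list(w = w)
}

#' Build an untrained deconvolution autoencoder
#'
#' @param config a [model_config()].
#' @param probe_ids optional character vector of length `n_features` naming
#'   the CpG features the model consumes (stored for alignment at prediction
#'   time).
#' @return A list of class `deconv_model` holding encoder layers (`w`, `b`),
#'   bias-free decoder layers (`w`), the config and the probe IDs.
#' @export
build_model <- function(config, probe_ids = NULL) {
  if (!inherits(config, "model_config")) stop2("config must be a model_config")
  if (is.null(probe_ids)) probe_ids <- paste0("feature_", seq_len(config$n_features))
  if (length(probe_ids) != config$n_features || anyDuplicated(probe_ids)) {
    stop2("probe_ids must be ", config$n_features, " unique names")
  }
  enc_dims <- c(config$n_features, config$hidden_widths, config$latent_dim)
  dec_dims <- c(config$latent_dim, rev(config$hidden_widths), config$n_features)
  with_seed(config$seed, {
    encoder <- lapply(seq_len(length(enc_dims) - 1), function(l) {
      init_layer(enc_dims[l], enc_dims[l + 1], bias = TRUE)
    })
    decoder <- lapply(seq_len(length(dec_dims) - 1), function(l) {
      init_layer(dec_dims[l], dec_dims[l + 1], bias = FALSE)
    })
    structure(list(encoder = encoder, decoder = decoder, config = config,
                   probe_ids = probe_ids, format_version = 1L),
              class = "deconv_model")
  })
}

celu <- function(x) ifelse(x > 0, x, exp(x) - 1)
dcelu <- function(x) ifelse(x > 0, 1, exp(x))
sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass through the encoder keeping intermediates for backprop.
# Dropout (inverted scaling) is applied only when training = TRUE; masks are
# drawn from the current RNG stream.
encoder_forward <- function(model, x, training = FALSE) {
  n_layers <- length(model$encoder)
  p <- model$config$dropout
  z <- vector("list", n_layers)
  h <- vector("list", n_layers + 1)
  masks <- vector("list", n_layers - 1)
  h[[1]] <- x
  for (l in seq_len(n_layers)) {
    lay <- model$encoder[[l]]
    z[[l]] <- sweep(h[[l]] %*% lay$w, 2, lay$b, "+")
    if (l < n_layers) {
      a <- celu(z[[l]])
      if (training && p > 0) {
        m <- matrix(stats::rbinom(length(a), 1, 1 - p), nrow(a), ncol(a)) / (1 - p)
        masks[[l]] <- m
        a <- a * m
      }
      h[[l + 1]] <- a
    } else {
      h[[l + 1]] <- z[[l]]  # raw latent, no activation
    }
  }
  list(z = z, h = h, masks = masks, latent = h[[n_layers + 1]])
}

#' Encode beta profiles to fraction latents
#'
#' Maps a batch of methylation profiles through the encoder. At inference a
#' ReLU clamps the latent to non-negative fractions and dropout is inactive,
#' so repeated calls are identical; with `inference = FALSE` the raw
#' (unclamped, dropout-free) latent used by the composition loss is returned.
#'
#' @param model a [build_model()] or [train_deconv()] result.
#' @param x batch-by-features numeric matrix of beta-values in `[0, 1]`.
#' @param inference apply the inference-time ReLU. Default TRUE.
#' @return batch-by-2 latent matrix (columns healthy, tumor).
#' @export
encode <- function(model, x, inference = TRUE) {
  if (!inherits(model, "deconv_model")) stop2("model must be a deconv_model")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$config$n_features) {
    stop2("x has ", ncol(x), " features but the model expects ",
          model$config$n_features)
  }
  latent <- encoder_forward(model, x, training = FALSE)$latent
  if (inference) latent <- pmax(latent, 0)
  colnames(latent) <- c("healthy", "tumor")
  latent
}

# product of the bias-free decoder weights: latent_dim x n_features
decoder_effective <- function(model) {
  Reduce(`%*%`, lapply(model$decoder, `[[`, "w"))
}

#' Extract the learned methylation atlas
#'
#' The effective decoder matrix (product of the five bias-free layers),
#' squashed elementwise through a sigmoid so every entry is a valid beta-value
#' in `(0, 1)`, read as an `n_features`-by-2 atlas whose columns are the
#' healthy-plasma and tumor-tissue methylation profiles the model has learned.
#'
#' @param model a `deconv_model`.
#' @return Numeric matrix (probes by 2, columns `healthy`, `tumor`, rownames
#'   the model's probe IDs) with entries strictly in `(0, 1)`.
#' @export
effective_atlas <- function(model) {
  if (!inherits(model, "deconv_model")) stop2("model must be a deconv_model")
  a <- t(sigmoid(decoder_effective(model)))
  dimnames(a) <- list(model$probe_ids, c("healthy", "tumor"))
  a
}

#' Reconstruct beta profiles from fraction vectors
#'
#' Linear mixing through the learned atlas: `x_hat = fractions %*% t(atlas)`.
#' Pure fractions `(1, 0)` / `(0, 1)` reproduce the corresponding atlas column.
#'
#' @param model a `deconv_model`.
#' @param fractions batch-by-2 non-negative matrix (healthy, tumor).
#' @return batch-by-features reconstruction.
#' @export
reconstruct <- function(model, fractions) {
  if (!is.matrix(fractions)) fractions <- matrix(fractions, nrow = 1)
  if (ncol(fractions) != 2) stop2("fractions must have two columns (healthy, tumor)")
  if (min(fractions) < 0) stop2("fractions must be non-negative")
  fractions %*% t(effective_atlas(model))
}

# Per-probe population means of a tumor_/plasma_ reference matrix, as the
# n_features x 2 target for the methylation likelihood losses.
reference_means <- function(ref, probe_ids) {
  check_matrix(ref, "ref", range = c(0, 1))
  if (anyNA(ref)) stop2("reference matrix must not contain missing values")
  missing <- setdiff(probe_ids, rownames(ref))
  if (length(missing)) {
    stop2("reference is missing model probes: ",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) paste0(" ... (", length(missing), " total)"))
  }
  ref <- ref[probe_ids, , drop = FALSE]
  tumor_cols <- grep("tumor", colnames(ref))
  plasma_cols <- grep("plasma", colnames(ref))
  if (length(tumor_cols) == 0 || length(plasma_cols) == 0) {
    stop2("reference columns must carry 'tumor' and 'plasma' prefixes")
  }
  cbind(healthy = rowMeans(ref[, plasma_cols, drop = FALSE]),
        tumor = rowMeans(ref[, tumor_cols, drop = FALSE]))
}

#' Evaluate the four training loss terms
#'
#' `comp` is the mean absolute error between the raw latent and the fraction
#' labels; `recon` the mean absolute error between the input and its
#' atlas-mixed reconstruction; `methy_h`/`methy_t` the per-probe Bernoulli
#' negative log-likelihood of the healthy / tumor reference mean profile under
#' the corresponding atlas column. Reference means at exactly 0 or 1 are
#' clipped to `[1e-6, 1 - 1e-6]` (warned once).
#'
#' @param model a `deconv_model`.
#' @param x batch-by-features beta matrix.
#' @param y batch-by-2 fraction labels (healthy, tumor).
#' @param ref_means features-by-2 matrix of per-probe population mean
#'   beta-values (columns healthy, tumor), aligned with the model features.
#' @return Named numeric vector `comp`, `recon`, `methy_h`, `methy_t`,
#'   `total` (weighted by the config's `loss_weights`).
#' @export
loss_components <- function(model, x, y, ref_means) {
  latent <- encode(model, x, inference = FALSE)
  atlas_t <- sigmoid(decoder_effective(model))  # 2 x N, rows healthy/tumor
  xhat <- latent %*% atlas_t
  r <- clip_ref_means(ref_means, model$config$n_features)
  w <- model$config$loss_weights
  comp <- mean(abs(latent - y))
  recon <- mean(abs(x - xhat))
  methy_h <- bernoulli_nll(atlas_t[1, ], r[, 1])
  methy_t <- bernoulli_nll(atlas_t[2, ], r[, 2])
  total <- w["comp"] * comp + w["recon"] * recon +
    w["methy_h"] * methy_h + w["methy_t"] * methy_t
  c(comp = comp, recon = recon, methy_h = methy_h, methy_t = methy_t,
    total = unname(total))
}

bernoulli_nll <- function(a, r) {
  -mean(r * log(a) + (1 - r) * log(1 - a))
}

clip_ref_means <- function(ref_means, n_features, eps = 1e-6) {
  if (!is.matrix(ref_means) || ncol(ref_means) != 2 || nrow(ref_means) != n_features) {
    stop2("ref_means must be an n_features-by-2 matrix (healthy, tumor)")
  }
  if (any(ref_means <= 0 | ref_means >= 1)) {
    warn2("reference means at 0/1 clipped to [1e-6, 1 - 1e-6] for the likelihood")
  }
  pmin(pmax(ref_means, eps), 1 - eps)
}

# flatten model parameters into a single list for the Adam state
param_list <- function(model) {
  ps <- list()
  for (l in seq_along(model$encoder)) {
    ps[[paste0("enc_w", l)]] <- model$encoder[[l]]$w
    ps[[paste0("enc_b", l)]] <- model$encoder[[l]]$b
  }
  for (l in seq_along(model$decoder)) {
    ps[[paste0("dec_w", l)]] <- model$decoder[[l]]$w
  }
  ps
}

set_params <- function(model, ps) {
  for (l in seq_along(model$encoder)) {
    model$encoder[[l]]$w <- ps[[paste0("enc_w", l)]]
    model$encoder[[l]]$b <- ps[[paste0("enc_b", l)]]
  }
  for (l in seq_along(model$decoder)) {
    model$decoder[[l]]$w <- ps[[paste0("dec_w", l)]]
  }
  model
}

# one training batch: forward, four-term loss, full backprop.
# Returns gradients (same shape list as param_list) and the loss terms.
batch_gradients <- function(model, x, y, r_clip) {
  w <- model$config$loss_weights
  B <- nrow(x)
  N <- model$config$n_features
  fw <- encoder_forward(model, x, training = TRUE)
  latent <- fw$latent                       # B x 2
  dec_w <- lapply(model$decoder, `[[`, "w")
  n_dec <- length(dec_w)
  prefix <- vector("list", n_dec)           # product of layers before l (2 x in_l)
  prefix[[1]] <- diag(2)
  for (l in 2:n_dec) prefix[[l]] <- prefix[[l - 1]] %*% dec_w[[l - 1]]
  M <- prefix[[n_dec]] %*% dec_w[[n_dec]]   # 2 x N effective matrix
  P <- sigmoid(M)
  xhat <- latent %*% P

  comp <- mean(abs(latent - y))
  recon <- mean(abs(x - xhat))
  methy_h <- bernoulli_nll(P[1, ], r_clip[, 1])
  methy_t <- bernoulli_nll(P[2, ], r_clip[, 2])
  losses <- c(comp = comp, recon = recon, methy_h = methy_h, methy_t = methy_t)
  bad <- names(losses)[!is.finite(losses)]
  if (length(bad)) {
    stop2("non-finite training loss in term(s): ", paste(bad, collapse = ", "))
  }

  # gradients of the weighted total
  g_xhat <- w[["recon"]] * sign(xhat - x) / (B * N)          # B x N
  g_latent <- w[["comp"]] * sign(latent - y) / (B * 2) +
    g_xhat %*% t(P)                                          # B x 2
  g_P <- t(latent) %*% g_xhat                                # 2 x N
  g_P[1, ] <- g_P[1, ] + w[["methy_h"]] * (P[1, ] - r_clip[, 1]) /
    (P[1, ] * (1 - P[1, ]) * N)
  g_P[2, ] <- g_P[2, ] + w[["methy_t"]] * (P[2, ] - r_clip[, 2]) /
    (P[2, ] * (1 - P[2, ]) * N)
  g_M <- g_P * P * (1 - P)

  grads <- list()
  # decoder: dV_l = prefix_l' %*% g_M %*% suffix_l', suffix_l = V_{l+1}...V_n
  suffix <- NULL  # identity for the last layer
  for (l in n_dec:1) {
    gms <- if (is.null(suffix)) g_M else g_M %*% t(suffix)
    grads[[paste0("dec_w", l)]] <- t(prefix[[l]]) %*% gms
    suffix <- if (is.null(suffix)) dec_w[[l]] else dec_w[[l]] %*% suffix
  }
  # encoder backprop
  g <- g_latent
  for (l in length(model$encoder):1) {
    grads[[paste0("enc_w", l)]] <- t(fw$h[[l]]) %*% g
    grads[[paste0("enc_b", l)]] <- colSums(g)
    if (l > 1) {
      g <- g %*% t(model$encoder[[l]]$w)
      if (!is.null(fw$masks[[l - 1]])) g <- g * fw$masks[[l - 1]]
      g <- g * dcelu(fw$z[[l - 1]])
    }
  }
  list(grads = grads, losses = losses)
}

#' Train the deconvolution autoencoder
#'
#' Optimizes the four-term loss (composition MAE, reconstruction MAE, and the
#' healthy/tumor atlas likelihoods) with Adam over shuffled mini-batches.
#' Initialization, dropout and shuffling are all driven by `config$seed`, so
#' training is reproducible end to end on one machine.
#'
#' @param train_x samples-by-probes beta matrix (e.g.
#'   [generate_simulated_data()]'s `x`).
#' @param train_y samples-by-2 fraction labels (healthy, tumor).
#' @param ref probe-by-sample reference matrix with `tumor_*`/`plasma_*`
#'   columns (or a path to one); its per-population probe means anchor the
#'   methylation likelihood losses.
#' @param config a [model_config()]; `n_features` must equal `ncol(train_x)`.
#' @return The trained `deconv_model`, with a `loss_trace` element: an
#'   epochs-by-5 matrix of batch-averaged loss terms per epoch.
#' @export
train_deconv <- function(train_x, train_y, ref, config) {
  if (is.character(ref) && length(ref) == 1) ref <- read_matrix(ref)
  if (!is.matrix(train_x) || !is.matrix(train_y)) {
    stop2("train_x and train_y must be matrices")
  }
  if (nrow(train_x) != nrow(train_y) || ncol(train_y) != 2) {
    stop2("train_y must be an nrow(train_x)-by-2 fraction matrix")
  }
  if (ncol(train_x) != config$n_features) {
    stop2("config$n_features (", config$n_features, ") must equal ncol(train_x) (",
          ncol(train_x), ")")
  }
  probe_ids <- colnames(train_x)
  if (is.null(probe_ids)) stop2("train_x needs probe IDs as column names")
  r_clip <- clip_ref_means(reference_means(ref, probe_ids), config$n_features)

  model <- build_model(config, probe_ids = probe_ids)
  ps <- param_list(model)
  m1 <- lapply(ps, function(p) p * 0)
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  n <- nrow(train_x)
  n_batches <- ceiling(n / config$batch_size)
  trace <- matrix(NA_real_, config$epochs, 5,
                  dimnames = list(NULL, c("comp", "recon", "methy_h", "methy_t", "total")))
  w <- config$loss_weights

  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      epoch_losses <- numeric(4)
      for (bi in seq_len(n_batches)) {
        rows <- idx[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
        model_tmp <- set_params(model, ps)
        bg <- batch_gradients(model_tmp, train_x[rows, , drop = FALSE],
                              train_y[rows, , drop = FALSE], r_clip)
        epoch_losses <- epoch_losses + bg$losses / n_batches
        step <- step + 1L
        for (nm in names(ps)) {
          g <- bg$grads[[nm]]
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g * g
          mhat <- m1[[nm]] / (1 - b1^step)
          vhat <- m2[[nm]] / (1 - b2^step)
          ps[[nm]] <- ps[[nm]] - config$lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      trace[epoch, ] <- c(epoch_losses,
                          sum(epoch_losses * w[c("comp", "recon", "methy_h", "methy_t")]))
    }
  })
  model <- set_params(model, ps)
  model$loss_trace <- trace
  model$ref_means <- r_clip
  model
}

#' Predict healthy and tumor fractions for cfDNA samples
#'
#' Runs inference-mode encoding (ReLU-clamped latent) on a probe-by-sample
#' beta matrix. Probes are aligned to the model's training features by name;
#' missing probes raise an error. By default fractions are renormalized to sum
#' to one; a sample whose raw fractions are both zero is reported as fully
#' healthy with a warning.
#'
#' @param model a trained `deconv_model`.
#' @param x probe-by-sample beta matrix covering all model probes.
#' @param normalize renormalize fractions to sum to 1. Default TRUE.
#' @return data.frame with columns `sample_id`, `healthy_fraction`,
#'   `tumor_fraction`.
#' @export
predict_fractions <- function(model, x, normalize = TRUE) {
  check_matrix(x, "x", range = c(0, 1))
  missing <- setdiff(model$probe_ids, rownames(x))
  if (length(missing)) {
    stop2("input is missing model probes: ",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) paste0(" ... (", length(missing), " total)"))
  }
  if (anyNA(x[model$probe_ids, ])) stop2("input contains missing values on model probes")
  latent <- encode(model, t(x[model$probe_ids, , drop = FALSE]), inference = TRUE)
  if (normalize) {
    tot <- rowSums(latent)
    zero <- tot == 0
    if (any(zero)) {
      warn2(sum(zero), " sample(s) had zero raw fractions; reported as fully healthy")
      latent[zero, 1] <- 1
      latent[zero, 2] <- 0
      tot[zero] <- 1
    }
    latent <- latent / tot
  }
  data.frame(sample_id = colnames(x), healthy_fraction = latent[, 1],
             tumor_fraction = latent[, 2], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Save a deconvolution model
#'
#' Serializes parameters, config and probe list; [load_model()] restores them
#' bit-exactly.
#'
#' @param model a `deconv_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "deconv_model")) stop2("model must be a deconv_model")
  saveRDS(model, path)
  invisible(path)
}

#' Load a deconvolution model saved by [save_model()]
#'
#' @param path file path.
#' @return The `deconv_model`.
#' @export
load_model <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop2("not a readable model file (", conditionMessage(e), "): ", path)
  })
  if (!inherits(model, "deconv_model") || is.null(model$format_version)) {
    stop2("file is not a saved deconv_model: ", path)
  }
  if (model$format_version != 1L) {
    stop2("unsupported model format version ", model$format_version,
          " (this build reads version 1)")
  }
  model
}
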
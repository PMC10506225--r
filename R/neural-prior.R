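#' Initialize prior-network parameters
#'
#' Creates the parameters of the map from a gene's feature vector to the
#' beta prior of its relative LOF rate. Two variants exist: a linear map
#' (`hidden_units = NULL`), where `mu = logistic(w_m' x + b_m)` and
#' `kappa = exp(w_k' x + b_k)`, and a one-hidden-layer network with ReLU
#' activation and dropout, where the same two heads read a hidden vector
#' `z = Dropout(ReLU(W_h' x + b_h))` instead of `x`.
#'
#' Weights are drawn Glorot-uniform, biases start at zero, so an
#' uninformative prior (`mu` near 0.5, `kappa` near 1) is the starting
#' point for centered features.
#'
#' @param n_features number of input features F (0 gives the intercept-only
#'   "flat" model with a shared prior across genes).
#' @param hidden_units NULL for the linear variant, otherwise the hidden
#'   width H of the nonlinear variant.
#' @param dropout_rate dropout probability applied after the ReLU during
#'   training (inverted-dropout scaling, so inference needs no rescale).
#' @param feature_names optional names for the F inputs.
#' @param seed RNG seed for the weight draw.
#' @return an object of class `deeplof_params`.
#' @export
init_prior_params <- function(n_features, hidden_units = NULL,
                              dropout_rate = 0.5, feature_names = NULL,
                              seed = 1L) {
  if (!is.numeric(n_features) || n_features < 0 ||
      n_features != floor(n_features)) {
    stop_domain("`n_features` must be a nonnegative integer")
  }
  F <- as.integer(n_features)
  if (!is.null(feature_names) && length(feature_names) != F) {
    stop_domain("`feature_names` must have length `n_features`")
  }
  glorot <- function(fan_in, fan_out, nr, nc) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  local_seed(seed, {
    if (is.null(hidden_units)) {
      p <- list(
        variant = "linear",
        w_m = drop(glorot(F, 1, max(F, 1L), 1))[seq_len(F)],
        b_m = 0,
        w_k = drop(glorot(F, 1, max(F, 1L), 1))[seq_len(F)],
        b_k = 0,
        dropout_rate = 0
      )
    } else {
      if (!is.numeric(hidden_units) || hidden_units < 1 ||
          hidden_units != floor(hidden_units)) {
        stop_domain("`hidden_units` must be a positive integer")
      }
      if (dropout_rate < 0 || dropout_rate >= 1) {
        stop_domain("`dropout_rate` must be in [0, 1)")
      }
      H <- as.integer(hidden_units)
      p <- list(
        variant = "nonlinear",
        W_h = glorot(F, H, F, H),
        b_h = numeric(H),
        w_m = drop(glorot(H, 1, H, 1)),
        b_m = 0,
        w_k = drop(glorot(H, 1, H, 1)),
        b_k = 0,
        dropout_rate = dropout_rate
      )
    }
    p$feature_names <- feature_names
    structure(p, class = "deeplof_params")
  })
}

as_feature_matrix <- function(x, F) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != F) {
    stop_domain(sprintf("feature matrix has %d column(s); parameters expect %d",
                        ncol(x), F))
  }
  x
}

# Forward pass retaining intermediates needed for backpropagation.
prior_forward_full <- function(params, x, training = FALSE, seed = NULL) {
  if (!inherits(params, "deeplof_params")) {
    stop_domain("`params` must be created with init_prior_params()")
  }
  if (params$variant == "linear") {
    x <- as_feature_matrix(x, length(params$w_m))
    z <- x
    mask <- NULL
    pre <- NULL
  } else {
    x <- as_feature_matrix(x, nrow(params$W_h))
    pre <- sweep(x %*% params$W_h, 2L, params$b_h, "+")
    z <- pmax(pre, 0)
    mask <- NULL
    if (training && params$dropout_rate > 0) {
      draw <- function() {
        matrix(stats::rbinom(length(z), 1L, 1 - params$dropout_rate),
               nrow(z), ncol(z)) / (1 - params$dropout_rate)
      }
      mask <- if (is.null(seed)) draw() else local_seed(seed, draw())
      z <- z * mask
    }
  }
  a <- drop(z %*% params$w_m) + params$b_m
  c_ <- drop(z %*% params$w_k) + params$b_k
  # clamp pre-link activations so mu and kappa stay representable
  a <- pmin(pmax(a, -30), 30)
  c_ <- pmin(pmax(c_, -30), 30)
  list(mu = stats::plogis(a), kappa = exp(c_), a = a, c = c_,
       z = z, pre = pre, mask = mask, x = x)
}

#' Map features to beta prior parameters
#'
#' Applies the fitted (or freshly initialized) prior network to a feature
#' matrix. With `training = FALSE` the forward pass is deterministic; with
#' `training = TRUE` the nonlinear variant applies seeded inverted dropout.
#'
#' @param params a `deeplof_params` object.
#' @param x feature matrix (genes in rows) or a single feature vector.
#' @param training apply dropout (nonlinear variant only)?
#' @param seed RNG seed for the dropout mask; required for reproducible
#'   training-mode output.
#' @return a data.frame with columns `mu` and `kappa`, one row per gene.
#' @export
prior_forward <- function(params, x, training = FALSE, seed = NULL) {
  fw <- prior_forward_full(params, x, training = training, seed = seed)
  data.frame(mu = fw$mu, kappa = fw$kappa)
}

#' @rdname prior_forward
#' @details `linear_prior_forward()` and `nonlinear_prior_forward()` are
#'   variant-checked wrappers around `prior_forward()`.
#' @export
linear_prior_forward <- function(params, x) {
  if (params$variant != "linear") stop_domain("`params` is not a linear model")
  prior_forward(params, x)
}

#' @rdname prior_forward
#' @export
nonlinear_prior_forward <- function(params, x, training = FALSE, seed = NULL) {
  if (params$variant != "nonlinear") {
    stop_domain("`params` is not a nonlinear model")
  }
  prior_forward(params, x, training = training, seed = seed)
}

#' Per-feature contribution scores of a linear model
#'
#' The contribution score of feature j is minus its fitted weight on the
#' prior-mean head. A positive score means the feature is associated with
#' LOF intolerance (it pushes the prior mean relative LOF rate down).
#' Contributions are defined only for the linear variant.
#'
#' @param params a fitted linear `deeplof_params` object.
#' @return named numeric vector of length F.
#' @export
contribution_scores <- function(params) {
  if (!inherits(params, "deeplof_params")) {
    stop_domain("`params` must be created with init_prior_params()")
  }
  if (params$variant != "linear") {
    stop_domain("contribution scores are defined only for the linear model")
  }
  s <- -params$w_m
  names(s) <- params$feature_names %||%
    paste0("feature_", seq_along(params$w_m))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save or load prior-network parameters
#'
#' Parameters are serialized as a flat name-to-array JSON archive (matrices
#' carry their dimensions), so checkpoints are plain text and portable.
#'
#' @param params a `deeplof_params` object.
#' @param path file path.
#' @return `read_checkpoint()` returns the restored `deeplof_params`.
#' @export
write_checkpoint <- function(params, path) {
  if (!inherits(params, "deeplof_params")) {
    stop_domain("`params` must be created with init_prior_params()")
  }
  flat <- lapply(unclass(params), function(v) {
    if (is.matrix(v)) list(dim = dim(v), data = as.vector(v)) else v
  })
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  flat <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(flat, function(v) {
    if (is.list(v) && !is.null(v$dim)) matrix(v$data, v$dim[1], v$dim[2])
    else v
  })
  if (length(p$feature_names) == 0L) p$feature_names <- NULL
  for (nm in c("w_m", "w_k", "b_h")) {
    if (!is.null(p[[nm]])) p[[nm]] <- as.numeric(p[[nm]])
  }
  structure(p, class = "deeplof_params")
}
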
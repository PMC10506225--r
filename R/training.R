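#' Bundle gene counts and features for model fitting
#'
#' @param gene_id character vector of gene identifiers.
#' @param y observed LOF counts (nonnegative integers).
#' @param n expected LOF counts under neutrality (positive).
#' @param x numeric feature matrix with one row per gene (G x F); use a
#'   zero-column matrix for the flat, feature-free model.
#' @return object of class `deeplof_data`.
#' @export
deeplof_data <- function(gene_id, y, n, x = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop_domain("duplicate gene_id")
  assert_count_vector(y)
  assert_positive(n, "n")
  G <- length(gene_id)
  if (length(y) != G || length(n) != G) {
    stop_domain("gene_id, y and n must have equal length")
  }
  if (is.null(x)) x <- matrix(numeric(0), G, 0)
  x <- as.matrix(x)
  if (nrow(x) != G) stop_domain("feature matrix row count must match genes")
  if (any(!is.finite(x))) stop_domain("feature matrix contains non-finite values")
  structure(list(gene_id = gene_id, y = as.numeric(y), n = as.numeric(n),
                 x = x),
            class = "deeplof_data")
}

subset_data <- function(data, idx) {
  deeplof_data(data$gene_id[idx], data$y[idx], data$n[idx],
               data$x[idx, , drop = FALSE])
}

#' Training configuration
#'
#' @param variant `"linear"`, `"nonlinear"`, or `"flat"` (intercept-only
#'   shared prior; implemented as the linear variant on zero features).
#' @param learning_rate Adam step size.
#' @param l2_penalty coefficient of the squared-weight penalty (weights
#'   only; biases are never penalized).
#' @param hidden_units hidden width for the nonlinear variant.
#' @param dropout_rate dropout probability after the ReLU (nonlinear only).
#' @param batch_size mini-batch size.
#' @param max_epochs hard cap on epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param grid_K quadrature resolution used during fitting.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(variant = c("linear", "nonlinear", "flat"),
                         learning_rate = 1e-3, l2_penalty = 0,
                         hidden_units = 64L, dropout_rate = 0.5,
                         batch_size = 64L, max_epochs = 1000L,
                         patience = 10L, grid_K = 4096L, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(learning_rate > 0, l2_penalty >= 0, batch_size >= 1,
            patience >= 1, max_epochs >= 1)
  structure(list(variant = variant, learning_rate = learning_rate,
                 l2_penalty = l2_penalty,
                 hidden_units = as.integer(hidden_units),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 grid_K = as.integer(grid_K), seed = as.integer(seed)),
            class = "train_config")
}

#' Split genes into training and validation sets
#'
#' Seeded random partition. The training size is `round(G * train_fraction)`
#' (round-half-even, R's default rounding), the validation set takes the
#' remainder.
#'
#' @param data a `deeplof_data` object.
#' @param train_fraction fraction of genes assigned to training.
#' @param seed RNG seed.
#' @return list with elements `train` and `validation` (`deeplof_data`).
#' @export
split_train_validation <- function(data, train_fraction = 0.8, seed = 1L) {
  if (!inherits(data, "deeplof_data")) stop_domain("`data` must be deeplof_data")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_domain("`train_fraction` must be in (0, 1)")
  }
  G <- length(data$gene_id)
  if (G < 2L) stop_domain("need at least 2 genes to split")
  n_train <- round(G * train_fraction)
  n_train <- min(max(n_train, 1L), G - 1L)
  perm <- local_seed(seed, sample.int(G))
  list(train = subset_data(data, sort(perm[seq_len(n_train)])),
       validation = subset_data(data, sort(perm[(n_train + 1L):G])))
}

# --- gradient machinery -----------------------------------------------------

# Gradients of the mean negative log marginal likelihood with respect to the
# pre-link activations a (logit of mu) and c (log of kappa), obtained from
# posterior expectations of log(eta) and log(1 - eta): differentiating the
# log beta density in its shape parameters yields digamma terms, and
# differentiating through the fixed midpoint grid makes this exact for the
# discretized objective.
activation_grads <- function(q, mu, kappa) {
  a <- q$a
  b <- q$b
  dlda <- q$post_mean_log - digamma(a) + digamma(a + b)    # d logm / d alpha
  dldb <- q$post_mean_log1m - digamma(b) + digamma(a + b)  # d logm / d beta
  B <- length(a)
  ga <- -(kappa * mu * (1 - mu) * (dlda - dldb)) / B
  gc <- -(a * dlda + b * dldb) / B
  list(ga = ga, gc = gc)
}

# Full loss gradient for one mini-batch; returns loss (data term only) and
# gradients for every parameter array, including the L2 term on weights.
loss_and_grads <- function(params, batch, grid, l2 = 0, training = FALSE,
                           dropout_seed = NULL) {
  fw <- prior_forward_full(params, batch$x, training = training,
                           seed = dropout_seed)
  q <- posterior_quantities(batch$y, batch$n, fw$mu, fw$kappa, grid)
  g <- activation_grads(q, fw$mu, fw$kappa)
  grads <- list()
  if (params$variant == "linear") {
    grads$w_m <- drop(crossprod(fw$z, g$ga)) + 2 * l2 * params$w_m
    grads$w_k <- drop(crossprod(fw$z, g$gc)) + 2 * l2 * params$w_k
    grads$b_m <- sum(g$ga)
    grads$b_k <- sum(g$gc)
  } else {
    gz <- tcrossprod(g$ga, params$w_m) + tcrossprod(g$gc, params$w_k)
    act <- (fw$pre > 0) * 1
    scale <- if (is.null(fw$mask)) act else act * fw$mask
    gpre <- gz * scale
    grads$W_h <- crossprod(fw$x, gpre) + 2 * l2 * params$W_h
    grads$b_h <- colSums(gpre)
    grads$w_m <- drop(crossprod(fw$z, g$ga)) + 2 * l2 * params$w_m
    grads$w_k <- drop(crossprod(fw$z, g$gc)) + 2 * l2 * params$w_k
    grads$b_m <- sum(g$ga)
    grads$b_k <- sum(g$gc)
  }
  list(loss = -mean(q$log_marginal), grads = grads)
}

penalized_loss <- function(params, data, grid, l2) {
  fw <- prior_forward_full(params, data$x, training = FALSE)
  q <- posterior_quantities(data$y, data$n, fw$mu, fw$kappa, grid)
  w2 <- sum(params$w_m^2) + sum(params$w_k^2) +
    if (params$variant == "nonlinear") sum(params$W_h^2) else 0
  -mean(q$log_marginal) + l2 * w2
}

data_loss <- function(params, data, grid) {
  fw <- prior_forward_full(params, data$x, training = FALSE)
  batch_loss(data$y, data$n, fw$mu, fw$kappa, grid)
}

adam_init <- function(params, trainable) {
  st <- lapply(trainable, function(nm) {
    list(m = params[[nm]] * 0, v = params[[nm]] * 0)
  })
  names(st) <- trainable
  st
}

adam_step <- function(params, grads, state, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(state)) {
    g <- grads[[nm]]
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * g
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * g^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Fit a DeepLOF model
#'
#' Minimizes the mean negative log marginal likelihood (plus an L2 penalty
#' on weights) with mini-batch Adam. Mini-batches are reshuffled every epoch
#' with a seeded RNG; after each epoch the unpenalized data loss is
#' evaluated on the full training and validation sets, and optimization
#' stops once the validation loss has not improved for `patience` epochs.
#' The returned parameters are the snapshot from the best-validation epoch.
#'
#' @param train,validation `deeplof_data` objects with identical feature
#'   columns.
#' @param config a [train_config()].
#' @return object of class `deeplof_fit`: `params`, `train_loss_history`,
#'   `val_loss_history`, `best_epoch`, `best_val_loss`, `config`.
#' @export
train_model <- function(train, validation, config = train_config()) {
  if (!inherits(train, "deeplof_data") ||
      !inherits(validation, "deeplof_data")) {
    stop_domain("`train` and `validation` must be deeplof_data")
  }
  if (ncol(train$x) != ncol(validation$x)) {
    stop_domain("train and validation feature counts differ")
  }
  F <- ncol(train$x)
  grid <- make_quadrature_grid(config$grid_K)
  feature_names <- colnames(train$x)
  params <- switch(config$variant,
    flat = init_prior_params(0L, seed = config$seed),
    linear = init_prior_params(F, feature_names = feature_names,
                               seed = config$seed),
    nonlinear = init_prior_params(F, hidden_units = config$hidden_units,
                                  dropout_rate = config$dropout_rate,
                                  feature_names = feature_names,
                                  seed = config$seed)
  )
  if (config$variant == "flat" && F > 0) {
    train <- deeplof_data(train$gene_id, train$y, train$n)
    validation <- deeplof_data(validation$gene_id, validation$y, validation$n)
  }
  trainable <- if (params$variant == "nonlinear") {
    c("W_h", "b_h", "w_m", "b_m", "w_k", "b_k")
  } else if (length(params$w_m) > 0) {
    c("w_m", "b_m", "w_k", "b_k")
  } else {
    c("b_m", "b_k")
  }
  state <- adam_init(params, trainable)
  G <- length(train$gene_id)
  n_batches <- ceiling(G / config$batch_size)

  train_hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf
  best_epoch <- 0L
  best_params <- params
  stall <- 0L
  t_step <- 0L

  local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(G)
      for (bi in seq_len(n_batches)) {
        idx <- perm[((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, G)]
        batch <- list(x = train$x[idx, , drop = FALSE],
                      y = train$y[idx], n = train$n[idx])
        lg <- loss_and_grads(params, batch, grid, l2 = config$l2_penalty,
                             training = TRUE)
        if (!is.finite(lg$loss)) {
          stop_domain(sprintf("training diverged at epoch %d", epoch))
        }
        t_step <- t_step + 1L
        upd <- adam_step(params, lg$grads, state, t_step,
                         config$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      tr_loss <- data_loss(params, train, grid)
      va_loss <- data_loss(params, validation, grid)
      if (!is.finite(tr_loss) || !is.finite(va_loss)) {
        stop_domain(sprintf("non-finite loss at epoch %d", epoch))
      }
      train_hist <- c(train_hist, tr_loss)
      val_hist <- c(val_hist, va_loss)
      if (va_loss < best_val) {
        best_val <- va_loss
        best_epoch <- epoch
        best_params <- params
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  structure(list(params = best_params,
                 train_loss_history = train_hist,
                 val_loss_history = val_hist,
                 best_epoch = best_epoch,
                 best_val_loss = best_val,
                 config = config),
            class = "deeplof_fit")
}

#' Hyperparameter grid search
#'
#' Exhaustive sweep over the Cartesian product of candidate L2 penalties,
#' learning rates and (for the nonlinear variant) hidden widths; the winner
#' has the lowest best validation loss. Ties are broken toward the smaller
#' hidden width, then the larger L2 penalty, then declaration order.
#'
#' @inheritParams train_model
#' @param l2_grid,lr_grid,hidden_grid candidate values. `hidden_grid` is
#'   ignored for linear/flat variants.
#' @param base_config settings shared by every fit.
#' @return list with `best_config`, `best_fit`, and a summary data.frame
#'   `results` (one row per grid cell).
#' @export
grid_search <- function(train, validation, base_config = train_config(),
                        l2_grid = c(0, 1e-2, 1e-3, 1e-4, 1e-5, 1e-6),
                        lr_grid = c(1e-3, 1e-4, 1e-5),
                        hidden_grid = c(64L, 128L, 256L, 512L, 1024L)) {
  if (length(l2_grid) == 0L || length(lr_grid) == 0L) {
    stop_domain("hyperparameter grids must be nonempty")
  }
  if (base_config$variant != "nonlinear") hidden_grid <- NA_integer_
  if (length(hidden_grid) == 0L) stop_domain("hidden grid must be nonempty")
  cells <- expand.grid(l2 = l2_grid, lr = lr_grid, hidden = hidden_grid,
                       KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_cfg <- NULL
  res <- cells
  res$best_val_loss <- NA_real_
  res$best_epoch <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    cfg <- base_config
    cfg$l2_penalty <- cells$l2[i]
    cfg$learning_rate <- cells$lr[i]
    if (!is.na(cells$hidden[i])) cfg$hidden_units <- as.integer(cells$hidden[i])
    fit <- train_model(train, validation, cfg)
    res$best_val_loss[i] <- fit$best_val_loss
    res$best_epoch[i] <- fit$best_epoch
    better <- is.null(best) ||
      fit$best_val_loss < best$best_val_loss ||
      (fit$best_val_loss == best$best_val_loss && !is.na(cells$hidden[i]) &&
         (cells$hidden[i] < best_cfg$hidden_units ||
            (cells$hidden[i] == best_cfg$hidden_units &&
               cells$l2[i] > best_cfg$l2_penalty)))
    if (better) {
      best <- fit
      best_cfg <- cfg
    }
  }
  list(best_config = best_cfg, best_fit = best, results = res)
}

#' Score genes with a fitted model
#'
#' Deterministic prediction pass: the prior network (dropout disabled) maps
#' features to beta prior parameters, the posterior mean relative LOF rate
#' is computed by midpoint quadrature, and the score is one minus that mean.
#'
#' @param data a `deeplof_data` object.
#' @param params fitted `deeplof_params`.
#' @param grid quadrature grid for the posterior integrals.
#' @return data.frame with `gene_id`, `posterior_mean_eta`, `deeplof_score`.
#' @export
score_genes <- function(data, params, grid = make_quadrature_grid()) {
  if (!inherits(data, "deeplof_data")) stop_domain("`data` must be deeplof_data")
  x <- data$x
  if (params$variant == "linear" && length(params$w_m) == 0L) {
    x <- matrix(numeric(0), length(data$gene_id), 0)
  }
  pr <- prior_forward(params, x, training = FALSE)
  pm <- posterior_mean(data$y, data$n, pr$mu, pr$kappa, grid)
  bad <- !is.finite(pm)
  if (any(bad)) {
    stop_domain("non-finite score for gene(s): ",
                paste(utils::head(data$gene_id[bad], 5), collapse = ", "))
  }
  data.frame(gene_id = data$gene_id,
             posterior_mean_eta = pm,
             deeplof_score = deeplof_score(pm),
             stringsAsFactors = FALSE)
}
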
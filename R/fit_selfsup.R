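#' Training configuration for the self-supervised fit
#'
#' Defaults follow the renal fitting setup: a fully connected network with
#' three hidden layers whose width equals the number of image volumes,
#' learning rate 1e-4 (Adam), dropout p = 0.5 on the hidden layers during
#' training, and early stopping on the training loss.
#'
#' @param hidden_layers number of hidden layers.
#' @param hidden_width hidden width (default 18, the full kidney protocol's
#'   volume count; kept at 18 for reduced schemes too, where the narrower
#'   input would otherwise leave too little capacity).
#' @param learning_rate Adam learning rate.
#' @param dropout_p dropout probability on hidden activations, in \[0, 1).
#' @param dropout_layers indices of the hidden layers that receive dropout.
#'   Default: the first hidden layer only. With these narrow (width-18)
#'   layers, dropping half the units of every layer leaves too little
#'   capacity and the reconstruction loss plateaus far above the noise
#'   floor; regularising the first layer alone trains to the floor while
#'   still randomising the learned representation.
#' @param patience early-stopping patience, epochs.
#' @param min_delta minimum loss improvement that resets the patience counter.
#' @param max_epochs epoch cap; hitting it without convergence flags the
#'   result (`converged = FALSE`) but does not raise.
#' @param batch_size minibatch size (masked voxels are reshuffled each epoch).
#' @param seed RNG seed governing initialisation, shuffling and dropout.
#' @return List of class `train_config`.
#' @export
train_config <- function(hidden_layers = 3L, hidden_width = 18L,
                         learning_rate = 1e-4, dropout_p = 0.5,
                         dropout_layers = 1L,
                         patience = 30L, min_delta = 1e-6,
                         max_epochs = 1000L, batch_size = 32L, seed = 1L) {
  stopifnot(hidden_layers >= 1L, learning_rate > 0,
            dropout_p >= 0, dropout_p < 1, max_epochs >= 1L, batch_size >= 1L)
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_width = hidden_width,
                 learning_rate = learning_rate, dropout_p = dropout_p,
                 dropout_layers = as.integer(dropout_layers),
                 patience = as.integer(patience), min_delta = min_delta,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "train_config")
}

# forward pass through the parameter network; returns caches when training
.ss_forward <- function(X, net, dropout_p, training, dropout_layers = 1L) {
  L <- length(net) - 1L
  h <- X
  pre <- vector("list", L); act <- vector("list", L); masks <- vector("list", L)
  for (l in seq_len(L)) {
    z <- sweep(h %*% net[[l]]$W, 2, net[[l]]$b, "+")
    a <- .elu(z)
    if (training && dropout_p > 0 && l %in% dropout_layers) {
      m <- .dropout_mask(nrow(a), ncol(a), dropout_p)
      a <- a * m
      masks[[l]] <- m
    }
    pre[[l]] <- z; act[[l]] <- a
    h <- a
  }
  out <- net[[L + 1L]]
  raw <- sweep(h %*% out$W, 2, out$b, "+")
  list(raw = raw, pre = pre, act = act, masks = masks, input = X)
}

# map raw network outputs to constrained parameters; returns the mapping
# Jacobian pieces needed for backprop
.ss_map <- function(raw) {
  f_ic_c <- pmin(pmax(raw[, 1], 0), 1)
  f_ees_c <- pmin(pmax(raw[, 2], 0), 1)
  in1 <- raw[, 1] >= 0 & raw[, 1] <= 1
  in2 <- raw[, 2] >= 0 & raw[, 2] <= 1
  s <- f_ic_c + f_ees_c
  over <- s > 1
  f_ic <- ifelse(over, f_ic_c / s, f_ic_c)
  f_ees <- ifelse(over, f_ees_c / s, f_ees_c)
  R <- pmin(pmax(raw[, 3], 0), 15)
  inR <- raw[, 3] >= 0 & raw[, 3] <= 15
  # d(mapped fractions)/d(clamped fractions): identity below the simplex,
  # proportional-renormalisation Jacobian above it
  j11 <- ifelse(over, f_ees_c / s^2, 1)
  j12 <- ifelse(over, -f_ic_c / s^2, 0)
  j21 <- ifelse(over, -f_ees_c / s^2, 0)
  j22 <- ifelse(over, f_ic_c / s^2, 1)
  list(f_ic = f_ic, f_ees = f_ees, f_vasc = pmax(0, 1 - f_ic - f_ees), R = R,
       j11 = j11 * in1, j12 = j12 * in2, j21 = j21 * in1, j22 = j22 * in2,
       jR = inR * 1)
}

# reconstructed DW signal and the loss gradient w.r.t. the raw outputs
.ss_loss_grad <- function(raw, y_dw, scheme, constants, n_slots,
                          fd_step = 1e-4) {
  p <- .ss_map(raw)
  nb <- nrow(raw)
  stick <- signal_astrosticks(scheme$b, 50)
  ball <- signal_ball(scheme$b, 2)
  sph <- .sphere_gpd_matrix(p$R, 2, scheme$b, scheme$delta, scheme$Delta,
                            constants$n_gpd_roots)
  sph_h <- .sphere_gpd_matrix(pmin(p$R + fd_step, 15), 2, scheme$b,
                              scheme$delta, scheme$Delta,
                              constants$n_gpd_roots)
  hstep <- pmin(p$R + fd_step, 15) - p$R
  pred <- p$f_vasc * matrix(stick, nb, length(stick), byrow = TRUE) +
    p$f_ic * sph +
    p$f_ees * matrix(ball, nb, length(ball), byrow = TRUE)
  resid <- pred - y_dw
  # loss averages over all volume slots; b0 slots contribute zero residual
  loss <- sum(resid^2) / (nb * n_slots)
  dS <- 2 * resid / (nb * n_slots)
  # gradients in mapped-parameter space
  g_fic <- rowSums(dS * sweep(sph, 2, stick, "-"))
  g_fees <- rowSums(dS * matrix(ball - stick, nb, length(ball), byrow = TRUE))
  dSdR <- p$f_ic * (sph_h - sph) / ifelse(hstep > 0, hstep, 1)
  g_R <- rowSums(dS * dSdR)
  draw <- cbind(g_fic * p$j11 + g_fees * p$j21,
                g_fic * p$j12 + g_fees * p$j22,
                g_R * p$jR)
  list(loss = loss, draw = draw, pred = pred, params = p)
}

#' Self-supervised VERDICT model fitting
#'
#' Trains a small fully connected network that maps each voxel's normalised
#' measurement vector to the three free VERDICT parameters. The network
#' output is hard-clamped into the parameter ranges (fractions \[0, 1\] with
#' proportional renormalisation when their sum exceeds 1, radius \[0, 15\]
#' um), fed through the forward model, and the training loss is the mean
#' squared error between the reconstructed and input signals. No labels are
#' involved: training and inference run on the same masked dataset, and the
#' final maps are produced by the best (lowest training loss) weights in
#' deterministic mode (dropout off).
#'
#' @param dataset a [voxel_dataset()] consistent with `scheme`.
#' @param scheme an [acq_scheme()].
#' @param config a [train_config()].
#' @param constants a [model_constants()].
#' @return An object of class `c("verdict_selfsup", "verdict_fit")`:
#'   `coefficients` (voxels x 4 matrix of f_ic, f_ees, f_vasc, R), `maps`
#'   (a [param_maps()] when the dataset carries grid coordinates),
#'   `loss_trace`, `best_epoch`, `converged`, plus the scheme and data.
#' @seealso [fit_nlls()] for the classical per-ROI fit.
#' @export
fit_selfsupervised <- function(dataset, scheme = dataset$scheme,
                               config = train_config(),
                               constants = model_constants()) {
  stopifnot(inherits(dataset, "voxel_dataset"), inherits(config, "train_config"))
  X <- dataset$volumes
  if (nrow(X) == 0L) stop("empty mask: no voxels to fit")
  lay <- .volume_layout(scheme)
  if (ncol(X) != lay$n_volumes) stop("dataset inconsistent with scheme")
  y_dw <- X[, lay$dw_idx, drop = FALSE]
  n_in <- ncol(X)
  width <- if (is.null(config$hidden_width)) n_in else config$hidden_width

  set.seed(config$seed)
  sizes <- c(n_in, rep(width, config$hidden_layers), 3L)
  net <- lapply(seq_len(length(sizes) - 1L),
                function(l) .dense_init(sizes[l], sizes[l + 1L]))
  # start the (pre-clamp) outputs mid-range so no voxel is born clamped
  net[[length(net)]]$b <- c(0.35, 0.35, 8)

  flat <- function(net) unlist(lapply(net, function(l) list(l$W, l$b)),
                               recursive = FALSE)
  unflat <- function(par) {
    k <- 1L
    for (l in seq_along(net)) {
      net[[l]]$W <<- par[[k]]; net[[l]]$b <<- as.numeric(par[[k + 1L]])
      k <- k + 2L
    }
  }
  params <- flat(net)
  adam <- .adam_init(params)

  nv <- nrow(X)
  bs <- min(config$batch_size, nv)
  eval_loss <- function() {
    fw <- .ss_forward(X, net, 0, training = FALSE)
    .ss_loss_grad(fw$raw, y_dw, scheme, constants, lay$n_volumes)$loss
  }

  trace <- numeric(0)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  converged <- FALSE
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nv)
    for (start in seq(1L, nv, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nv)]
      fw <- .ss_forward(X[idx, , drop = FALSE], net, config$dropout_p, TRUE,
                        config$dropout_layers)
      lg <- .ss_loss_grad(fw$raw, y_dw[idx, , drop = FALSE], scheme,
                          constants, lay$n_volumes)
      # backprop
      L <- length(net) - 1L
      grads <- vector("list", length(params))
      delta <- lg$draw
      hprev <- if (L >= 1L) fw$act[[L]] else fw$input
      grads[[2L * L + 1L]] <- crossprod(hprev, delta)
      grads[[2L * L + 2L]] <- colSums(delta)
      for (l in rev(seq_len(L))) {
        delta <- delta %*% t(net[[l + 1L]]$W)
        if (!is.null(fw$masks[[l]])) delta <- delta * fw$masks[[l]]
        delta <- delta * .elu_grad(fw$pre[[l]])
        hin <- if (l == 1L) fw$input else fw$act[[l - 1L]]
        grads[[2L * l - 1L]] <- crossprod(hin, delta)
        grads[[2L * l]] <- colSums(delta)
      }
      st <- .adam_step(params, grads, adam, config$learning_rate)
      params <- st$params; adam <- st$state
      unflat(params)
    }
    ep_loss <- eval_loss()
    trace <- c(trace, ep_loss)
    if (ep_loss < best$loss - config$min_delta) {
      best <- list(loss = ep_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { converged <- TRUE; break }
    }
  }

  unflat(best$params)
  fw <- .ss_forward(X, net, 0, training = FALSE)
  p <- .ss_map(fw$raw)
  coefs <- cbind(f_ic = p$f_ic, f_ees = p$f_ees, f_vasc = p$f_vasc, R = p$R)
  pred <- .ss_loss_grad(fw$raw, y_dw, scheme, constants, lay$n_volumes)

  maps <- NULL
  if (!is.null(dataset$coords) && !is.null(dataset$dim)) {
    vols <- lapply(colnames(coefs), function(nm) {
      arr <- array(NA_real_, dataset$dim)
      arr[dataset$coords] <- coefs[, nm]
      arr
    })
    names(vols) <- colnames(coefs)
    mask <- array(FALSE, dataset$dim)
    mask[dataset$coords] <- TRUE
    maps <- param_maps(vols, mask = mask)
  }

  structure(list(model = "verdict", method = "selfsupervised",
                 coefficients = coefs, fitted = pred$pred, maps = maps,
                 mse = pred$loss * lay$n_volumes / length(lay$dw_idx),
                 loss_trace = trace, best_epoch = best$epoch,
                 best_loss = best$loss, converged = converged,
                 scheme = scheme, data = X, config = config),
            class = c("verdict_selfsup", "verdict_fit"))
}
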
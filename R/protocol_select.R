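#' Configuration for the dual-network measurement selector
#'
#' A Feature Scoring Network (27 inputs, one 64-unit hidden layer with ReLU
#' and batch normalisation, 27 sigmoid outputs) scores every
#' direction-resolved DW measurement; the 12 highest-scoring measurements,
#' weighted by their scores, feed a Prediction Network (12 inputs, one
#' 64-unit ReLU hidden layer, 27 linear outputs) that reconstructs the full
#' measurement set. Both are trained in tandem for 100 epochs with Adam at
#' learning rate 1e-5; the loss is the MSE between the reconstruction and
#' the input measurements.
#'
#' @param n_features_in number of candidate DW measurements (27 for the full
#'   kidney protocol: 9 combos x 3 directions).
#' @param k_selected measurements retained (12); must be smaller than
#'   `n_features_in` and divisible by `n_directions`.
#' @param hidden_width hidden units in both networks.
#' @param epochs training epochs.
#' @param learning_rate Adam learning rate.
#' @param dropout_p dropout on the scoring network's hidden activations
#'   (rate and placement unreported for these networks; 0.2 by default,
#'   configurable). The prediction path is left undropped: knocking out
#'   prediction-net hidden units biases the reconstruction low, which
#'   spuriously rewards uninformative near-constant inputs.
#' @param batch_size minibatch size.
#' @param n_directions directions per b-value (3).
#' @param seed RNG seed.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(n_features_in = 27L, k_selected = 12L,
                             hidden_width = 64L, epochs = 100L,
                             learning_rate = 1e-5, dropout_p = 0.2,
                             batch_size = 8L, n_directions = 3L,
                             seed = 1L) {
  stopifnot(k_selected < n_features_in, k_selected %% n_directions == 0L,
            epochs >= 1L, learning_rate > 0, dropout_p >= 0, dropout_p < 1)
  structure(list(n_features_in = as.integer(n_features_in),
                 k_selected = as.integer(k_selected),
                 hidden_width = as.integer(hidden_width),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout_p = as.integer(0) + dropout_p,
                 batch_size = as.integer(batch_size),
                 n_directions = as.integer(n_directions),
                 seed = as.integer(seed)), class = "selection_config")
}

# train the scoring + prediction pair on one subject's voxel matrix (V x 27);
# returns the subject's averaged importance scores and the loss trace
.train_subject_pair <- function(X, cfg) {
  nf <- cfg$n_features_in
  k <- cfg$k_selected
  H <- cfg$hidden_width
  set.seed(cfg$seed)

  # per-measurement standardisation of the subject's dataset before it
  # enters the networks. This puts every candidate measurement on the same
  # footing: with raw signals, near-noise-floor measurements act as cheap
  # constant inputs and high-signal measurements dominate the loss purely
  # through their scale, both of which mask the cross-measurement structure
  # the selector is meant to rank.
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev < 1e-12] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdev, "/")

  sc1 <- .dense_init(nf, H); sc2 <- .dense_init(H, nf)
  # near-zero scoring head: all measurements start essentially tied at 0.5,
  # so early membership of the top-k gate reflects learned structure rather
  # than the random initialisation
  sc2$W <- sc2$W * 0.05
  bn <- list(gamma = rep(1, H), beta = rep(0, H),
             running = list(mean = rep(0, H), var = rep(1, H)))
  pr1 <- .dense_init(k, H); pr2 <- .dense_init(H, nf)
  # start the reconstruction at the per-measurement mean, so the early
  # gradient reflects cross-measurement structure, not mean levels
  pr2$b <- colMeans(X)

  params <- list(sc1$W, sc1$b, sc2$W, sc2$b, bn$gamma, bn$beta,
                 pr1$W, pr1$b, pr2$W, pr2$b)
  adam <- .adam_init(params)
  sync <- function() {
    sc1$W <<- params[[1]]; sc1$b <<- as.numeric(params[[2]])
    sc2$W <<- params[[3]]; sc2$b <<- as.numeric(params[[4]])
    bn$gamma <<- as.numeric(params[[5]]); bn$beta <<- as.numeric(params[[6]])
    pr1$W <<- params[[7]]; pr1$b <<- as.numeric(params[[8]])
    pr2$W <<- params[[9]]; pr2$b <<- as.numeric(params[[10]])
  }

  # dataset-level scores in deterministic mode (running BN stats, no
  # dropout); these drive the top-k selection and are what the caller gets
  eval_scores <- function() {
    z1 <- sweep(X %*% sc1$W, 2, sc1$b, "+")
    bnf <- .bn_forward(z1, bn$gamma, bn$beta, bn$running, training = FALSE)
    a1 <- .relu(bnf$out)
    colMeans(.sigmoid(sweep(a1 %*% sc2$W, 2, sc2$b, "+")))
  }

  nv <- nrow(X)
  bs <- min(cfg$batch_size, nv)
  trace <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    # the 12 highest-scoring measurements of the dataset, re-evaluated once
    # per epoch (selection is per dataset, not per minibatch); slots stay in
    # measurement order so the prediction net sees a stable input layout
    sel <- sort(order(-eval_scores())[seq_len(k)])
    ord <- sample.int(nv)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, nv, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, nv)]
      if (length(idx) < 2L) next   # batch norm needs >= 2 samples
      x <- X[idx, , drop = FALSE]
      B <- nrow(x)

      # --- scoring net forward: dense -> BN -> ReLU -> dropout -> dense -> sigmoid
      z1 <- sweep(x %*% sc1$W, 2, sc1$b, "+")
      bnf <- .bn_forward(z1, bn$gamma, bn$beta, bn$running, training = TRUE)
      bn$running <- bnf$running
      a1 <- .relu(bnf$out)
      m1 <- .dropout_mask(B, H, cfg$dropout_p)
      a1d <- if (is.null(m1)) a1 else a1 * m1
      logits <- sweep(a1d %*% sc2$W, 2, sc2$b, "+")
      s <- .sigmoid(logits)                          # B x nf scores
      u <- (s * x)[, sel, drop = FALSE]              # score-weighted inputs

      # --- prediction net forward: dense -> ReLU -> dense
      q1 <- sweep(u %*% pr1$W, 2, pr1$b, "+")
      p1 <- .relu(q1)
      yhat <- sweep(p1 %*% pr2$W, 2, pr2$b, "+")

      resid <- yhat - x
      loss <- mean(resid^2)
      ep_loss <- ep_loss + loss; nb <- nb + 1L

      # --- backward
      dy <- 2 * resid / (B * nf)
      gpr2W <- crossprod(p1, dy); gpr2b <- colSums(dy)
      dp1 <- dy %*% t(pr2$W)
      dq1 <- dp1 * .relu_grad(q1)
      gpr1W <- crossprod(u, dq1); gpr1b <- colSums(dq1)
      du <- dq1 %*% t(pr1$W)                         # B x k
      # gradient reaches the scores only through the retained features
      ds <- matrix(0, B, nf)
      ds[, sel] <- du * x[, sel, drop = FALSE]
      dlogits <- ds * s * (1 - s)
      gsc2W <- crossprod(a1d, dlogits); gsc2b <- colSums(dlogits)
      da1 <- dlogits %*% t(sc2$W)
      if (!is.null(m1)) da1 <- da1 * m1
      dbn_out <- da1 * .relu_grad(bnf$out)
      bb <- .bn_backward(dbn_out, bnf, bn$gamma)
      gsc1W <- crossprod(x, bb$dA); gsc1b <- colSums(bb$dA)

      grads <- list(gsc1W, gsc1b, gsc2W, gsc2b, bb$dgamma, bb$dbeta,
                    gpr1W, gpr1b, gpr2W, gpr2b)
      st <- .adam_step(params, grads, adam, cfg$learning_rate)
      params <- st$params; adam <- st$state
      sync()
    }
    trace[epoch] <- ep_loss / max(nb, 1L)
  }

  list(scores = eval_scores(), trace = trace)
}

#' Train the dual-network measurement selector over a cohort
#'
#' Trains one scoring/prediction network pair per subject on that subject's
#' direction-resolved normalised DW measurements, then averages the
#' importance scores across subjects.
#'
#' @param cohort list with one element per subject: a [voxel_dataset()]
#'   carrying a `dw_directions` table, or directly a voxels x 27 numeric
#'   matrix (a single 27-vector is accepted as a one-voxel subject).
#' @param config a [selection_config()].
#' @return Object of class `importance_scores`: `per_subject` (subjects x
#'   27 matrix), `cohort` (averaged scores), `loss_traces`, `config`.
#' @export
train_dual_network <- function(cohort, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (length(cohort) == 0L) stop("empty cohort")
  mats <- lapply(cohort, function(s) {
    x <- if (inherits(s, "voxel_dataset")) s$dw_directions else s
    if (is.null(x)) stop("subject has no direction-resolved DW table")
    if (is.vector(x)) x <- matrix(x, 1L)
    if (ncol(x) != config$n_features_in)
      stop("subject has ", ncol(x), " DW measurements; expected ",
           config$n_features_in)
    x
  })
  res <- lapply(seq_along(mats), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i   # independent init/shuffle per subject
    .train_subject_pair(mats[[i]], cfg)
  })
  per_subject <- do.call(rbind, lapply(res, `[[`, "scores"))
  structure(list(per_subject = per_subject,
                 cohort = colMeans(per_subject),
                 loss_traces = lapply(res, `[[`, "trace"),
                 config = config),
            class = "importance_scores")
}

#' Select the reduced protocol from importance scores
#'
#' Aggregates the cohort-averaged per-measurement scores per b-value (mean
#' over that b-value's three directions) and retains the top
#' `k_selected / n_directions` b-values, i.e. whole direction triplets, so
#' the result is an acquirable protocol. Ties are broken towards the lower
#' b-value. Per-measurement top-k (possibly incomplete triplets) is
#' available with `granularity = "measurement"`.
#'
#' @param scores an `importance_scores` object (or plain numeric vector of
#'   cohort-averaged scores).
#' @param scheme the [acq_scheme()] the measurements came from.
#' @param config a [selection_config()].
#' @param granularity `"bvalue"` (default: whole triplets) or
#'   `"measurement"`.
#' @return Object of class `selected_protocol`: `measurement_idx` (retained
#'   indices into the 27), `b_values` (distinct retained b-values),
#'   `scores`, `loss_traces`.
#' @export
select_protocol <- function(scores, scheme = kidney_full_protocol(),
                            config = selection_config(),
                            granularity = c("bvalue", "measurement")) {
  granularity <- match.arg(granularity)
  traces <- NULL
  if (inherits(scores, "importance_scores")) {
    traces <- scores$loss_traces
    scores <- scores$cohort
  }
  nd <- config$n_directions
  nc <- length(scores) / nd
  if (nc != nrow(scheme))
    stop("score vector implies ", nc, " b-values; scheme has ", nrow(scheme))
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  k_b <- config$k_selected / nd
  if (nrow(scheme) < k_b) stop("fewer than ", k_b, " distinct b-values")
  if (granularity == "bvalue") {
    by_b <- vapply(seq_len(nc), function(j)
      mean(scores[((j - 1L) * nd + 1L):(j * nd)]), numeric(1))
    keep_b <- sort(order(-by_b, scheme$b)[seq_len(k_b)])
    idx <- sort(unlist(lapply(keep_b, function(j)
      ((j - 1L) * nd + 1L):(j * nd))))
  } else {
    idx <- sort(order(-scores, rep(scheme$b, each = nd))[
      seq_len(config$k_selected)])
    keep_b <- sort(unique((idx - 1L) %/% nd + 1L))
  }
  structure(list(measurement_idx = idx, b_values = scheme$b[keep_b],
                 combo_idx = keep_b, scores = scores, loss_traces = traces),
            class = "selected_protocol")
}

#' Restrict a scheme to a selected protocol
#'
#' Returns the sub-scheme containing only the retained b-values, matched b0s
#' included (they are never selection candidates and re-attach
#' automatically).
#'
#' @param scheme the full [acq_scheme()].
#' @param selected a `selected_protocol`, or a numeric vector of b-values.
#' @return The reduced [acq_scheme()].
#' @export
#' @examples
#' reduce_scheme(kidney_full_protocol(), c(70, 150, 1000, 2000))
reduce_scheme <- function(scheme, selected) {
  stopifnot(inherits(scheme, "acq_scheme"))
  bsel <- if (inherits(selected, "selected_protocol")) selected$b_values
          else as.numeric(selected)
  unknown <- setdiff(bsel, scheme$b)
  if (length(unknown) > 0)
    stop("b-value(s) not in scheme: ", paste(unknown, collapse = ", "))
  keep <- scheme$b %in% bsel
  acq_scheme(b = scheme$b[keep], delta = scheme$delta[keep],
             Delta = scheme$Delta[keep], TE = scheme$TE[keep],
             n_directions = attr(scheme, "n_directions"),
             has_matched_b0 = scheme$has_matched_b0[keep])
}

#' @export
print.selected_protocol <- function(x, ...) {
  cat("selected protocol: ", length(x$measurement_idx), " measurements, b = ",
      paste(x$b_values, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' @export
print.importance_scores <- function(x, ...) {
  cat("importance scores: ", nrow(x$per_subject), " subject(s) x ",
      ncol(x$per_subject), " measurements\ncohort average:\n", sep = "")
  print(round(x$cohort, 4))
  invisible(x)
}
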
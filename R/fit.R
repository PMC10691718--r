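#' Training configuration for the host-prediction model
#'
#' Collects every tunable hyperparameter with its default. Defaults follow
#' the model's reference setting: 128-dimensional embeddings, 3 propagation
#' layers, contrastive weight 0.1, noise magnitude 0.1, temperature 0.2 and
#' Adam with learning rate 0.001.
#'
#' @param d Embedding dimension (>= 1).
#' @param K Number of light-graph-convolution layers (>= 1).
#' @param lambda Weight of the auxiliary contrastive loss (>= 0); `0`
#'   disables the contrastive branch entirely.
#' @param epsilon L2 magnitude of each per-layer noise vector (>= 0).
#' @param rho InfoNCE temperature (> 0).
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience: stop when the total loss has
#'   not improved by more than `tol` for this many consecutive epochs.
#'   `Inf` disables early stopping.
#' @param tol Minimal improvement counted as progress by early stopping.
#' @param weight_decay Optional L2 penalty on the layer-0 table (default 0).
#' @param seed Integer seed driving every random draw of the run.
#' @return A list of class `"phagehost_control"`.
#' @export
phagehost_control <- function(d = 128L, K = 3L, lambda = 0.1, epsilon = 0.1,
                              rho = 0.2, lr = 0.001, epochs = 200L,
                              patience = 20L, tol = 1e-6,
                              weight_decay = 0, seed = 1L) {
  stopifnot(d >= 1, K >= 1, lambda >= 0, epsilon >= 0, rho > 0, lr > 0,
            epochs >= 1, weight_decay >= 0)
  structure(list(d = as.integer(d), K = as.integer(K), lambda = lambda,
                 epsilon = epsilon, rho = rho, lr = lr,
                 epochs = as.integer(epochs), patience = patience, tol = tol,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "phagehost_control")
}

# (1/K) * sum_{k=1..K} A^k %*% G  -- the layer-combined propagation
# polynomial; A is symmetric so this is also the backward operator.
apply_layer_poly <- function(A_norm, G, K) {
  S <- matrix(0, nrow(G), ncol(G))
  X <- G
  for (k in seq_len(K)) {
    X <- as.matrix(A_norm %*% X)
    S <- S + X
  }
  S / K
}

#' Fit the phage-host ranking model
#'
#' Learns a layer-0 embedding for every node of the heterogeneous graph by
#' jointly minimizing a Bayesian personalized ranking loss over observed
#' (virus, host) training pairs and, when `lambda > 0`, an InfoNCE
#' contrastive loss between two noise-perturbed encodings:
#' `L = L_bpr + lambda * L_nce`. Optimization is full-batch Adam on the
#' layer-0 table; negatives are resampled and fresh noise is drawn every
#' epoch. When `lambda = 0` (or `contrastive = FALSE`) the contrastive
#' branch is skipped entirely, including its random draws, so such runs are
#' bit-identical to each other under the same seed.
#'
#' @param graph A `"phg_graph"` from [assemble_graph()], built with
#'   training-split interactions only.
#' @param train_pairs Data.frame with columns `virus_id`, `prokaryote_id`
#'   of positive training interactions.
#' @param control A [phagehost_control()] object.
#' @param contrastive Logical; `FALSE` disables the auxiliary branch
#'   regardless of `lambda`.
#' @param verbose Print a progress line every 50 epochs.
#' @return An object of class `"phagehost"`: list with the trained tables
#'   (`H0`, final `embedding`), `history` (per-epoch `main`, `aux`,
#'   `total`), the `graph`, `control`, and bookkeeping fields.
#' @examples
#' eco <- make_ecosystem(ecosystem_params(seed = 7))
#' g <- ecosystem_graph(eco)
#' fit <- phagehost(g, eco$train_pairs,
#'                  control = phagehost_control(d = 16, epochs = 30, seed = 7))
#' print(fit)
#' @export
phagehost <- function(graph, train_pairs, control = phagehost_control(),
                      contrastive = TRUE, verbose = FALSE) {
  stopifnot(inherits(graph, "phg_graph"),
            inherits(control, "phagehost_control"))
  if (!nrow(train_pairs)) stop("train_pairs must be nonempty")
  nodes <- graph$nodes
  V <- length(graph$viruses)
  P <- length(graph$prokaryotes)
  v_idx <- match(as.character(train_pairs$virus_id), nodes)
  p_idx <- match(as.character(train_pairs$prokaryote_id), nodes)
  if (anyNA(v_idx) || anyNA(p_idx)) {
    stop("train_pairs contain ids absent from the graph")
  }
  if (any(p_idx <= V)) stop("prokaryote_id column contains virus nodes")
  pos <- cbind(v = v_idx, p = p_idx)
  prok_rows <- V + seq_len(P)
  use_aux <- contrastive && control$lambda > 0

  A_norm <- normalized_operator(graph)
  if (use_aux && length(graph$isolated)) {
    warning(length(graph$isolated), " isolated node(s) receive no messages; ",
            "their zero rows are excluded from the contrastive loss")
  }
  # repeated per-epoch zero-norm warnings carry no new information
  aux_loss <- function(H1, H2) {
    withCallingHandlers(
      infonce_loss(H1, H2, control$rho, grad = TRUE),
      warning = function(w) {
        if (grepl("zero-norm", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  set.seed(control$seed)
  H0 <- init_embeddings(V + P, control$d)

  # Adam state
  m <- matrix(0, nrow(H0), ncol(H0)); v2 <- matrix(0, nrow(H0), ncol(H0))
  b1 <- 0.9; b2 <- 0.999; eps_adam <- 1e-8
  history <- data.frame(epoch = integer(), main = numeric(),
                        aux = numeric(), total = numeric())
  best <- Inf; stall <- 0L; epochs_run <- 0L
  for (ep in seq_len(control$epochs)) {
    triples <- sample_negatives(pos, prok_rows)
    enc <- encode(A_norm, H0, control$K)
    lm_ <- bpr_loss(enc$final, triples, grad = TRUE)
    G_final <- attr(lm_, "gradient")
    main <- as.numeric(lm_)
    if (use_aux) {
      view1 <- encode_perturbed(A_norm, H0, control$K, control$epsilon)
      view2 <- encode_perturbed(A_norm, H0, control$K, control$epsilon)
      la_ <- aux_loss(view1$final, view2$final)
      aux <- as.numeric(la_)
      G_aux <- attr(la_, "gradient1") + attr(la_, "gradient2")
      total <- main + control$lambda * aux
      G_up <- G_final + control$lambda * G_aux
    } else {
      aux <- NA_real_
      total <- main
      G_up <- G_final
    }
    if (!is.finite(total)) {
      stop(sprintf("non-finite loss at epoch %d (main=%g, aux=%g)",
                   ep, main, aux))
    }
    # backprop through the (linear) encoder: dL/dH0 = poly(A) %*% dL/dH
    G0 <- apply_layer_poly(A_norm, G_up, control$K)
    if (control$weight_decay > 0) G0 <- G0 + control$weight_decay * H0
    m <- b1 * m + (1 - b1) * G0
    v2 <- b2 * v2 + (1 - b2) * G0^2
    mh <- m / (1 - b1^ep); vh <- v2 / (1 - b2^ep)
    H0 <- H0 - control$lr * mh / (sqrt(vh) + eps_adam)
    history <- rbind(history,
                     data.frame(epoch = ep, main = main, aux = aux,
                                total = total))
    epochs_run <- ep
    if (verbose && ep %% 50 == 0) {
      message(sprintf("epoch %4d  main %.4f  aux %s  total %.4f", ep, main,
                      ifelse(is.na(aux), "  --", sprintf("%.4f", aux)), total))
    }
    if (total < best - control$tol) {
      best <- total; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }
  enc <- encode(A_norm, H0, control$K)
  structure(list(H0 = H0, embedding = enc$final, layer_states = enc$layer_states,
                 graph = graph, A_norm = A_norm, control = control,
                 contrastive = use_aux, history = history,
                 epochs_run = epochs_run,
                 train_pairs = train_pairs, nodes = nodes, n_virus = V),
            class = "phagehost")
}

#' @method print phagehost
#' @export
print.phagehost <- function(x, ...) {
  cat("Phage-host ranking model (light graph convolution",
      if (x$contrastive) "+ contrastive augmentation)" else "only)", "\n")
  cat(sprintf("  graph: %d viruses, %d prokaryotes\n",
              x$n_virus, length(x$nodes) - x$n_virus))
  cat(sprintf("  d = %d, K = %d, lambda = %g, epsilon = %g\n",
              x$control$d, x$control$K, x$control$lambda, x$control$epsilon))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  trained %d epoch(s); final loss %.4f (ranking %.4f)\n",
              x$epochs_run, last$total, last$main))
  invisible(x)
}

#' @method summary phagehost
#' @export
summary.phagehost <- function(object, ...) {
  h <- object$history
  out <- list(control = object$control,
              epochs_run = object$epochs_run,
              loss_first = h$total[1], loss_last = h$total[nrow(h)],
              main_last = h$main[nrow(h)], aux_last = h$aux[nrow(h)],
              n_train_pairs = nrow(object$train_pairs),
              n_virus = object$n_virus,
              n_prokaryote = length(object$nodes) - object$n_virus)
  class(out) <- "summary.phagehost"
  out
}

#' @method print summary.phagehost
#' @export
print.summary.phagehost <- function(x, ...) {
  cat("Phage-host ranking model\n")
  cat(sprintf("  nodes: %d viruses + %d prokaryotes; %d training pairs\n",
              x$n_virus, x$n_prokaryote, x$n_train_pairs))
  cat(sprintf("  epochs run: %d; total loss %.4f -> %.4f\n",
              x$epochs_run, x$loss_first, x$loss_last))
  cat(sprintf("  final ranking loss %.4f; contrastive loss %s\n",
              x$main_last,
              ifelse(is.na(x$aux_last), "(disabled)",
                     sprintf("%.4f", x$aux_last))))
  invisible(x)
}

#' Extract embeddings from a fitted model
#'
#' @param object A `"phagehost"` fit.
#' @param layer `"final"` (default) for the layer-combined embedding used
#'   in scoring, or `"input"` for the trainable layer-0 table.
#' @param ... Unused.
#' @return Numeric matrix with node ids as row names.
#' @method coef phagehost
#' @export
coef.phagehost <- function(object, layer = c("final", "input"), ...) {
  layer <- match.arg(layer)
  M <- if (layer == "final") object$embedding else object$H0
  rownames(M) <- object$nodes
  M
}

#' Plot the training history of a fitted model
#'
#' Draws the per-epoch total loss, with the ranking and (if enabled)
#' weighted contrastive components overlaid.
#'
#' @param x A `"phagehost"` fit.
#' @param ... Passed to [graphics::plot()].
#' @method plot phagehost
#' @export
plot.phagehost <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$total, type = "l", lwd = 2,
                 xlab = "epoch", ylab = "loss", ...)
  graphics::lines(h$epoch, h$main, lty = 2)
  if (!all(is.na(h$aux))) {
    graphics::lines(h$epoch, x$control$lambda * h$aux, lty = 3)
    graphics::legend("topright", lty = 1:3, lwd = c(2, 1, 1),
                     legend = c("total", "ranking", "lambda * contrastive"),
                     bty = "n")
  } else {
    graphics::legend("topright", lty = 1:2, lwd = c(2, 1),
                     legend = c("total", "ranking"), bty = "n")
  }
  invisible(x)
}
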
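## Negative-binomial variational autoencoder, written directly on base matrix
## algebra.  Architecture: 2-hidden-layer encoder and decoder, 30 latent
## variables, softmax decoder output scaled by the observed library size,
## gene-by-batch (modality) dispersion, optional one-hot conditioning on the
## modality label injected at the encoder input and at the latent space.

relu <- function(x) (x > 0) * x

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

## bo is initialized at the log mean expression proportions and log_theta at a
## moment estimate, so optimization starts from the global mean profile and
## only has to learn deviations -- a standard warm start for NB autoencoders.
vae_init_params <- function(n_in, n_hidden, n_latent, n_genes, n_cond, n_cat,
                            bo_init = numeric(n_genes),
                            log_theta_init = matrix(0, n_cat, n_genes)) {
  list(A1 = he_init(n_in + n_cond, n_hidden), a1 = numeric(n_hidden),
       A2 = he_init(n_hidden, n_hidden),      a2 = numeric(n_hidden),
       Am = he_init(n_hidden, n_latent),      am = numeric(n_latent),
       Av = he_init(n_hidden, n_latent) * 0.1, av = numeric(n_latent),
       B1 = he_init(n_latent + n_cond, n_hidden), b1 = numeric(n_hidden),
       B2 = he_init(n_hidden, n_hidden),      b2 = numeric(n_hidden),
       Bo = he_init(n_hidden, n_genes) * 0.1, bo = bo_init,
       log_theta = log_theta_init)
}

row_softmax <- function(lo) {
  lo <- lo - apply(lo, 1, max)
  e <- exp(lo)
  e / rowSums(e)
}

nb_loglik_entries <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * (log(theta) - log(theta + mu)) +
    y * (log(mu + 1e-12) - log(theta + mu))
}

## forward + loss (+ cache when grad needed).  Y: counts n x G, C: n x n_cond
## one-hot (or NULL), cat: integer batch index per cell for dispersion.
vae_forward <- function(p, Y, C, cat, sample_z = TRUE, eps = NULL,
                        kl_weight = 1) {
  n <- nrow(Y)
  l <- rowSums(Y)
  x <- log1p(Y)
  E0 <- if (is.null(C)) x else cbind(x, C)
  P1 <- sweep(E0 %*% p$A1, 2, p$a1, "+"); H1 <- relu(P1)
  P2 <- sweep(H1 %*% p$A2, 2, p$a2, "+"); H2 <- relu(P2)
  MU <- sweep(H2 %*% p$Am, 2, p$am, "+")
  LV <- pmin(pmax(sweep(H2 %*% p$Av, 2, p$av, "+"), -10), 10)
  if (sample_z) {
    if (is.null(eps)) eps <- matrix(stats::rnorm(length(MU)), nrow = n)
    Z <- MU + exp(LV / 2) * eps
  } else {
    eps <- NULL
    Z <- MU
  }
  D0 <- if (is.null(C)) Z else cbind(Z, C)
  Q1 <- sweep(D0 %*% p$B1, 2, p$b1, "+"); G1 <- relu(Q1)
  Q2 <- sweep(G1 %*% p$B2, 2, p$b2, "+"); G2 <- relu(Q2)
  LO <- sweep(G2 %*% p$Bo, 2, p$bo, "+")
  RHO <- row_softmax(LO)
  MUg <- RHO * l
  TH <- exp(p$log_theta[cat, , drop = FALSE])
  nll <- -sum(nb_loglik_entries(Y, MUg, TH))
  kl <- 0.5 * sum(exp(LV) + MU^2 - 1 - LV)
  loss <- (nll + kl_weight * kl) / n
  list(loss = loss, nll = nll / n, kl = kl / n,
       cache = list(E0 = E0, P1 = P1, H1 = H1, P2 = P2, H2 = H2, MU = MU,
                    LV = LV, eps = eps, Z = Z, D0 = D0, Q1 = Q1, G1 = G1,
                    Q2 = Q2, G2 = G2, RHO = RHO, MUg = MUg, TH = TH,
                    l = l, n = n))
}

vae_backward <- function(p, Y, cat, cache, n_latent, kl_weight = 1) {
  with(cache, {
    g_mu <- ((Y + TH) / (TH + MUg) - Y / (MUg + 1e-12)) / n
    u <- g_mu * l
    gLO <- RHO * (u - rowSums(u * RHO))
    g <- list()
    g$bo <- colSums(gLO); g$Bo <- crossprod(G2, gLO)
    gG2 <- tcrossprod(gLO, p$Bo); gQ2 <- gG2 * (Q2 > 0)
    g$b2 <- colSums(gQ2); g$B2 <- crossprod(G1, gQ2)
    gG1 <- tcrossprod(gQ2, p$B2); gQ1 <- gG1 * (Q1 > 0)
    g$b1 <- colSums(gQ1); g$B1 <- crossprod(D0, gQ1)
    gD0 <- tcrossprod(gQ1, p$B1)
    gZ <- gD0[, seq_len(n_latent), drop = FALSE]
    gMU <- gZ + kl_weight * MU / n
    gLV <- gZ * eps * exp(LV / 2) * 0.5 + kl_weight * 0.5 * (exp(LV) - 1) / n
    g$am <- colSums(gMU); g$Am <- crossprod(H2, gMU)
    g$av <- colSums(gLV); g$Av <- crossprod(H2, gLV)
    gH2 <- tcrossprod(gMU, p$Am) + tcrossprod(gLV, p$Av)
    gP2 <- gH2 * (P2 > 0)
    g$a2 <- colSums(gP2); g$A2 <- crossprod(H1, gP2)
    gH1 <- tcrossprod(gP2, p$A2); gP1 <- gH1 * (P1 > 0)
    g$a1 <- colSums(gP1); g$A1 <- crossprod(E0, gP1)
    dtheta <- digamma(Y + TH) - digamma(TH) + log(TH) + 1 -
      log(TH + MUg) - (Y + TH) / (TH + MUg)
    glt_cells <- -(dtheta * TH) / n
    glt <- matrix(0, nrow(p$log_theta), ncol(p$log_theta))
    for (k in seq_len(nrow(glt))) {
      sel <- cat == k
      if (any(sel)) glt[k, ] <- colSums(glt_cells[sel, , drop = FALSE])
    }
    g$log_theta <- glt
    g
  })
}

adam_step <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(g)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, state = state)
}

one_hot_modality <- function(modality, levels) {
  m <- matrix(0, length(modality), length(levels))
  m[cbind(seq_along(modality), match(modality, levels))] <- 1
  m
}

#' Fit a negative-binomial variational autoencoder
#'
#' Trains a VAE with 2-hidden-layer encoder and decoder, 30 latent variables
#' by default, a negative-binomial observation likelihood whose mean is the
#' cell's library size times a softmax decoder output, and a gene-by-modality
#' dispersion. When `conditional = TRUE` the modality label is one-hot
#' encoded at the encoder input and injected again at the latent space, so a
#' cell can later be decoded under the other modality's label. Optimization
#' is Adam on the evidence lower bound with a 90/10 train/validation split
#' and early stopping when the validation objective fails to improve for
#' `patience` consecutive epochs (the best-validation parameters are kept).
#'
#' @param train `labeled_counts` with integer counts.
#' @param conditional Condition on the modality label?
#' @param held_out Optional cell type that must NOT be present in `train`;
#'   an error is raised if it is (held-out protocol guard).
#' @param n_latent,n_hidden Latent dimension (default 30) and hidden width
#'   (default 128).
#' @param max_epochs,patience Training length controls.
#' @param lr,batch_size,val_frac Adam learning rate, minibatch size,
#'   validation fraction.
#' @param kl_warmup Epochs over which the KL term is linearly ramped from 0
#'   to its full weight (standard annealing against posterior collapse).
#' @param seed Integer seed controlling initialization, the split, shuffling
#'   and reparameterization noise; the same seed reproduces the trajectory.
#' @param verbose Print per-epoch losses?
#' @return A `vae_model`.
#' @export
fit_vae <- function(train, conditional = FALSE, held_out = NULL,
                    n_latent = 30, n_hidden = 128, max_epochs = 100,
                    patience = 10, lr = 3e-3, batch_size = 32,
                    val_frac = 0.1, kl_warmup = 10, seed = 1L,
                    verbose = FALSE) {
  Y <- as_dense(train$values)
  if (any(Y != round(Y))) stop("fit_vae requires integer counts")
  if (!is.null(held_out) && any(train$cell_type == held_out)) {
    stop("held-out cell type '", held_out, "' present in the training data")
  }
  modalities <- sort(unique(train$modality))
  if (conditional && length(modalities) < 2) {
    stop("conditional model needs both modalities in the training data")
  }
  n_cond <- if (conditional) length(modalities) else 0L
  cat_idx <- match(train$modality, modalities)
  C_all <- if (conditional) one_hot_modality(train$modality, modalities) else NULL

  with_seed(seed, {
    mean_prop <- colSums(Y) / sum(Y)
    mexp <- colMeans(Y); vexp <- apply(Y, 2, stats::var)
    alpha0 <- pmax((vexp - mexp) / mexp^2, 0.01)
    alpha0[!is.finite(alpha0)] <- 1
    p <- vae_init_params(ncol(Y), n_hidden, n_latent, ncol(Y), n_cond,
                         length(modalities),
                         bo_init = log(mean_prop + 1e-10),
                         log_theta_init = matrix(rep(-log(alpha0),
                                                     each = length(modalities)),
                                                 nrow = length(modalities)))
    state <- list(m = lapply(p, function(x) x * 0),
                  v = lapply(p, function(x) x * 0))
    n <- nrow(Y)
    idx <- sample(n)
    n_val <- max(1L, floor(val_frac * n))
    val <- idx[seq_len(n_val)]
    tr <- idx[-seq_len(n_val)]
    best <- list(loss = Inf, p = p, epoch = 0L)
    history <- data.frame(epoch = integer(), train = numeric(), val = numeric())
    t_step <- 0L
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; n_b <- 0
      klw <- if (kl_warmup > 0) min(1, epoch / kl_warmup) else 1
      for (start in seq(1, length(ord), by = batch_size)) {
        b <- ord[start:min(start + batch_size - 1, length(ord))]
        Cb <- if (conditional) C_all[b, , drop = FALSE] else NULL
        fw <- vae_forward(p, Y[b, , drop = FALSE], Cb, cat_idx[b],
                          sample_z = TRUE, kl_weight = klw)
        if (!is.finite(fw$loss)) {
          stop(sprintf("VAE training diverged (non-finite loss) at epoch %d",
                       epoch))
        }
        gr <- vae_backward(p, Y[b, , drop = FALSE], cat_idx[b], fw$cache,
                           n_latent, kl_weight = klw)
        t_step <- t_step + 1L
        upd <- adam_step(p, gr, state, lr, t_step)
        p <- upd$p; state <- upd$state
        ep_loss <- ep_loss + fw$loss; n_b <- n_b + 1
      }
      Cv <- if (conditional) C_all[val, , drop = FALSE] else NULL
      vl <- vae_forward(p, Y[val, , drop = FALSE], Cv, cat_idx[val],
                        sample_z = FALSE)$loss
      history <- rbind(history,
                       data.frame(epoch = epoch, train = ep_loss / n_b, val = vl))
      if (verbose) message(sprintf("epoch %3d  train %.2f  val %.2f",
                                   epoch, ep_loss / n_b, vl))
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, p = p, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    structure(list(params = best$p, conditional = conditional,
                   modalities = modalities, gene_ids = train$gene_ids,
                   n_latent = n_latent, n_hidden = n_hidden,
                   history = history, best_epoch = best$epoch,
                   held_out = held_out, seed = seed),
              class = "vae_model")
  })
}

#' @export
print.vae_model <- function(x, ...) {
  cat(sprintf("<vae_model>%s %d genes, latent %d, hidden %d; best epoch %d (val loss %.2f)\n",
              if (x$conditional) " conditional," else "",
              length(x$gene_ids), x$n_latent, x$n_hidden, x$best_epoch,
              min(x$history$val)))
  invisible(x)
}

#' Encode cells to VAE latent posterior means
#'
#' @param model A `vae_model`.
#' @param lc `labeled_counts` gene-aligned to the model.
#' @param modality_label Override the one-hot modality label used by a
#'   conditional encoder (default: each cell's own label).
#' @return Matrix of posterior mean latent coordinates (cells x latent).
#' @export
vae_encode <- function(model, lc, modality_label = NULL) {
  if (!identical(model$gene_ids, lc$gene_ids)) {
    stop("input must be gene-aligned to the model")
  }
  Y <- as_dense(lc$values)
  mod <- modality_label %||% lc$modality
  if (length(mod) == 1) mod <- rep(mod, nrow(Y))
  C <- if (model$conditional) one_hot_modality(mod, model$modalities) else NULL
  cat_idx <- match(lc$modality, model$modalities)
  cat_idx[is.na(cat_idx)] <- 1L
  vae_forward(model$params, Y, C, cat_idx, sample_z = FALSE)$cache$MU
}

#' Decode latent coordinates to expression proportions
#'
#' @param model A `vae_model`.
#' @param Z Latent matrix (cells x latent).
#' @param modality_label Modality label(s) injected at the latent space of a
#'   conditional decoder.
#' @return Matrix of per-cell expression proportions (rows sum to 1).
#' @export
vae_decode <- function(model, Z, modality_label = NULL) {
  p <- model$params
  if (model$conditional) {
    if (is.null(modality_label)) stop("conditional decoder needs a modality label")
    if (length(modality_label) == 1) modality_label <- rep(modality_label, nrow(Z))
    D0 <- cbind(Z, one_hot_modality(modality_label, model$modalities))
  } else D0 <- Z
  Q1 <- sweep(D0 %*% p$B1, 2, p$b1, "+"); G1 <- relu(Q1)
  Q2 <- sweep(G1 %*% p$B2, 2, p$b2, "+"); G2 <- relu(Q2)
  row_softmax(sweep(G2 %*% p$Bo, 2, p$bo, "+"))
}

#' Deterministic reconstruction log-likelihood of a dataset under the model
#'
#' Encodes each cell to its posterior mean, decodes, scales by the cell's
#' library size, and sums the negative-binomial log-likelihood with the
#' model's dispersion. Used to compare the fit against simple baselines.
#'
#' @param model A `vae_model`.
#' @param lc `labeled_counts` gene-aligned to the model.
#' @return Total log-likelihood (a scalar).
#' @export
vae_reconstruction_loglik <- function(model, lc) {
  Y <- as_dense(lc$values)
  Z <- vae_encode(model, lc)
  RHO <- vae_decode(model, Z,
                    modality_label = if (model$conditional) lc$modality)
  MUg <- RHO * rowSums(Y)
  cat_idx <- match(lc$modality, model$modalities)
  cat_idx[is.na(cat_idx)] <- 1L
  TH <- exp(model$params$log_theta[cat_idx, , drop = FALSE])
  sum(nb_loglik_entries(Y, MUg, TH))
}

#' Transform missing-type nucleus cells through the VAE latent-space shift
#'
#' The non-conditional analogue of the PCA neighbour shift: encoder posterior
#' means replace PCA coordinates. The centroid is computed from the encoded
#' scRNA-seq training cells, shift vectors from the encoded overlapping
#' snRNA-seq cells, and each missing-type cell is moved by the mean shift
#' vector of its `k` nearest overlapping cells before decoding. Decoded
#' means are rescaled so each cell totals `L` (median scRNA-seq library by
#' default).
#'
#' @param model A non-conditional `vae_model`.
#' @param sn_overlap,sn_missing,sc_train Gene-aligned `labeled_counts`.
#' @param k Neighbour count (default 10).
#' @param L Target library size (default: median of `sc_train` totals).
#' @return `labeled_counts` of transformed cells with modality `"cell"`.
#' @export
apply_latent_shift <- function(model, sn_overlap, sn_missing, sc_train,
                               k = 10, L = NULL) {
  if (model$conditional) stop("latent-space shift uses the non-conditional model")
  if (!is.null(model$held_out) &&
      any(c(sn_overlap$cell_type, sc_train$cell_type) == model$held_out)) {
    stop("held-out type leaked into the shift anchors")
  }
  z_sc <- vae_encode(model, sc_train)
  z_ov <- vae_encode(model, sn_overlap)
  z_ms <- vae_encode(model, sn_missing)
  centroid <- colMeans(z_sc)
  shifts <- sweep(-z_ov, 2, centroid, "+")
  kk <- min(k, nrow(z_ov))
  if (kk < k) warning(sprintf("only %d anchor cells; k lowered to %d",
                              nrow(z_ov), kk))
  nn <- knn_indices(z_ms, z_ov, kk)
  shift <- do.call(rbind, lapply(seq_len(nrow(nn)), function(i) {
    colMeans(shifts[nn[i, ], , drop = FALSE])
  }))
  RHO <- vae_decode(model, z_ms + shift)
  if (is.null(L)) L <- stats::median(rowSums(as_dense(sc_train$values)))
  expr <- RHO * L
  labeled_counts(expr, cell_type = sn_missing$cell_type,
                 modality = rep("cell", nrow(expr)),
                 donor = sn_missing$donor, gene_ids = model$gene_ids,
                 cell_ids = paste0(sn_missing$cell_ids, "_vaels"),
                 dataset_tag = sn_missing$dataset_tag)
}

#' Transform missing-type nucleus cells by conditional label switching
#'
#' Cells are encoded with their true nucleus label and decoded with the cell
#' label, asking the conditional decoder to impute the whole-cell profile of
#' each nucleus. Decoded means are rescaled so each cell totals `L`.
#'
#' @param model A conditional `vae_model`.
#' @param sn_missing Gene-aligned nucleus `labeled_counts`.
#' @param L Target library size (required; use the median scRNA-seq library).
#' @param decode_label Label used at decoding (default `"cell"`; passing
#'   `"nucleus"` gives the ordinary reconstruction control path).
#' @return `labeled_counts` of transformed cells.
#' @export
apply_conditional <- function(model, sn_missing, L,
                              decode_label = "cell") {
  if (!model$conditional) stop("apply_conditional needs a conditional model")
  Z <- vae_encode(model, sn_missing, modality_label = "nucleus")
  RHO <- vae_decode(model, Z, modality_label = decode_label)
  expr <- RHO * L
  labeled_counts(expr, cell_type = sn_missing$cell_type,
                 modality = rep(if (decode_label == "cell") "cell" else "nucleus",
                                nrow(expr)),
                 donor = sn_missing$donor, gene_ids = model$gene_ids,
                 cell_ids = paste0(sn_missing$cell_ids, "_vaecond"),
                 dataset_tag = sn_missing$dataset_tag)
}
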
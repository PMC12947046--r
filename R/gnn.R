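# Distance-based graph neural scorer.
#
# Pipeline per structure: atom embedding -> n_interactions rounds of
# [message-passing interaction, shared atom-wise dense layer] -> a
# skip-connection prediction layer combining the embedding with the outputs
# of the two final atom-wise layers -> sum pooling -> linear readout to one
# scalar score.  Messages are weighted by a learnable quintic cutoff and a
# filter MLP over the RBF-expanded interatomic distance, so the score
# depends only on atomic numbers and pairwise distances (hence is invariant
# to rigid motions and atom permutations by construction).
#
# Gradients of the score with respect to every parameter are computed by
# hand-written reverse-mode differentiation (gnn_backward); no automatic
# differentiation framework is used.

#' Radial-basis-function expansion configuration
#'
#' Distances are encoded as Gaussian responses
#' `exp(-width_coefficient * (d - mu_k)^2)` on a grid of centers.  The
#' default grid has 300 centers uniformly spaced from 0 to 30 Angstrom with
#' step 0.1, and unit width coefficient (the magnitude of the scaling
#' factor; the exponent is always negative so the Gaussians decay).
#'
#' @param n_centers number of centers (default 300).
#' @param centers numeric vector of strictly increasing centers (Angstrom).
#' @param width_coefficient positive Gaussian width coefficient.
#' @return an object of class `RBFConfig`.
#' @export
rbf_config <- function(n_centers = 300L,
                       centers = seq(0, by = 0.1, length.out = n_centers),
                       width_coefficient = 1.0) {
  if (length(centers) != n_centers) {
    stop("length(centers) must equal n_centers")
  }
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("centers must be strictly increasing")
  }
  if (width_coefficient <= 0) stop("width_coefficient must be > 0")
  structure(list(n_centers = as.integer(n_centers),
                 centers = as.numeric(centers),
                 width_coefficient = as.numeric(width_coefficient)),
            class = "RBFConfig")
}

#' Shifted softplus activation
#'
#' `ssp(x) = ln(0.5 e^x + 0.5)`, a smooth activation with `ssp(0) = 0`,
#' computed overflow-safely for large `|x|`.
#'
#' @param x numeric vector/matrix.
#' @return same shape as `x`.
#' @export
shifted_softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x))) - log(2)
}

#' Expand a distance over Gaussian radial basis functions
#'
#' Component `k` is `exp(-width_coefficient * (d - mu_k)^2)`.
#'
#' @param d non-negative distance (Angstrom); vectorised.
#' @param cfg an [rbf_config()].
#' @return for scalar `d` a vector of length `n_centers`; for a vector of
#'   distances a `length(d) x n_centers` matrix.
#' @export
rbf_expand <- function(d, cfg = rbf_config()) {
  if (any(d < 0)) stop("distance must be non-negative")
  out <- exp(-cfg$width_coefficient *
               (outer(as.numeric(d), cfg$centers, `-`))^2)
  if (length(d) == 1L) drop(out) else out
}

#' Quintic cutoff decay function
#'
#' `phi(d) = 1 - 6u^5 + 15u^4 - 10u^3` with `u = d / r_cut`, clamped to 0
#' for `d > r_cut`.  Smooth, monotonically non-increasing, with vanishing
#' slope at both 0 and `r_cut`; it down-weights and eventually removes the
#' contribution of distant atoms.
#'
#' @param d non-negative distance(s) (Angstrom).
#' @param r_cut positive cutoff radius (Angstrom).
#' @return values in `[0, 1]`, same shape as `d`.
#' @export
cutoff_decay <- function(d, r_cut) {
  if (r_cut <= 0) stop("r_cut must be > 0")
  u <- d / r_cut
  out <- 1 - 6 * u^5 + 15 * u^4 - 10 * u^3
  out[u >= 1] <- 0
  out
}

# d phi / d r_cut, used for the learnable-cutoff gradient.
.cutoff_decay_drcut <- function(d, r_cut) {
  u <- d / r_cut
  dphi_du <- -30 * u^4 + 60 * u^3 - 30 * u^2
  out <- dphi_du * (-d / r_cut^2)
  out[u >= 1] <- 0
  out
}

.softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# fan-in-scaled uniform initialisation for a dense layer
.init_dense <- function(fan_in, fan_out) {
  a <- 1 / sqrt(fan_in)
  list(W = matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out),
       b = numeric(fan_out))
}

#' Initialise a GNN scorer model
#'
#' Creates all learnable quantities: the per-element embedding table,
#' per-round atom-wise weights, filter and update MLPs of each interaction,
#' the three elementwise prediction-layer vectors, the linear readout, and
#' the unconstrained cutoff parameter (mapped to `r_cut` by a softplus so
#' the learned cutoff stays positive; initialised so `r_cut` is
#' approximately `r_cut_init`).
#'
#' @param elements integer vector of atomic numbers the model can embed.
#' @param n_features feature width F (default 128).
#' @param n_interactions number of interaction/atom-wise rounds
#'   (default 3).
#' @param rbf an [rbf_config()].
#' @param r_cut_init initial cutoff radius in Angstrom (default 10).
#' @param seed integer seed for the random initialisation.
#' @return an object of class `gnn_model`.
#' @export
gnn_init <- function(elements, n_features = 128L, n_interactions = 3L,
                     rbf = rbf_config(), r_cut_init = 10, seed = 1L) {
  if (n_interactions < 1L) stop("n_interactions must be >= 1")
  elements <- sort(unique(as.integer(elements)))
  F <- as.integer(n_features)
  K <- rbf$n_centers
  T <- as.integer(n_interactions)
  params <- with_seed(seed, {
    p <- list(
      embed = matrix(stats::rnorm(length(elements) * F) / sqrt(F),
                     length(elements), F,
                     dimnames = list(as.character(elements), NULL)),
      atomwise = lapply(seq_len(T), function(t) .init_dense(F, F)),
      filter = lapply(seq_len(T), function(t) {
        list(inner = .init_dense(K, F), outer = .init_dense(F, F))
      }),
      update = lapply(seq_len(T), function(t) {
        list(inner = .init_dense(F, F), outer = .init_dense(F, F))
      }),
      pred = list(u = stats::runif(F, -1, 1),
                  w1 = stats::runif(F, -1, 1),
                  w2 = stats::runif(F, -1, 1)),
      readout = .init_dense(F, 1L)
    )
    p$readout$W <- drop(p$readout$W)
    p$readout$b <- as.numeric(p$readout$b)
    p$cutoff_raw <- log(expm1(r_cut_init))
    p
  })
  structure(list(params = params, elements = elements, n_features = F,
                 n_interactions = T, rbf = rbf, seed = as.integer(seed)),
            class = "gnn_model")
}

#' @export
print.gnn_model <- function(x, ...) {
  cat("<gnn_model> F=", x$n_features, " interactions=", x$n_interactions,
      " elements={", paste(x$elements, collapse = ","), "} r_cut=",
      signif(r_cut(x), 4), " (", length(unlist(x$params)),
      " parameters)\n", sep = "")
  invisible(x)
}

#' Current cutoff radius of a model
#'
#' @param model a `gnn_model`.
#' @return `r_cut` in Angstrom (softplus of the raw parameter).
#' @export
r_cut <- function(model) .softplus(model$params$cutoff_raw)

#' Embed atoms into initial feature vectors
#'
#' Row `i` of the result is the learned embedding of element `Z_i`; atoms
#' with equal atomic number receive identical rows.
#'
#' @param atomic_numbers integer vector of nuclear charges.
#' @param model a `gnn_model`.
#' @return `n x F` feature matrix (layer 0).
#' @export
embed_atoms <- function(atomic_numbers, model) {
  rows <- match(as.integer(atomic_numbers), model$elements)
  if (anyNA(rows)) {
    bad <- unique(atomic_numbers[is.na(rows)])
    stop("element(s) not in embedding table: Z = ",
         paste(bad, collapse = ", "))
  }
  model$params$embed[rows, , drop = FALSE]
}

#' Apply a shared atom-wise dense layer
#'
#' Every atom's feature row is mapped by the same affine transform
#' `x W + b`; weights are shared across atoms.
#'
#' @param features `n x F` feature matrix.
#' @param layer which atom-wise layer (1-based round index).
#' @param model a `gnn_model`.
#' @return updated `n x F` matrix.
#' @export
atom_wise <- function(features, layer, model) {
  lay <- model$params$atomwise[[layer]]
  if (ncol(features) != nrow(lay$W)) {
    stop("feature width ", ncol(features), " does not match layer input ",
         nrow(lay$W))
  }
  sweep(features %*% lay$W, 2L, lay$b, `+`)
}

# --- internal pair-level machinery -----------------------------------------

# Ordered atom pairs (i, j != i) with distances and RBF rows for one
# structure; parameter-independent, so it can be cached across epochs.
gnn_cache <- function(structure, model) {
  zrow <- match(structure$atomic_numbers, model$elements)
  if (anyNA(zrow)) {
    bad <- unique(structure$atomic_numbers[is.na(zrow)])
    stop("element(s) not in embedding table: Z = ",
         paste(bad, collapse = ", "))
  }
  n <- length(structure$atomic_numbers)
  if (n > 1L) {
    D <- distance_matrix(structure$positions)
    idx <- which(row(D) != col(D))
    ii <- row(D)[idx]
    jj <- col(D)[idx]
    dvec <- D[idx]
    R <- rbf_expand(dvec, model$rbf)
    if (is.null(dim(R))) R <- matrix(R, nrow = length(dvec))
  } else {
    ii <- jj <- integer(0)
    dvec <- numeric(0)
    R <- matrix(0, 0, model$rbf$n_centers)
  }
  list(n = n, zrow = zrow, ii = ii, jj = jj, dvec = dvec, R = R)
}

# rowsum into exactly n rows (rowsum() drops absent groups)
.rowsum_n <- function(x, g, n) {
  out <- matrix(0, n, ncol(x))
  if (nrow(x)) {
    tmp <- rowsum(x, g)
    out[as.integer(rownames(tmp)), ] <- tmp
  }
  out
}

# One interaction step on feature matrix X given cache and round t.
# Returns the updated features and (if keep) the intermediates needed by
# the backward pass.
.interaction_forward <- function(X, cache, model, t, phi, keep = FALSE) {
  p <- model$params
  n <- cache$n
  F <- model$n_features
  if (length(cache$ii)) {
    fil <- p$filter[[t]]
    H1 <- sweep(cache$R %*% fil$inner$W, 2L, fil$inner$b, `+`)
    S1 <- shifted_softplus(H1)
    Fm <- sweep(S1 %*% fil$outer$W, 2L, fil$outer$b, `+`)
    G <- phi * Fm
    M <- .rowsum_n(X[cache$jj, , drop = FALSE] * G, cache$ii, n)
  } else {
    H1 <- S1 <- Fm <- G <- matrix(0, 0, F)
    M <- matrix(0, n, F)
  }
  upd <- p$update[[t]]
  Z1 <- sweep(M %*% upd$inner$W, 2L, upd$inner$b, `+`)
  S2 <- shifted_softplus(Z1)
  Y <- X + sweep(S2 %*% upd$outer$W, 2L, upd$outer$b, `+`)
  if (!keep) return(list(Y = Y))
  list(Y = Y, X = X, H1 = H1, S1 = S1, Fm = Fm, M = M, Z1 = Z1, S2 = S2)
}

#' One message-passing interaction step
#'
#' Each atom receives the cutoff- and filter-weighted features of all other
#' atoms: `m_i = sum_{j != i} phi(d_ij) * x_j (*) FilterMLP(rbf(d_ij))`,
#' followed by a residual update `x_i + UpdateMLP(m_i)`.  Both MLPs are
#' dense -> shifted softplus -> dense.
#'
#' @param features `n x F` feature matrix.
#' @param distances symmetric `n x n` distance matrix (Angstrom) with zero
#'   diagonal and positive off-diagonal entries.
#' @param model a `gnn_model`.
#' @param layer interaction round whose weights to use (default 1).
#' @return updated `n x F` feature matrix.
#' @export
interaction_step <- function(features, distances, model, layer = 1L) {
  distances <- as.matrix(distances)
  n <- nrow(features)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(distances)) > 1e-12)) {
    stop("distance matrix must have a zero diagonal")
  }
  if (n > 1L && any(distances[row(distances) != col(distances)] <= 0)) {
    stop("off-diagonal distances must be positive")
  }
  idx <- which(row(distances) != col(distances))
  dvec <- distances[idx]
  R <- rbf_expand(dvec, model$rbf)
  if (is.null(dim(R))) R <- matrix(R, nrow = length(dvec))
  cache <- list(n = n, ii = row(distances)[idx], jj = col(distances)[idx],
                dvec = dvec, R = R)
  phi <- cutoff_decay(dvec, r_cut(model))
  .interaction_forward(features, cache, model, layer, phi)$Y
}

#' Skip-connection prediction layer
#'
#' Merges the embedding with the outputs of the two final atom-wise layers
#' by learned elementwise gates:
#' `p_i = u (*) E_i + w1 (*) atw1_i + w2 (*) atw2_i`.
#'
#' @param embedding `n x F` layer-0 features.
#' @param atw1,atw2 `n x F` outputs of the two tapped atom-wise layers.
#' @param model a `gnn_model`.
#' @return `n x F` matrix of per-atom vectors `p_i`.
#' @export
prediction_layer <- function(embedding, atw1, atw2, model) {
  F <- model$n_features
  dims <- list(dim(embedding), dim(atw1), dim(atw2))
  if (length(unique(dims)) != 1L || ncol(embedding) != F) {
    stop("embedding, atw1, atw2 must share shape n x ", F)
  }
  n <- nrow(embedding)
  p <- model$params$pred
  embedding * rep(p$u, each = n) + atw1 * rep(p$w1, each = n) +
    atw2 * rep(p$w2, each = n)
}

# Full forward pass from a geometry cache.  keep=TRUE retains every
# intermediate required by gnn_backward.
gnn_forward <- function(cache, model, keep = FALSE) {
  p <- model$params
  n <- cache$n
  T <- model$n_interactions
  rcut <- .softplus(p$cutoff_raw)
  phi <- if (length(cache$dvec)) cutoff_decay(cache$dvec, rcut) else numeric(0)
  X0 <- p$embed[cache$zrow, , drop = FALSE]
  X <- X0
  rounds <- vector("list", T)
  A <- vector("list", T)
  for (t in seq_len(T)) {
    it <- .interaction_forward(X, cache, model, t, phi, keep = keep)
    At <- sweep(it$Y %*% p$atomwise[[t]]$W, 2L, p$atomwise[[t]]$b, `+`)
    if (keep) {
      it$A <- At
      rounds[[t]] <- it
    }
    A[[t]] <- At
    X <- At
  }
  t1 <- max(1L, T - 1L)
  P <- X0 * rep(p$pred$u, each = n) + A[[t1]] * rep(p$pred$w1, each = n) +
    A[[T]] * rep(p$pred$w2, each = n)
  pooled <- colSums(P)
  score <- sum(pooled * p$readout$W) + p$readout$b
  if (!keep) return(list(score = score))
  list(score = score, X0 = X0, A = A, P = P, pooled = pooled,
       rounds = rounds, phi = phi, rcut = rcut, t1 = t1)
}

# Zero-filled gradient skeleton matching model$params.
gnn_zero_grad <- function(model) {
  rapply(model$params, function(x) {
    z <- x
    z[] <- 0
    z
  }, how = "replace")
}

# Reverse-mode gradient of the score w.r.t. every parameter.  `fw` must be
# the output of gnn_forward(..., keep = TRUE).  Returns a list shaped like
# model$params.  When `grad` is supplied, gradients are accumulated into it
# after scaling by `weight` (d loss / d score).
gnn_backward <- function(cache, model, fw, weight = 1, grad = NULL) {
  p <- model$params
  n <- cache$n
  F <- model$n_features
  T <- model$n_interactions
  if (is.null(grad)) grad <- gnn_zero_grad(model)
  w <- weight

  # readout
  grad$readout$b <- grad$readout$b + w
  grad$readout$W <- grad$readout$W + w * fw$pooled
  dP <- matrix(w * p$readout$W, n, F, byrow = TRUE)

  # prediction layer
  grad$pred$u <- grad$pred$u + colSums(dP * fw$X0)
  grad$pred$w1 <- grad$pred$w1 + colSums(dP * fw$A[[fw$t1]])
  grad$pred$w2 <- grad$pred$w2 + colSums(dP * fw$A[[T]])
  dX0 <- dP * rep(p$pred$u, each = n)
  dA <- vector("list", T)
  for (t in seq_len(T)) dA[[t]] <- matrix(0, n, F)
  dA[[fw$t1]] <- dA[[fw$t1]] + dP * rep(p$pred$w1, each = n)
  dA[[T]] <- dA[[T]] + dP * rep(p$pred$w2, each = n)

  drcut <- 0
  dX_down <- matrix(0, n, F)
  for (t in rev(seq_len(T))) {
    rd <- fw$rounds[[t]]
    dAt <- dA[[t]] + dX_down
    # atom-wise: A = Y W + b
    grad$atomwise[[t]]$W <- grad$atomwise[[t]]$W + crossprod(rd$Y, dAt)
    grad$atomwise[[t]]$b <- grad$atomwise[[t]]$b + colSums(dAt)
    dY <- tcrossprod(dAt, p$atomwise[[t]]$W)
    # update MLP: Y = X + ssp(M U1 + c1) U2 + c2
    upd <- p$update[[t]]
    grad$update[[t]]$outer$b <- grad$update[[t]]$outer$b + colSums(dY)
    grad$update[[t]]$outer$W <- grad$update[[t]]$outer$W +
      crossprod(rd$S2, dY)
    dS2 <- tcrossprod(dY, upd$outer$W)
    dZ1 <- dS2 * sigmoid(rd$Z1)
    grad$update[[t]]$inner$b <- grad$update[[t]]$inner$b + colSums(dZ1)
    grad$update[[t]]$inner$W <- grad$update[[t]]$inner$W +
      crossprod(rd$M, dZ1)
    dM <- tcrossprod(dZ1, upd$inner$W)
    dXin <- dY
    if (length(cache$ii)) {
      fil <- p$filter[[t]]
      dMi <- dM[cache$ii, , drop = FALSE]
      Xj <- rd$X[cache$jj, , drop = FALSE]
      G <- fw$phi * rd$Fm
      dG <- Xj * dMi
      dXin <- dXin + .rowsum_n(G * dMi, cache$jj, n)
      dFm <- fw$phi * dG
      dphi <- rowSums(rd$Fm * dG)
      grad$filter[[t]]$outer$b <- grad$filter[[t]]$outer$b + colSums(dFm)
      grad$filter[[t]]$outer$W <- grad$filter[[t]]$outer$W +
        crossprod(rd$S1, dFm)
      dS1 <- tcrossprod(dFm, fil$outer$W)
      dH1 <- dS1 * sigmoid(rd$H1)
      grad$filter[[t]]$inner$b <- grad$filter[[t]]$inner$b + colSums(dH1)
      grad$filter[[t]]$inner$W <- grad$filter[[t]]$inner$W +
        crossprod(cache$R, dH1)
      drcut <- drcut + sum(dphi * .cutoff_decay_drcut(cache$dvec, fw$rcut))
    }
    dX_down <- dXin
  }
  dX0 <- dX0 + dX_down
  # embedding rows (scatter-add by element row)
  demb <- .rowsum_n(dX0, cache$zrow, nrow(p$embed))
  grad$embed <- grad$embed + demb
  grad$cutoff_raw <- grad$cutoff_raw + drcut * sigmoid(p$cutoff_raw)
  grad
}

#' Score one structure with the GNN
#'
#' Runs the full pipeline (embedding, interaction/atom-wise rounds,
#' prediction layer, sum pooling, linear readout) and returns the scalar
#' score.  The score is deterministic given the parameters and invariant to
#' rigid rotation, translation, and atom permutation of the input.
#'
#' @param model a `gnn_model`.
#' @param structure a `Structure`.
#' @return a single numeric score.
#' @export
forward_score <- function(model, structure) {
  gnn_forward(gnn_cache(structure, model), model)$score
}

#' Score a list of structures
#'
#' @param model a `gnn_model`.
#' @param structures list of `Structure` objects.
#' @return numeric vector of scores, named by structure id.
#' @export
score_structures <- function(model, structures) {
  out <- vapply(structures, function(s) forward_score(model, s), numeric(1))
  names(out) <- vapply(structures, function(s) s$structure_id, character(1))
  out
}

#' Turn a model into a scoring function
#'
#' @param model a `gnn_model` or `mlp_model`.
#' @return a function mapping one structure (or embedding vector) to its
#'   scalar score; usable wherever a scorer is expected.
#' @export
as_scorer <- function(model) {
  if (inherits(model, "gnn_model")) {
    function(x) forward_score(model, x)
  } else if (inherits(model, "mlp_model")) {
    function(x) mlp_head_score(model, x)
  } else {
    stop("no scorer available for class ", paste(class(model), collapse = "/"))
  }
}
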
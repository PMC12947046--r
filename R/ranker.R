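# Siamese pairwise combination and training objectives.
#
# Both branches of the Siamese ranker are the SAME scorer applied twice
# (shared weights), and the pair output is a logistic of the score
# difference.  Antisymmetry -- p(a,b) + p(b,a) = 1 -- and reflexivity --
# p(x,x) = 0.5 -- therefore hold exactly by construction, not by learning.

.PROB_CLIP <- 1e-7

#' Probability that structure a outranks structure b
#'
#' The logistic-difference head: `p = 1 / (1 + exp(-(score_a - score_b)))`.
#' Exactly antisymmetric in its arguments.
#'
#' @param score_a,score_b branch scores (vectorised).
#' @return probability in (0, 1).
#' @export
pairwise_probability <- function(score_a, score_b) {
  sigmoid(score_a - score_b)
}

#' Pairwise cross-entropy loss
#'
#' Binary cross-entropy between the predicted outranking probability and a
#' (possibly soft) pair label: `-(l1 log p + l2 log(1 - p))`.  The
#' probability is clipped to `[1e-7, 1 - 1e-7]` for numerical stability;
#' tie labels (0.5, 0.5) are handled natively.
#'
#' @param probability predicted probability in (0, 1) (vectorised).
#' @param label length-2 numeric label summing to 1, e.g. `c(1, 0)`.
#' @return non-negative loss value(s).
#' @export
entropy_loss <- function(probability, label) {
  p <- pmin(pmax(probability, .PROB_CLIP), 1 - .PROB_CLIP)
  -(label[1] * log(p) + label[2] * log(1 - p))
}

#' Pairwise squared loss on score differences
#'
#' The regression variant of pairwise training: the scorer difference is
#' regressed on the true property difference,
#' `((score_a - score_b) - target_diff)^2`.  Swapping the pair and negating
#' the target leaves the loss unchanged.
#'
#' @param score_a,score_b branch scores.
#' @param target_diff true property difference `t_a - t_b`.
#' @return non-negative loss.
#' @export
squared_pair_loss <- function(score_a, score_b, target_diff) {
  ((score_a - score_b) - target_diff)^2
}

#' Pointwise squared loss
#'
#' The traditional regression baseline: each structure's score is regressed
#' on its property value independently, `(score - target)^2`.
#'
#' @param score predicted score.
#' @param target true property value.
#' @return non-negative loss.
#' @export
pointwise_loss <- function(score, target) {
  (score - target)^2
}

# ---------------------------------------------------------------------------
# MLP head over precomputed molecular embeddings
# ---------------------------------------------------------------------------

#' Initialise an MLP head for precomputed embeddings
#'
#' A small feed-forward scorer for fixed-length molecular embedding vectors
#' (e.g. from a pretrained 3-D representation model):
#' dense(128) -> tanh -> dense(64) -> tanh -> dense(1), the final layer
#' linear.  Trained with the same pairwise/pointwise objectives as the GNN.
#'
#' @param input_dim embedding length D.
#' @param hidden widths of the two hidden layers (default `c(128, 64)`).
#' @param seed integer seed for initialisation.
#' @return an object of class `mlp_model`.
#' @export
mlp_init <- function(input_dim, hidden = c(128L, 64L), seed = 1L) {
  dims <- c(as.integer(input_dim), as.integer(hidden), 1L)
  params <- with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(i) {
      .init_dense(dims[i], dims[i + 1L])
    })
  })
  structure(list(params = params, input_dim = as.integer(input_dim),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> input=", x$input_dim, " hidden=",
      paste(x$hidden, collapse = "->"), "->1\n", sep = "")
  invisible(x)
}

# forward pass keeping intermediates for backprop
mlp_forward <- function(model, x, keep = FALSE) {
  p <- model$params
  L <- length(p)
  if (length(x) != model$input_dim) {
    stop("embedding length ", length(x), " does not match head input width ",
         model$input_dim)
  }
  a <- matrix(as.numeric(x), 1L)
  acts <- vector("list", L)
  pre <- vector("list", L)
  for (i in seq_len(L)) {
    acts[[i]] <- a
    z <- a %*% p[[i]]$W + matrix(p[[i]]$b, 1L)
    pre[[i]] <- z
    a <- if (i < L) tanh(z) else z
  }
  if (!keep) return(list(score = drop(a)))
  list(score = drop(a), acts = acts, pre = pre)
}

# gradient of score w.r.t. parameters, scaled by weight, accumulated in grad
mlp_backward <- function(model, fw, weight = 1, grad = NULL) {
  p <- model$params
  L <- length(p)
  if (is.null(grad)) {
    grad <- rapply(p, function(x) { x[] <- 0; x }, how = "replace")
  }
  da <- matrix(weight, 1L, 1L)
  for (i in rev(seq_len(L))) {
    dz <- if (i < L) da * (1 - tanh(fw$pre[[i]])^2) else da
    grad[[i]]$W <- grad[[i]]$W + crossprod(fw$acts[[i]], dz)
    grad[[i]]$b <- grad[[i]]$b + drop(dz)
    da <- tcrossprod(dz, p[[i]]$W)
  }
  grad
}

#' Score an embedding vector with the MLP head
#'
#' @param model an `mlp_model`.
#' @param vector numeric embedding of length `input_dim`.
#' @return a single numeric score (deterministic).
#' @export
mlp_head_score <- function(model, vector) {
  mlp_forward(model, vector)$score
}

#' Read an embedding table from a delimited file
#'
#' Expects columns `structure_id`, `group_id`, any number of property
#' columns, then the embedding columns `v0 .. v(D-1)`.
#'
#' @param path file path (csv or tsv, header required).
#' @return list with `records` (data.frame of ids and properties),
#'   `vectors` (numeric matrix, one row per record), and `dim`.
#' @export
read_embedding_table <- function(path) {
  df <- read_property_table(path)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (!length(vcols)) stop("no embedding columns v0..v(D-1) found")
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  vectors <- as.matrix(df[, vcols, drop = FALSE])
  storage.mode(vectors) <- "double"
  if (!all(is.finite(vectors))) stop("non-finite embedding entries")
  records <- df[, setdiff(names(df), vcols), drop = FALSE]
  list(records = records, vectors = vectors, dim = length(vcols))
}

#' Build pair examples from an embedding table
#'
#' The embedding analogue of [make_all_pairs()]: pairs are drawn within
#' each `group_id`, labelled by the property comparison, and carry the two
#' embedding vectors in place of structures.
#'
#' @param table result of [read_embedding_table()] (or a list with
#'   `records` and `vectors`).
#' @param property_name property column to compare.
#' @param budget maximum pairs per group (default all).
#' @param seed integer seed.
#' @param tie_tol absolute tie tolerance (default 0).
#' @return list of `PairExample` objects whose `a`/`b` are numeric vectors.
#' @export
make_embedding_pairs <- function(table, property_name, budget = Inf,
                                 seed = 1L, tie_tol = 0) {
  rec <- table$records
  if (!property_name %in% names(rec)) {
    stop("property '", property_name, "' not in table; available: ",
         paste(setdiff(names(rec), c("structure_id", "group_id")),
               collapse = ", "))
  }
  out <- list()
  gids <- unique(rec$group_id)
  for (gi in seq_along(gids)) {
    idx <- which(rec$group_id == gids[gi])
    if (length(idx) < 2L) next
    vals <- as.numeric(rec[[property_name]][idx])
    cmb <- utils::combn(length(idx), 2L)
    with_seed(seed + gi, {
      if (budget < ncol(cmb)) {
        cmb <- cmb[, sample.int(ncol(cmb), budget), drop = FALSE]
      }
      flip <- sample(c(TRUE, FALSE), ncol(cmb), replace = TRUE)
    })
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1L, k]; j <- cmb[2L, k]
      if (flip[k]) { tmp <- i; i <- j; j <- tmp }
      d <- vals[i] - vals[j]
      label <- if (abs(d) <= tie_tol) c(0.5, 0.5) else if (d > 0) c(1, 0) else
        c(0, 1)
      if (abs(d) <= tie_tol) d <- 0
      out[[length(out) + 1L]] <- structure(
        list(a = table$vectors[idx[i], ], b = table$vectors[idx[j], ],
             label = label, target_diff = d),
        class = "PairExample")
    }
  }
  out
}
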
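# Seeded mini-batch training for the three objectives (pairwise entropy,
# pairwise squared, pointwise) over either the GNN backbone or the MLP
# embedding head.  Gradients come from the hand-written backward passes;
# the optimiser works on a flat parameter vector (unlist/relist round
# trip), so both model families share one loop.

.OBJECTIVES <- c("pairwise_entropy", "pairwise_squared", "pointwise")

#' Training configuration
#'
#' Defaults follow the reference protocol for large-ensemble training:
#' batches of 64 pairs, up to 60 epochs, learning rate 1e-4.  The optimiser
#' is Adam (standard moment coefficients); plain stochastic gradient
#' descent is available via `optimizer = "sgd"`.
#'
#' @param objective one of `"pairwise_entropy"`, `"pairwise_squared"`,
#'   `"pointwise"`.
#' @param batch_size examples per batch (pairs for pairwise objectives).
#' @param max_epochs maximum number of epochs.
#' @param learning_rate optimiser step size.
#' @param seed integer seed controlling shuffling (and nothing else).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param patience if a validation set is supplied to [train()], stop after
#'   this many epochs without improvement (`NULL`, the default, disables
#'   early stopping).
#' @param verbose emit one log line per epoch to stderr.
#' @param log_file optional path; epoch log lines are appended there too.
#' @return an object of class `TrainConfig`.
#' @export
train_config <- function(objective = "pairwise_entropy", batch_size = 64L,
                         max_epochs = 60L, learning_rate = 1e-4, seed = 1L,
                         optimizer = c("adam", "sgd"), patience = NULL,
                         verbose = FALSE, log_file = NULL) {
  objective <- match.arg(objective, .OBJECTIVES)
  optimizer <- match.arg(optimizer)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  structure(list(objective = objective, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 optimizer = optimizer, patience = patience,
                 verbose = isTRUE(verbose), log_file = log_file),
            class = "TrainConfig")
}

#' Pointwise training example
#'
#' @param x a `Structure` (GNN path) or numeric embedding vector (MLP path).
#' @param target the property value to regress on.
#' @return an object of class `PointExample`.
#' @export
point_example <- function(x, target) {
  structure(list(x = as_input(x), target = as.numeric(target)),
            class = "PointExample")
}

as_input <- function(x) x

#' Build pointwise examples from conformer groups
#'
#' One example per structure.  Targets can optionally be standardised
#' (z-scored over the whole training set), the usual practice when property
#' scales are large.
#'
#' @param groups list of `ConformerGroup`.
#' @param property_name property to regress on.
#' @param standardize z-score the targets (default TRUE).
#' @return list of `PointExample`; the standardisation constants are
#'   attached as attributes `center` and `scale`.
#' @export
make_pointwise_examples <- function(groups, property_name,
                                    standardize = TRUE) {
  structs <- do.call(c, lapply(groups, function(g) g$structures))
  targets <- vapply(structs, function(s) {
    v <- s$properties[[property_name]]
    if (is.null(v)) {
      stop("structure '", s$structure_id, "' lacks property '",
           property_name, "'")
    }
    as.numeric(v)
  }, numeric(1))
  ctr <- 0; scl <- 1
  if (standardize) {
    ctr <- mean(targets)
    scl <- stats::sd(targets)
    if (!is.finite(scl) || scl == 0) scl <- 1
    targets <- (targets - ctr) / scl
  }
  out <- Map(point_example, structs, targets)
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

# --- model-family dispatch --------------------------------------------------

.fw_one <- function(model, x, keep, cache_env) {
  if (inherits(model, "gnn_model")) {
    key <- x$structure_id
    cache <- if (!is.null(cache_env) && !is.null(cache_env[[key]])) {
      cache_env[[key]]
    } else {
      cc <- gnn_cache(x, model)
      if (!is.null(cache_env)) cache_env[[key]] <- cc
      cc
    }
    fw <- gnn_forward(cache, model, keep = keep)
    fw$cache <- cache
    fw
  } else {
    mlp_forward(model, x, keep = keep)
  }
}

.bw_one <- function(model, fw, weight, grad) {
  if (inherits(model, "gnn_model")) {
    gnn_backward(fw$cache, model, fw, weight = weight, grad = grad)
  } else {
    mlp_backward(model, fw, weight = weight, grad = grad)
  }
}

.zero_grad <- function(model) {
  rapply(model$params, function(x) { x[] <- 0; x }, how = "replace")
}

# Mean loss over a batch and (optionally) the accumulated mean gradient.
.batch_loss_grad <- function(model, batch, objective, with_grad = TRUE,
                             cache_env = NULL) {
  n <- length(batch)
  grad <- if (with_grad) .zero_grad(model) else NULL
  total <- 0
  for (ex in batch) {
    if (objective == "pointwise") {
      fw <- .fw_one(model, ex$x, keep = with_grad, cache_env)
      total <- total + pointwise_loss(fw$score, ex$target)
      if (with_grad) {
        grad <- .bw_one(model, fw, weight = 2 * (fw$score - ex$target) / n,
                        grad = grad)
      }
    } else {
      fa <- .fw_one(model, ex$a, keep = with_grad, cache_env)
      fb <- .fw_one(model, ex$b, keep = with_grad, cache_env)
      if (objective == "pairwise_entropy") {
        p <- pairwise_probability(fa$score, fb$score)
        total <- total + entropy_loss(p, ex$label)
        w <- (p - ex$label[1]) / n
      } else {
        r <- (fa$score - fb$score) - ex$target_diff
        total <- total + r^2
        w <- 2 * r / n
      }
      if (with_grad) {
        grad <- .bw_one(model, fa, weight = w, grad = grad)
        grad <- .bw_one(model, fb, weight = -w, grad = grad)
      }
    }
  }
  list(loss = total / n, grad = grad)
}

#' Mean loss of a model on a data set
#'
#' Evaluation only (no gradients, no updates); useful for validation and
#' for checking calibration properties such as the expected ln 2
#' cross-entropy of an uninformed scorer on balanced pairs.
#'
#' @param model a `gnn_model` or `mlp_model`.
#' @param data list of `PairExample` (pairwise objectives) or
#'   `PointExample` (pointwise).
#' @param objective one of the three training objectives.
#' @return mean loss (single numeric).
#' @export
batch_loss <- function(model, data, objective = "pairwise_entropy") {
  objective <- match.arg(objective, .OBJECTIVES)
  .batch_loss_grad(model, data, objective, with_grad = FALSE)$loss
}

#' Train a model
#'
#' Seeded mini-batch gradient training.  Data are shuffled each epoch with
#' a deterministic stream derived from `cfg$seed`, so identical
#' (model, data, config) inputs reproduce identical loss traces and final
#' parameters.  Training aborts with a diagnostic naming the epoch and
#' batch if a non-finite loss appears.
#'
#' @param model a `gnn_model` or `mlp_model`.
#' @param data list of `PairExample` (for the pairwise objectives) or
#'   `PointExample` (for pointwise).
#' @param cfg a [train_config()].
#' @param validation optional held-out examples of the same shape; when
#'   supplied together with `cfg$patience`, training stops early once the
#'   validation loss has not improved for `patience` epochs.
#' @return a `TrainReport`: list with the trained `model`, `loss_trace`
#'   (per-epoch mean training loss), optional `validation_trace`, `seed`,
#'   and `seconds` (wall clock).
#' @export
train <- function(model, data, cfg = train_config(), validation = NULL) {
  stopifnot(inherits(cfg, "TrainConfig"))
  if (!length(data)) stop("data is empty")
  kind <- class(data[[1]])[1]
  if (cfg$objective == "pointwise" && kind != "PointExample") {
    stop("pointwise objective needs PointExample data, got ", kind)
  }
  if (cfg$objective != "pointwise" && kind != "PairExample") {
    stop("pairwise objectives need PairExample data, got ", kind)
  }
  t0 <- proc.time()[["elapsed"]]
  cache_env <- new.env(parent = emptyenv())
  flat <- unlist(model$params, use.names = FALSE)
  skeleton <- model$params
  m <- v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(data)
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- Inf
  stall <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      epoch_sum <- 0
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
        lg <- .batch_loss_grad(model, data[idx], cfg$objective,
                               with_grad = TRUE, cache_env = cache_env)
        if (!is.finite(lg$loss)) {
          stop("non-finite loss at epoch ", epoch, ", batch ", bi)
        }
        epoch_sum <- epoch_sum + lg$loss * length(idx)
        g <- unlist(lg$grad, use.names = FALSE)
        if (cfg$optimizer == "adam") {
          step <- step + 1L
          m <- b1 * m + (1 - b1) * g
          v <- b2 * v + (1 - b2) * g * g
          mhat <- m / (1 - b1^step)
          vhat <- v / (1 - b2^step)
          flat <- flat - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        } else {
          flat <- flat - cfg$learning_rate * g
        }
        model$params <- utils::relist(flat, skeleton)
      }
      loss_trace[epoch] <- epoch_sum / n
      msg <- sprintf("epoch %d mean_loss %.6g elapsed_s %.1f", epoch,
                     loss_trace[epoch], proc.time()[["elapsed"]] - t0)
      if (cfg$verbose) message(msg)
      if (!is.null(cfg$log_file)) cat(msg, "\n", file = cfg$log_file,
                                      append = TRUE)
      if (!is.null(validation) && !is.null(cfg$patience)) {
        vl <- batch_loss(model, validation, cfg$objective)
        val_trace[epoch] <- vl
        if (vl < best_val - 1e-12) {
          best_val <- vl
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= cfg$patience) break
        }
      }
    }
  })
  structure(list(model = model, loss_trace = loss_trace,
                 validation_trace = if (length(val_trace)) val_trace,
                 seed = cfg$seed, config = cfg,
                 seconds = proc.time()[["elapsed"]] - t0),
            class = "TrainReport")
}

#' @export
print.TrainReport <- function(x, ...) {
  cat("<TrainReport> epochs=", length(x$loss_trace), " final_loss=",
      signif(utils::tail(x$loss_trace, 1), 6), " seconds=",
      round(x$seconds, 1), "\n", sep = "")
  invisible(x)
}
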
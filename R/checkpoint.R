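# Plain-text (JSON) checkpoints: a metadata block describing the
# architecture plus the flat parameter vector.  The model is rebuilt from
# the metadata and the parameters are poured back into its skeleton, so a
# checkpoint is self-describing and portable.

#' Save a model checkpoint
#'
#' Writes a single JSON document with a metadata block (model family,
#' feature width, interaction count, RBF configuration, element palette,
#' current cutoff) and all parameters as one named numeric array.
#'
#' @param model a `gnn_model` or `mlp_model`.
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  meta <- if (inherits(model, "gnn_model")) {
    list(family = "gnn", n_features = model$n_features,
         n_interactions = model$n_interactions, elements = model$elements,
         rbf = list(n_centers = model$rbf$n_centers,
                    centers = model$rbf$centers,
                    width_coefficient = model$rbf$width_coefficient),
         r_cut = r_cut(model))
  } else if (inherits(model, "mlp_model")) {
    list(family = "mlp", input_dim = model$input_dim, hidden = model$hidden)
  } else {
    stop("cannot checkpoint class ", paste(class(model), collapse = "/"))
  }
  jsonlite::write_json(
    list(metadata = meta,
         parameters = unlist(model$params, use.names = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path written by [save_checkpoint()].
#' @return the reconstructed `gnn_model` or `mlp_model`.
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  meta <- doc$metadata
  model <- if (identical(meta$family, "gnn")) {
    gnn_init(elements = meta$elements, n_features = meta$n_features,
             n_interactions = meta$n_interactions,
             rbf = rbf_config(meta$rbf$n_centers, meta$rbf$centers,
                              meta$rbf$width_coefficient),
             seed = 0L)
  } else if (identical(meta$family, "mlp")) {
    mlp_init(meta$input_dim, meta$hidden, seed = 0L)
  } else {
    stop("unknown checkpoint family: ", meta$family)
  }
  flat <- as.numeric(doc$parameters)
  skel <- model$params
  if (length(flat) != length(unlist(skel, use.names = FALSE))) {
    stop("parameter count mismatch in checkpoint ", path)
  }
  model$params <- utils::relist(flat, skel)
  model
}
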
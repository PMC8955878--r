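#' Save a trained model bundle
#'
#' Writes a self-describing model directory: for a convolutional net, a
#' JSON architecture/weights file plus the scaler sidecar and label order;
#' for the two-criteria tree, its fitted object plus a JSON descriptor.
#'
#' @param model a `glove_net` or `glove_tree`.
#' @param dir bundle directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(model, "glove_net")) {
    desc <- list(
      kind = "cnn", task = model$task, ns = model$ns,
      n_channels = model$n_channels, width = model$width,
      filters = model$filters, dense = model$dense,
      labels = model$labels,
      params = lapply(model$params, function(p) {
        if (is.matrix(p)) list(dim = dim(p), values = as.numeric(p))
        else list(dim = length(p), values = as.numeric(p))
      }))
    jsonlite::write_json(desc, file.path(dir, "model.json"),
                         digits = NA, auto_unbox = TRUE)
    if (!is.null(model$scaler)) {
      write_scaler(model$scaler, file.path(dir, "scaler.json"))
    }
  } else if (inherits(model, "glove_tree")) {
    jsonlite::write_json(list(kind = "tree", max_depth = model$max_depth),
                         file.path(dir, "model.json"), auto_unbox = TRUE)
    saveRDS(model, file.path(dir, "tree.rds"))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  path <- file.path(dir, "model.json")
  if (!file.exists(path)) stop("no model.json under ", dir, call. = FALSE)
  desc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(desc$kind, "tree")) {
    return(readRDS(file.path(dir, "tree.rds")))
  }
  net <- build_net(desc$task, ns = desc$ns, n_channels = desc$n_channels,
                   filters = desc$filters, dense = desc$dense)
  for (k in names(net$params)) {
    v <- desc$params[[k]]$values
    d <- desc$params[[k]]$dim
    net$params[[k]] <- if (length(d) == 2L) matrix(v, d[1L], d[2L]) else v
  }
  sc <- file.path(dir, "scaler.json")
  if (file.exists(sc)) net$scaler <- read_scaler(sc)
  net$trained <- TRUE
  net
}
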
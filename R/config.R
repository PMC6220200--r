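#' Assemble a run configuration
#'
#' A run configuration bundles the global seed, output directory, logging
#' level and the nested architecture / training / phantom parameter blocks.
#' It round-trips losslessly through JSON ([write_config()] /
#' [read_config()]), and every command-line flag can override one of its
#' fields.
#'
#' @param seed integer global seed; per-component seeds are derived from it
#'   with [derive_seed()] so adding a pipeline stage never perturbs the
#'   randomness of earlier stages.
#' @param output_dir directory where artifacts are written.
#' @param log_level one of `"quiet"`, `"info"`, `"debug"`.
#' @param architecture an [architecture_spec()] or NULL.
#' @param train a [train_config()] or NULL.
#' @param phantom a [phantom_params()] or NULL.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, output_dir = ".", log_level = "info",
                       architecture = NULL, train = NULL, phantom = NULL) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("run_config: seed must be an integer", call. = FALSE)
  log_level <- match.arg(log_level, c("quiet", "info", "debug"))
  structure(list(seed = seed, output_dir = output_dir, log_level = log_level,
                 architecture = architecture, train = train,
                 phantom = phantom),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed `run_config` (read).
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(strip_classes(cfg), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

# recursively drop S3 classes so nested configs serialize as plain JSON
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(seed = raw$seed %||% 1L,
                    output_dir = raw$output_dir %||% ".",
                    log_level = raw$log_level %||% "info")
  if (!is.null(raw$architecture)) {
    cfg$architecture <- do.call(architecture_spec, as_plain_list(raw$architecture))
  }
  if (!is.null(raw$train)) {
    cfg$train <- do.call(train_config, as_plain_list(raw$train))
  }
  if (!is.null(raw$phantom)) {
    ph <- as_plain_list(raw$phantom)
    for (nm in c("lesion", "foldover")) {
      if (!is.null(ph[[nm]])) ph[[nm]] <- as_plain_list(ph[[nm]])
    }
    cfg$phantom <- do.call(phantom_params, ph)
  }
  cfg
}

as_plain_list <- function(x) {
  x <- as.list(x)
  x[!vapply(x, is.null, logical(1L))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component-specific seed from the global seed
#'
#' A fixed component-name hash is folded into the global seed so each
#' pipeline stage draws from an independent, reproducible stream and the
#' set of stages can grow without changing existing streams.
#'
#' @param seed integer global seed.
#' @param component component name, e.g. `"phantom"`, `"train"`.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, component) {
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 1999999973
  as.integer((((as.numeric(seed) %% 65011 + 1) * 32707) + h) %% 2147483629)
}

log_event <- function(log_file, level, cfg_level, ...) {
  ranks <- c(quiet = 0L, info = 1L, debug = 2L)
  if (ranks[[level]] > ranks[[cfg_level %||% "info"]]) return(invisible(NULL))
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                paste(..., collapse = " "))
  if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  invisible(NULL)
}
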
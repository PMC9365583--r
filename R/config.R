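# Run configuration: one object bundling every tunable, serializable to
# YAML with full validation and reference defaults for unspecified fields.

#' Assemble a full run configuration
#'
#' @param network A [network_config()].
#' @param weights A [loss_weights()].
#' @param msssim A [msssim_params()].
#' @param mechanism A [mechanism_config()].
#' @param trainer A [train_config()].
#' @param data List with optional `train_dir`, `val_dir` and a
#'   [normalization_spec()] under `normalization`.
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(network = network_config(), weights = loss_weights(),
                       msssim = msssim_params(), mechanism = mechanism_config(),
                       trainer = train_config(),
                       data = list(train_dir = NULL, val_dir = NULL,
                                   normalization = normalization_spec()),
                       seed = 1L) {
  stopifnot(inherits(network, "network_config"),
            inherits(weights, "loss_weights"),
            inherits(msssim, "msssim_params"),
            inherits(mechanism, "mechanism_config"),
            inherits(trainer, "train_config"))
  structure(list(network = network, weights = weights, msssim = msssim,
                 mechanism = mechanism, trainer = trainer, data = data,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Section name -> (constructor, fields that are persisted / accepted).
.config_sections <- function() {
  list(network = list(fun = network_config,
                      keys = c("stem_channels", "growth_channels",
                               "dense_layers_per_block", "bottleneck_channels",
                               "n_levels", "decoder_channels", "use_irdb",
                               "init_std")),
       weights = list(fun = loss_weights,
                      keys = c("lambda1", "lambda2", "lambda3")),
       msssim = list(fun = msssim_params,
                     keys = c("scale_weights", "n_scales", "window_size",
                              "window_sigma", "dynamic_range")),
       mechanism = list(fun = mechanism_config,
                        keys = c("threshold", "enabled", "pretrain_epochs",
                                 "mechanism_epochs")),
       trainer = list(fun = train_config,
                      keys = c("batch_size", "lr", "lr_drop_epoch",
                               "lr_after_drop", "beta1", "beta2", "epsilon",
                               "shuffle")))
}

#' Load a run configuration from YAML or JSON
#'
#' Unspecified fields take the reference defaults (batch size 8, loss
#' weights (1, 0.15, 0.8), Adam betas (0.9, 0.999), learning rate 1e-4);
#' unknown keys and invalid values raise configuration errors naming the
#' key.
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`; an empty file gives all
#'   defaults).
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: file not found: ", path, call. = FALSE)
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  sections <- .config_sections()
  known_top <- c(names(sections), "data", "seed")
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0)
    stop("load_config: unknown key: ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- list()
  for (sec in names(sections)) {
    given <- raw[[sec]]
    if (is.null(given)) given <- list()
    bad <- setdiff(names(given), sections[[sec]]$keys)
    if (length(bad) > 0)
      stop("load_config: unknown key: ", sec, ".",
           paste(bad, collapse = paste0(", ", sec, ".")), call. = FALSE)
    args[[sec]] <- tryCatch(do.call(sections[[sec]]$fun, given),
                            error = function(e)
                              stop("load_config: invalid section '", sec, "': ",
                                   conditionMessage(e), call. = FALSE))
  }
  data <- raw$data
  if (is.null(data)) data <- list(train_dir = NULL, val_dir = NULL,
                                  normalization = normalization_spec())
  else {
    bad <- setdiff(names(data), c("train_dir", "val_dir", "normalization"))
    if (length(bad) > 0)
      stop("load_config: unknown key: data.", paste(bad, collapse = ", data."),
           call. = FALSE)
    nr <- data$normalization
    data$normalization <- if (is.null(nr)) normalization_spec()
    else do.call(normalization_spec, nr)
  }
  run_config(network = args$network, weights = args$weights,
             msssim = args$msssim, mechanism = args$mechanism,
             trainer = args$trainer, data = data,
             seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

#' Save a run configuration to YAML
#'
#' Writes every field so that `load_config(save_config(cfg))` reproduces
#' `cfg` exactly.
#'
#' @param cfg A [run_config()].
#' @param path Output path (`.yaml`).
#' @return Invisibly, the path.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  sections <- .config_sections()
  out <- list()
  for (sec in names(sections)) {
    flds <- sections[[sec]]$keys
    out[[sec]] <- lapply(unclass(cfg[[sec]])[intersect(flds, names(cfg[[sec]]))],
                         identity)
  }
  dat <- cfg$data
  if (!is.null(dat$normalization)) dat$normalization <- unclass(dat$normalization)
  out$data <- dat
  out$seed <- cfg$seed
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}
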
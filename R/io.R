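#' Read and write twin datasets, item banks and posterior draws
#'
#' Datasets are stored as tab-separated tables (one row per twin; missing
#' values as empty fields) with an optional YAML sidecar (`<path>.meta.yml`)
#' recording the generating [scenario_config()]. Item banks are three-column
#' TSV tables. Posterior draws are written long (chain, iteration, parameter,
#' value).
#'
#' @param data A twin dataset tibble (see [simulate_twin_data()]).
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return tibbles.
#' @name acem_io
NULL

#' @rdname acem_io
#' @export
write_twin_data <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  cfg <- attr(data, "config")
  if (!is.null(cfg)) {
    yaml::write_yaml(config_to_list(cfg), paste0(path, ".meta.yml"),
                     precision = 15)
  }
  bank <- attr(data, "item_bank")
  if (!is.null(bank)) {
    write_item_bank(bank, paste0(path, ".bank.tsv"))
  }
  invisible(path)
}

#' @rdname acem_io
#' @export
read_twin_data <- function(path) {
  data <- readr::read_tsv(path, na = "", show_col_types = FALSE,
                          progress = FALSE)
  meta <- paste0(path, ".meta.yml")
  if (file.exists(meta)) {
    attr(data, "config") <- config_from_list(yaml::read_yaml(meta))
  }
  bank_path <- paste0(path, ".bank.tsv")
  if (file.exists(bank_path)) {
    attr(data, "item_bank") <- read_item_bank(bank_path)
  }
  data
}

#' @rdname acem_io
#' @param bank An [item_bank()] tibble.
#' @export
write_item_bank <- function(bank, path) {
  readr::write_tsv(validate_item_bank(bank), path)
  invisible(path)
}

#' @rdname acem_io
#' @export
read_item_bank <- function(path) {
  validate_item_bank(readr::read_tsv(path, show_col_types = FALSE,
                                     progress = FALSE))
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$params <- unclass(out$params)
  out
}

config_from_list <- function(x) {
  x$params <- do.call(acem_params, x$params)
  do.call(scenario_config, x)
}

#' @rdname acem_io
#' @param fit An `acem_fit` object.
#' @export
write_posterior_draws <- function(fit, path) {
  stopifnot(inherits(fit, "acem_fit"))
  readr::write_csv(fit$draws, path)
  invisible(path)
}

#' @rdname acem_io
#' @export
read_posterior_draws <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
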
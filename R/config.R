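# Configuration file support: every numeric constant of the generator and
# pipeline stages round-trips through one YAML file.

#' Write a configuration to a YAML file
#'
#' @param config a configuration list ([sleep_config()], [task_config()],
#'   [pipeline_config()], or any nested named list of scalars/vectors).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' Values found in the file override the supplied defaults by name
#' (nested lists merge recursively), so a partial file customises only
#' the constants it mentions.
#'
#' @param path YAML file.
#' @param defaults base configuration to merge into (default
#'   [pipeline_config()]).
#' @return merged configuration list.
#' @export
read_config <- function(path, defaults = pipeline_config()) {
  vals <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_cfg(defaults, vals)
}
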
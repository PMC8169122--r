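## Structured text configuration: one YAML file whose top-level keys mirror
## the parameter objects of the generators, so a simulation or analysis run
## is fully described by (config, seed).

#' Read or write a simulation/analysis configuration
#'
#' The file is YAML with up to three top-level keys whose fields mirror the
#' constructor arguments: `cell_cycle` ([cell_cycle_params()]), `lenti_mix`
#' ([lenti_mix_model()]) and `foci_kinetics` ([foci_kinetics()]); missing
#' keys fall back to the defaults, unknown fields are an error.
#'
#' @param path path to the YAML file.
#' @return `read_sim_config()`: a list with elements `cell_cycle`,
#'   `lenti_mix`, `foci_kinetics` (constructed parameter objects) and
#'   `raw` (the parsed file). `write_sim_config()`: `path`, invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(key, ctor) {
    fields <- raw[[key]]
    if (is.null(fields)) return(ctor())
    bad <- setdiff(names(fields), names(formals(ctor)))
    if (length(bad)) {
      stop("unknown ", key, " field(s) in config: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    do.call(ctor, fields)
  }
  list(
    cell_cycle = build("cell_cycle", cell_cycle_params),
    lenti_mix = build("lenti_mix", lenti_mix_model),
    foci_kinetics = build("foci_kinetics", foci_kinetics),
    raw = raw
  )
}

#' @rdname read_sim_config
#' @param config named list of parameter lists (as in the file layout), or
#'   parameter objects created by the constructors.
#' @export
write_sim_config <- function(config, path) {
  strip <- function(x) {
    if (inherits(x, c("cell_cycle_params", "lenti_mix_model",
                      "foci_kinetics"))) {
      unclass(x)
    } else x
  }
  yaml::write_yaml(lapply(config, strip), path)
  invisible(path)
}
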
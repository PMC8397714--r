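# Run configuration: nested YAML with one section per module, a global RNG
# seed and an output directory.  Unknown keys are rejected so typos fail
# loudly; the file round-trips losslessly through yaml.

RUN_CONFIG_SECTIONS <- c("ga", "decoder", "predictor", "constraints",
                         "benchmarks", "phases", "fixtures")

default_run_config <- function() {
  list(rng_seed = 1L,
       output_dir = ".",
       ga = unclass(ga_config()),
       decoder = list(hidden = c(64, 64), epochs = 30, batch_size = 100,
                      lr = 1e-3, dropout = 0, cond_dim = 32,
                      type = "nn"),
       predictor = list(hidden = c(64, 64), epochs = 60, batch_size = 100,
                        lr = 1e-3, dropout = 0.1),
       constraints = c(unclass(blacklist_config()),
                       list(homo_window = c(-7, -5), lumo_max = 0)),
       benchmarks = list(n_generate = 500, top_k = c(1, 10, 100),
                         n_seeds = 8, max_generations = 40, patience = 15),
       phases = unclass(phase_config()),
       fixtures = list(n_molecules = 500, rng_seed = 1L,
                       max_heavy_atoms = 40, mw_range = c(200, 600),
                       property_range = c(1.5, 7.0)))
}

#' Load a run configuration file
#'
#' Reads a YAML run configuration, fills unset values with the package
#' defaults (which are the published settings), and rejects unknown keys.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad_top <- setdiff(names(user), c(RUN_CONFIG_SECTIONS, "rng_seed",
                                    "output_dir"))
  if (length(bad_top) > 0) {
    stopf("unknown config keys: %s", paste(bad_top, collapse = ", "))
  }
  for (nm in names(user)) {
    if (nm %in% RUN_CONFIG_SECTIONS) {
      bad <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
      if (length(bad) > 0) {
        stopf("unknown keys in section '%s': %s", nm,
              paste(bad, collapse = ", "))
      }
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

#' Write a run configuration file
#' @param cfg Configuration list.
#' @param path Destination YAML path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# stable hash of a configuration for the run manifest
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg)
  sprintf("%08x", hash_ints(utf8ToInt(txt)))
}

write_manifest <- function(cfg, seed, path) {
  manifest <- list(config_hash = config_hash(cfg),
                   rng_seed = seed,
                   package_version = as.character(utils::packageVersion("molevo")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
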
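# YAML run configuration: one file drives the whole pipeline. Unknown keys
# are rejected (typos in a config should fail loudly, not silently fall back
# to defaults); every section mirrors a module's config constructor.

.RUN_SCHEMA <- list(
  seed = NULL,
  log_level = NULL,
  dialects = list(vital = NULL, registry = NULL),
  linkage = list(match_threshold = NULL, review_low = NULL,
                 truncation_length = NULL, default_review_decision = NULL,
                 asymmetric_truncation = NULL),
  filter = list(armenian_suffixes = NULL, russian_suffixes = NULL,
                min_length = NULL, long_name_exempt_length = NULL),
  build = list(target_birthplace = NULL, harvest_father_surname = NULL,
               emit_truncated_reference = NULL,
               collapse_punctuation_variants = NULL),
  evaluate = list(target_birthplace = NULL, match_mode = NULL,
                  truncation_length = NULL),
  simulate = list(n_target_stems = NULL, n_other_surnames = NULL,
                  convention_mix = NULL, p_in_reference = NULL,
                  p_reference_only = NULL,
                  p_truncated_in_reference = NULL, p_variant_spelling = NULL,
                  p_target_birthplace_missing = NULL, birthplace_mix = NULL,
                  p_particle = NULL, n_trap_short = NULL,
                  n_trap_nosuffix = NULL, truncation_length = NULL,
                  target_birthplace = NULL, seed = NULL))

config_error <- function(...) {
  stop(structure(class = c("skit_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

check_keys <- function(x, schema, path = "") {
  unknown <- setdiff(names(x), names(schema))
  if (length(unknown)) {
    config_error("unknown config key(s): ",
                 paste0(path, unknown, collapse = ", "))
  }
  for (k in names(x)) {
    if (is.list(schema[[k]]) && length(schema[[k]])) {
      check_keys(as.list(x[[k]]), schema[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a pipeline run configuration
#'
#' Loads a YAML file with optional sections `dialects`, `linkage`, `filter`,
#' `build`, `evaluate`, `simulate` plus top-level `seed` and `log_level`.
#' Unknown keys anywhere raise a configuration error naming the key; absent
#' keys take the module defaults. Section values are materialized into the
#' corresponding config objects ([linkage_config()], [filter_config()],
#' [build_config()], [world_config()]).
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return a list of class `run_config` with elements `seed`, `log_level`,
#'   `dialects`, `linkage`, `filter`, `build`, `evaluate`, `simulate`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) config_error("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  check_keys(raw, .RUN_SCHEMA)
  get_sec <- function(name) as.list(raw[[name]])
  lk <- do.call(linkage_config, get_sec("linkage"))
  fl <- do.call(filter_config, get_sec("filter"))
  bsec <- get_sec("build")
  bd <- do.call(build_config,
                c(bsec, list(linkage = lk, filter = fl)))
  sim_args <- get_sec("simulate")
  if (is.null(sim_args$seed) && !is.null(raw$seed)) sim_args$seed <- raw$seed
  if (!is.null(sim_args$convention_mix)) {
    sim_args$convention_mix <- unlist(sim_args$convention_mix)
  }
  if (!is.null(sim_args$birthplace_mix)) {
    sim_args$birthplace_mix <- unlist(sim_args$birthplace_mix)
  }
  sim <- do.call(world_config, sim_args)
  ev <- utils::modifyList(
    list(target_birthplace = bd$target_birthplace, match_mode = "exact",
         truncation_length = lk$truncation_length),
    get_sec("evaluate"))
  structure(list(seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 log_level = if (is.null(raw$log_level)) "info"
                             else raw$log_level,
                 dialects = get_sec("dialects"),
                 linkage = lk, filter = fl, build = bd, evaluate = ev,
                 simulate = sim),
            class = "run_config")
}
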
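# Shared fixtures and independent oracles. All fixtures are built in code;
# worlds are cached per (seed, noise) so the suite generates each one once.

.world_cache <- new.env(parent = emptyenv())

cached_world <- function(seed = 42L, noise = TRUE) {
  key <- paste0("w", seed, "_", noise)
  if (is.null(.world_cache[[key]])) {
    cfg <- if (noise) world_config(seed = seed) else
      world_config(p_variant_spelling = 0, p_truncated_in_reference = 0,
                   p_target_birthplace_missing = 0, seed = seed)
    .world_cache[[key]] <- generate_world(cfg)
  }
  .world_cache[[key]]
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent brute-force linkage oracle: score every left x right pair,
# keep same-block pairs whose category is match (no blocking machinery)
brute_force_matches <- function(left, right, config = linkage_config()) {
  out <- character(0)
  for (l in left) {
    for (r in right) {
      if (soundex(l) != soundex(r)) next
      sc <- score_pair(l, r, config)
      if (sc$category == "match") out <- c(out, paste(l, r, sep = "\r"))
    }
  }
  sort(out)
}

pair_keys <- function(pairs) {
  sort(paste(pairs$left, pairs$right, sep = "\r"))
}

# independent filter oracle: the two deletion criteria written as one
# boolean expression over (letter count, has-listed-suffix)
oracle_keep <- function(n_letters, has_suffix, min_len = 5, exempt = 12) {
  if (n_letters < min_len) return(FALSE)
  if (!has_suffix && n_letters < exempt) return(FALSE)
  TRUE
}

# stem alphabet contains no letter of any suffix-critical ending (no n, v)
stem_of <- function(len) {
  if (len <= 0) return("")
  paste(rep_len(strsplit("bakelomitu", "")[[1]], len), collapse = "")
}
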
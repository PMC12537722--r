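# Internal helpers shared across modules.

# Evaluate `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never leak global RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("`seed` must be a single non-missing number", call. = FALSE)
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

check_porosity <- function(porosity) {
  stop_if_not_scalar_number(porosity, "porosity")
  if (porosity <= 0 || porosity >= 1)
    stop(sprintf("`porosity` must lie strictly in (0, 1), got %g", porosity),
         call. = FALSE)
  invisible(porosity)
}

# Weak-but-stable fingerprint of a configuration list, used only for the
# provenance header written next to result tables.
config_fingerprint <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  txt <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97 + 1)) %% .Machine$integer.max)
}
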
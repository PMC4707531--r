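# Internal helpers: deterministic substreams and RNG hygiene.

# Stable 31-adic string hash into [0, 2^31 - 59). Used to derive per-feature
# RNG substreams so that adding or reordering features never reshuffles the
# draws of other features.
.phx_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483589
  h
}

# Substream seed for (global seed, id parts ...). Always < 2^31.
.phx_substream <- function(seed, ...) {
  id <- paste(c(...), collapse = "\r")
  (as.numeric(seed) %% 2147483589 * 48271 + .phx_hash(id)) %% 2147483589
}

# Save the caller-visible RNG state; returns a restore function.
.phx_push_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    function() assign(".Random.seed", old, envir = globalenv())
  } else {
    function() {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }
  }
}

.phx_stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
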
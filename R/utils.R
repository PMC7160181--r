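# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions do not perturb user scripts.
#' A `NULL` seed leaves the RNG untouched.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stable string hash (polynomial rolling hash over UTF-8 bytes, modulo a
#' prime below 2^31) combined with the master seed, so any simulation cell
#' can be regenerated in isolation from its label alone.
#'
#' @param master integer master seed.
#' @param label character scalar identifying the cell/stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "scaleA|500|10-20|rep01")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.character(label), length(label) == 1L)
  p <- 2147483629 # prime < 2^31; keeps intermediate products < 2^53
  h <- as.numeric(master) %% p
  for (b in as.integer(charToRaw(label))) h <- (h * 131 + b) %% p
  as.integer(h + 1)
}

# Abort with a classed condition so callers can distinguish validation errors.
abort_cladiv <- function(msg, class = "cladiv_error") {
  stop(structure(class = c(class, "cladiv_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# sample() without its scalar-x surprise: sample_int(5, 1) never means 1:5.
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

write_tsv_na <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}
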
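# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gs <- function(..., class = "gaitstride_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

warn_gs <- function(...) warning(paste0(...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gs(name, " must be a single finite number")
  if (positive && x <= 0) stop_gs(name, " must be > 0")
  if (nonneg && x < 0) stop_gs(name, " must be >= 0")
  invisible(x)
}

#' Deterministic 32-bit string/seed hash
#'
#' FNV-1a style hash folding a master seed together with arbitrary string
#' tokens, used to derive independent per-trial and per-subject random
#' substreams from one master seed. Result is a non-negative integer
#' strictly below 2^31 so it is always a valid `set.seed()` argument.
#'
#' @param seed integer master seed.
#' @param ... character or numeric tokens identifying the substream.
#' @return a single integer in `[0, 2^31)`.
#' @keywords internal
hash_seed <- function(seed, ...) {
  tokens <- paste(c(format(seed), vapply(list(...), format, "")),
                  collapse = "\r")
  bytes <- utf8ToInt(tokens)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% .Machine$integer.max)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Truncated normal (mean 0) by rejection, truncation at +-2 sd -- the
# convention used for convolution/dense kernel initialisation.
rtruncnorm0 <- function(n, sd) {
  out <- stats::rnorm(n, 0, sd)
  bad <- which(abs(out) > 2 * sd)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), 0, sd)
    bad <- bad[abs(out[bad]) > 2 * sd]
  }
  out
}

# Fixed-format number printing for byte-stable CSV output.
fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "f")
}
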
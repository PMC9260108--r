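# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
# A NULL seed means "use the current stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a stream so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage substream derived from one study seed.
# Keeps the derived seed inside 32-bit integer range.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# Uniform sample inside the unit ball (rejection sampling).
runif_ball <- function(n) {
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    p <- matrix(stats::runif(3 * (n - got), -1, 1), ncol = 3)
    keep <- rowSums(p^2) <= 1
    k <- sum(keep)
    if (k > 0) {
      out[(got + 1L):(got + k), ] <- p[keep, , drop = FALSE]
      got <- got + k
    }
  }
  out
}

# Consistent "no value" result used where the spec demands an explicit
# non-answer instead of NaN arithmetic.
no_value <- function(reason) {
  structure(list(value = NA_real_, reason = reason), class = "mpmri_no_value")
}

is_no_value <- function(x) inherits(x, "mpmri_no_value")

#' @export
print.mpmri_no_value <- function(x, ...) {
  cat("<no value>:", x$reason, "\n")
  invisible(x)
}

as_3d <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  x
}
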
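# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("holomass_config_error", "error")))
}

stop_data <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("holomass_data_error", "error")))
}

# signed DFT frequency axis in cycles/sample, matching stats::fft bin order
freq_axis <- function(n) {
  idx <- 0:(n - 1)
  ifelse(idx > n / 2, idx - n, idx) / n
}

# circular shift of a matrix by (di, dj) (positive = down/right)
circshift <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  di <- ((di %% nr) + nr) %% nr
  dj <- ((dj %% nc) + nc) %% nc
  if (di > 0) m <- rbind(m[(nr - di + 1):nr, , drop = FALSE],
                         m[1:(nr - di), , drop = FALSE])
  if (dj > 0) m <- cbind(m[, (nc - dj + 1):nc, drop = FALSE],
                         m[, 1:(nc - dj), drop = FALSE])
  m
}

# wrap to the interval (-pi, pi]
wrap_to_pi <- function(x) pi - (pi - x) %% (2 * pi)

# run expr with a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(...) {
  parts <- as.numeric(c(...))
  s <- 104729
  for (p in parts) s <- (s * 31 + (p * 1000) %% 1000003) %% 2147483629
  as.integer(floor(abs(s))) + 1L
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
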
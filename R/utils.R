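# Internal helpers shared across modules.

# Round half away from zero (the encoder's rounding rule; base round()
# rounds half to even, which would map 63.5 -> 64 but 64.5 -> 64).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Expand one master seed into named per-stage seeds so that every
# intermediate of a pipeline is independently reproducible.  Seeds are
# kept below 2^31 - 1 (R integers).
expand_seed <- function(master, stages) {
  stopifnot(length(master) == 1L, is.finite(master))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

# Dimensions of a 3-D array-of-values container, always length 3.
dim3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (length(d) == 2L) d <- c(d, 1L)
  stopifnot(length(d) == 3L)
  as.integer(d)
}

stop_if_not_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be positive and finite", call. = FALSE)
  }
  invisible(x)
}
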
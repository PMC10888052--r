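# Internal helpers shared across modules.
#
# Volume convention: a single case (batch size 1) is an R array with
# dim c(H, W, D, C) -- channel-last so that each channel is a contiguous
# block in memory. Label volumes are integer arrays dim c(H, W, D).

sigmoid <- function(x) 1 / (1 + exp(-x))

elu_fn <- function(x, alpha = 1) ifelse(x > 0, x, alpha * (exp(x) - 1))

check_volume <- function(x, what = "volume") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a 4-d array [H, W, D, C]")
  if (any(dim(x) < 1L)) stop(what, " has a degenerate axis of length 0")
  if (!all(is.finite(x))) stop(what, " contains non-finite values")
  invisible(x)
}

n_channels <- function(x) dim(x)[4L]
n_voxels <- function(x) prod(dim(x)[1:3])

# broadcast a per-channel vector over the spatial dims of x-like array
bcast_channel <- function(a, dims) {
  array(rep(a, each = prod(dims[1:3])), dim = dims)
}

zero_like <- function(params) lapply(params, function(p) {
  z <- p
  z[] <- 0
  z
})

largest_divisor_leq <- function(n, cap) {
  for (g in seq(min(cap, n), 1L)) if (n %% g == 0L) return(as.integer(g))
  1L
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
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

# deterministic 31-bit sub-seed derivation
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 31 + as.numeric(p)) %% 2147483629
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
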
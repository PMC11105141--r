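#' @importFrom stats rnorm runif
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state, so seeded operations never perturb
#' the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Row-wise softmax with max-subtraction for stability.
softmax_rows <- function(z) {
  z <- as.matrix(z)
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_vec <- function(z) {
  z <- as.numeric(z)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

one_hot <- function(idx, k) {
  v <- numeric(k)
  v[idx] <- 1
  v
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# 32-bit FNV-1a string hash, kept in double arithmetic (exact below 2^53).
str_hash32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# Deterministic pseudo-random vector for a token, independent of R's RNG.
# Linear-congruential stream seeded by the token hash; values uniform on
# [-0.5, 0.5] scaled by 1/sqrt(d).
hash_vector <- function(token, d) {
  state <- str_hash32(token)
  out <- numeric(d)
  for (i in seq_len(d)) {
    state <- (state * 1103515245 + 12345) %% 2147483648
    out[i] <- (state / 2147483648 - 0.5) / sqrt(d)
  }
  out
}

# ---- Adam optimiser over a named list of numeric arrays -------------------

adam_init <- function(params) {
  list(
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]    # decoupled decay
  }
  list(params = params, state = state)
}

# Flatten a nested list of numeric arrays into one vector (for checksums).
flatten_params <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.list(x)) return(unlist(lapply(x, flatten_params), use.names = FALSE))
  numeric(0)
}

#' Checksum of a parameter collection
#'
#' Deterministic digest used to compare trained models for exact equality.
#'
#' @param x nested list of numeric arrays.
#' @return A single numeric value.
#' @export
param_checksum <- function(x) {
  v <- flatten_params(x)
  sum(v * seq_along(v) %% 997) + sum(abs(v))
}

stop_tkg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
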
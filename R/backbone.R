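#' Tokenize text for the bundled backbone
#'
#' Lowercases and splits on whitespace, with punctuation characters as
#' separate tokens. Marker tokens are inserted by [mark_events()] at the
#' token level and never pass through this function.
#'
#' @param x character scalar.
#' @return Character vector of tokens.
#' @export
tokenize_text <- function(x) {
  x <- tolower(x)
  m <- gregexpr("[a-z0-9']+|[^a-z0-9'[:space:]]", x)
  regmatches(x, m)[[1L]]
}

marker_tokens <- c("<e1>", "</e1>", "<e2>", "</e2>")
special_tokens <- c("<pad>", "<unk>", marker_tokens, "<gap>")

#' Build a token vocabulary
#'
#' Special tokens (padding, unknown, the four event markers and the
#' truncation gap token) occupy the first slots; remaining tokens are
#' sorted for determinism.
#'
#' @param token_lists list of character vectors (e.g. tokenized documents).
#' @param min_count minimum corpus frequency for inclusion.
#' @return Object of class `tkg_vocab` with `$tokens` and `$index`.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  tab <- table(unlist(token_lists, use.names = FALSE))
  keep <- names(tab)[tab >= min_count]
  toks <- c(special_tokens, sort(setdiff(keep, special_tokens)))
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks), toks)),
            class = "tkg_vocab")
}

vocab_ids <- function(vocab, tokens) {
  idx <- unname(vocab$index[tokens])
  idx[is.na(idx)] <- vocab$index[["<unk>"]]
  idx
}

#' Bundled desk-scale text backbone
#'
#' A shallow trainable contextualizer fulfilling the backbone contract:
#' learned token embeddings followed by `n_layers` bidirectional
#' convolutional mixing layers of odd width `width` with tanh
#' nonlinearity. Output length equals input length and the embedding
#' dimension is constant, so heavier pretrained encoders can be swapped in
#' behind the same contract.
#'
#' @param vocab a [build_vocab()] vocabulary (must contain the marker
#'   tokens, which it does by construction).
#' @param d embedding dimension.
#' @param n_layers number of mixing layers.
#' @param width convolution width (odd); the receptive field is
#'   `n_layers * (width - 1) / 2` tokens each side.
#' @param seed parameter-initialization seed.
#' @return Object of class `tkg_backbone`.
#' @export
bundled_backbone <- function(vocab, d = 48L, n_layers = 2L, width = 5L,
                             seed = 1L) {
  stopifnot(width %% 2L == 1L, n_layers >= 1L)
  V <- length(vocab$tokens)
  params <- with_local_seed(seed, {
    p <- list(E = matrix(rnorm(V * d, sd = 0.1), V, d))
    for (l in seq_len(n_layers)) {
      p[[paste0("M", l)]] <- array(rnorm(d * d * width, sd = 1 / sqrt(d * width)),
                                   dim = c(d, d, width))
      p[[paste0("b", l)]] <- numeric(d)
    }
    p
  })
  structure(list(kind = "bundled", vocab = vocab, dim = d,
                 n_layers = n_layers, width = width, params = params,
                 seed = seed),
            class = "tkg_backbone")
}

# ---- batched forward / backward over flattened (n*L, d) matrices ----------

# Rows are laid out sequence-major: row (i-1)*L + l is token l of item i.
# shift_valid(o) gives destination rows whose source row (same sequence,
# token l + o) exists.
make_shift_index <- function(n, L, offsets) {
  l_of_row <- rep(seq_len(L), n)
  lapply(offsets, function(o) {
    which(l_of_row + o >= 1L & l_of_row + o <= L)
  })
}

backbone_forward <- function(backbone, ids, mask, cache = FALSE) {
  n <- nrow(ids); L <- ncol(ids); d <- backbone$dim
  half <- (backbone$width - 1L) %/% 2L
  offsets <- seq(-half, half)
  shifts <- make_shift_index(n, L, offsets)
  flat_ids <- as.integer(t(ids))
  mvec <- as.numeric(t(mask))
  H <- backbone$params$E[flat_ids, , drop = FALSE] * mvec
  Hs <- list(H)
  for (l in seq_len(backbone$n_layers)) {
    M <- backbone$params[[paste0("M", l)]]
    Z <- matrix(backbone$params[[paste0("b", l)]], n * L, d, byrow = TRUE)
    for (oi in seq_along(offsets)) {
      o <- offsets[[oi]]
      valid <- shifts[[oi]]
      S <- matrix(0, n * L, d)
      S[valid, ] <- H[valid + o, , drop = FALSE]
      Z <- Z + S %*% M[, , oi]
    }
    H <- tanh(Z) * mvec
    Hs[[l + 1L]] <- H
  }
  if (!cache) return(H)
  list(H = H, Hs = Hs, flat_ids = flat_ids, mvec = mvec, shifts = shifts,
       offsets = offsets, n = n, L = L)
}

backbone_backward <- function(backbone, cache, dH) {
  grads <- list()
  d <- backbone$dim
  for (l in rev(seq_len(backbone$n_layers))) {
    Hl <- cache$Hs[[l + 1L]]
    Hin <- cache$Hs[[l]]
    dZ <- dH * (1 - Hl * Hl) * cache$mvec
    M <- backbone$params[[paste0("M", l)]]
    dM <- array(0, dim = dim(M))
    dHin <- matrix(0, nrow(dH), d)
    for (oi in seq_along(cache$offsets)) {
      o <- cache$offsets[[oi]]
      valid <- cache$shifts[[oi]]
      S <- matrix(0, nrow(dH), d)
      S[valid, ] <- Hin[valid + o, , drop = FALSE]
      dM[, , oi] <- crossprod(S, dZ)
      back <- dZ[valid, , drop = FALSE] %*% t(M[, , oi])
      dHin[valid + o, ] <- dHin[valid + o, , drop = FALSE] + back
    }
    grads[[paste0("M", l)]] <- dM
    grads[[paste0("b", l)]] <- colSums(dZ)
    dH <- dHin
  }
  dH0 <- dH * cache$mvec
  agg <- rowsum(dH0, group = cache$flat_ids)
  dE <- matrix(0, nrow(backbone$params$E), d)
  dE[as.integer(rownames(agg)), ] <- agg
  grads$E <- dE
  grads
}
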
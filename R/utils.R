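# shared internal helpers

sigmoid <- function(x) 1 / (1 + exp(-x))

# run code with a temporary RNG state when seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# broadcast a per-channel vector over an (H, W, C, N) array
bc_channel <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# broadcast a C x N matrix over an (H, W, C, N) array
bc_cn <- function(m, d) {
  rep(as.vector(m), each = d[1] * d[2])
}

# per-channel reshape: (H, W, C, N) -> (H*W*N) x C matrix
as_channel_mat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
}

# inverse of as_channel_mat
from_channel_mat <- function(m, d) {
  aperm(array(m, dim = c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
}

# concatenate two (H, W, C, N) arrays along the channel axis
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
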
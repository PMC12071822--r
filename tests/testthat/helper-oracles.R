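# Independent brute-force oracles, implemented separately from the package
# (plain R, rle-based run scanning, pairwise concordance counting) so that
# package results can be checked against a second code path.

# maximal-run scanner: extract every line of the image along a direction
# and count runs with rle()
oracle_glrlm <- function(img, nlevels, directions) {
  nr <- nrow(img); nc <- ncol(img)
  counts <- matrix(0L, nlevels, max(nr, nc))
  lines_for <- function(dir) {
    if (dir == 0) return(lapply(seq_len(nr), function(r) img[r, ]))
    if (dir == 90) return(lapply(seq_len(nc), function(c) img[, c]))
    # diagonals: enumerate start cells (no in-bounds predecessor) and walk
    step <- if (dir == 45) c(-1, 1) else c(1, 1)
    starts <- list()
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      pr <- r - step[1]; pc <- c - step[2]
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next
      starts[[length(starts) + 1]] <- c(r, c)
    }
    lapply(starts, function(s0) {
      v <- c(); r <- s0[1]; c <- s0[2]
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        v <- c(v, img[r, c]); r <- r + step[1]; c <- c + step[2]
      }
      v
    })
  }
  for (dir in directions) {
    for (ln in lines_for(dir)) {
      rl <- rle(as.integer(ln))
      for (k in seq_along(rl$lengths))
        counts[rl$values[k], rl$lengths[k]] <- counts[rl$values[k], rl$lengths[k]] + 1L
    }
  }
  counts
}

oracle_lrhgle <- function(counts) {
  i2 <- seq_len(nrow(counts))^2
  j2 <- seq_len(ncol(counts))^2
  sum(counts * outer(i2, j2)) / sum(counts)
}

# AUC as the pairwise concordance probability (ties count 1/2)
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# adaptive max-pooling oracle with explicit bin index ranges
oracle_spp <- function(x, levels) {
  d <- dim(x)
  out <- c()
  for (L in levels) {
    v <- array(0, c(L, L, d[3]))
    for (c in seq_len(d[3])) for (bj in seq_len(L)) for (bi in seq_len(L)) {
      hs <- floor((bi - 1) * d[1] / L) + 1; he <- ceiling(bi * d[1] / L)
      ws <- floor((bj - 1) * d[2] / L) + 1; we <- ceiling(bj * d[2] / L)
      v[bi, bj, c] <- max(x[hs:he, ws:we, c])
    }
    out <- c(out, as.vector(v))
  }
  out
}

# small uniform phantom truth for fit-recovery tests
uniform_truth <- function(alpha = 3, beta = 0.05, amp = 120, t2 = 80,
                          adc = 1e-3, shape = c(4, 4, 1)) {
  ones <- array(1, shape)
  phantom_truth(alpha * ones, beta * ones, amp * ones, t2 * ones,
                adc * ones, array(TRUE, shape), class_label = 0L,
                event_time = 12, censored = FALSE)
}
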
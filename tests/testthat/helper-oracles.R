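# Shared brute-force oracles, kept deliberately naive and independent of the
# package's vectorized implementations.

# Exhaustive nearest-target distance between cell centers.
oracle_distance <- function(mask, spec) {
  ctr <- cell_centers(spec)
  tx <- ctr$x[mask]; ty <- ctr$y[mask]
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      out[r, c] <- sqrt(min((tx - ctr$x[r, c])^2 + (ty - ctr$y[r, c])^2))
    }
  }
  out
}

# Descendant counting by walking every cell's flow path.
oracle_accumulation <- function(receiver, n_cells) {
  acc <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    cur <- i
    repeat {
      acc[cur] <- acc[cur] + 1L
      nxt <- receiver[cur]
      if (is.na(nxt)) break
      cur <- nxt
    }
  }
  acc
}

# Recursive Strahler order on the stream cell graph.
oracle_strahler <- function(receiver, stream_idx, cap = 9L) {
  ups <- lapply(stream_idx, function(j) {
    stream_idx[!is.na(receiver[stream_idx]) & receiver[stream_idx] == j]
  })
  names(ups) <- stream_idx
  memo <- new.env()
  ord <- function(i) {
    key <- as.character(i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    up <- ups[[key]]
    val <- if (length(up) == 0L) 1L else {
      uo <- vapply(up, ord, integer(1))
      mx <- max(uo)
      if (sum(uo == mx) >= 2L) mx + 1L else mx
    }
    val <- min(val, cap)
    memo[[key]] <- val
    val
  }
  vapply(stream_idx, ord, integer(1))
}

# Recursive flood fill labelling (small grids only).
oracle_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  off <- if (connectivity == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  fill <- function(r, c, l) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(invisible())
    if (!mask[r, c] || lab[r, c] != 0L) return(invisible())
    lab[r, c] <<- l
    for (k in seq_len(nrow(off))) fill(r + off[k, 1], c + off[k, 2], l)
  }
  l <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) { l <- l + 1L; fill(r, c, l) }
  }
  lab
}

# Brute-force windowed mean with shrinking edges.
oracle_windowed <- function(b, window) {
  half <- (window - 1L) %/% 2L
  nr <- nrow(b); nc <- ncol(b)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - half):min(nr, r + half)
    cs <- max(1, c - half):min(nc, c + half)
    out[r, c] <- mean(b[rs, cs])
  }
  out
}

# All-pairs AUC with half-weight ties.
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]; neg <- probs[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exhaustive threshold scan over the same candidate set contract.
oracle_threshold <- function(probs, labels) {
  u <- sort(unique(probs))
  cand <- u
  if (length(u) > 1) cand <- sort(c(u, (u[-1] + u[-length(u)]) / 2))
  best <- Inf; best_t <- NA
  for (t in cand) {
    sens <- mean(probs[labels == 1] >= t)
    spec <- mean(probs[labels == 0] < t)
    gap <- abs(sens - spec)
    if (gap < best - 1e-12) { best <- gap; best_t <- t }
  }
  best_t
}

random_dem <- function(nr, nc, seed) {
  set.seed(seed)
  matrix(stats::runif(nr * nc, 0, 10), nr, nc)
}
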
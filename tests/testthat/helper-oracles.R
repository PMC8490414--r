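# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Per-pixel, per-annotation Gaussian map with pointwise-max combination.
oracle_confidence_map <- function(ann, H, W, sigma, scale = 1) {
  g <- matrix(0, H, W)
  if (!nrow(ann)) return(g)
  cx <- pmin(round(ann$x / scale), W - 1)
  cy <- pmin(round(ann$y / scale), H - 1)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    y <- i - 1; x <- j - 1
    for (a in seq_len(nrow(ann))) {
      v <- exp(-((x - cx[a])^2 + (y - cy[a])^2) / (2 * sigma^2))
      if (v > g[i, j]) g[i, j] <- v
    }
  }
  g
}

# Exhaustive strict-4-neighbour local-maximum scan.
oracle_local_maxima <- function(g) {
  H <- nrow(g); W <- ncol(g)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && g[ii, jj] >= g[i, j])
        ok <- FALSE
    }
    if (ok) out <- rbind(out, data.frame(cell_x = j - 1, cell_y = i - 1,
                                         value = g[i, j]))
  }
  if (is.null(out))
    data.frame(cell_x = integer(0), cell_y = integer(0), value = numeric(0))
  else out
}

# Threshold + greedy descending-score suppression, re-derived from scratch.
oracle_suppress <- function(maxima, tau, delta) {
  cand <- maxima[maxima$value > tau, , drop = FALSE]
  cand <- cand[order(-cand$value, cand$cell_y, cand$cell_x), , drop = FALSE]
  acc <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(acc) == 0 ||
        min(sqrt((acc$cell_x - cand$cell_x[i])^2 +
                 (acc$cell_y - cand$cell_y[i])^2)) > delta)
      acc <- rbind(acc, cand[i, ])
  }
  acc
}

# Exhaustive optimal one-to-one matching: enumerates every assignment of
# detections to annotations (including leaving points unmatched) and keeps
# the one with most gated pairs, then least total distance.
oracle_match <- function(det, ann, gate) {
  nd <- nrow(det); na <- nrow(ann)
  d <- if (nd && na)
    sqrt(outer(det$x, ann$x, "-")^2 + outer(det$y, ann$y, "-")^2)
  else matrix(0, 0, 0)
  best <- list(n = -1, dist = Inf, pairs = NULL)
  recurse <- function(i, used, pairs, total) {
    if (i > nd) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && total < best$dist))
        best <<- list(n = n, dist = total, pairs = pairs)
      return(invisible(NULL))
    }
    recurse(i + 1, used, pairs, total)              # detection i unmatched
    for (j in seq_len(na)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE
        recurse(i + 1, used, rbind(pairs,
                data.frame(detection = i, annotation = j,
                           distance = d[i, j])), total + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, na),
          data.frame(detection = integer(0), annotation = integer(0),
                     distance = numeric(0)), 0)
  best
}

# Largest-remainder apportionment, written independently.
oracle_apportion <- function(n, fr) {
  q <- n * fr
  s <- floor(q)
  r <- q - s
  while (sum(s) < n) {
    k <- which.max(r)
    s[k] <- s[k] + 1
    r[k] <- -1
  }
  s
}
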
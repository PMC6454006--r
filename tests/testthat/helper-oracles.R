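# Independent oracles used across tests. These deliberately re-derive results
# with naive algorithms (flood fill, exhaustive enumeration, brute-force
# distance scans) so the package implementations are checked against a
# different code path.

# Flood-fill component count of a binary matrix (8- or 4-connectivity).
floodFillComponents <- function(bin, connectivity = 8) {
  H <- nrow(bin); W <- ncol(bin)
  seen <- matrix(FALSE, H, W)
  nb <- if (connectivity == 8)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  count <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!bin[i, j] || seen[i, j]) next
    count <- count + 1L
    stack <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb$dr[k]; c <- p[2] + nb$dc[k]
        if (r >= 1 && r <= H && c >= 1 && c <= W && bin[r, c] &&
            !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Brute-force Ensemble Dice: explicit pixel-set enumeration of every object
# pair, maximal-overlap matching with smallest-id tie-break, in both
# directions.
bruteDice2 <- function(ref, pred) {
  objs <- function(m) {
    ids <- sort(unique(m[m > 0]))
    lapply(ids, function(id) which(m == id))
  }
  Q <- objs(ref); P <- objs(pred)
  if (!length(Q) && !length(P)) return(1)
  if (!length(Q) || !length(P)) return(0)
  directed <- function(A, B) {
    num <- 0; den <- 0
    for (a in A) {
      ov <- vapply(B, function(b) length(intersect(a, b)), 0L)
      den <- den + length(a)
      if (any(ov > 0)) {
        bi <- which(ov == max(ov))[1]  # smallest id on ties (ordered list)
        num <- num + 2 * ov[bi]
        den <- den + length(B[[bi]])
      }
    }
    if (den == 0) 1 else num / den
  }
  (directed(Q, P) + directed(P, Q)) / 2
}

# Random labeled mask with a few blob-like objects (possibly overlapping in
# placement; later objects overwrite).
randomMask <- function(h, w, nObjects, seed) {
  set.seed(seed)
  m <- matrix(0L, h, w)
  for (id in seq_len(nObjects)) {
    cy <- sample.int(h, 1); cx <- sample.int(w, 1)
    r <- sample(1:3, 1)
    for (i in max(1, cy - r):min(h, cy + r))
      for (j in max(1, cx - r):min(w, cx + r))
        if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- id
  }
  m
}

# A minimal in-memory tile with a single centered square nucleus.
squareNucleusTile <- function(side = 240L, nucSide = 10L, id = "sq") {
  mask <- matrix(0L, side, side)
  c0 <- (side - nucSide) %/% 2
  mask[c0 + seq_len(nucSide), c0 + seq_len(nucSide)] <- 1L
  img <- array(0.8, c(side, side, 3))
  img[, , 1][mask > 0] <- 0.3
  NucleiTile(img, mask, id = id)
}
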
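# Independent oracles used across the test suite.  These deliberately share
# no code with the package internals they check.

# --- convex hull: a point is a hull vertex iff it is not strictly inside any
#     triangle formed by three other points (O(n^4) brute force, vectorized
#     over triangles) --------------------------------------------------------
oracle_hull <- function(pts) {
  n <- nrow(pts)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    o <- pts[-i, , drop = FALSE]
    inside <- FALSE
    if (nrow(o) >= 3) {
      cb <- utils::combn(nrow(o), 3)
      A <- o[cb[1, ], , drop = FALSE]
      B <- o[cb[2, ], , drop = FALSE]
      C <- o[cb[3, ], , drop = FALSE]
      s1 <- (B[, 2] - A[, 2]) * (p[1] - A[, 1]) - (B[, 1] - A[, 1]) * (p[2] - A[, 2])
      s2 <- (C[, 2] - B[, 2]) * (p[1] - B[, 1]) - (C[, 1] - B[, 1]) * (p[2] - B[, 2])
      s3 <- (A[, 2] - C[, 2]) * (p[1] - C[, 1]) - (A[, 1] - C[, 1]) * (p[2] - C[, 2])
      inside <- any((s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0))
    }
    keep[i] <- !inside
  }
  pts[keep, , drop = FALSE]
}

# canonical form for comparing vertex sets
canon_pts <- function(m) {
  m <- as.matrix(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

# --- point-in-polygon (even-odd ray casting + exact on-boundary test) -------
oracle_point_in_polygon <- function(r, c, verts) {
  n <- nrow(verts)
  nxt <- c(seq_len(n)[-1], 1L)
  # on an edge?
  for (k in seq_len(n)) {
    a <- verts[k, ]; b <- verts[nxt[k], ]
    cross <- (b[2] - a[2]) * (r - a[1]) - (b[1] - a[1]) * (c - a[2])
    if (cross == 0 &&
        r >= min(a[1], b[1]) && r <= max(a[1], b[1]) &&
        c >= min(a[2], b[2]) && c <= max(a[2], b[2])) return(TRUE)
  }
  # even-odd crossings of a horizontal ray toward +col
  crossings <- 0L
  for (k in seq_len(n)) {
    a <- verts[k, ]; b <- verts[nxt[k], ]
    if ((a[1] > r) != (b[1] > r)) {
      xc <- a[2] + (r - a[1]) * (b[2] - a[2]) / (b[1] - a[1])
      if (xc > c) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

oracle_fill <- function(verts, nrow, ncol) {
  out <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) for (c in seq_len(ncol))
    out[r, c] <- oracle_point_in_polygon(r, c, verts)
  out
}

# --- 26-connected components via igraph -------------------------------------
oracle_components_26 <- function(fg) {
  d <- dim(fg)
  idx <- which(fg)
  comp <- array(0L, dim = d)
  if (!length(idx)) return(comp)
  pos <- arrayInd(idx, d)
  id_of <- array(0L, dim = d)
  id_of[idx] <- seq_along(idx)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
                 (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(pos, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_id <- rep(0L, nrow(nb))
    nb_id[ok] <- id_of[nb[ok, , drop = FALSE]]
    hit <- nb_id > 0L
    if (any(hit)) edges <- rbind(edges, cbind(which(hit), nb_id[hit]))
  }
  g <- if (is.null(edges)) igraph::make_empty_graph(length(idx), directed = FALSE)
       else igraph::make_graph(edges = as.vector(t(edges)), n = length(idx),
                               directed = FALSE)
  comp[idx] <- igraph::components(g)$membership
  comp
}

# union of 26-connected components of `fg` that contain at least one seed
oracle_seeded_components <- function(fg, seeds) {
  comp <- oracle_components_26(fg)
  keep <- unique(comp[seeds & fg])
  keep <- keep[keep > 0L]
  array(comp %in% keep & fg, dim = dim(fg))
}

# --- voxel-by-voxel confusion loop ------------------------------------------
oracle_confusion <- function(pred, truth, domain) {
  tp <- fp <- tn <- fn <- 0L
  d <- dim(pred)
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (c in seq_len(d[3])) {
    if (!domain[s, r, c]) next
    p <- pred[s, r, c]; t <- truth[s, r, c]
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# --- small, fast phantom spec for module tests ------------------------------
small_spec <- function(...) {
  phantom_spec(grid_shape = c(4, 128, 128), spacing = c(1.5, 1.5, 5),
               body_semiaxes_mm = c(60, 85), sat_mm = 12, muscle_mm = 8,
               n_blobs = 10, blob_r_mm = c(6, 14), spine_r_mm = 12,
               spine_offset_frac = 0.5, ...)
}
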
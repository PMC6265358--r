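# Near-uniform directions on the unit sphere from a subdivided
# icosahedron, with the vertex adjacency needed for angular-median
# regularization of per-ray radii.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  midpoint_cache <- new.env(hash = TRUE)
  get_mid <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    idx <- midpoint_cache[[key]]
    if (!is.null(idx)) return(idx)
    m <- (v[a, ] + v[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    v <<- rbind(v, m)
    idx <- nrow(v)
    midpoint_cache[[key]] <- idx
    idx
  }
  nf <- matrix(0L, nrow(f) * 4L, 3L)
  k <- 0L
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
    nf[k + 1L, ] <- c(a, ab, ca)
    nf[k + 2L, ] <- c(b, bc, ab)
    nf[k + 3L, ] <- c(cc, ca, bc)
    nf[k + 4L, ] <- c(ab, bc, ca)
    k <- k + 4L
  }
  list(vertices = v, faces = nf)
}

# directions + adjacency for >= n_min vertices (42, 162, 642, 2562, ...)
icosphere_directions <- function(n_min = 642) {
  mesh <- icosahedron()
  while (nrow(mesh$vertices) < n_min) mesh <- subdivide_mesh(mesh)
  nv <- nrow(mesh$vertices)
  adj <- vector("list", nv)
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
    adj[[a]] <- c(adj[[a]], b, cc)
    adj[[b]] <- c(adj[[b]], a, cc)
    adj[[cc]] <- c(adj[[cc]], a, b)
  }
  adj <- lapply(adj, unique)
  list(directions = mesh$vertices, neighbors = adj)
}
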
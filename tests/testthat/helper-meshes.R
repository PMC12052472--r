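# mesh fixtures built in code: icosphere, grid planes, hemisphere, cone

# subdivided icosahedron projected to a sphere (closed manifold)
icosphere <- function(subdiv = 4, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nV <- nrow(V)
    Vlist <- vector("list", 3L * nrow(F))
    Vcount <- 0L
    midmap <- new.env(hash = TRUE)
    getmid <- function(a, b) {
      key <- paste0(min(a, b), "_", max(a, b))
      hit <- midmap[[key]]
      if (!is.null(hit)) return(hit)
      p <- V[a, ] + V[b, ]
      p <- p / sqrt(sum(p^2))
      Vcount <<- Vcount + 1L
      Vlist[[Vcount]] <<- p
      midmap[[key]] <- nV + Vcount
      nV + Vcount
    }
    newF <- matrix(0L, 4L * nrow(F), 3L)
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; c <- F[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, c); ca <- getmid(c, a)
      newF[4L * i - 3L, ] <- c(a, ab, ca)
      newF[4L * i - 2L, ] <- c(b, bc, ab)
      newF[4L * i - 1L, ] <- c(c, ca, bc)
      newF[4L * i, ]      <- c(ab, bc, ca)
    }
    V <- rbind(V, do.call(rbind, Vlist[seq_len(Vcount)]))
    F <- newF
  }
  triangle_mesh(V * radius, F)
}

# regular grid plane z = 0 over [0, size] x [0, size]
grid_plane <- function(n = 10, size = 10) {
  g <- seq(0, size, length.out = n + 1)
  xy <- expand.grid(x = g, y = g)
  triangle_mesh(cbind(xy$x, xy$y, 0), eggscore:::.grid_faces(n + 1, n + 1))
}

# plane tilted by `deg` about the X axis
tilted_plane <- function(deg, n = 10, size = 10) {
  m <- grid_plane(n, size)
  th <- deg * pi / 180
  V <- m$vertices
  triangle_mesh(cbind(V[, 1], V[, 2] * cos(th), V[, 2] * sin(th)), m$faces)
}

# UV-tessellated unit hemisphere (pole up), fine enough for 1% integrals
uv_hemisphere <- function(n_polar = 120, n_azimuth = 240) {
  pol <- seq(0, pi / 2, length.out = n_polar)
  az <- seq(0, 2 * pi, length.out = n_azimuth + 1)[-(n_azimuth + 1)]
  V <- cbind(sin(rep(pol, each = n_azimuth)) * cos(az),
             sin(rep(pol, each = n_azimuth)) * sin(az),
             cos(rep(pol, each = n_azimuth)))
  F <- NULL
  idx <- function(i, j) (i - 1L) * n_azimuth + ((j - 1L) %% n_azimuth) + 1L
  i <- rep(seq_len(n_polar - 1L), each = n_azimuth)
  j <- rep(seq_len(n_azimuth), times = n_polar - 1L)
  F <- rbind(cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
             cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j)))
  # drop degenerate triangles at the pole (first polar ring collapses)
  m <- triangle_mesh(V, F)
  keep <- m$face_areas > 1e-15
  eggscore:::.subset_faces(m, keep)
}

# rotationally symmetric open cone, apex up
cone_mesh <- function(n = 180, radius = 1, height = 1) {
  az <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  V <- rbind(c(0, 0, height), cbind(radius * cos(az), radius * sin(az), 0))
  F <- cbind(1L, 1L + seq_len(n), 1L + c(seq_len(n)[-1], 1L))
  triangle_mesh(V, F)
}

# random 3D rotation matrix (uniform via QR of gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force exact two-sample KS p-value by full enumeration
ks_brute <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  vals <- sort(unique(pooled))
  D_of <- function(ia) {
    av <- pooled[ia]; bv <- pooled[-ia]
    Fa <- vapply(vals, function(v) mean(av <= v), 0)
    Fb <- vapply(vals, function(v) mean(bv <= v), 0)
    max(abs(Fa - Fb))
  }
  D0 <- D_of(seq_len(n))
  cmb <- utils::combn(n + m, n)
  ge <- apply(cmb, 2L, function(ia) D_of(ia) >= D0 - 1e-12)
  list(statistic = D0, p_value = mean(ge))
}
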
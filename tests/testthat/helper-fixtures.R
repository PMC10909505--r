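# Shared fixtures, all built in code.

# Four cells around a short central vertical edge: the canonical T1 setup.
# Cells E and W share the edge; N and S flank it.
pinwheel_mesh <- function(h = 0.02) {
  V <- rbind(c(0, -h), c(0, h),          # central edge a = 1, b = 2
             c(1, -1), c(1, 1), c(-1, 1), c(-1, -1))
  tissue_mesh(V, list(
    c(1, 3, 4, 2),   # E
    c(2, 4, 5),      # N
    c(2, 5, 6, 1),   # W
    c(1, 6, 3)))     # S
}

# A small interior triangle (area < 0.02) surrounded by three quads inside a
# big triangle: the canonical T2 setup.
triangle_in_triangle_mesh <- function(scale = 0.1) {
  a <- c(0, scale); b <- c(-scale, -0.6 * scale); cc <- c(scale, -0.6 * scale)
  P1 <- c(0, 2); P2 <- c(-2, -1.5); P3 <- c(2, -1.5)
  V <- rbind(a, b, cc, P1, P2, P3)
  tissue_mesh(V, list(
    c(1, 2, 3),        # inner triangle (a, b, c)
    c(2, 1, 4, 5),     # left
    c(3, 2, 5, 6),     # bottom
    c(1, 3, 6, 4)))    # right
}

# Hexagonal patch with jittered vertices: a generic irregular-but-valid mesh.
jittered_patch <- function(n_cells = 7, jitter = 0.03, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- build_hexagonal_lattice(n_cells)
  m$vertices <- m$vertices +
    matrix(stats::rnorm(length(m$vertices), 0, jitter), ncol = 2)
  m
}

# Energy of a regular hexagon of side s with target area a0 (closed form).
hexagon_energy <- function(s, a0, K = 1, Lambda = 0.05, Gamma = 0.02) {
  A <- 3 * sqrt(3) / 2 * s^2
  K / 2 * (A - a0)^2 + Gamma / 2 * (6 * s)^2 + Lambda * 6 * s
}

# 1D oracle: optimal side of a single regular hexagon under the full energy.
hexagon_optimal_side <- function(a0 = 1, K = 1, Lambda = 0.05, Gamma = 0.02) {
  stats::optimize(hexagon_energy, c(1e-3, 3), a0 = a0, K = K,
                  Lambda = Lambda, Gamma = Gamma)$minimum
}

# Central finite differences of total_energy (the force oracle).
fd_forces <- function(mesh, targets, params, h = 1e-6) {
  G <- matrix(0, nrow(mesh$vertices), 2)
  for (i in seq_len(nrow(mesh$vertices))) {
    for (d in 1:2) {
      mp <- mesh; mp$vertices[i, d] <- mp$vertices[i, d] + h
      mm <- mesh; mm$vertices[i, d] <- mm$vertices[i, d] - h
      G[i, d] <- -(total_energy(mp, targets, params) -
                     total_energy(mm, targets, params)) / (2 * h)
    }
  }
  G
}
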
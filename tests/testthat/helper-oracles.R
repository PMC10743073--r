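# Shared fixtures and independent oracles.
#
# The LOF oracle below is deliberately written from the definitions with
# explicit loops and full sorts, sharing no code with the package
# implementation: neighbourhoods from a per-point sorted distance list,
# reachability distances pair by pair.

oracle_dist <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    }
  }
  D
}

oracle_kdist <- function(D, q, k) {
  sort(D[q, -q])[k]
}

oracle_neighbors <- function(D, p, k) {
  kd <- oracle_kdist(D, p, k)
  setdiff(which(D[p, ] <= kd), p)
}

oracle_rd <- function(D, p, q, k) {
  max(D[p, q], oracle_kdist(D, q, k))
}

oracle_lrd <- function(D, p, k) {
  nb <- oracle_neighbors(D, p, k)
  total <- 0
  for (q in nb) total <- total + oracle_rd(D, p, q, k)
  m <- total / length(nb)
  if (m <= 0) 1e12 else min(1 / m, 1e12)
}

oracle_lof <- function(D, p, k) {
  nb <- oracle_neighbors(D, p, k)
  acc <- 0
  for (q in nb) acc <- acc + oracle_lrd(D, q, k) / oracle_lrd(D, p, k)
  acc / length(nb)
}

oracle_lof_all <- function(X, k) {
  D <- oracle_dist(as.matrix(X))
  vapply(seq_len(nrow(D)), function(p) oracle_lof(D, p, k), numeric(1))
}

# Regular n-gon on the unit circle: the symmetry group acts transitively on
# the vertices, so every LOF is 1.
make_polygon <- function(n, radius = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  feature_dataset(cbind(x = radius * cos(th), y = radius * sin(th)))
}

# Small integer-grid dataset: exact distance ties to exercise the
# tie-inclusive neighbourhood convention.
make_grid_dataset <- function(n, seed) {
  pts <- with_local_seed(seed, {
    grid <- as.matrix(expand.grid(x = 0:3, y = 0:3))
    grid[sample(nrow(grid), n), , drop = FALSE]
  })
  feature_dataset(pts)
}

make_gaussian_dataset <- function(n, seed, d = 2L) {
  X <- with_local_seed(seed, matrix(rnorm(n * d), n, d))
  feature_dataset(X)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Proper rigid motion applied to a macrocycle (and its iron/axial fields).
rigid_motion <- function(mac, angles, translation) {
  R <- hemescan:::euler_rotation(angles)
  xyz <- mac$xyz %*% t(R)
  xyz <- sweep(xyz, 2L, translation, "+")
  dimnames(xyz) <- dimnames(mac$xyz)
  iron <- if (is.null(mac$iron)) NULL else
    as.numeric(mac$iron %*% t(R)) + translation
  axial <- if (is.null(mac$axial)) NULL else as.numeric(mac$axial %*% t(R))
  hemescan:::new_macrocycle(mac$heme_id, xyz, iron, axial)
}

# The C4 rotation + cyclic pyrrole relabel permutation used in D4h checks:
# perm[i] is the index whose label is the relabelled form of label i.
c4_relabel_perm <- function() {
  lab <- macrocycle_atom_labels()
  relab <- paste0(substr(lab, 1L, nchar(lab) - 1L),
                  chartr("ABCD", "BCDA", substring(lab, nchar(lab))))
  match(relab, lab)
}
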
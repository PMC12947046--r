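# Shared fixtures: everything is generated in code at test time.

# A random point-cloud structure with safe interatomic distances.
random_structure <- function(n = 5L, seed = 1L, elements = c(1L, 6L, 8L),
                             id = "s", gid = "g") {
  set.seed(seed)
  repeat {
    pos <- matrix(runif(n * 3, 0, 2.2 * n^(1 / 3)), n, 3)
    if (n == 1L || min(dist(pos)) > 0.7) break
  }
  structure_new(id, gid, sample(elements, n, replace = TRUE), pos)
}

# A small model that keeps tests fast: narrow features, short RBF grid.
tiny_model <- function(n_features = 8L, n_interactions = 2L, seed = 1L,
                       elements = c(1L, 6L, 7L, 8L), n_centers = 12L) {
  gnn_init(elements = elements, n_features = n_features,
           n_interactions = n_interactions,
           rbf = rbf_config(n_centers,
                            seq(0, by = 0.75, length.out = n_centers)),
           r_cut_init = 6, seed = seed)
}

# A rigid rotation matrix from three angles.
rotation_matrix <- function(a, b, c) {
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# Apply a random rigid motion (+ optional permutation) to a structure.
transformed_copy <- function(s, seed = 1L, permute = FALSE) {
  set.seed(seed)
  R <- rotation_matrix(runif(1, 0, 2 * pi), runif(1, 0, 2 * pi),
                       runif(1, 0, 2 * pi))
  shift <- matrix(runif(3, -10, 10), nrow(s$positions), 3, byrow = TRUE)
  pos <- s$positions %*% R + shift
  z <- s$atomic_numbers
  if (permute) {
    perm <- sample(length(z))
    z <- z[perm]
    pos <- pos[perm, , drop = FALSE]
  }
  structure_new(paste0(s$structure_id, "_t"), s$group_id, z, pos,
                s$properties)
}

# A small conformer group with the synthetic energy attached.
small_group <- function(n_structs = 4L, n_atoms = 4L, seed = 1L,
                        gid = "g1") {
  set.seed(seed)
  base <- random_structure(n_atoms, seed = seed, gid = gid)
  structs <- lapply(seq_len(n_structs), function(k) {
    pos <- base$positions +
      if (k == 1L) 0 else matrix(rnorm(n_atoms * 3, 0, 0.25), n_atoms, 3)
    s <- structure_new(sprintf("%s_s%d", gid, k), gid, base$atomic_numbers,
                       pos)
    s$properties$energy <- coulomb_like_energy(s)
    s
  })
  conformer_group(gid, structs)
}
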
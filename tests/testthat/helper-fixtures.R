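# shared fixtures built in code

# minimal phenotyped cell table from coordinates and codes
make_cells <- function(x, y, phenotype = 0L, sample_id = "S1") {
  n <- length(x)
  data.frame(cell_id = sprintf("%s_c%04d", rep_len(sample_id, n),
                               seq_len(n)),
             sample_id = rep_len(sample_id, n), x_um = x, y_um = y,
             phenotype = rep_len(as.integer(phenotype), n),
             stringsAsFactors = FALSE)
}

# uniform random phenotyped cells in a square field
random_cells <- function(n, field = 1000, seed = 1) {
  set.seed(seed)
  make_cells(runif(n, 0, field), runif(n, 0, field),
             sample(0:7, n, replace = TRUE))
}

# small, fast simulation config (a few hundred cells); aggregate offsets
# shrunk so lymphoid aggregates fit the reduced field
small_config <- function(archetype = "inflamed_margin", seed = 1, ...) {
  simulation_config(archetype = archetype,
                    field_size_um = c(1500, 1500),
                    tumor_radius_um = 400, stroma_margin_um = 250,
                    aggregate_offset_um = c(250, 350),
                    seed = seed, ...)
}

# isotropic Gaussian blobs with known memberships
make_blobs <- function(k, n_per = 200, sep = 10, sigma = 0.5, seed = 1) {
  set.seed(seed)
  centers <- cbind(sep * seq_len(k), sep * (seq_len(k) %% 2))
  pts <- do.call(rbind, lapply(seq_len(k), function(i)
    cbind(rnorm(n_per, centers[i, 1], sigma),
          rnorm(n_per, centers[i, 2], sigma))))
  list(points = pts, labels = rep(seq_len(k), each = n_per))
}
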
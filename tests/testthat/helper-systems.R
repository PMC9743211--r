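# Shared fixtures, all generated in code.

# Small grid used by most voxel tests.
test_grid <- function(d = 9L, r = 3, sigma = 0.5)
  grid_spec(d = d, r_grid = r, sigma = sigma, sigma_units = "angstrom")

# A tiny model configuration that keeps gradient checks fast.
tiny_config <- function(grid = grid_spec(d = 9L, r_grid = 8, sigma = 1,
                                         sigma_units = "angstrom"),
                        n_atoms = 4L, n_beads = 2L)
  model_config(n_atoms, n_beads, grid, d_latent = 3L, hidden = 8L,
               n_blocks = 1L)

# Write a synthetic alanine-dipeptide-like topology (22 atoms, standard
# atom names for ACE-ALA-NME); coordinates are placeholders.
write_adp_topology <- function(path) {
  atoms <- list(
    c("HH31", "ACE", 1), c("CH3", "ACE", 1), c("HH32", "ACE", 1),
    c("HH33", "ACE", 1), c("C", "ACE", 1), c("O", "ACE", 1),
    c("N", "ALA", 2), c("H", "ALA", 2), c("CA", "ALA", 2),
    c("HA", "ALA", 2), c("CB", "ALA", 2), c("HB1", "ALA", 2),
    c("HB2", "ALA", 2), c("HB3", "ALA", 2), c("C", "ALA", 2),
    c("O", "ALA", 2),
    c("N", "NME", 3), c("H", "NME", 3), c("CH3", "NME", 3),
    c("HH31", "NME", 3), c("HH32", "NME", 3), c("HH33", "NME", 3))
  set.seed(4)
  # PDB fixed columns: 4-character atom names start in column 13,
  # shorter names in column 14
  fmt_name <- function(n)
    if (nchar(n) >= 4L) sprintf("%-4s", n) else sprintf(" %-3s", n)
  lines <- vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    xyz <- round(rnorm(3, 0, 2), 3)
    sprintf("ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, fmt_name(a[[1]]), a[[2]], as.integer(a[[3]]),
            xyz[1], xyz[2], xyz[3])
  }, "")
  writeLines(c(lines, "END"), path)
  path
}

# Synthetic 10-residue backbone-only topology (N, CA, C per residue).
write_cln_topology <- function(path, n_res = 10L) {
  lines <- character()
  i <- 0L
  set.seed(5)
  for (r in seq_len(n_res)) {
    for (nm in c("N", "CA", "C")) {
      i <- i + 1L
      xyz <- round(rnorm(3, 0, 3), 3)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, nm, "GLY", as.integer(r), xyz[1], xyz[2], xyz[3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# Random frame with all particles comfortably inside a grid.
random_inbounds_frame <- function(n, spec, seed = NULL, frac = 0.8) {
  if (!is.null(seed)) set.seed(seed)
  margin <- (spec$r_grid - 3 * spec$sigma) * frac
  frame(matrix(runif(3 * n, -margin, margin), n, 3L))
}
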
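# Shared fixture builders. Everything is generated in code at test time.

# A small desk-scale design: full concentration ladder, reduced depth.
desk_design <- function(depth = 0.01, ...) {
  scale_design(sort_design(...), depth)
}

# A random library with log-uniform KD across the sensitivity window.
random_library <- function(n, seed, lo = -9.5, hi = -5, ...) {
  withr::with_seed(seed, ground_truth_library(kd = 10^runif(n, lo, hi), ...))
}

# Write a minimal PDB file from an atom table; returns the path.
toy_pdb <- function(atoms, file = tempfile(fileext = ".pdb")) {
  write_coordinate_file(atoms, file)
  file
}

toy_atom <- function(resno, x, y, z, elety = "CA", chain = "A",
                     type = "ATOM", resid = "GLY", elesy = "C") {
  data.frame(type = type, elety = elety, resid = resid, chain = chain,
             resno = resno, x = x, y = y, z = z, elesy = elesy,
             stringsAsFactors = FALSE)
}
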
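# shared fixtures, built in code

random_peptides <- function(n, len_range = c(5L, 30L), seed = 1L) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# fixed-width PDB ATOM line (wwPDB v3.3 columns)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resno, x, y, z, element)
}

# three-residue toy structure: GLY-ALA-LYS with hand-written coordinates;
# ALA has a single CB so its centroid is exactly the CB position
write_toy_pdb <- function(path, third_res = "LYS") {
  lines <- c(
    pdb_atom_line(1, " N  ", "GLY", "A", 1, 0.0, 0.0, 0.0, "N"),
    pdb_atom_line(2, " CA ", "GLY", "A", 1, 1.5, 0.0, 0.0, "C"),
    pdb_atom_line(3, " C  ", "GLY", "A", 1, 2.0, 1.4, 0.0, "C"),
    pdb_atom_line(4, " O  ", "GLY", "A", 1, 1.5, 2.4, 0.0, "O"),
    pdb_atom_line(5, " N  ", "ALA", "A", 2, 3.3, 1.4, 0.0, "N"),
    pdb_atom_line(6, " CA ", "ALA", "A", 2, 0.0, 0.0, 0.0, "C"),
    pdb_atom_line(7, " CB ", "ALA", "A", 2, 1.0, 0.0, 0.0, "C"),
    pdb_atom_line(8, " C  ", "ALA", "A", 2, 4.8, 2.8, 0.0, "C"),
    pdb_atom_line(9, " O  ", "ALA", "A", 2, 4.3, 3.9, 0.0, "O"),
    pdb_atom_line(10, " N  ", third_res, "A", 3, 6.1, 2.8, 0.0, "N"),
    pdb_atom_line(11, " CA ", third_res, "A", 3, 7.0, 3.9, 0.0, "C"),
    pdb_atom_line(12, " CB ", third_res, "A", 3, 8.4, 3.4, 0.0, "C"),
    pdb_atom_line(13, " CG ", third_res, "A", 3, 9.4, 4.5, 0.0, "C"),
    pdb_atom_line(14, " C  ", third_res, "A", 3, 7.1, 5.1, 0.0, "C"),
    pdb_atom_line(15, " O  ", third_res, "A", 3, 6.5, 6.1, 0.0, "O"),
    "TER", "END")
  writeLines(lines, path)
  path
}

# small labelled separable feature table for model tests
toy_feature_table <- function(n_per_class = 30L, p = 13L, shift = 3,
                              seed = 1L) {
  set.seed(seed)
  x_pos <- matrix(rnorm(n_per_class * p, mean = shift), n_per_class, p)
  x_neg <- matrix(rnorm(n_per_class * p, mean = 0), n_per_class, p)
  x <- rbind(x_pos, x_neg)
  colnames(x) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(
      id = sprintf("r%03d", seq_len(2 * n_per_class)),
      label = rep(c("CPP", "nonCPP"), each = n_per_class)),
    tibble::as_tibble(x))
}
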
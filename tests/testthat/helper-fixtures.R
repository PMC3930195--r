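# shared in-code fixtures: hand-formatted PDB records, random atom
# clusters, single-column alignments and labelled residue sets

pdb_atom_line <- function(serial, name, alt, resname, chain, resno,
                          x, y, z, occ = 1, elem = "C", record = "ATOM  ") {
  sprintf("%s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resname, chain, resno,
          x, y, z, occ, 0, elem)
}

pdb_text <- function(...) paste(c(..., "END"), collapse = "\n")

# seeded random heavy-atom cluster in a box, radii from the element table
random_cluster <- function(seed, n_max = 10L, box = 6) {
  set.seed(seed)
  n <- sample(2:n_max, 1L)
  data.frame(x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
             radius = sample(unname(vdw_radii()[c("C", "N", "O", "S")]), n,
                             replace = TRUE))
}

# alignment with query "V" and one homolog row per supplied character
column_aln <- function(chars) {
  fasta <- paste(c(">q", "V", rbind(paste0(">h", seq_along(chars)), chars)),
                 collapse = "\n")
  parse_alignment(fasta, "q")
}

# multi-protein labelled residue set with seeded names and states
random_labelled_set <- function(seed, n_prot = 3L, len = 40L) {
  set.seed(seed)
  aas <- c("V", "I", "L", "M", "F", "A", "S", "T", "D", "E",
           "K", "R", "G", "Y", "W", "N", "Q", "H", "P", "C")
  do.call(rbind, lapply(seq_len(n_prot), function(p) {
    data.frame(protein_id = paste0("p", p), chain = "A",
               residue_index = seq_len(len),
               residue_name = sample(aas, len, replace = TRUE),
               state = sample(c("buried", "exposed"), len, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
}

# brute-force pair-enumeration oracle for flanking propensity
flanking_oracle <- function(data, offset, type, anchor_state,
                            anchors = c("V", "I", "L", "M", "F")) {
  aa <- data$residue_name
  num <- 0L; den <- 0L
  for (r in seq_len(nrow(data))) {
    if (!(aa[r] %in% anchors) || data$state[r] != anchor_state) next
    nb <- which(data$protein_id == data$protein_id[r] &
                data$chain == data$chain[r] &
                data$residue_index == data$residue_index[r] + offset)
    if (length(nb) != 1L) next
    den <- den + 1L
    if (aa[nb] == type) num <- num + 1L
  }
  (num / den) / (sum(aa == type) / length(aa))
}
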
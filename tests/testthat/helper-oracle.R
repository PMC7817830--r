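# Frozen expected values, computed independently (residue-by-residue
# summation from atomic compositions, cross-checked with pyteomics) before
# the implementation was written.
oracle <- list(
  gg_mono            = 132.05349,     # C4H8N2O3
  backbone_mono      = 1393.767762,   # IISKIENHEGVR
  branch_residue_sum = 2135.920495,   # ELGMEEEDVIEVYQEQTGG minus water
  conjugate_mono     = 3529.688258,
  b1_E_mz            = 130.049870,    # branch-b1, charge 1
  light = c(yp2 = 754.9126, yp3 = 805.4365, yp5 = 933.9870, b4 = 860.0791),
  heavy = c(yp2 = 757.9195, yp3 = 808.4434, yp5 = 936.9940, b4 = 862.4182),
  printed_light = c(yp2 = 754.92, yp3 = 805.44, yp5 = 933.99, b4 = 860.08),
  printed_heavy = c(yp2 = 757.92, yp3 = 808.44, yp5 = 936.99, b4 = 862.42)
)

# independent digestion oracle: regex split after K/R not before P
oracle_digest <- function(seq) {
  strsplit(seq, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

aa_alphabet <- function() residue_masses()$residue

rand_seq <- function(n, exclude = character()) {
  paste(sample(setdiff(aa_alphabet(), exclude), n, replace = TRUE),
        collapse = "")
}

# a random branched conjugate: backbone with one K, arbitrary branch
rand_conjugate <- function(len_backbone = 8, len_branch = 5) {
  pos <- sample(seq_len(len_backbone), 1)
  chars <- strsplit(rand_seq(len_backbone, exclude = "K"), "")[[1]]
  chars[pos] <- "K"
  branched_conjugate(paste(chars, collapse = ""), pos,
                     branch = rand_seq(len_branch))
}

k270_conjugate <- function(...) {
  branched_conjugate("IISKIENHEGVR", 4, protein_site = 270, ...)
}

k270_heavy_labels <- function() {
  make_heavy_labels(k270_conjugate(), backbone_positions = 11,
                    branch_positions = 2)
}

k270_transitions <- function() {
  design_transitions(
    k270_conjugate(),
    products = data.frame(
      series = c("branch-y'", "branch-y'", "branch-y'", "backbone-b"),
      index = c(2L, 3L, 5L, 4L), charge = c(2L, 2L, 2L, 3L)),
    heavy_labels = k270_heavy_labels(), peptide_id = "K270")
}

pkm2_fasta <- function() {
  system.file("extdata", "PKM2_human.fasta", package = "branchms")
}
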
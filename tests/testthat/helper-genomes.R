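# build a Genome (and matching fabricated role table) from a vector of
# roles (NA for background), one gene per rank on a single contig
make_role_genome <- function(roles, genome_id = "G1",
                             taxon = "Hyphomicrobiales", contig = "c1",
                             seqs = NULL) {
  n <- length(roles)
  genes <- data.frame(
    genome_id = genome_id, contig_id = contig, locus_index = seq_len(n) - 1L,
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 300L,
    strand = rep("+", n), gene_id = sprintf("%s_g%02d", genome_id, seq_len(n)),
    product = "", protein_seq = if (is.null(seqs)) rep("MKL", n) else seqs,
    stringsAsFactors = FALSE)
  g <- structure(list(genome_id = genome_id, taxon_order = taxon,
                      genes = genes), class = "Genome")
  validate_genome(g)
  role_tab <- data.frame(gene_id = genes$gene_id, role = roles,
                         best_seed = ifelse(is.na(roles), NA, "fab"),
                         pct_identity = ifelse(is.na(roles), 0, 100),
                         coverage = 1, stringsAsFactors = FALSE)
  list(genome = g, roles = role_tab)
}

# genomes with real planted sequences (exact seed copies) for alignment-backed
# census tests; layout: roles vector as above, background genes random
make_planted_genome <- function(roles, genome_id, taxon,
                                seeds = default_seed_db(), identity = 1) {
  aa <- setdiff(AA_ALPHABET, "X")
  seqs <- vapply(seq_along(roles), function(i) {
    if (is.na(roles[i])) paste(sample(aa, 150, replace = TRUE), collapse = "")
    else if (identity >= 1) seed_by_role(seeds, roles[i])
    else mutate_to_identity(seed_by_role(seeds, roles[i]), identity)
  }, character(1))
  make_role_genome(roles, genome_id, taxon, seqs = seqs)$genome
}
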
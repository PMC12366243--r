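test_that("mutate_to_identity hits its target and is reproducible", {
  seeds <- default_seed_db()
  s <- seed_by_role(seeds, "PbfF")  # 340 aa
  expect_identical(mutate_to_identity(s, 1.0, rng = 1), s)
  ids <- vapply(1:25, function(i)
    global_align(mutate_to_identity(s, 0.5, rng = i), s)$pct_identity,
    numeric(1))
  expect_true(all(abs(ids - 50) <= 2))
  expect_identical(mutate_to_identity(s, 0.5, rng = 42),
                   mutate_to_identity(s, 0.5, rng = 42))
  expect_error(mutate_to_identity(s, 0.1), "target")
  # mutation is substitution-only: length preserved
  expect_equal(nchar(mutate_to_identity(s, 0.3, rng = 3)), nchar(s))
})

test_that("a zero-genome config yields an empty collection and manifest", {
  cfg <- synthetic_config(n_genomes = c(Hyphomicrobiales = 0))
  out <- tempfile()
  gen <- generate_collection(cfg, out)
  expect_length(gen$manifest, 0L)
  expect_equal(nrow(read_table(gen$metadata_path)), 0L)
})

test_that("generated files re-read through genome_io reproduce the manifest placement", {
  cfg <- synthetic_config(n_genomes = c(Hyphomicrobiales = 3,
                                        Rhodobacterales = 2), seed = 11)
  out <- tempfile()
  gen <- generate_collection(cfg, out)
  genomes <- load_genome_collection(out, gen$metadata_path)
  expect_length(genomes, 5L)
  for (m in gen$manifest) {
    g <- genomes[[m$genome_id]]
    expect_equal(g$taxon_order, m$taxon_order)
    for (cl in c(m$clusters, m$decoys)) {
      idx <- match(cl$gene_ids, g$genes$gene_id)
      expect_false(anyNA(idx))
      # planted unit members are consecutive genes
      ranks <- sort(g$genes$locus_index[idx])
      expect_equal(ranks, seq(min(ranks), max(ranks)))
    }
    for (p in m$phnA_copies)
      expect_true(p$gene_id %in% g$genes$gene_id)
  }
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synthetic_config(recipe_probs = c(none = 0.5, phnWX = 0.1,
                                                 phnWYA = 0.1)), "sum to 1")
  expect_error(synthetic_config(identity_target = 0.1), "identity target")
})

test_that("planted markers are recovered and background draws no role calls", {
  cfg <- synthetic_config(n_genomes = c(Hyphomicrobiales = 2), seed = 23,
                          recipe_probs = c(none = 0, phnWX = 0, phnWYA = 1),
                          ancillary_probs = c(PbfA = 1, PbfC = 0, PbfD = 0,
                                              PbfF = 1))
  out <- tempfile()
  gen <- generate_collection(cfg, out)
  genomes <- load_genome_collection(out, gen$metadata_path)
  for (m in gen$manifest) {
    g <- genomes[[m$genome_id]]
    roles <- assign_roles(g)
    truth <- stats::setNames(
      unlist(lapply(c(m$clusters, m$decoys), function(u) u$roles)),
      unlist(lapply(c(m$clusters, m$decoys), function(u) u$gene_ids)))
    for (k in seq_len(nrow(roles))) {
      expected <- truth[roles$gene_id[k]]
      if (is.na(expected)) {
        expect_true(is.na(roles$role[k]),
                    info = paste("false positive on", roles$gene_id[k],
                                 "->", roles$role[k]))
      } else {
        expect_equal(roles$role[k], unname(expected))
      }
    }
  }
})

test_that("generation is deterministic at fixed seed", {
  cfg <- synthetic_config(n_genomes = c(Hyphomicrobiales = 2), seed = 99)
  g1 <- generate_collection(cfg, tempfile())
  g2 <- generate_collection(cfg, tempfile())
  f1 <- list.files(g1$dir); f2 <- list.files(g2$dir)
  expect_equal(f1, f2)
  for (f in setdiff(f1, "manifest.json"))
    expect_identical(readLines(file.path(g1$dir, f)),
                     readLines(file.path(g2$dir, f)))
  expect_equal(g1$manifest, g2$manifest)
})
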
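test_that("role assignment recovers exact and mutated seed copies", {
  seeds <- default_seed_db()
  set.seed(31)
  g <- make_planted_genome(c(NA, "PbfF", NA), "G1", "Hyphomicrobiales")
  roles <- assign_roles(g, seeds)
  expect_equal(roles$role[2], "PbfF")
  expect_equal(roles$pct_identity[2], 100)
  expect_true(all(is.na(roles$role[c(1, 3)])))

  # ~50% identity is called; ~20% identity is not
  g50 <- make_planted_genome(c("PhnY"), "G2", "Hyphomicrobiales",
                             identity = 0.5)
  expect_equal(assign_roles(g50, seeds)$role, "PhnY")
  g20 <- make_planted_genome(c("PhnY"), "G3", "Hyphomicrobiales",
                             identity = 0.2)
  expect_true(is.na(assign_roles(g20, seeds)$role))
})

test_that("ties go to the highest-identity seed", {
  set.seed(17)
  aa <- setdiff(AA_ALPHABET, "X")
  base <- paste(sample(aa, 250, replace = TRUE), collapse = "")
  seedA <- mutate_to_identity(base, 0.7)
  db <- data.frame(seed_id = c("S_PHNA", "S_PHNY"),
                   role = c("PhnA", "PhnY"),
                   sequence = c(seedA, base), stringsAsFactors = FALSE)
  class(db) <- c("seed_db", "data.frame")
  query <- mutate_to_identity(seedA, 0.6)  # closer to the PhnA seed
  gm <- make_role_genome(c("PhnA"), "G4", seqs = query)$genome
  r <- assign_roles(gm, db)
  idA <- global_align(query, seedA)$pct_identity
  idY <- global_align(query, base)$pct_identity
  expect_gt(idA, idY)
  expect_gte(idY, 35)  # both seeds pass the threshold; max rule decides
  expect_equal(r$role, "PhnA")
  expect_equal(r$best_seed, "S_PHNA")
})

test_that("a genome without protein sequences yields an empty assignment with warning", {
  mk <- make_role_genome(c(NA, NA), "G5")
  mk$genome$genes$protein_seq <- NA_character_
  expect_warning(r <- assign_roles(mk$genome), "no protein sequences")
  expect_equal(nrow(r), 0L)
})

test_that("neighborhood scan respects the +/-k window and contig edges", {
  roles <- rep(NA_character_, 30)
  roles[c(1, 12, 24)] <- c("PhnA", "PbfA", "PbfF")
  mk <- make_role_genome(roles)
  focal <- mk$genome$genes$gene_id[13]  # locus_index 12, no role

  nb <- scan_neighborhood(mk$genome, focal, 10, mk$roles)
  expect_true("PbfA" %in% nb)          # locus 11, distance 1
  expect_false("PhnA" %in% nb)         # locus 0, distance 12 -> excluded
  # PbfF at locus 23, distance 11 -> excluded at k = 10, included at k = 11
  expect_false("PbfF" %in% nb)
  expect_true("PbfF" %in% scan_neighborhood(mk$genome, focal, 11, mk$roles))
  # the focal gene itself is never reported
  expect_length(scan_neighborhood(mk$genome, mk$genome$genes$gene_id[12],
                                  0, mk$roles), 0L)

  # focal at locus 2: window truncates at the contig start (covers 0-12)
  focal2 <- mk$genome$genes$gene_id[3]
  nb2 <- scan_neighborhood(mk$genome, focal2, 10, mk$roles)
  expect_setequal(nb2, c("PhnA", "PbfA"))

  # a gene alone on a contig has no neighbors
  solo <- make_role_genome(c("PhnA"), "solo")
  expect_length(scan_neighborhood(solo$genome, solo$genome$genes$gene_id[1],
                                  10, solo$roles), 0L)
  expect_error(scan_neighborhood(mk$genome, "nope", 10, mk$roles),
               "unknown gene_id")
})

test_that("cluster detection types cores and collects ancillaries", {
  # phnW and phnX adjacent: minimal phnWX cluster
  mk <- make_role_genome(c(NA, "PhnW", "PhnX", NA))
  cl <- detect_clusters(mk$genome, mk$roles)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$core_type, "phnWX")
  expect_length(cl[[1]]$ancillary, 0L)

  # phnW alone: no cluster
  mk2 <- make_role_genome(c(NA, "PhnW", NA))
  expect_length(detect_clusters(mk2$genome, mk2$roles), 0L)

  # phnW-phnX-pbfA-pbfF arrangement: phnWX core with {PbfA, PbfF}
  mk3 <- make_role_genome(c("PhnW", "PhnX", "PbfA", "PbfF"))
  cl3 <- detect_clusters(mk3$genome, mk3$roles)
  expect_length(cl3, 1L)
  expect_equal(cl3[[1]]$core_type, "phnWX")
  expect_equal(cl3[[1]]$ancillary, c("PbfA", "PbfF"))
  expect_equal(cl3[[1]]$span, c(0L, 3L))

  # phnW and phnX separated by 11 background genes (rank distance 12): no cluster
  mk4 <- make_role_genome(c("PhnW", rep(NA, 11), "PhnX"))
  expect_length(detect_clusters(mk4$genome, mk4$roles), 0L)
  # 9 background genes (rank distance 10) sit exactly on the window edge
  mk5 <- make_role_genome(c("PhnW", rep(NA, 9), "PhnX"))
  expect_length(detect_clusters(mk5$genome, mk5$roles), 1L)
})

test_that("phnWYA typing, the 'both' type, and context genes", {
  mk <- make_role_genome(c("PhnW", "PhnY", "PhnA", "transporter", "PbfF"))
  cl <- detect_clusters(mk$genome, mk$roles)
  expect_equal(cl[[1]]$core_type, "phnWYA")
  expect_equal(cl[[1]]$ancillary, "PbfF")
  # transporter is a member but not part of typing or span
  expect_true(mk$genome$genes$gene_id[4] %in% cl[[1]]$member_gene_ids)
  expect_equal(cl[[1]]$span, c(0L, 4L))

  mk2 <- make_role_genome(c("PhnW", "PhnX", "PhnY", "PhnA"))
  expect_equal(detect_clusters(mk2$genome, mk2$roles)[[1]]$core_type, "both")
})

test_that("every reported cluster satisfies its core-type requirement", {
  set.seed(12)
  pool <- c(CORE_ROLES, ANCILLARY_ROLES, NA, NA, NA, NA)
  for (i in 1:25) {
    roles <- sample(pool, sample(5:25, 1), replace = TRUE)
    mk <- make_role_genome(roles)
    for (cl in detect_clusters(mk$genome, mk$roles)) {
      present <- mk$roles$role[match(cl$core_gene_ids, mk$roles$gene_id)]
      ok <- switch(cl$core_type,
                   phnWX = all(c("PhnW", "PhnX") %in% present),
                   phnWYA = all(c("PhnW", "PhnY", "PhnA") %in% present),
                   both = all(CORE_ROLES %in% present))
      expect_true(ok, info = paste(roles, collapse = ","))
    }
  }
})

test_that("cluster detection is invariant under gene-order reversal", {
  set.seed(13)
  pool <- c(CORE_ROLES, ANCILLARY_ROLES, NA, NA, NA)
  for (i in 1:10) {
    roles <- sample(pool, sample(6:20, 1), replace = TRUE)
    fwd <- make_role_genome(roles)
    rev_mk <- make_role_genome(rev(roles))
    f <- detect_clusters(fwd$genome, fwd$roles)
    r <- detect_clusters(rev_mk$genome, rev_mk$roles)
    sig <- function(cls) sort(vapply(cls, function(cl)
      paste(cl$core_type, paste(cl$ancillary, collapse = "+")), character(1)))
    expect_equal(sig(f), sig(r), info = paste(roles, collapse = ","))
  }
})
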
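nesting_genomes <- function() {
  # planted ground truth: A has all four, B lacks pbfF, C lacks pbfA too,
  # D has phnA alone, E has nothing
  list(make_role_genome(c("PhnA", "PhnY", "PbfA", "PbfF"), "A"),
       make_role_genome(c("PhnA", "PhnY", "PbfA"), "B"),
       make_role_genome(c("PhnA", "PhnY"), "C", taxon = "Rhodobacterales"),
       make_role_genome(c("PhnA", NA), "D", taxon = "Rhodobacterales"),
       make_role_genome(c(NA, NA), "E"))
}

test_that("the planted nesting fixture yields counts 4, 3, 2, 1", {
  mks <- nesting_genomes()
  genomes <- lapply(mks, function(m) m$genome)
  roles <- lapply(mks, function(m) m$roles)
  names(roles) <- vapply(genomes, function(g) g$genome_id, character(1))
  tab <- run_census(genomes, roles_by_genome = roles)
  tot <- tab[tab$taxon_order == "TOTAL", ]
  expect_equal(tot$n_genomes, 5L)
  expect_equal(unlist(tot[, 3:6], use.names = FALSE), c(4L, 3L, 2L, 1L))
  # stratification by order
  hyp <- tab[tab$taxon_order == "Hyphomicrobiales", ]
  expect_equal(unlist(hyp[, 3:6], use.names = FALSE), c(2L, 2L, 2L, 1L))
  rho <- tab[tab$taxon_order == "Rhodobacterales", ]
  expect_equal(unlist(rho[, 3:6], use.names = FALSE), c(2L, 1L, 0L, 0L))
  # TOTAL equals the column-wise sum of the order rows
  expect_equal(unlist(tot[, 2:6], use.names = FALSE),
               unlist(hyp[, 2:6] + rho[, 2:6], use.names = FALSE))
  expect_true(census_is_nested(tab))
})

test_that("census counts per hit, not per genome, and is order-invariant", {
  # one genome with two phnA paralogs in different contexts
  mk <- make_role_genome(c("PhnA", "PhnY", rep(NA, 12), "PhnA"), "P1")
  tab <- run_census(list(mk$genome),
                    roles_by_genome = stats::setNames(list(mk$roles), "P1"))
  tot <- tab[tab$taxon_order == "TOTAL", ]
  expect_equal(tot$n_phnA_hits, 2L)
  expect_equal(tot$n_with_phnY, 1L)  # the distant paralog has no phnY neighbor

  mks <- nesting_genomes()
  genomes <- lapply(mks, function(m) m$genome)
  roles <- stats::setNames(lapply(mks, function(m) m$roles),
                           vapply(genomes, function(g) g$genome_id, character(1)))
  t1 <- run_census(genomes, roles_by_genome = roles)
  perm <- c(4, 2, 5, 1, 3)
  t2 <- run_census(genomes[perm], roles_by_genome = roles)
  attr(t1, "hits") <- NULL; attr(t2, "hits") <- NULL
  expect_equal(t1, t2)
})

test_that("removing all pbfF genes zeroes only the fourth column", {
  mks <- nesting_genomes()
  genomes <- lapply(mks, function(m) m$genome)
  roles <- stats::setNames(lapply(mks, function(m) m$roles),
                           vapply(genomes, function(g) g$genome_id, character(1)))
  before <- run_census(genomes, roles_by_genome = roles)
  roles_noF <- lapply(roles, function(r) {
    r$role[!is.na(r$role) & r$role == "PbfF"] <- NA
    r
  })
  after <- run_census(genomes, roles_by_genome = roles_noF)
  expect_equal(after$n_phnA_hits, before$n_phnA_hits)
  expect_equal(after$n_with_phnY, before$n_with_phnY)
  expect_equal(after$n_with_phnY_pbfA, before$n_with_phnY_pbfA)
  expect_true(all(after$n_with_all_four == 0L))
})

test_that("nesting monotonicity holds on adversarial role layouts", {
  set.seed(55)
  pool <- c(CORE_ROLES, ANCILLARY_ROLES, NA, NA)
  for (i in 1:30) {
    mks <- lapply(1:3, function(k)
      make_role_genome(sample(pool, sample(3:20, 1), replace = TRUE),
                       sprintf("R%d_%d", i, k),
                       taxon = sample(c("Hyphomicrobiales", "Rhodobacterales"), 1)))
    genomes <- lapply(mks, function(m) m$genome)
    roles <- stats::setNames(lapply(mks, function(m) m$roles),
                             vapply(genomes, function(g) g$genome_id, character(1)))
    expect_true(census_is_nested(run_census(genomes, roles_by_genome = roles)))
  }
})

test_that("phnA hit finding aligns every protein against the query seed", {
  seeds <- default_seed_db()
  phnA <- seed_by_role(seeds, "PhnA")
  set.seed(61)
  g1 <- make_planted_genome(c("PhnA", NA, "PhnA"), "H1", "Hyphomicrobiales")
  g2 <- make_planted_genome(c(NA, NA), "H2", "Hyphomicrobiales")
  hits <- find_phnA_hits(list(g1, g2), phnA)
  expect_equal(nrow(hits), 2L)  # paralogs counted per hit
  expect_equal(unique(hits$genome_id), "H1")
  expect_equal(nrow(find_phnA_hits(list(), phnA)), 0L)
  expect_equal(nrow(find_phnA_hits(list(g2), phnA)), 0L)
})
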
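#' Find phnA homologs across a genome collection
#'
#' Aligns every protein of every genome against a PhnA query sequence and
#' reports each protein meeting the identity and coverage thresholds as a
#' hit. Counting is per hit, not per genome: paralogs in one genome yield
#' multiple hits, and each hit's genome context is examined individually by
#' the census.
#'
#' @param genomes list of `Genome` objects.
#' @param phnA_seed PhnA query protein sequence.
#' @param min_identity,min_coverage thresholds as in [assign_roles()].
#' @param scheme a [scoring_scheme()].
#' @return data.frame with columns `genome_id`, `gene_id`, `pct_identity`,
#'   `coverage`.
#' @export
find_phnA_hits <- function(genomes, phnA_seed, min_identity = 35,
                           min_coverage = 0.5, scheme = scoring_scheme()) {
  rows <- list()
  for (g in genomes) {
    genes <- g$genes
    has_seq <- !is.na(genes$protein_seq) & nzchar(genes$protein_seq)
    for (i in which(has_seq)) {
      r <- global_align(genes$protein_seq[i], phnA_seed, scheme)
      if (r$pct_identity >= min_identity && r$coverage >= min_coverage)
        rows[[length(rows) + 1L]] <-
          data.frame(genome_id = g$genome_id, gene_id = genes$gene_id[i],
                     pct_identity = r$pct_identity, coverage = r$coverage,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(genome_id = character(), gene_id = character(),
                      pct_identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Nested census of phnA genomic neighborhoods
#'
#' For every phnA hit (role assignment against the seed database), the
#' ±`k`-gene neighborhood is scanned and the hit contributes to the nested
#' columns: `n_with_phnY` if PhnY is present, `n_with_phnY_pbfA` if PhnY
#' and PbfA are present, `n_with_all_four` if PhnY, PbfA and PbfF are all
#' present. Counts are strictly nested by construction
#' (`n_phnA_hits >= n_with_phnY >= n_with_phnY_pbfA >= n_with_all_four`),
#' and combinations outside the nesting (e.g. PbfA without PhnY) are not
#' tabulated. Rows are aggregated by taxonomic order plus a TOTAL row.
#'
#' @param genomes list of `Genome` objects.
#' @param seeds a `seed_db`.
#' @param k neighborhood half-width in genes (default 10).
#' @param min_identity,min_coverage thresholds as in [assign_roles()].
#' @param scheme a [scoring_scheme()].
#' @param roles_by_genome optional precomputed list of role tables (named by
#'   genome_id) to avoid re-aligning.
#' @return data.frame of class `census_table` with columns `taxon_order`,
#'   `n_genomes`, `n_phnA_hits`, `n_with_phnY`, `n_with_phnY_pbfA`,
#'   `n_with_all_four`; orders sorted alphabetically, TOTAL last. Per-hit
#'   detail is attached as attribute `hits`.
#' @export
run_census <- function(genomes, seeds = default_seed_db(), k = 10,
                       min_identity = 35, min_coverage = 0.5,
                       scheme = scoring_scheme(), roles_by_genome = NULL) {
  orders <- vapply(genomes, function(g) g$taxon_order, character(1))
  hit_rows <- list()
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    roles <- if (!is.null(roles_by_genome)) roles_by_genome[[g$genome_id]]
             else suppressWarnings(assign_roles(g, seeds, min_identity,
                                                min_coverage, scheme))
    if (is.null(roles) || nrow(roles) == 0L) next
    hits <- roles$gene_id[!is.na(roles$role) & roles$role == "PhnA"]
    for (h in hits) {
      nb <- scan_neighborhood(g, h, k, roles)
      has_y <- "PhnY" %in% nb
      has_a <- "PbfA" %in% nb
      has_f <- "PbfF" %in% nb
      hit_rows[[length(hit_rows) + 1L]] <-
        data.frame(taxon_order = g$taxon_order, genome_id = g$genome_id,
                   gene_id = h, with_phnY = has_y,
                   with_phnY_pbfA = has_y && has_a,
                   with_all_four = has_y && has_a && has_f,
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows)
          else data.frame(taxon_order = character(), genome_id = character(),
                          gene_id = character(), with_phnY = logical(),
                          with_phnY_pbfA = logical(), with_all_four = logical(),
                          stringsAsFactors = FALSE)
  tab <- census_from_hits(hits, orders)
  attr(tab, "hits") <- hits
  tab
}

# aggregate per-hit rows into the nested census table
census_from_hits <- function(hits, orders) {
  order_levels <- sort(unique(orders))
  rows <- lapply(order_levels, function(o) {
    h <- hits[hits$taxon_order == o, , drop = FALSE]
    data.frame(taxon_order = o, n_genomes = sum(orders == o),
               n_phnA_hits = nrow(h), n_with_phnY = sum(h$with_phnY),
               n_with_phnY_pbfA = sum(h$with_phnY_pbfA),
               n_with_all_four = sum(h$with_all_four),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(data.frame(
    taxon_order = "TOTAL", n_genomes = length(orders),
    n_phnA_hits = nrow(hits), n_with_phnY = sum(hits$with_phnY),
    n_with_phnY_pbfA = sum(hits$with_phnY_pbfA),
    n_with_all_four = sum(hits$with_all_four), stringsAsFactors = FALSE))))
  rownames(tab) <- NULL
  class(tab) <- c("census_table", "data.frame")
  tab
}

#' Check the nesting invariant of a census table
#'
#' @param tab a `census_table`.
#' @return TRUE if every row satisfies
#'   `n_phnA_hits >= n_with_phnY >= n_with_phnY_pbfA >= n_with_all_four`.
#' @export
census_is_nested <- function(tab) {
  all(tab$n_phnA_hits >= tab$n_with_phnY &
        tab$n_with_phnY >= tab$n_with_phnY_pbfA &
        tab$n_with_phnY_pbfA >= tab$n_with_all_four)
}
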
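#' Assign catabolic roles to the proteins of a genome
#'
#' Each protein is globally aligned against every seed; it is assigned the
#' role of its highest-identity seed provided both the identity and coverage
#' thresholds are met, otherwise no role. Identity is the shorter-sequence
#' percent identity; coverage is the fraction of the shorter sequence inside
#' the alignment core (outside terminal gaps). Ties are broken by higher
#' identity, then lexically by seed id.
#'
#' @param genome a `Genome`.
#' @param seeds a `seed_db` (default: the bundled synthetic stand-ins).
#' @param min_identity minimum percent identity (default 35). Under the
#'   shorter-sequence denominator with free terminal gaps, unrelated
#'   proteins of mismatched lengths reach about 31 percent identity, so the
#'   default sits above that empirical null tail while staying far below
#'   close homologs; lower it deliberately (with the coverage guard) when
#'   hunting distant homologs in the 30-36 percent band.
#' @param min_coverage minimum coverage fraction (default 0.5).
#' @param scheme a [scoring_scheme()].
#' @return data.frame with one row per protein-bearing gene: `gene_id`,
#'   `role` (NA when unassigned), `best_seed`, `pct_identity`, `coverage`.
#' @export
assign_roles <- function(genome, seeds = default_seed_db(), min_identity = 35,
                         min_coverage = 0.5, scheme = scoring_scheme()) {
  stopifnot(inherits(genome, "Genome"))
  genes <- genome$genes
  has_seq <- !is.na(genes$protein_seq) & nzchar(genes$protein_seq)
  if (!any(has_seq)) {
    warning("genome ", genome$genome_id, " has no protein sequences")
    return(data.frame(gene_id = character(), role = character(),
                      best_seed = character(), pct_identity = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  genes <- genes[has_seq, , drop = FALSE]
  seed_order <- order(seeds$seed_id)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    best <- list(role = NA_character_, seed = NA_character_,
                 ident = 0, cov = 0)
    for (s in seed_order) {  # lexical seed order makes the tie-break deterministic
      r <- global_align(genes$protein_seq[i], seeds$sequence[s], scheme)
      if (r$pct_identity >= min_identity && r$coverage >= min_coverage &&
          r$pct_identity > best$ident) {
        best <- list(role = seeds$role[s], seed = seeds$seed_id[s],
                     ident = r$pct_identity, cov = r$coverage)
      }
    }
    data.frame(gene_id = genes$gene_id[i], role = best$role,
               best_seed = best$seed, pct_identity = best$ident,
               coverage = best$cov, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Roles present in the gene-rank neighborhood of a focal gene
#'
#' Collects the roles of all genes on the focal contig whose `locus_index`
#' is within `k` of the focal gene's, excluding the focal gene itself. The
#' window is truncated at contig ends. Distances are gene ranks, never base
#' pairs.
#'
#' @param genome a `Genome`.
#' @param focal_gene_id gene to center the window on.
#' @param k window half-width in genes (default 10).
#' @param roles role-assignment table from [assign_roles()].
#' @return character vector of distinct roles present (possibly empty).
#' @export
scan_neighborhood <- function(genome, focal_gene_id, k = 10, roles) {
  stopifnot(inherits(genome, "Genome"), k >= 0)
  genes <- genome$genes
  fi <- match(focal_gene_id, genes$gene_id)
  if (is.na(fi)) stop("unknown gene_id: ", focal_gene_id)
  focal_contig <- genes$contig_id[fi]
  focal_rank <- genes$locus_index[fi]
  nb <- genes$contig_id == focal_contig &
    abs(genes$locus_index - focal_rank) <= k &
    genes$gene_id != focal_gene_id
  nb_roles <- roles$role[roles$gene_id %in% genes$gene_id[nb]]
  sort(unique(nb_roles[!is.na(nb_roles)]))
}

#' Detect and type AEP-degradation gene clusters
#'
#' Core-role genes (PhnW, PhnX, PhnY, PhnA) on one contig are chained by
#' single linkage: each member is within `window` gene ranks of another
#' member, so overlapping windows merge into one maximal group. A group is
#' reported as a cluster only if it contains a valid core: PhnW with PhnX
#' (`phnWX`), PhnW with PhnY and PhnA (`phnWYA`), or all four (`both`).
#' The ancillary set (PbfA/PbfC/PbfD/PbfF) is filled by scanning the window
#' around every core member. Transporter/regulator genes in those windows
#' are recorded among the members but never affect typing. Strand is
#' ignored throughout.
#'
#' @param genome a `Genome`.
#' @param roles role-assignment table from [assign_roles()].
#' @param window colocalization window in gene ranks (default 10, the same
#'   distance rule as the census neighborhood scan).
#' @return list of `gene_cluster` objects, each a list with `genome_id`,
#'   `contig_id`, `member_gene_ids`, `core_gene_ids`, `span`
#'   (min/max locus_index of core and ancillary members), `core_type`,
#'   `ancillary`.
#' @export
detect_clusters <- function(genome, roles, window = 10) {
  stopifnot(inherits(genome, "Genome"))
  genes <- genome$genes
  if (nrow(genes) == 0L) return(list())
  role_of <- stats::setNames(roles$role, roles$gene_id)
  genes$role <- unname(role_of[genes$gene_id])
  out <- list()
  for (cid in unique(genes$contig_id)) {
    sub <- genes[genes$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$locus_index), , drop = FALSE]
    core <- sub[!is.na(sub$role) & sub$role %in% CORE_ROLES, , drop = FALSE]
    if (nrow(core) == 0L) next
    gap <- c(0, diff(core$locus_index))
    group <- cumsum(gap > window)
    for (gid in unique(group)) {
      members_core <- core[group == gid, , drop = FALSE]
      present <- unique(members_core$role)
      has_wx <- all(c("PhnW", "PhnX") %in% present)
      has_wya <- all(c("PhnW", "PhnY", "PhnA") %in% present)
      if (!has_wx && !has_wya) next
      core_type <- if (has_wx && has_wya) "both" else if (has_wx) "phnWX" else "phnWYA"
      # windows around every core member pick up ancillary + context genes
      in_window <- rep(FALSE, nrow(sub))
      for (li in members_core$locus_index)
        in_window <- in_window | abs(sub$locus_index - li) <= window
      near <- sub[in_window, , drop = FALSE]
      ancillary <- sort(intersect(unique(near$role), ANCILLARY_ROLES))
      member_rows <- near[!is.na(near$role) &
                            near$role %in% c(CORE_ROLES, ANCILLARY_ROLES,
                                             CONTEXT_ROLES), , drop = FALSE]
      span_rows <- member_rows[member_rows$role %in% c(CORE_ROLES,
                                                       ANCILLARY_ROLES), ,
                               drop = FALSE]
      cl <- structure(list(genome_id = genome$genome_id, contig_id = cid,
                           member_gene_ids = member_rows$gene_id,
                           core_gene_ids = members_core$gene_id,
                           span = c(min(span_rows$locus_index),
                                    max(span_rows$locus_index)),
                           core_type = core_type, ancillary = ancillary),
                      class = "gene_cluster")
      out[[length(out) + 1L]] <- cl
    }
  }
  out
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("cluster [%s %s] type %s span %d-%d ancillary {%s}\n",
              x$genome_id, x$contig_id, x$core_type, x$span[1], x$span[2],
              paste(x$ancillary, collapse = ", ")))
  invisible(x)
}

#' Flatten clusters to a table
#'
#' @param clusters list of `gene_cluster` objects.
#' @return data.frame with one row per cluster: `genome_id`, `contig_id`,
#'   `span_min`, `span_max`, `core_type`, `ancillary` (comma-separated),
#'   `member_gene_ids` (comma-separated).
#' @export
clusters_to_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(genome_id = character(), contig_id = character(),
                      span_min = integer(), span_max = integer(),
                      core_type = character(), ancillary = character(),
                      member_gene_ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(genome_id = cl$genome_id, contig_id = cl$contig_id,
               span_min = cl$span[1], span_max = cl$span[2],
               core_type = cl$core_type,
               ancillary = paste(cl$ancillary, collapse = ","),
               member_gene_ids = paste(cl$member_gene_ids, collapse = ","),
               stringsAsFactors = FALSE)))
}
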
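#' Mutate a protein to a target percent identity
#'
#' Substitution-only mutagenesis: `round((1 - target) * L)` distinct
#' positions are replaced by a uniformly drawn different residue, so the
#' realized identity against the original (shorter-sequence statistic,
#' global alignment) tracks the target closely for long sequences. No
#' indels are introduced, which keeps the realized identity analytically
#' controllable.
#'
#' @param seq protein sequence.
#' @param target target identity fraction in \[0.2, 1\].
#' @param rng optional integer seed; when given, the current RNG state is
#'   left untouched.
#' @return the mutated sequence.
#' @export
mutate_to_identity <- function(seq, target, rng = NULL) {
  if (!is.numeric(target) || target < 0.2 || target > 1)
    stop("identity target must lie in [0.2, 1]")
  if (!is.null(rng)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rng)
  }
  chars <- strsplit(toupper(seq), "")[[1]]
  L <- length(chars)
  k <- round((1 - target) * L)
  if (k == 0L) return(paste(chars, collapse = ""))
  pos <- sample.int(L, k)
  std <- setdiff(AA_ALPHABET, "X")
  for (p in pos) {
    alt <- setdiff(std, chars[p])
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(setdiff(AA_ALPHABET, "X"), len, replace = TRUE), collapse = "")
}

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate the collections behind the published cluster typology
#' and nested census: two Alphaproteobacteria orders with Hyphomicrobiales
#' outnumbering Rhodobacterales roughly 2:1, a mix of phnWX/phnWYA cluster
#' recipes with ancillary pbf genes, marker mutants at 60 percent identity
#' to their seeds, random-background genes, and occasional partial-core
#' decoys.
#'
#' @param n_genomes named integer vector: genomes per taxon order.
#' @param recipe_probs probabilities for the per-genome cluster recipe over
#'   `none`, `phnWX`, `phnWYA`; must sum to 1.
#' @param ancillary_probs independent inclusion probability of each
#'   ancillary role in a planted cluster.
#' @param identity_target marker mutation identity in \[0.2, 1\].
#' @param background_n range (min, max) of background genes per genome.
#' @param background_len range of background protein lengths.
#' @param decoy_prob probability that a genome additionally carries a decoy
#'   unit (a core with one required role removed).
#' @param context_prob probability that a planted cluster carries a
#'   transporter gene (cluster metadata only, never affects typing).
#' @param seed RNG seed for [generate_collection()].
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genomes = c(Hyphomicrobiales = 7, Rhodobacterales = 3),
                             recipe_probs = c(none = 0.25, phnWX = 0.3, phnWYA = 0.45),
                             ancillary_probs = c(PbfA = 0.5, PbfC = 0.25,
                                                 PbfD = 0.2, PbfF = 0.35),
                             identity_target = 0.6,
                             background_n = c(18L, 30L),
                             background_len = c(120L, 350L),
                             decoy_prob = 0.3, context_prob = 0.3,
                             seed = 1L) {
  if (abs(sum(recipe_probs) - 1) > 1e-9)
    stop("recipe_probs must sum to 1")
  if (identity_target < 0.2 || identity_target > 1)
    stop("identity target must lie in [0.2, 1]")
  stopifnot(all(names(recipe_probs) %in% c("none", "phnWX", "phnWYA")),
            all(names(ancillary_probs) %in% ANCILLARY_ROLES),
            length(n_genomes) >= 1, !is.null(names(n_genomes)))
  structure(list(n_genomes = n_genomes, recipe_probs = recipe_probs,
                 ancillary_probs = ancillary_probs,
                 identity_target = identity_target,
                 background_n = as.integer(background_n),
                 background_len = as.integer(background_len),
                 decoy_prob = decoy_prob, context_prob = context_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

CLUSTER_CORES <- list(phnWX = c("PhnW", "PhnX"),
                      phnWYA = c("PhnW", "PhnY", "PhnA"))

#' Generate a synthetic genome collection with a ground-truth manifest
#'
#' Emits one GFF3 + protein FASTA per genome, a metadata TSV, and a
#' manifest recording every planted cluster, phnA copy and decoy with its
#' gene ids. Planted unit members are consecutive genes; units on the same
#' contig are separated by more than the colocalization window of
#' background genes, so planted neighborhoods never bleed into each other.
#' Background proteins are uniform-composition random sequences. Gene
#' coordinates are non-overlapping with fixed 50-bp spacing (cosmetic: the
#' miner is rank-based).
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @param seeds a `seed_db` supplying the marker sequences to mutate.
#' @return invisibly, a list with `dir`, `metadata_path`, `manifest_path`
#'   and `manifest` (list with one entry per genome).
#' @export
generate_collection <- function(config, out_dir,
                                seeds = default_seed_db()) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  meta <- list(); manifest <- list()
  gnum <- 0L
  for (ord in names(config$n_genomes)) {
    for (rep in seq_len(config$n_genomes[[ord]])) {
      gnum <- gnum + 1L
      gid <- sprintf("SYNG%03d", gnum)
      gen <- build_synthetic_genome(gid, ord, config, seeds)
      gff <- file.path(out_dir, paste0(gid, ".gff3"))
      faa <- file.path(out_dir, paste0(gid, ".faa"))
      write_synthetic_genome(gen$genes, gid, gff, faa)
      meta[[gnum]] <- data.frame(genome_id = gid, taxon_order = ord,
                                 gff3 = basename(gff), faa = basename(faa),
                                 stringsAsFactors = FALSE)
      manifest[[gid]] <- gen$truth
    }
  }
  meta_df <- if (length(meta)) do.call(rbind, meta)
             else data.frame(genome_id = character(), taxon_order = character(),
                             gff3 = character(), faa = character(),
                             stringsAsFactors = FALSE)
  metadata_path <- file.path(out_dir, "metadata.tsv")
  write_table(meta_df, metadata_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, metadata_path = metadata_path,
                 manifest_path = manifest_path, manifest = manifest))
}

# one genome: background genes plus 0-2 planted units on a single contig
build_synthetic_genome <- function(gid, ord, config, seeds) {
  recipe <- sample(names(config$recipe_probs), 1L, prob = config$recipe_probs)
  units <- list()
  if (recipe != "none") {
    anc <- names(config$ancillary_probs)[
      stats::runif(length(config$ancillary_probs)) < config$ancillary_probs]
    roles <- c(CLUSTER_CORES[[recipe]], anc)
    context <- stats::runif(1) < config$context_prob
    if (context) roles <- c(roles, "transporter")
    units[[length(units) + 1L]] <- list(kind = "cluster", type = recipe,
                                        roles = sample(roles), ancillary = anc)
  }
  if (stats::runif(1) < config$decoy_prob) {
    type <- sample(names(CLUSTER_CORES), 1L)
    core <- CLUSTER_CORES[[type]]
    drop <- sample(core, 1L)
    units[[length(units) + 1L]] <- list(kind = "decoy", type = type,
                                        roles = setdiff(core, drop),
                                        ancillary = character())
  }

  n_bg <- sample(seq(config$background_n[1], config$background_n[2]), 1L)
  n_units <- length(units)
  # split background genes into blocks; interior blocks keep units > window apart
  min_sep <- 12L
  needed <- if (n_units > 1) (n_units - 1L) * min_sep else 0L
  n_bg <- max(n_bg, needed + 4L)
  sep <- if (n_units > 1) rep(min_sep, n_units - 1L) else integer(0)
  spare <- n_bg - sum(sep)
  cuts <- if (n_units >= 1) sort(stats::runif(n_units)) else numeric(0)
  blocks <- diff(c(0, cuts, 1))
  blocks <- round(blocks / sum(blocks) * spare)
  blocks[length(blocks)] <- spare - sum(blocks[-length(blocks)])

  slots <- list()  # sequence of gene descriptors
  add_bg <- function(n) {
    for (i in seq_len(max(0L, n))) {
      len <- sample(seq(config$background_len[1], config$background_len[2]), 1L)
      slots[[length(slots) + 1L]] <<- list(role = NA_character_,
                                           seq = random_protein(len),
                                           unit = NA_integer_)
    }
  }
  for (u in seq_len(n_units)) {
    add_bg(blocks[u])
    for (role in units[[u]]$roles) {
      mut <- mutate_to_identity(seed_by_role(seeds, role),
                                config$identity_target)
      slots[[length(slots) + 1L]] <- list(role = role, seq = mut, unit = u)
    }
    if (u < n_units) add_bg(sep[u])
  }
  add_bg(blocks[length(blocks)])

  n <- length(slots)
  gene_ids <- sprintf("%s_g%04d", gid, seq_len(n))
  starts <- integer(n); ends <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    len_nt <- 3L * nchar(slots[[i]]$seq) + 3L
    starts[i] <- pos; ends[i] <- pos + len_nt - 1L
    pos <- ends[i] + 51L  # fixed 50-bp spacing
  }
  genes <- data.frame(
    contig_id = "ctg1", locus_index = seq_len(n) - 1L,
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = gene_ids,
    product = vapply(slots, function(s)
      if (is.na(s$role)) "hypothetical protein" else paste0(s$role, "-like protein"),
      character(1)),
    protein_seq = vapply(slots, function(s) s$seq, character(1)),
    role = vapply(slots, function(s) s$role, character(1)),
    unit = vapply(slots, function(s) s$unit, integer(1)),
    stringsAsFactors = FALSE)

  truth_units <- lapply(seq_len(n_units), function(u) {
    rows <- genes[!is.na(genes$unit) & genes$unit == u, , drop = FALSE]
    core_rows <- rows[rows$role %in% CORE_ROLES, , drop = FALSE]
    anc_rows <- rows[rows$role %in% ANCILLARY_ROLES, , drop = FALSE]
    list(kind = units[[u]]$kind, type = units[[u]]$type,
         ancillary = sort(units[[u]]$ancillary),
         roles = rows$role, gene_ids = rows$gene_id,
         core_gene_ids = core_rows$gene_id,
         span = c(min(c(core_rows$locus_index, anc_rows$locus_index)),
                  max(c(core_rows$locus_index, anc_rows$locus_index))))
  })
  phnA <- genes$gene_id[!is.na(genes$role) & genes$role == "PhnA"]
  phnA_truth <- lapply(phnA, function(pg) {
    u <- genes$unit[genes$gene_id == pg]
    others <- genes$role[!is.na(genes$unit) & genes$unit == u &
                           genes$gene_id != pg]
    list(gene_id = pg, neighborhood_roles = sort(unique(others)))
  })
  list(genes = genes,
       truth = list(genome_id = gid, taxon_order = ord,
                    clusters = Filter(function(x) x$kind == "cluster", truth_units),
                    decoys = Filter(function(x) x$kind == "decoy", truth_units),
                    phnA_copies = phnA_truth))
}

write_synthetic_genome <- function(genes, gid, gff_path, faa_path) {
  attrs <- sprintf("ID=%s;product=%s", genes$gene_id, genes$product)
  lines <- c("##gff-version 3",
             sprintf("%s\tphosmine_synth\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     genes$contig_id, genes$start, genes$end,
                     genes$strand, attrs))
  writeLines(lines, gff_path)
  fa <- character(0)
  for (i in seq_len(nrow(genes))) {
    wrapped <- gsub("(.{70})", "\\1\n", genes$protein_seq[i])
    fa <- c(fa, paste0(">", genes$gene_id[i]), strsplit(wrapped, "\n")[[1]])
  }
  writeLines(fa, faa_path)
}

#' Expected census counts implied by a truth manifest
#'
#' Tabulates, from planted ground truth alone, the nested counts the census
#' should report on the generated collection.
#'
#' @param manifest manifest list from [generate_collection()].
#' @return a `census_table` data.frame.
#' @export
manifest_census <- function(manifest) {
  orders <- vapply(manifest, function(m) m$taxon_order, character(1))
  rows <- list()
  for (m in manifest) {
    for (p in m$phnA_copies) {
      nb <- unlist(p$neighborhood_roles)
      has_y <- "PhnY" %in% nb; has_a <- "PbfA" %in% nb; has_f <- "PbfF" %in% nb
      rows[[length(rows) + 1L]] <-
        data.frame(taxon_order = m$taxon_order, genome_id = m$genome_id,
                   gene_id = p$gene_id, with_phnY = has_y,
                   with_phnY_pbfA = has_y && has_a,
                   with_all_four = has_y && has_a && has_f,
                   stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows)
          else data.frame(taxon_order = character(), genome_id = character(),
                          gene_id = character(), with_phnY = logical(),
                          with_phnY_pbfA = logical(), with_all_four = logical(),
                          stringsAsFactors = FALSE)
  census_from_hits(hits, orders)
}

#' Precision and recall of detected clusters against a manifest
#'
#' A detected cluster matches a planted one when genome, core type, core
#' gene set and ancillary set all agree.
#'
#' @param clusters list of `gene_cluster` objects (all genomes pooled).
#' @param manifest manifest list from [generate_collection()].
#' @return list with `precision`, `recall`, `n_detected`, `n_planted`.
#' @export
cluster_precision_recall <- function(clusters, manifest) {
  key <- function(genome_id, type, core_ids, anc)
    paste(genome_id, type, paste(sort(unlist(core_ids)), collapse = "+"),
          paste(sort(unlist(anc)), collapse = "+"), sep = "|")
  planted <- unlist(lapply(manifest, function(m)
    vapply(m$clusters, function(cl)
      key(m$genome_id, cl$type, cl$core_gene_ids, cl$ancillary),
      character(1))))
  detected <- vapply(clusters, function(cl)
    key(cl$genome_id, cl$core_type, cl$core_gene_ids, cl$ancillary),
    character(1))
  n_tp <- length(intersect(detected, planted))
  list(precision = if (length(detected)) n_tp / length(detected) else NA_real_,
       recall = if (length(planted)) n_tp / length(planted) else NA_real_,
       n_detected = length(detected), n_planted = length(planted))
}
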
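#' Read one annotated genome into the internal gene-table model
#'
#' Parses a GFF3 file and its companion protein FASTA into a `Genome`
#' object: an ordered gene table in which each CDS carries a 0-based
#' `locus_index` (its rank along the contig by ascending start coordinate).
#' All neighborhood arithmetic downstream is done on `locus_index` — gene
#' rank, never base pairs. Only CDS features are modeled; other feature
#' types are skipped (a message reports how many). FASTA records are linked
#' to CDS features by the `ID` attribute, then `protein_id`, then
#' `locus_tag`. CDS features without a protein sequence are retained with
#' `protein_seq = NA` (pseudogenes); FASTA records matching no CDS are
#' dropped with a warning.
#'
#' @param gff3_path path to a GFF3 annotation file.
#' @param faa_path path to the protein FASTA (one record per CDS).
#' @param genome_id identifier for this genome.
#' @param taxon_order taxonomic order label (census stratifier); must be
#'   non-empty.
#' @return an object of class `Genome`: list with `genome_id`,
#'   `taxon_order` and `genes`, a data.frame with columns `genome_id`,
#'   `contig_id`, `locus_index`, `start`, `end`, `strand`, `gene_id`,
#'   `product`, `protein_seq`.
#' @export
read_genome <- function(gff3_path, faa_path, genome_id, taxon_order) {
  if (!file.exists(gff3_path)) stop("GFF3 file not found: ", gff3_path)
  if (!nzchar(taxon_order)) stop("taxon_order must be non-empty")
  validate_gff3_lines(gff3_path)

  gff <- as.data.frame(rtracklayer::readGFF(gff3_path))
  n_other <- sum(gff$type != "CDS")
  if (n_other > 0)
    message("read_genome: skipped ", n_other, " non-CDS feature(s)")
  gff <- gff[gff$type == "CDS", , drop = FALSE]

  if (nrow(gff) == 0L) {
    genes <- empty_gene_table()
  } else {
    attr_col <- function(col) {
      if (col %in% names(gff)) as.character(gff[[col]]) else rep(NA_character_, nrow(gff))
    }
    id <- attr_col("ID")
    protein_id <- attr_col("protein_id")
    locus_tag <- attr_col("locus_tag")
    gene_id <- ifelse(!is.na(id), id,
                      ifelse(!is.na(protein_id), protein_id, locus_tag))
    if (anyNA(gene_id))
      stop("CDS feature without ID/protein_id/locus_tag in ", gff3_path)
    if (anyDuplicated(gene_id))
      stop("duplicate gene_id in ", genome_id, ": ",
           paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))

    seqs <- link_fasta(faa_path, id, protein_id, locus_tag)

    product <- attr_col("product")
    genes <- data.frame(genome_id = genome_id,
                        contig_id = as.character(gff$seqid),
                        locus_index = NA_integer_,
                        start = as.integer(gff$start),
                        end = as.integer(gff$end),
                        strand = as.character(gff$strand),
                        gene_id = gene_id,
                        product = ifelse(is.na(product), "", product),
                        protein_seq = seqs,
                        stringsAsFactors = FALSE)
    genes <- assign_locus_index(genes)
  }
  g <- structure(list(genome_id = genome_id, taxon_order = taxon_order,
                      genes = genes), class = "Genome")
  validate_genome(g)
  g
}

# every non-comment, non-empty GFF3 line must have 9 tab-delimited fields
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fasta_start <- which(lines == "##FASTA")
  if (length(fasta_start)) lines <- lines[seq_len(fasta_start[1] - 1L)]
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    bad_line <- which(body)[which(nfield != 9L)[1]]
    stop(sprintf("malformed GFF3 line %d in %s: expected 9 tab-delimited fields, found %d",
                 bad_line, path, nfield[which(nfield != 9L)[1]]))
  }
  invisible(TRUE)
}

link_fasta <- function(faa_path, id, protein_id, locus_tag) {
  if (!file.exists(faa_path)) stop("protein FASTA not found: ", faa_path)
  aa <- Biostrings::readAAStringSet(faa_path)
  fa_ids <- sub("\\s.*$", "", names(aa))
  fa_seq <- as.character(aa)
  names(fa_seq) <- fa_ids
  seqs <- rep(NA_character_, length(id))
  matched <- rep(FALSE, length(fa_ids))
  for (key in list(id, protein_id, locus_tag)) {
    hit <- !is.na(key) & is.na(seqs) & key %in% fa_ids
    seqs[hit] <- fa_seq[key[hit]]
    matched <- matched | fa_ids %in% key[hit]
  }
  if (any(!matched))
    warning("dropped ", sum(!matched),
            " FASTA record(s) with no matching CDS: ",
            paste(utils::head(fa_ids[!matched], 5), collapse = ", "))
  seqs
}

assign_locus_index <- function(genes) {
  contigs <- unique(genes$contig_id)  # order of first appearance
  out <- lapply(contigs, function(cid) {
    sub <- genes[genes$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end, sub$gene_id), , drop = FALSE]
    sub$locus_index <- seq_len(nrow(sub)) - 1L
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_gene_table <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             locus_index = integer(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             product = character(), protein_seq = character(),
             stringsAsFactors = FALSE)
}

#' Validate Genome invariants
#'
#' Checks coordinate sanity (`start <= end`, positive), consecutive 0-based
#' `locus_index` within each contig ordered by start, gene_id uniqueness,
#' and genome_id consistency. Called by every read path.
#'
#' @param g a `Genome`.
#' @return the genome, invisibly; errors on violation.
#' @export
validate_genome <- function(g) {
  stopifnot(inherits(g, "Genome"))
  if (!nzchar(g$taxon_order)) stop("taxon_order must be non-empty")
  genes <- g$genes
  if (nrow(genes) == 0L) return(invisible(g))
  if (!all(genes$genome_id == g$genome_id))
    stop("gene table genome_id mismatch in ", g$genome_id)
  if (any(genes$start > genes$end) || any(genes$start <= 0))
    stop("invalid coordinates in ", g$genome_id)
  if (!all(genes$strand %in% c("+", "-", "*", ".")))
    stop("invalid strand values in ", g$genome_id)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", g$genome_id)
  for (cid in unique(genes$contig_id)) {
    sub <- genes[genes$contig_id == cid, , drop = FALSE]
    sub <- sub[order(sub$locus_index), , drop = FALSE]
    if (!identical(sub$locus_index, seq_len(nrow(sub)) - 1L))
      stop("locus_index not consecutive on contig ", cid, " of ", g$genome_id)
    if (is.unsorted(sub$start))
      stop("locus_index order disagrees with start coordinates on contig ",
           cid, " of ", g$genome_id)
  }
  invisible(g)
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome %s (%s): %d gene(s) on %d contig(s)\n",
              x$genome_id, x$taxon_order, nrow(x$genes),
              length(unique(x$genes$contig_id))))
  invisible(x)
}

#' Load a genome collection described by a metadata table
#'
#' @param directory directory containing the genome files; `gff3`/`faa`
#'   columns of the metadata are interpreted relative to it (absolute paths
#'   are kept as-is).
#' @param metadata_tsv TSV with columns `genome_id`, `taxon_order`, `gff3`,
#'   `faa`; one genome per row, row order preserved.
#' @return list of `Genome` objects.
#' @export
load_genome_collection <- function(directory, metadata_tsv) {
  meta <- read_table(metadata_tsv,
                     required_cols = c("genome_id", "taxon_order", "gff3", "faa"))
  if (nrow(meta) == 0L) return(list())
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(directory, p))
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (is.na(meta$taxon_order[i]) || !nzchar(meta$taxon_order[i]))
      stop("metadata row ", i, " (", meta$genome_id[i],
           "): taxon_order is blank")
    gff <- resolve(meta$gff3[i]); faa <- resolve(meta$faa[i])
    missing <- c(gff, faa)[!file.exists(c(gff, faa))]
    if (length(missing))
      stop("metadata row ", i, " (", meta$genome_id[i],
           ") references missing file(s): ", paste(missing, collapse = ", "))
    out[[i]] <- read_genome(gff, faa, meta$genome_id[i], meta$taxon_order[i])
  }
  names(out) <- meta$genome_id
  out
}

#' Write / read tab-delimited tables
#'
#' UTF-8, tab-delimited with a header row. `read_table` is permissive about
#' extra columns but errors if a required column is missing. Empty cells are
#' read as NA.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param required_cols character vector of columns that must be present.
#' @return `read_table` returns a data.frame; `write_table` returns `path`
#'   invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, required_cols = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE, quote = "", comment.char = "",
                         na.strings = "")
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(x))
    if (length(missing))
      stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  x
}

#' Serialize a Genome to the gene-table TSV and back
#'
#' @param g a `Genome`.
#' @param path file path.
#' @param include_seq include the `protein_seq` column (needed for a
#'   lossless round trip).
#' @return `write_gene_table` returns `path` invisibly; `read_gene_table`
#'   returns a `Genome`.
#' @export
write_gene_table <- function(g, path, include_seq = TRUE) {
  stopifnot(inherits(g, "Genome"))
  tab <- g$genes
  tab$taxon_order <- g$taxon_order
  if (!include_seq) tab$protein_seq <- NULL
  write_table(tab, path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  need <- c("genome_id", "contig_id", "locus_index", "start", "end",
            "strand", "gene_id", "product", "taxon_order")
  tab <- read_table(path, required_cols = need)
  if (nrow(tab) == 0L) stop("empty gene table: ", path)
  genome_id <- tab$genome_id[1]
  taxon_order <- tab$taxon_order[1]
  if (!"protein_seq" %in% names(tab)) tab$protein_seq <- NA_character_
  genes <- tab[, c("genome_id", "contig_id", "locus_index", "start", "end",
                   "strand", "gene_id", "product", "protein_seq")]
  genes$locus_index <- as.integer(genes$locus_index)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$product <- ifelse(is.na(genes$product), "", as.character(genes$product))
  g <- structure(list(genome_id = genome_id, taxon_order = taxon_order,
                      genes = genes), class = "Genome")
  validate_genome(g)
  g
}
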
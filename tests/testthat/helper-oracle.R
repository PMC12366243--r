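# Exhaustive-enumeration oracle for global alignment with affine gaps
# (gap of length k costs open + k * ext) and free terminal gap runs.
# Pure depth-first enumeration of every alignment path, scoring gap runs
# as they close; independent of the Gotoh recurrence it checks.
oracle_align_score <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  mat <- scheme$matrix
  open <- scheme$gap_open; ext <- scheme$gap_extend
  rec <- function(i, j, state, from_start, rlen, ncol) {
    if (i == la && j == lb) return(0)  # any open run touches the last column: free
    best <- -Inf
    if (i < la && j < lb) {
      pen <- if (state != 0L && !from_start) open + rlen * ext else 0
      best <- max(best, -pen + mat[av[i + 1], bv[j + 1]] +
                    rec(i + 1, j + 1, 0L, FALSE, 0L, ncol + 1L))
    }
    if (i < la) {  # gap in b, consumes a
      if (state == 1L) {
        best <- max(best, rec(i + 1, j, 1L, from_start, rlen + 1L, ncol + 1L))
      } else {
        pen <- if (state == 2L && !from_start) open + rlen * ext else 0
        best <- max(best, -pen + rec(i + 1, j, 1L, ncol == 0L, 1L, ncol + 1L))
      }
    }
    if (j < lb) {  # gap in a, consumes b
      if (state == 2L) {
        best <- max(best, rec(i, j + 1, 2L, from_start, rlen + 1L, ncol + 1L))
      } else {
        pen <- if (state == 1L && !from_start) open + rlen * ext else 0
        best <- max(best, -pen + rec(i, j + 1, 2L, ncol == 0L, 1L, ncol + 1L))
      }
    }
    best
  }
  rec(0L, 0L, 0L, FALSE, 0L, 0L)
}

random_seq <- function(len, alphabet = c("A", "C", "D", "E", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# small two-genome fixture used across genome_io / context tests
write_fixture_genome <- function(dir, genes, genome = "G1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, paste0(genome, ".gff3"))
  faa <- file.path(dir, paste0(genome, ".faa"))
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     genes$contig, genes$start, genes$end, genes$strand,
                     genes$id, genes$product))
  writeLines(lines, gff)
  fa <- unlist(lapply(seq_len(nrow(genes)), function(i)
    c(paste0(">", genes$id[i]), genes$seq[i])))
  writeLines(fa, faa)
  list(gff = gff, faa = faa)
}
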
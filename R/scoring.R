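#' @useDynLib phosmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# amino-acid alphabet used throughout: the 20 standard residues plus X
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Scoring scheme for global protein alignment
#'
#' Bundles a substitution matrix with affine gap penalties. The default
#' reproduces the web defaults of the EMBOSS global aligner: BLOSUM62,
#' gap open 10, gap extend 0.5, and no penalty for terminal gaps. A gap of
#' length k costs `gap_open + k * gap_extend`. The ambiguous residue X
#' scores 0 against every residue and never counts as an identity.
#'
#' @param matrix_name name of the substitution matrix; currently only
#'   `"BLOSUM62"` (taken from \pkg{Biostrings}).
#' @param gap_open non-negative gap opening penalty.
#' @param gap_extend non-negative per-residue gap extension penalty; must not
#'   exceed `gap_open`.
#' @return an object of class `scoring_scheme` with elements `matrix`
#'   (21 x 21, rows/columns in the order of the standard alphabet plus X),
#'   `gap_open`, `gap_extend` and `matrix_name`.
#' @export
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]  # 4
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 10,
                           gap_extend = 0.5) {
  if (!identical(matrix_name, "BLOSUM62"))
    stop("unsupported substitution matrix: ", matrix_name)
  if (gap_open < 0 || gap_extend < 0)
    stop("gap penalties must be non-negative")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  m <- get_blosum62()
  structure(list(matrix = m, gap_open = gap_open, gap_extend = gap_extend,
                 matrix_name = matrix_name),
            class = "scoring_scheme")
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    full <- env$BLOSUM62
    m <- full[AA_ALPHABET, AA_ALPHABET]
    m["X", ] <- 0  # X is uninformative: scores 0 against everything
    m[, "X"] <- 0
    storage.mode(m) <- "double"
    cache <<- m
    m
  }
})

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("scoring scheme:", x$matrix_name,
      sprintf("(gap open %g, gap extend %g, terminal gaps free)\n",
              x$gap_open, x$gap_extend))
  invisible(x)
}

# encode a protein string as 0-based indices into AA_ALPHABET;
# errors name the first illegal position
encode_protein <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L)
    stop(what, " is empty")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("illegal character '%s' at position %d of %s",
                 chars[bad], bad, what))
  }
  idx - 1L
}
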
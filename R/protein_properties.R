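# isotope-averaged residue masses (Da), i.e. amino-acid masses minus one water
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Average molecular mass of a protein
#'
#' Sum of isotope-averaged residue masses plus one water (18.0153 Da). X is
#' rejected because its mass is undefined.
#'
#' @param seq protein sequence over the 20 standard residues.
#' @return mass in Da.
#' @export
#' @examples
#' molecular_mass("G")   # 75.0672
molecular_mass <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  m <- RESIDUE_MASS[chars]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("mass undefined for character '%s' at position %d",
                 chars[bad], bad))
  }
  sum(m) + WATER_MASS
}

#' Molar extinction coefficient at 280 nm
#'
#' Gill-von Hippel coefficients as used by the common web calculators:
#' 5500 per Trp and 1490 per Tyr; the cystine variant adds 125 per disulfide
#' (floor(nCys / 2) pairs). Both variants are always reported because
#' published values rarely state which was used.
#'
#' @param seq protein sequence over the 20 standard residues plus X.
#' @return named numeric vector `c(eps280_reduced, eps280_cystine)` in
#'   M^-1 cm^-1.
#' @export
#' @examples
#' extinction_280("WWYCC")  # 12490, 12615
extinction_280 <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) stop("empty sequence")
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("illegal character(s): ", paste(bad, collapse = ", "))
  nw <- sum(chars == "W"); ny <- sum(chars == "Y"); nc <- sum(chars == "C")
  reduced <- 5500 * nw + 1490 * ny
  c(eps280_reduced = reduced,
    eps280_cystine = reduced + 125 * (nc %/% 2))
}

#' Sequence-derived physical parameters
#'
#' @param seq protein sequence.
#' @return list with `length`, `mass_kda`, `eps280_reduced`,
#'   `eps280_cystine`.
#' @export
protein_properties <- function(seq) {
  eps <- extinction_280(seq)
  list(length = nchar(seq),
       mass_kda = molecular_mass(seq) / 1000,
       eps280_reduced = unname(eps["eps280_reduced"]),
       eps280_cystine = unname(eps["eps280_cystine"]))
}

#' Protein parameters for every record of a FASTA file
#'
#' @param faa_path path to a protein FASTA file.
#' @return data.frame with columns `id`, `length`, `mass_kda`,
#'   `eps280_reduced`, `eps280_cystine`.
#' @export
protein_properties_fasta <- function(faa_path) {
  seqs <- Biostrings::readAAStringSet(faa_path)
  ids <- sub("\\s.*$", "", names(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    p <- protein_properties(as.character(seqs[[i]]))
    data.frame(id = ids[i], length = p$length, mass_kda = p$mass_kda,
               eps280_reduced = p$eps280_reduced,
               eps280_cystine = p$eps280_cystine, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
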
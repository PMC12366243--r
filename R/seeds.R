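# catabolic roles recognized by the miner
CORE_ROLES <- c("PhnW", "PhnX", "PhnY", "PhnA")
ANCILLARY_ROLES <- c("PbfA", "PbfC", "PbfD", "PbfF")
CONTEXT_ROLES <- c("transporter", "regulator")
ALL_ROLES <- c(CORE_ROLES, ANCILLARY_ROLES, CONTEXT_ROLES)

#' Load a marker-seed database
#'
#' A seed database maps marker protein sequences to catabolic roles
#' (PhnW/PhnX/PhnY/PhnA cores, PbfA/PbfC/PbfD/PbfF ancillaries, plus
#' transporter and regulator context genes). The bundled default consists of
#' *synthetic stand-in* sequences — deterministic random proteins, one per
#' role, shipped as `synthetic_seed_proteins.faa` with a role map TSV. They
#' let the planted-cluster pipeline run self-contained; to reproduce
#' identities against published enzymes, load the real marker records
#' (e.g. GenBank CDX32929 for PbfF, WP_010975822 for PhnA) with this same
#' function.
#'
#' @param faa_path protein FASTA of seed sequences.
#' @param roles_tsv TSV with columns `seed_id`, `role`.
#' @return a data.frame of class `seed_db` with columns `seed_id`, `role`,
#'   `sequence`.
#' @export
load_seed_db <- function(faa_path, roles_tsv) {
  seqs <- Biostrings::readAAStringSet(faa_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate seed_id in ", faa_path)
  roles <- read_table(roles_tsv, required_cols = c("seed_id", "role"))
  missing <- setdiff(ids, roles$seed_id)
  if (length(missing))
    stop("seed(s) without a role: ", paste(missing, collapse = ", "))
  bad <- setdiff(roles$role, ALL_ROLES)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  db <- data.frame(seed_id = ids,
                   role = roles$role[match(ids, roles$seed_id)],
                   sequence = as.character(seqs),
                   stringsAsFactors = FALSE)
  class(db) <- c("seed_db", "data.frame")
  db
}

#' @rdname load_seed_db
#' @export
default_seed_db <- function() {
  load_seed_db(system.file("extdata", "synthetic_seed_proteins.faa",
                           package = "phosmine", mustWork = TRUE),
               system.file("extdata", "synthetic_seed_roles.tsv",
                           package = "phosmine", mustWork = TRUE))
}

seed_by_role <- function(seeds, role) {
  hit <- seeds$sequence[seeds$role == role]
  if (length(hit) == 0L) stop("no seed for role ", role)
  hit[1]
}
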
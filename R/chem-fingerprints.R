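# Chemical fingerprints: Morgan (hashed circular substructures via
# OpenBabel's extended-connectivity implementation, folded to 2048 bits),
# an 881-entry substructure-key vector driven by a vendored rule table,
# and a SMILES-subword presence vector over a vendored vocabulary.

MORGAN_BITS <- 2048L
PUBCHEM_BITS <- 881L
ESPF_BITS <- 2586L

fp_cache <- new.env(parent = emptyenv())

default_keys_path <- function() {
  system.file("extdata", "substructure_keys_synthetic.tsv",
              package = "mographdrp", mustWork = FALSE)
}

default_vocab_path <- function() {
  system.file("extdata", "espf_vocab_synthetic.txt",
              package = "mographdrp", mustWork = FALSE)
}

#' Load the substructure-key rule table
#'
#' Reads the vendored 881-entry rule table (element-count, ring-count and
#' SMARTS rules) used for the substructure-key fingerprint.  The packaged
#' table is synthetic: it follows the layout and rule classes of the
#' public 881-key scheme but was constructed for this package; its version
#' string is recorded in fingerprint metadata.
#'
#' @param path Path to a rule table; default is the packaged one.
#' @return A data frame with columns `bit`, `type`, `arg`, `threshold`.
#' @export
load_substructure_keys <- function(path = NULL) {
  path <- path %||% default_keys_path()
  if (!nzchar(path) || !file.exists(path))
    drp_abort("substructure key table not found", "drp_config_error")
  first <- readLines(path, n = 1L)
  version <- if (startsWith(first, "#")) sub("^#\\s*", "", first) else "unknown"
  tab <- utils::read.delim(path, skip = if (startsWith(first, "#")) 1L else 0L,
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("bit", "type", "arg", "threshold")
  if (!all(need %in% names(tab)) || nrow(tab) == 0L)
    drp_abort("substructure key table is truncated or malformed",
              "drp_config_error")
  attr(tab, "version") <- version
  tab
}

#' Load the SMILES-subword vocabulary
#'
#' Reads the vendored subword vocabulary used for the subword-presence
#' fingerprint.  Entries are SMILES token sequences joined by single
#' spaces, ranked by corpus frequency.  The packaged vocabulary is
#' synthetic (derived from the packaged drug corpus).
#'
#' @param path Path to a vocabulary file; default is the packaged one.
#' @return A character vector of subwords.
#' @export
load_espf_vocab <- function(path = NULL) {
  path <- path %||% default_vocab_path()
  if (!nzchar(path) || !file.exists(path))
    drp_abort("subword vocabulary file not found", "drp_config_error")
  lines <- readLines(path)
  # only the first line may be a version header; "#" is a SMILES token
  has_header <- length(lines) > 0L && startsWith(lines[1], "# ")
  version_line <- if (has_header) lines[1] else NA_character_
  vocab <- lines[if (has_header) -1L else TRUE]
  vocab <- vocab[nzchar(vocab)]
  if (length(vocab) == 0L)
    drp_abort("subword vocabulary file is empty or truncated",
              "drp_config_error")
  attr(vocab, "version") <-
    if (is.na(version_line)) "unknown" else sub("^#\\s*", "", version_line)
  vocab
}

tokenize_smiles <- function(smiles) {
  regmatches(smiles, gregexpr("\\[[^]]*\\]|Cl|Br|%[0-9]{2}|.", smiles))[[1]]
}

obmols_from_smiles <- function(smiles) {
  ChemmineOB::forEachMol("SMILES",
                         paste0(paste(smiles, collapse = "\n"), "\n"),
                         identity)
}

morgan_matrix <- function(smiles, radius = 2L) {
  mols <- obmols_from_smiles(smiles)
  raw <- ChemmineOB::fingerprint_OB(mols, paste0("ECFP", 2L * radius))
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  nb <- ncol(raw)
  if (nb < MORGAN_BITS)
    drp_abort("unexpected fingerprint width from backend",
              "drp_config_error")
  folds <- nb / MORGAN_BITS
  out <- matrix(0L, nrow = nrow(raw), ncol = MORGAN_BITS)
  for (f in seq_len(folds)) {
    blk <- raw[, (f - 1L) * MORGAN_BITS + seq_len(MORGAN_BITS), drop = FALSE]
    out <- pmax(out, (blk > 0) * 1L)
  }
  out
}

pubchem_matrix <- function(smiles, parsed, keys) {
  n <- length(smiles)
  out <- matrix(0L, nrow = n, ncol = nrow(keys))

  counts <- lapply(parsed, function(m) table(m$symbol))
  ring_sizes <- lapply(parsed, function(m) m$ring_sizes)
  ring_arom <- lapply(parsed, function(m) m$ring_aromatic)

  smarts_rows <- which(keys$type == "smarts")
  uniq_smarts <- unique(keys$arg[smarts_rows])
  smarts_counts <- NULL
  if (length(uniq_smarts) > 0L) {
    mols <- obmols_from_smiles(smiles)
    smarts_counts <- matrix(0L, nrow = n, ncol = length(uniq_smarts),
                            dimnames = list(NULL, uniq_smarts))
    for (p in uniq_smarts) {
      hits <- tryCatch(ChemmineOB::smartsSearch_OB(mols, p),
                       error = function(e) rep(0L, n))
      smarts_counts[, p] <- as.integer(hits)[seq_len(n)]
    }
  }

  for (r in seq_len(nrow(keys))) {
    type <- keys$type[r]; arg <- keys$arg[r]; th <- keys$threshold[r]
    val <- switch(
      type,
      element_count = vapply(counts, function(tb)
        if (arg %in% names(tb)) as.integer(tb[[arg]]) else 0L, integer(1)),
      ring_count = if (arg == "any")
        vapply(ring_sizes, length, integer(1))
      else
        vapply(ring_sizes, function(s) sum(s == as.integer(arg)),
               integer(1)),
      aromatic_ring_count = vapply(ring_arom, sum, integer(1)),
      smarts = smarts_counts[, arg],
      rep(0L, n))
    out[, r] <- as.integer(val >= th)
  }
  out
}

espf_matrix <- function(smiles, vocab) {
  streams <- vapply(smiles, function(s)
    paste0(" ", paste(tokenize_smiles(s), collapse = " "), " "),
    character(1), USE.NAMES = FALSE)
  out <- matrix(0L, nrow = length(smiles), ncol = length(vocab))
  for (j in seq_along(vocab))
    out[, j] <- as.integer(grepl(paste0(" ", vocab[j], " "), streams,
                                 fixed = TRUE))
  out
}

#' Compute a chemical fingerprint for one drug
#'
#' @param smiles A single SMILES string.
#' @param kind One of `"morgan"` (2048-bit folded circular fingerprint),
#'   `"pubchem"` (881 substructure keys) or `"espf"` (subword presence
#'   over the packaged vocabulary).
#' @param drug_id Identifier carried into error conditions.
#' @param radius Circular-neighbourhood radius for `kind = "morgan"`.
#' @return An integer 0/1 vector of the kind's fixed length.
#' @export
#' @examples
#' length(fingerprint("CCO", "morgan"))  # 2048
fingerprint <- function(smiles, kind = c("morgan", "pubchem", "espf"),
                        drug_id = "<drug>", radius = 2L) {
  kind <- match.arg(kind)
  mol <- parse_molecule(smiles, drug_id)  # validates the SMILES
  switch(kind,
    morgan = morgan_matrix(smiles, radius)[1L, ],
    pubchem = pubchem_matrix(smiles, list(mol),
                             load_substructure_keys())[1L, ],
    espf = espf_matrix(smiles, load_espf_vocab())[1L, ])
}

#' Featurize a drug table
#'
#' Converts every drug in a table into the two representations the model
#' consumes: a heavy-atom molecular graph (see [smiles_to_graph()]) and
#' the three binary fingerprints.  All drugs are validated first;
#' unparseable SMILES raise a featurization error naming the drug.
#'
#' @param drug_tbl Data frame with columns `drug_id` and `smiles`.
#' @param kinds Fingerprint kinds to compute.
#' @param morgan_radius Circular-neighbourhood radius for the Morgan path.
#' @param keys_path,vocab_path Optional overrides for the packaged rule
#'   table / vocabulary.
#' @return An object of class `drug_features`: named graphs, one binary
#'   matrix per fingerprint kind (rows = drugs), and version metadata.
#' @export
featurize_drugs <- function(drug_tbl,
                            kinds = c("morgan", "pubchem", "espf"),
                            morgan_radius = 2L,
                            keys_path = NULL, vocab_path = NULL) {
  if (!all(c("drug_id", "smiles") %in% names(drug_tbl)))
    drp_abort("drug table must have columns drug_id, smiles",
              "drp_data_error")
  drug_tbl$drug_id <- trimws(as.character(drug_tbl$drug_id))
  drug_tbl$smiles <- trimws(as.character(drug_tbl$smiles))
  if (anyDuplicated(drug_tbl$drug_id))
    drp_abort("duplicate drug_id values in drug table", "drp_data_error")
  kinds <- match.arg(kinds, several.ok = TRUE)

  parsed <- lapply(seq_len(nrow(drug_tbl)), function(i) {
    m <- parse_molecule(drug_tbl$smiles[i], drug_tbl$drug_id[i])
    m
  })
  graphs <- lapply(seq_len(nrow(drug_tbl)), function(i)
    smiles_to_graph(drug_tbl$smiles[i], drug_tbl$drug_id[i]))
  names(graphs) <- drug_tbl$drug_id

  fps <- list()
  versions <- list(featurizer = FEATURIZER_VERSION,
                   morgan_radius = as.integer(morgan_radius))
  if ("morgan" %in% kinds)
    fps$morgan <- morgan_matrix(drug_tbl$smiles, morgan_radius)
  if ("pubchem" %in% kinds) {
    keys <- load_substructure_keys(keys_path)
    fps$pubchem <- pubchem_matrix(drug_tbl$smiles, parsed, keys)
    versions$substructure_keys <- attr(keys, "version")
  }
  if ("espf" %in% kinds) {
    vocab <- load_espf_vocab(vocab_path)
    fps$espf <- espf_matrix(drug_tbl$smiles, vocab)
    versions$espf_vocab <- attr(vocab, "version")
  }
  for (k in names(fps)) rownames(fps[[k]]) <- drug_tbl$drug_id

  structure(
    list(drug_ids = drug_tbl$drug_id, graphs = graphs,
         fingerprints = fps, versions = versions),
    class = "drug_features")
}

#' @export
print.drug_features <- function(x, ...) {
  cat(sprintf("<drug_features: %d drugs; fingerprints: %s>\n",
              length(x$drug_ids),
              paste(sprintf("%s[%d]", names(x$fingerprints),
                            vapply(x$fingerprints, ncol, integer(1))),
                    collapse = ", ")))
  invisible(x)
}
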
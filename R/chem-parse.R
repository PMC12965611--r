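# SMILES parsing and molecular-graph featurization.
#
# OpenBabel (through ChemmineOB) does all chemistry perception: SMILES
# syntax, kekulization and implicit-hydrogen bookkeeping.  The V2000
# molblock it emits is read here directly, which keeps single-atom
# molecules (no bond block) on the same code path as everything else.
# Aromaticity is perceived with ChemmineR's ring detector.

# Fixed element list for the symbol one-hot; the final slot catches
# everything else.  43 named symbols + "other" = 44.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb")

ATOM_FEATURE_DIM <- 44L + 11L + 11L + 11L + 1L  # = 78

# typical valences used to infer implicit hydrogen counts from the
# kekulized bond orders; metals and anything absent default to 0 H
TYPICAL_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                     Br = 1, I = 1, B = 3, Si = 4)

FEATURIZER_VERSION <- "1.0"

# Parse one SMILES into atom/bond tables. Returns list(symbol, charge,
# aromatic, degree, n_h, implicit_valence, bonds [m x 3: i, j, order]).
parse_molecule <- function(smiles, drug_id = "<drug>") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles)))
    drp_abort(sprintf("drug '%s': empty or non-character SMILES", drug_id),
              "drp_featurization_error", drug_id = drug_id)
  smiles <- trimws(smiles)

  msg <- character()
  molblock <- withCallingHandlers(
    tryCatch(ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n")),
             error = function(e) NULL),
    warning = function(w) {
      msg <<- c(msg, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  lines <- if (is.null(molblock)) character() else
    strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L)
    drp_abort(sprintf("drug '%s': unparseable SMILES '%s'", drug_id, smiles),
              "drp_featurization_error", drug_id = drug_id)

  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L || is.na(n_bonds))
    drp_abort(sprintf(
      "drug '%s': SMILES '%s' yields no heavy atoms", drug_id, smiles),
      "drp_featurization_error", drug_id = drug_id)

  atom_lines <- lines[4L + seq_len(n_atoms)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  bonds <- matrix(0L, nrow = n_bonds, ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (n_bonds > 0L) {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    bonds[, "i"] <- as.integer(substr(bond_lines, 1, 3))
    bonds[, "j"] <- as.integer(substr(bond_lines, 4, 6))
    bonds[, "order"] <- as.integer(substr(bond_lines, 7, 9))
  }

  charge <- integer(n_atoms)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))),
                                "\\s+")[[1]])
    nset <- flds[1]
    for (k in seq_len(nset))
      charge[flds[2 * k]] <- flds[2 * k + 1]
  }

  # drop explicit hydrogens (heavy-atom graph); count them as bound H
  explicit_h <- integer(n_atoms)
  keep <- symbol != "H"
  if (!all(keep)) {
    h_idx <- which(!keep)
    for (r in seq_len(nrow(bonds))) {
      if (bonds[r, "i"] %in% h_idx) explicit_h[bonds[r, "j"]] <-
          explicit_h[bonds[r, "j"]] + 1L
      if (bonds[r, "j"] %in% h_idx) explicit_h[bonds[r, "i"]] <-
          explicit_h[bonds[r, "i"]] + 1L
    }
    remap <- cumsum(keep)
    bonds <- bonds[keep[bonds[, "i"]] & keep[bonds[, "j"]], , drop = FALSE]
    bonds[, "i"] <- remap[bonds[, "i"]]
    bonds[, "j"] <- remap[bonds[, "j"]]
    symbol <- symbol[keep]; charge <- charge[keep]
    explicit_h <- explicit_h[keep]
    n_atoms <- length(symbol)
    if (n_atoms < 1L)
      drp_abort(sprintf("drug '%s': no heavy atoms", drug_id),
                "drp_featurization_error", drug_id = drug_id)
  }

  degree <- tabulate(c(bonds[, "i"], bonds[, "j"]), nbins = n_atoms)
  bond_order_sum <- numeric(n_atoms)
  for (r in seq_len(nrow(bonds))) {
    o <- bonds[r, "order"]
    bond_order_sum[bonds[r, "i"]] <- bond_order_sum[bonds[r, "i"]] + o
    bond_order_sum[bonds[r, "j"]] <- bond_order_sum[bonds[r, "j"]] + o
  }
  val <- unname(TYPICAL_VALENCE[symbol])
  val[is.na(val)] <- 0
  implicit_h <- pmax(0L, as.integer(val + charge - bond_order_sum))

  ringinfo <- perceive_rings(lines, n_atoms, bonds)

  list(symbol = symbol, charge = charge, aromatic = ringinfo$aromatic_atoms,
       degree = as.integer(degree),
       n_h = implicit_h + explicit_h,
       implicit_valence = implicit_h,
       bonds = bonds,
       ring_sizes = ringinfo$sizes,
       ring_aromatic = ringinfo$aromatic)
}

# ring perception (sizes, per-ring aromaticity, aromatic atom flags) via
# ChemmineR on the molblock
perceive_rings <- function(lines, n_atoms, bonds) {
  out <- list(aromatic_atoms = logical(n_atoms), sizes = integer(),
              aromatic = logical())
  if (nrow(bonds) < 3L || n_atoms < 3L) return(out)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(lines)),
    error = function(e) NULL)
  if (is.null(sdf)) return(out)
  rr <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(rr) || length(rr$RINGS) == 0L) return(out)
  for (k in seq_along(rr$RINGS)) {
    out$sizes <- c(out$sizes, length(rr$RINGS[[k]]))
    arom <- isTRUE(rr$AROMATIC[[k]])
    out$aromatic <- c(out$aromatic, arom)
    if (arom) {
      idx <- as.integer(sub("^.*_", "", rr$RINGS[[k]]))
      idx <- idx[idx >= 1 & idx <= n_atoms]
      out$aromatic_atoms[idx] <- TRUE
    }
  }
  out
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)  # final slot is the catch-all
  v[i] <- 1
  v
}

#' Per-atom descriptor vector
#'
#' Encodes one heavy atom as a fixed 78-length numeric vector: a 44-slot
#' element one-hot (43 named symbols plus a final catch-all), one-hots for
#' heavy-atom degree, total hydrogen count and implicit valence (each over
#' 0--10), and an aromaticity flag.  Out-of-range degree/H/valence values
#' clamp to the final slot of their block.
#'
#' @param symbol Element symbol, e.g. `"C"`.
#' @param degree Number of heavy-atom neighbours.
#' @param n_h Total number of bound hydrogens.
#' @param implicit_valence Implicit valence (implicit hydrogen count).
#' @param aromatic `TRUE` if the atom belongs to an aromatic ring.
#' @return Numeric vector of length 78.
#' @export
#' @examples
#' v <- atom_feature_vector("C", degree = 0, n_h = 4,
#'                          implicit_valence = 4, aromatic = FALSE)
#' length(v)
atom_feature_vector <- function(symbol, degree, n_h, implicit_valence,
                                aromatic) {
  c(one_hot(symbol, c(ATOM_SYMBOLS, "other")),
    one_hot(min(degree, 10L), 0:10),
    one_hot(min(n_h, 10L), 0:10),
    one_hot(min(implicit_valence, 10L), 0:10),
    as.numeric(aromatic))
}

#' Convert a SMILES string to a molecular graph
#'
#' Builds the heavy-atom graph of one drug: one node per heavy atom in the
#' parser's canonical order, one undirected edge per covalent bond between
#' heavy atoms, and a 78-column node feature matrix (see
#' [atom_feature_vector()]).  Hydrogens are implicit and bond orders are
#' not encoded.
#'
#' @param smiles A single SMILES string.
#' @param drug_id Identifier carried into error conditions.
#' @return An object of class `molecular_graph`: a list with
#'   `node_features` (`n_atoms` x 78 matrix), `edges` (`m` x 2 integer
#'   matrix of unordered pairs, `i < j`) and `n_atoms`.
#' @export
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms   # 3
#' nrow(g$edges)  # 2
smiles_to_graph <- function(smiles, drug_id = "<drug>") {
  mol <- parse_molecule(smiles, drug_id)
  feats <- matrix(0, nrow = length(mol$symbol), ncol = ATOM_FEATURE_DIM)
  for (a in seq_along(mol$symbol))
    feats[a, ] <- atom_feature_vector(
      mol$symbol[a], mol$degree[a], mol$n_h[a],
      mol$implicit_valence[a], mol$aromatic[a])

  edges <- mol$bonds[, c("i", "j"), drop = FALSE]
  if (nrow(edges) > 0L) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  }
  structure(
    list(node_features = feats, edges = edges,
         n_atoms = length(mol$symbol)),
    class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d atoms, %d bonds>\n",
              x$n_atoms, nrow(x$edges)))
  invisible(x)
}
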
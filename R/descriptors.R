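#' Molecular descriptors from SMILES
#'
#' Computes the three structure-derived model inputs for each molecule:
#' molecular weight (`mw`, g/mol, standard atomic weights including implicit
#' hydrogens), hydrogen-bond donor count (`hbd`, N/O atoms bearing at least
#' one hydrogen) and topological polar surface area (`tpsa`, A^2, Ertl
#' fragment-contribution scheme). Computation delegates to OpenBabel through
#' the ChemmineOB package; a bundled precomputed descriptor table (validated
#' against two independent toolkits) covers the molecules shipped with the
#' package so that the pipeline also runs where ChemmineOB is unavailable.
#'
#' The fourth model feature, `tyr_inhib`, is an experimental bioactivity
#' annotation and is never computed from structure.
#'
#' @param smiles Character vector of SMILES strings.
#' @param method `"auto"` (OpenBabel when installed, else table lookup),
#'   `"openbabel"`, or `"table"`.
#' @return A tibble with columns `smiles`, `mw`, `hbd`, `tpsa`, one row per
#'   input.
#' @examples
#' compute_descriptors("NCC1CCC(CC1)C(=O)O") # tranexamic acid
#' @export
compute_descriptors <- function(smiles,
                                method = c("auto", "openbabel", "table")) {
  method <- match.arg(method)
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (method == "auto") {
    method <- if (has_chemmine_ob()) "openbabel" else "table"
  }
  if (method == "openbabel") {
    rows <- lapply(smiles, descriptors_ob)
  } else {
    tab <- descriptor_table()
    rows <- lapply(smiles, function(s) {
      hit <- match(s, tab$smiles)
      if (is.na(hit)) {
        abort(paste0("SMILES not in bundled descriptor table ",
                     "(install ChemmineOB to compute): ", s),
              class = "coformerscout_parse_error")
      }
      tibble(mw = tab$mw[hit], hbd = tab$hbd[hit], tpsa = tab$tpsa[hit])
    })
  }
  dplyr::bind_cols(tibble(smiles = smiles), dplyr::bind_rows(rows))
}

has_chemmine_ob <- function() {
  isTRUE(requireNamespace("ChemmineOB", quietly = TRUE))
}

descriptors_ob <- function(smi) {
  p <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smi,
                           function(m) ChemmineOB::prop_OB(m)),
    error = function(e) NULL
  )
  if (is.list(p) && !is.data.frame(p) && length(p) >= 1) p <- p[[1]]
  if (!is.data.frame(p) || nrow(p) == 0 || !is.finite(p$MW[1]) ||
      p$MW[1] <= 0) {
    abort(paste0("unparseable SMILES: ", smi),
          class = "coformerscout_parse_error")
  }
  tibble(mw = p$MW[1], hbd = as.double(p$HBD[1]), tpsa = p$TPSA[1])
}

# Bundled descriptor table for the molecules shipped with the package.
descriptor_table <- function() {
  path <- system.file("extdata", "coformer_smiles_pool.csv",
                      package = "coformerscout", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccddd", progress = FALSE)
}

#' Bundled pool of real small-molecule SMILES
#'
#' About 180 named small hydrophilic-to-moderately-hydrophobic molecules
#' (amino acids, organic and phenolic acids, polyols, amides, flavonoids,
#' common actives) with precomputed `mw`, `hbd` and `tpsa`. Used by the
#' synthetic-library generator to attach realistic structures to generated
#' records, and as hermetic fixtures for the descriptor and encoding code.
#'
#' @return A tibble with columns `name`, `smiles`, `mw`, `hbd`, `tpsa`.
#' @export
smiles_pool <- function() descriptor_table()

#' Canonicalize a SMILES string
#'
#' @param smiles Character vector of SMILES strings.
#' @return Canonical SMILES (OpenBabel canonical form), same length.
#' @export
canonical_smiles <- function(smiles) {
  if (!has_chemmine_ob()) {
    abort("canonical_smiles() requires the ChemmineOB package",
          class = "coformerscout_dependency_error")
  }
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMILES", "CAN", s),
                    error = function(e) "")
    out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
    if (!nzchar(out)) {
      abort(paste0("unparseable SMILES: ", s),
            class = "coformerscout_parse_error")
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

# --- molecular graph -------------------------------------------------------

# Parse one molecule from SMILES into an atom/bond graph via an SDF (V2000)
# round-trip. Implicit hydrogen counts are reconstructed from standard
# valences adjusted by formal charge.
smiles_graph <- function(smi) {
  if (!has_chemmine_ob()) {
    abort("SMILES graph construction requires the ChemmineOB package",
          class = "coformerscout_dependency_error")
  }
  sdf <- tryCatch(ChemmineOB::convertFormat("SMILES", "SDF", smi),
                  error = function(e) "")
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) {
    abort(paste0("unparseable SMILES: ", smi),
          class = "coformerscout_parse_error")
  }
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1) {
    abort(paste0("unparseable SMILES: ", smi),
          class = "coformerscout_parse_error")
  }
  atom_lines <- lines[5:(4 + n_atoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    cbind(a = as.integer(substr(bl, 1, 3)),
          b = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else {
    cbind(a = integer(0), b = integer(0), order = integer(0))
  }
  charge <- integer(n_atoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) {
      charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
               F = 1, Cl = 1, Br = 1, I = 1)
  bond_sum <- numeric(n_atoms)
  deg <- integer(n_atoms)
  if (n_bonds > 0) {
    for (r in seq_len(n_bonds)) {
      o <- bonds[r, "order"]
      if (o == 4) o <- 1.5  # aromatic SDF bonds (OpenBabel kekulizes; guard)
      bond_sum[bonds[r, "a"]] <- bond_sum[bonds[r, "a"]] + o
      bond_sum[bonds[r, "b"]] <- bond_sum[bonds[r, "b"]] + o
      deg[bonds[r, "a"]] <- deg[bonds[r, "a"]] + 1L
      deg[bonds[r, "b"]] <- deg[bonds[r, "b"]] + 1L
    }
  }
  base_val <- unname(valence[elem])
  base_val[is.na(base_val)] <- 0
  h <- pmax(0, round(base_val + charge - bond_sum))
  list(elem = elem, charge = charge, degree = deg, h = h, bonds = bonds)
}

#' Encode a SMILES string as hashed fragment counts
#'
#' Realizes the "SMILES string" model feature as a fixed-length numeric
#' vector: the molecule is canonicalized, its circular substructure
#' fragments up to radius 2 are enumerated (Morgan-style iterated atom
#' environments built from element, degree, attached-hydrogen count and
#' formal charge), and each fragment identifier is hashed into one of `k`
#' buckets whose occurrence counts form the encoding. The encoding is
#' deterministic for a fixed molecule, `k` and `seed`, and invariant to how
#' the SMILES string was written.
#'
#' @param smiles Character vector of SMILES strings.
#' @param k Number of hash buckets (default 32, minimum 8).
#' @param seed Integer salt mixed into the fragment hash.
#' @param canonicalize Canonicalize before fragment enumeration (default
#'   `TRUE`).
#' @return An integer matrix with `length(smiles)` rows and `k` columns of
#'   non-negative fragment counts.
#' @examples
#' if (requireNamespace("ChemmineOB", quietly = TRUE)) {
#'   identical(encode_smiles("OCC"), encode_smiles("C(O)C"))
#' }
#' @export
encode_smiles <- function(smiles, k = 32L, seed = 0L, canonicalize = TRUE) {
  assert_that(is_count(k) && k >= 8, "k must be an integer >= 8",
              class = "coformerscout_argument_error")
  if (canonicalize) smiles <- canonical_smiles(smiles)
  out <- matrix(0L, nrow = length(smiles), ncol = k,
                dimnames = list(NULL, sprintf("smiles_enc_%02d", seq_len(k))))
  for (i in seq_along(smiles)) {
    g <- smiles_graph(smiles[i])
    n <- length(g$elem)
    nbrs <- vector("list", n)
    if (nrow(g$bonds) > 0) {
      for (r in seq_len(nrow(g$bonds))) {
        a <- g$bonds[r, "a"]; b <- g$bonds[r, "b"]
        o <- g$bonds[r, "order"]
        nbrs[[a]] <- rbind(nbrs[[a]], c(b, o))
        nbrs[[b]] <- rbind(nbrs[[b]], c(a, o))
      }
    }
    inv <- sprintf("%s|%d|%d|%d", g$elem, g$degree, g$h, g$charge)
    frags <- inv
    for (radius in 1:2) {
      inv <- vapply(seq_len(n), function(a) {
        nb <- nbrs[[a]]
        if (is.null(nb)) return(paste0("(", inv[a], ")"))
        parts <- sort(sprintf("%d:%s", nb[, 2], inv[nb[, 1]]))
        paste0("(", inv[a], "{", paste(parts, collapse = ","), "})")
      }, character(1))
      frags <- c(frags, inv)
    }
    bucket <- vapply(frags, function(f) {
      (str_hash(f, salt = seed) %% k) + 1
    }, numeric(1), USE.NAMES = FALSE)
    tab <- tabulate(bucket, nbins = k)
    out[i, ] <- as.integer(tab)
  }
  out
}
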
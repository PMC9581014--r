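# Parsed coordinate model: a Structure holds one flat atom table for chain
# (polymer) atoms and one for ligand (non-water HETATM) groups. Residues are
# identified by (chain, resno, insertion code) and carry a 1-based rank
# within their chain; all loop windows in the package are 1-based inclusive
# ranges over these ranks.

.finalize_structure <- function(id, atom, ligand) {
  if (nrow(atom) > 0L) {
    key <- paste(atom$chain, atom$resno, atom$ins, sep = "|")
    atom$res_key <- key
    atom$res_rank <- NA_integer_
    for (ch in unique(atom$chain)) {
      i <- which(atom$chain == ch)
      atom$res_rank[i] <- match(key[i], unique(key[i]))
    }
  }
  structure(list(id = id, atom = atom, ligand = ligand),
            class = "efl_structure")
}

.empty_atom_df <- function() {
  data.frame(chain = character(), resno = integer(), ins = character(),
             resid = character(), aa1 = character(), elety = character(),
             element = character(), x = numeric(), y = numeric(),
             z = numeric(), o = numeric(), h = logical(),
             stringsAsFactors = FALSE)
}

.guess_element <- function(name, resid, record) {
  ions <- c("CA", "MG", "ZN", "FE", "NA", "K", "CL", "MN", "CU",
            "NI", "CO", "BR", "I", "CD", "HG", "SE")
  el <- character(length(name))
  for (i in seq_along(name)) {
    nm <- gsub("[0-9']", "", name[i])
    if (record[i] == "HETATM" && name[i] %in% ions && resid[i] %in% ions) {
      el[i] <- name[i]
    } else if (grepl("^H", nm) || grepl("^[0-9]H", name[i])) {
      el[i] <- "H"
    } else {
      el[i] <- substr(nm, 1, 1)
    }
  }
  el
}

#' Parse a PDB-format structure
#'
#' Reads ATOM/HETATM records from PDB text into the package's coordinate
#' model. Alternate locations are resolved to the highest-occupancy conformer
#' (ties favour altloc `A`), waters are dropped, non-water HETATM groups are
#' kept separately as ligands, and only the first MODEL of a multi-model file
#' is read. Nonstandard residues with a standard parent (e.g. MSE) are
#' treated as chain residues and map to the parent's one-letter code.
#'
#' @param pdb_text Character scalar (or vector of lines) with PDB records.
#' @param id Identifier stored on the returned structure.
#' @return An object of class `efl_structure`: a list with `id`, an `atom`
#'   data frame (chain atoms, one row per atom, with per-chain residue ranks)
#'   and a `ligand` data frame of the same shape.
#' @examples
#' s <- build_peptide(rep(-57, 3), rep(-47, 3), "AAA")
#' s2 <- parse_structure(write_structure(s))
#' chain_sequence(s2, "A")
#' @export
parse_structure <- function(pdb_text, id = "structure") {
  lines <- if (length(pdb_text) == 1L) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(pdb_text)
  }
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec6 <- substr(lines, 1, 6)
  sel <- which(rec6 %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0L) {
    stop("parse error: no ATOM records found in input")
  }
  ln <- lines[sel]
  record <- trimws(substr(ln, 1, 6))
  name <- trimws(substr(ln, 13, 16))
  altloc <- substr(ln, 17, 17)
  resid <- trimws(substr(ln, 18, 20))
  chain <- substr(ln, 22, 22)
  resno_s <- trimws(substr(ln, 23, 26))
  ins <- trimws(substr(ln, 27, 27))
  xs <- trimws(substr(ln, 31, 38))
  ys <- trimws(substr(ln, 39, 46))
  zs <- trimws(substr(ln, 47, 54))
  os <- trimws(substr(ln, 55, 60))
  elem <- trimws(substr(ln, 77, 78))

  coords <- suppressWarnings(cbind(as.numeric(xs), as.numeric(ys),
                                   as.numeric(zs)))
  bad <- which(!is.finite(coords[, 1]) | !is.finite(coords[, 2]) |
                 !is.finite(coords[, 3]))
  if (length(bad) > 0L) {
    stop(sprintf("parse error: malformed coordinate field at line %d: %s",
                 sel[bad[1]], ln[bad[1]]))
  }
  resno <- suppressWarnings(as.integer(resno_s))
  if (anyNA(resno)) {
    bad <- which(is.na(resno))[1]
    stop(sprintf("parse error: malformed residue number at line %d: %s",
                 sel[bad], ln[bad]))
  }
  occ <- suppressWarnings(as.numeric(os))
  occ[!is.finite(occ)] <- 1

  element <- elem
  miss <- element == ""
  if (any(miss)) {
    element[miss] <- .guess_element(name[miss], resid[miss], record[miss])
  }

  df <- data.frame(record = record, name = name, altloc = altloc,
                   resid = resid, chain = chain, resno = resno, ins = ins,
                   x = coords[, 1], y = coords[, 2], z = coords[, 3],
                   o = occ, element = element, stringsAsFactors = FALSE)

  df <- df[!(df$resid %in% WATER_NAMES), , drop = FALSE]

  # altloc resolution: per (chain, resno, ins, atom name) keep highest
  # occupancy; ties resolved in favour of altloc 'A'. Original record order
  # is restored afterwards.
  if (nrow(df) > 0L) {
    df$.line <- seq_len(nrow(df))
    akey <- paste(df$chain, df$resno, df$ins, df$name, df$resid, sep = "|")
    pref <- order(akey, -df$o, df$altloc != "A", df$altloc)
    df <- df[pref, , drop = FALSE]
    df <- df[!duplicated(akey[pref]), , drop = FALSE]
    df <- df[order(df$.line), , drop = FALSE]
  }

  is_poly <- df$record == "ATOM" | df$resid %in% names(AA_NONSTD)
  aa1 <- unname(AA3TO1[df$resid])
  aa1[is.na(aa1)] <- unname(AA_NONSTD[df$resid[is.na(aa1)]])
  aa1[is.na(aa1)] <- "X"

  mk <- function(d, a1) {
    data.frame(chain = d$chain, resno = d$resno, ins = d$ins,
               resid = d$resid, aa1 = a1, elety = d$name,
               element = d$element, x = d$x, y = d$y, z = d$z, o = d$o,
               h = d$element %in% c("H", "D"), stringsAsFactors = FALSE)
  }
  atom <- mk(df[is_poly, , drop = FALSE], aa1[is_poly])
  ligand <- mk(df[!is_poly, , drop = FALSE], aa1[!is_poly])
  if (nrow(atom) == 0L) {
    stop("parse error: no polymer ATOM records (only ligands/waters found)")
  }
  .finalize_structure(id, atom, ligand)
}

#' Residue table of a chain
#'
#' One row per residue of the chain, in file order, with its 1-based rank,
#' author residue number, insertion code and one-letter code.
#'
#' @param s An `efl_structure`.
#' @param chain Chain identifier.
#' @return Data frame with columns `res_rank`, `resno`, `ins`, `resid`, `aa1`.
#' @export
chain_residues <- function(s, chain) {
  stopifnot(inherits(s, "efl_structure"))
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) {
    stop(sprintf("unknown chain '%s' in structure '%s'", chain, s$id))
  }
  keep <- !duplicated(a$res_rank)
  data.frame(res_rank = a$res_rank[keep], resno = a$resno[keep],
             ins = a$ins[keep], resid = a$resid[keep], aa1 = a$aa1[keep],
             stringsAsFactors = FALSE)
}

.chain_ids <- function(s) unique(s$atom$chain)

#' One-letter sequence of a chain
#'
#' @inheritParams chain_residues
#' @return Character scalar; nonstandard residues without a mapped parent
#'   appear as `X`.
#' @export
chain_sequence <- function(s, chain) {
  paste(chain_residues(s, chain)$aa1, collapse = "")
}

.fmt_atom_name <- function(name, element) {
  # PDB convention: element symbol right-justified in columns 13-14.
  if (nchar(name) >= 4L) return(substr(name, 1, 4))
  if (nchar(element) == 2L) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
}

.pdb_lines <- function(df, record, serial0) {
  n <- nrow(df)
  out <- character(n)
  for (i in seq_len(n)) {
    serial <- (serial0 + i) %% 100000L  # serials wrap past 99999
    out[i] <- sprintf(
      "%-6s%5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, serial, .fmt_atom_name(df$elety[i], df$element[i]),
      df$resid[i], df$chain[i], df$resno[i],
      ifelse(df$ins[i] == "", " ", df$ins[i]),
      df$x[i], df$y[i], df$z[i], df$o[i], 0, df$element[i])
  }
  out
}

#' Write a structure as PDB text
#'
#' Emits ATOM/TER records per chain followed by HETATM records for ligand
#' groups. Coordinates are written to three decimals; atom serial numbers
#' wrap past 99999.
#'
#' @param s An `efl_structure`.
#' @return Character scalar of PDB text that re-parses to an equal structure.
#' @export
write_structure <- function(s) {
  stopifnot(inherits(s, "efl_structure"))
  if (nrow(s$atom) == 0L) stop("cannot write an empty structure")
  lines <- character(0)
  serial <- 0L
  for (ch in .chain_ids(s)) {
    a <- s$atom[s$atom$chain == ch, , drop = FALSE]
    a <- a[order(a$res_rank), , drop = FALSE]
    lines <- c(lines, .pdb_lines(a, "ATOM", serial))
    serial <- (serial + nrow(a)) %% 100000L
    last <- a[nrow(a), ]
    serial <- (serial + 1L) %% 100000L
    lines <- c(lines, sprintf("%-6s%5d      %3s %1s%4d%1s", "TER", serial,
                              last$resid, last$chain, last$resno,
                              ifelse(last$ins == "", " ", last$ins)))
  }
  if (nrow(s$ligand) > 0L) {
    lines <- c(lines, .pdb_lines(s$ligand, "HETATM", serial))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

#' @export
print.efl_structure <- function(x, ...) {
  chains <- .chain_ids(x)
  nres <- sum(vapply(chains, function(ch) nrow(chain_residues(x, ch)), 0L))
  cat(sprintf("<efl_structure '%s'> %d chain(s), %d residues, %d atoms",
              x$id, length(chains), nres, nrow(x$atom)))
  if (nrow(x$ligand) > 0L) {
    cat(sprintf(", %d ligand atoms", nrow(x$ligand)))
  }
  cat("\n")
  invisible(x)
}

# Coordinates of a named atom for each residue rank of a chain; NA rows where
# the atom is absent.
.atom_coords <- function(s, chain, elety, ranks) {
  a <- s$atom[s$atom$chain == chain & s$atom$elety == elety, , drop = FALSE]
  m <- matrix(NA_real_, nrow = length(ranks), ncol = 3)
  idx <- match(ranks, a$res_rank)
  ok <- !is.na(idx)
  m[ok, ] <- as.matrix(a[idx[ok], c("x", "y", "z")])
  m
}
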
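# Per-position structural features of loop windows: backbone phi/psi,
# van der Waals contact counts within 5 A, and geometric H-bond
# donor/acceptor counts within 3.5 A, with intra-loop and loop-to-fold
# contributions encoded separately. Pairs within one residue and between
# sequence-adjacent residues are never counted, so covalent geometry does
# not register as a contact.

# Side-chain donor/acceptor heavy atoms by residue type; the backbone amide
# N donates (except proline) and the carbonyl O (and OXT) accepts for every
# residue. Distance-only criterion: structures generally lack hydrogens.
SC_DONORS <- list(
  R = c("NE", "NH1", "NH2"), N = "ND2", Q = "NE2", H = c("ND1", "NE2"),
  K = "NZ", S = "OG", T = "OG1", W = "NE1", Y = "OH"
)
SC_ACCEPTORS <- list(
  D = c("OD1", "OD2"), E = c("OE1", "OE2"), N = "OD1", Q = "OE1",
  H = c("ND1", "NE2"), S = "OG", T = "OG1", Y = "OH"
)

#' Backbone dihedral angles of every residue
#'
#' Standard phi (C-, N, CA, C) and psi (N, CA, C, N+) torsions in degrees,
#' in (-180, 180]. Angles are undefined (`NA`) at chain termini, across
#' chain breaks (peptide C-N distance above 2.5 A or missing neighbour
#' atoms) and wherever backbone atoms are absent.
#'
#' @param s An `efl_structure`.
#' @return Data frame with columns `chain`, `res_rank`, `resno`, `ins`,
#'   `phi`, `psi`.
#' @export
compute_dihedrals <- function(s) {
  stopifnot(inherits(s, "efl_structure"))
  out <- list()
  for (ch in .chain_ids(s)) {
    res <- chain_residues(s, ch)
    n <- nrow(res)
    N <- .atom_coords(s, ch, "N", res$res_rank)
    CA <- .atom_coords(s, ch, "CA", res$res_rank)
    C <- .atom_coords(s, ch, "C", res$res_rank)
    phi <- psi <- rep(NA_real_, n)
    # residue i is peptide-bonded to i-1 when C(i-1)..N(i) is a bond length
    bonded <- rep(FALSE, n)
    if (n > 1L) {
      d <- sqrt(rowSums((C[-n, , drop = FALSE] - N[-1, , drop = FALSE])^2))
      bonded[-1] <- is.finite(d) & d < 2.5
    }
    for (i in seq_len(n)) {
      ok_self <- all(is.finite(N[i, ])) && all(is.finite(CA[i, ])) &&
        all(is.finite(C[i, ]))
      if (!ok_self) next
      if (i > 1L && bonded[i] && all(is.finite(C[i - 1, ]))) {
        phi[i] <- .torsion(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
      }
      if (i < n && bonded[i + 1L] && all(is.finite(N[i + 1, ]))) {
        psi[i] <- .torsion(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
      }
    }
    out[[ch]] <- data.frame(chain = ch, res_rank = res$res_rank,
                            resno = res$resno, ins = res$ins,
                            phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# All unordered heavy-atom index pairs within `cutoff`, computed blockwise.
.pairs_within <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  block <- 1500L
  acc <- list()
  for (i0 in seq(1L, n, by = block)) {
    i1 <- min(n, i0 + block - 1L)
    sub <- xyz[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(sub^2), rowSums(xyz^2), "+") -
      2 * tcrossprod(sub, xyz)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      gi <- hit[, 1] + i0 - 1L
      gj <- hit[, 2]
      keep <- gi < gj
      acc[[length(acc) + 1L]] <- cbind(i = gi[keep], j = gj[keep])
    }
  }
  do.call(rbind, acc)
}

# Contact machinery shared by VdW counting and H-bond detection. Returns,
# for each kind, a pair table of atom rows (chain atoms only; ligands are
# excluded from the feature model) with same-residue and sequence-adjacent
# pairs removed.
.contact_pairs <- function(s, cutoff, donors = NULL, acceptors = NULL) {
  a <- s$atom[!s$atom$h, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pr <- .pairs_within(xyz, cutoff)
  if (nrow(pr) == 0L) {
    return(data.frame(i = integer(), j = integer()))
  }
  ri <- pr[, 1]
  rj <- pr[, 2]
  same_res <- a$res_key[ri] == a$res_key[rj]
  # sequence-adjacent: author numbering one apart, or consecutive ranks
  # sharing a residue number (insertion codes)
  adjacent <- a$chain[ri] == a$chain[rj] &
    (abs(a$resno[ri] - a$resno[rj]) == 1L |
       (abs(a$res_rank[ri] - a$res_rank[rj]) == 1L &
          a$resno[ri] == a$resno[rj]))
  keep <- !same_res & !adjacent
  if (!is.null(donors)) {
    # directed donor -> acceptor pairs
    don <- .is_donor(a)
    acc <- .is_acceptor(a)
    fwd <- don[ri] & acc[rj]
    rev <- don[rj] & acc[ri]
    i <- c(ri[keep & fwd], rj[keep & rev])
    j <- c(rj[keep & fwd], ri[keep & rev])
    d <- data.frame(i = i, j = j)  # i = donor atom row, j = acceptor
  } else {
    d <- data.frame(i = ri[keep], j = rj[keep])
  }
  attr(d, "atoms") <- a
  d
}

.is_donor <- function(a) {
  bb <- a$elety == "N" & a$aa1 != "P"
  sc <- mapply(function(aa, nm) {
    !is.null(SC_DONORS[[aa]]) && nm %in% SC_DONORS[[aa]]
  }, a$aa1, a$elety, USE.NAMES = FALSE)
  bb | sc
}

.is_acceptor <- function(a) {
  bb <- a$elety %in% c("O", "OXT")
  sc <- mapply(function(aa, nm) {
    !is.null(SC_ACCEPTORS[[aa]]) && nm %in% SC_ACCEPTORS[[aa]]
  }, a$aa1, a$elety, USE.NAMES = FALSE)
  bb | sc
}

# Precompute per-structure pair tables once; window extraction then only
# classifies pairs. Radii are fixed at cache time.
structure_feature_cache <- function(s, vdw_radius = 5.0, hbond_radius = 3.5) {
  vdw <- .contact_pairs(s, vdw_radius)
  hb <- .contact_pairs(s, hbond_radius, donors = TRUE, acceptors = TRUE)
  list(s = s, dihedrals = compute_dihedrals(s),
       vdw = vdw, vdw_atoms = attr(vdw, "atoms"),
       hb = hb, hb_atoms = attr(hb, "atoms"),
       vdw_radius = vdw_radius, hbond_radius = hbond_radius)
}

.check_window <- function(s, chain, start, len) {
  res <- chain_residues(s, chain)
  if (start < 1L || start + len - 1L > nrow(res)) {
    stop(sprintf(
      "window out of range: chain '%s' has %d residues, requested %d..%d",
      chain, nrow(res), start, start + len - 1L))
  }
  res
}

# Tally pairs into per-window-position intra/external counts. `res_of`
# gives, for each atom row index, its (chain, rank); counts accrue to the
# endpoint(s) inside the window.
.window_counts <- function(pairs, atoms, chain, ranks, directed = FALSE) {
  n <- length(ranks)
  intra <- ext <- integer(n)
  if (nrow(pairs) == 0L) {
    return(list(intra = intra, external = ext))
  }
  in_win <- function(k) atoms$chain[k] == chain & atoms$res_rank[k] %in% ranks
  pos_of <- function(k) match(atoms$res_rank[k], ranks)
  wi <- in_win(pairs$i)
  wj <- in_win(pairs$j)
  add <- function(sel, side, bucket) {
    if (!any(sel)) return()
    p <- pos_of(if (side == "i") pairs$i[sel] else pairs$j[sel])
    t <- tabulate(p, nbins = n)
    if (bucket == "intra") intra <<- intra + t else ext <<- ext + t
  }
  add(wi & wj, "i", "intra")
  add(wi & !wj, "i", "ext")
  if (!directed) {
    add(wi & wj, "j", "intra")
    add(wj & !wi, "j", "ext")
  }
  list(intra = intra, external = ext)
}

#' Count van der Waals contacts of a loop window
#'
#' For every residue of the window: the number of heavy-atom pairs within
#' the VdW radius to other loop residues (`vdw_intra`) and to protein
#' residues outside the loop, any chain (`vdw_external`). Pairs within one
#' residue and between sequence-adjacent residues are excluded; ligand
#' atoms are not counted.
#'
#' @param s An `efl_structure`.
#' @param chain Chain of the loop.
#' @param start 1-based residue rank of the first loop position.
#' @param len Window length.
#' @param vdw_radius Contact radius in Angstrom.
#' @param cache Optional [structure_feature_cache()] of `s`.
#' @return Data frame with `vdw_intra` and `vdw_external`, one row per
#'   window position.
#' @export
count_vdw_contacts <- function(s, chain, start, len, vdw_radius = 5.0,
                               cache = NULL) {
  .check_window(s, chain, start, len)
  if (is.null(cache)) cache <- structure_feature_cache(s, vdw_radius = vdw_radius)
  ranks <- seq.int(start, start + len - 1L)
  ct <- .window_counts(cache$vdw, cache$vdw_atoms, chain, ranks)
  data.frame(vdw_intra = ct$intra, vdw_external = ct$external)
}

#' Count hydrogen-bond donors and acceptors of a loop window
#'
#' Geometric criterion: donor (N/O bearing an implicit hydrogen by residue
#' chemistry) to acceptor (carbonyl/side-chain O, or N lone-pair bearer)
#' heavy-atom distance at most the H-bond radius, with the same exclusion
#' rules as VdW contacts. Counts are reported per window residue, split
#' into donor/acceptor roles and intra/external partners.
#'
#' @inheritParams count_vdw_contacts
#' @param hbond_radius Donor-acceptor distance cutoff in Angstrom.
#' @return Data frame with `hd_intra`, `hd_external` (this residue donates)
#'   and `ha_intra`, `ha_external` (this residue accepts).
#' @export
detect_hbonds <- function(s, chain, start, len, hbond_radius = 3.5,
                          cache = NULL) {
  .check_window(s, chain, start, len)
  if (is.null(cache)) {
    cache <- structure_feature_cache(s, hbond_radius = hbond_radius)
  }
  ranks <- seq.int(start, start + len - 1L)
  a <- cache$hb_atoms
  # donor role: pairs whose donor endpoint (i) is a window residue
  don <- .window_counts(data.frame(i = cache$hb$i, j = cache$hb$j), a,
                        chain, ranks, directed = TRUE)
  # acceptor role: swap endpoints
  acc <- .window_counts(data.frame(i = cache$hb$j, j = cache$hb$i), a,
                        chain, ranks, directed = TRUE)
  data.frame(hd_intra = don$intra, hd_external = don$external,
             ha_intra = acc$intra, ha_external = acc$external)
}

#' Extract the full per-position feature bundle of a loop window
#'
#' Bundles the window's one-letter sequence with per-position dihedrals,
#' VdW contact counts and H-bond donor/acceptor counts (intra/external).
#' Positions lacking a complete backbone (chain breaks, unresolved
#' residues) are flagged `defined = FALSE`, carry `NA` dihedrals and zero
#' counts, and are later scored neutrally rather than erroring.
#'
#' @inheritParams count_vdw_contacts
#' @return An object of class `efl_loop`: list with `source` (structure id,
#'   chain, start), `length`, `sequence` and a `features` data frame.
#' @export
extract_loop_features <- function(s, chain, start, len = 30L, cache = NULL) {
  res <- .check_window(s, chain, start, len)
  if (is.null(cache)) cache <- structure_feature_cache(s)
  ranks <- seq.int(start, start + len - 1L)
  di <- cache$dihedrals
  di <- di[di$chain == chain, , drop = FALSE]
  idx <- match(ranks, di$res_rank)
  phi <- di$phi[idx]
  psi <- di$psi[idx]
  # a position is defined when its backbone is complete
  hasbb <- vapply(ranks, function(r) {
    at <- s$atom[s$atom$chain == chain & s$atom$res_rank == r, "elety"]
    all(c("N", "CA", "C") %in% at)
  }, TRUE)
  vdw <- count_vdw_contacts(s, chain, start, len, cache = cache)
  hb <- detect_hbonds(s, chain, start, len, cache = cache)
  feat <- cbind(data.frame(phi = phi, psi = psi), vdw, hb,
                data.frame(defined = hasbb))
  zero <- !feat$defined
  feat[zero, c("vdw_intra", "vdw_external", "hd_intra", "hd_external",
               "ha_intra", "ha_external")] <- 0L
  seq1 <- paste(res$aa1[match(ranks, res$res_rank)], collapse = "")
  structure(list(source = list(id = s$id, chain = chain,
                               start = as.integer(start)),
                 length = as.integer(len), sequence = seq1,
                 features = feat),
            class = "efl_loop")
}

#' @export
print.efl_loop <- function(x, ...) {
  cat(sprintf("<efl_loop> %s chain %s start %d, %d positions\n  %s\n",
              x$source$id, x$source$chain, x$source$start, x$length,
              x$sequence))
  invisible(x)
}
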
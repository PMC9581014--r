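# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive all-pairs double loops so they stay independent of the package's
# vectorized implementations.

# A minimal handcrafted PDB line.
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", altloc = " ",
                     resid = "ALA", chain = "A", resno = 1, ins = " ",
                     x = 0, y = 0, z = 0, occ = 1, elem = "C") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resid, chain, resno, ins,
          x, y, z, occ, 0, elem)
}

# CA-only chain with given per-residue CA coordinates.
ca_only_pdb <- function(coords, resid = "ALA", chain = "A") {
  lines <- vapply(seq_len(nrow(coords)), function(i) {
    pdb_line(serial = i, name = "CA", resid = resid, chain = chain,
             resno = i, x = coords[i, 1], y = coords[i, 2], z = coords[i, 3])
  }, "")
  paste(c(lines, "END"), collapse = "\n")
}

# Random compact structure for oracle equivalence: n_res CA-only residues in
# a box, so atom counts are controlled and distances are diverse.
random_ca_structure <- function(n_res, box = 18, seed = 1, id = "rnd") {
  set.seed(seed)
  coords <- matrix(runif(n_res * 3, 0, box), ncol = 3)
  parse_structure(ca_only_pdb(coords), id = id)
}

# Independent O(n^2) oracle for per-position VdW counts.
oracle_vdw <- function(s, chain, start, len, cutoff = 5) {
  a <- s$atom[!s$atom$h, ]
  ranks <- start:(start + len - 1)
  intra <- ext <- integer(len)
  for (p in seq_len(len)) {
    sel <- a$chain == chain & a$res_rank == ranks[p]
    A <- a[sel, , drop = FALSE]
    B <- a[!sel, , drop = FALSE]
    for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
      adj <- B$chain[j] == chain &&
        (abs(B$resno[j] - A$resno[i]) == 1 ||
           (abs(B$res_rank[j] - ranks[p]) == 1 && B$resno[j] == A$resno[i]))
      if (adj) next
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                  (A$z[i] - B$z[j])^2)
      if (d <= cutoff) {
        if (B$chain[j] == chain && B$res_rank[j] %in% ranks) {
          intra[p] <- intra[p] + 1L
        } else {
          ext[p] <- ext[p] + 1L
        }
      }
    }
  }
  list(intra = intra, external = ext)
}

# Independent oracle for donor/acceptor H-bond counts.
oracle_hbonds <- function(s, chain, start, len, cutoff = 3.5) {
  a <- s$atom[!s$atom$h, ]
  is_don <- (a$elety == "N" & a$aa1 != "P") | mapply(function(aa, nm) {
    !is.null(efloop:::SC_DONORS[[aa]]) && nm %in% efloop:::SC_DONORS[[aa]]
  }, a$aa1, a$elety)
  is_acc <- a$elety %in% c("O", "OXT") | mapply(function(aa, nm) {
    !is.null(efloop:::SC_ACCEPTORS[[aa]]) && nm %in% efloop:::SC_ACCEPTORS[[aa]]
  }, a$aa1, a$elety)
  ranks <- start:(start + len - 1)
  hd_i <- hd_e <- ha_i <- ha_e <- integer(len)
  n <- nrow(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!is_don[i] || !is_acc[j]) next
    same_res <- a$res_key[i] == a$res_key[j]
    adj <- a$chain[i] == a$chain[j] &&
      (abs(a$resno[i] - a$resno[j]) == 1 ||
         (abs(a$res_rank[i] - a$res_rank[j]) == 1 && a$resno[i] == a$resno[j]))
    if (same_res || adj) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                (a$z[i] - a$z[j])^2)
    if (d > cutoff) next
    pi_ <- if (a$chain[i] == chain) match(a$res_rank[i], ranks) else NA
    pj_ <- if (a$chain[j] == chain) match(a$res_rank[j], ranks) else NA
    if (!is.na(pi_)) {
      if (!is.na(pj_)) hd_i[pi_] <- hd_i[pi_] + 1L else
        hd_e[pi_] <- hd_e[pi_] + 1L
    }
    if (!is.na(pj_)) {
      if (!is.na(pi_)) ha_i[pj_] <- ha_i[pj_] + 1L else
        ha_e[pj_] <- ha_e[pj_] + 1L
    }
  }
  list(hd_intra = hd_i, hd_external = hd_e,
       ha_intra = ha_i, ha_external = ha_e)
}

# Exhaustive window-scoring oracle for profile scans (no greedy selection).
oracle_window_scores <- function(p, seq1) {
  lod <- log2(sweep(p$freqs, 2, p$background, "/"))
  letters <- strsplit(seq1, "")[[1]]
  L <- length(letters)
  N <- p$length
  if (L < N) return(numeric(0))
  vapply(seq_len(L - N + 1), function(w) {
    s <- 0
    for (i in seq_len(N)) {
      k <- match(letters[w + i - 1], colnames(p$freqs))
      if (!is.na(k)) s <- s + lod[i, k]
    }
    s
  }, 0)
}

# Exhaustive oracle for the best 7-window seed over a score matrix.
oracle_seed <- function(mat, valid, len = 7) {
  best <- NULL
  ids <- rownames(mat)
  for (src in seq_len(nrow(mat))) for (st in seq_len(ncol(mat) - len + 1)) {
    if (!all(valid[st:(st + len - 1)])) next
    sc <- sum(mat[src, st:(st + len - 1)])
    if (is.null(best) || sc > best$score ||
        (sc == best$score && st < best$start) ||
        (sc == best$score && st == best$start && ids[src] < best$source)) {
      best <- list(source = ids[src], start = st, score = sc)
    }
  }
  best
}

# Small helical family used by several grafting tests: conserved backbone
# (2 deg jitter), half-conserved sequence.
helix_family <- function(n = 6, len = 30, flank = 8, seed = 11) {
  sig <- rep("x", len)
  sig[seq(1, len, by = 3)] <- strsplit("ADKLGSTWNE", "")[[1]][
    seq_len(length(seq(1, len, by = 3)))]
  tpl <- matrix(rep(c(-57, -47), each = len), ncol = 2)
  generate_motif_family(motif_spec(length = len, signature = sig,
                                   template = tpl, jitter = 2,
                                   n_members = n, flank = flank,
                                   seed = seed))
}

# Loop instances + descriptor from a family, optionally on a train subset.
family_descriptor <- function(fam, idx = seq_along(fam$structures),
                              config = efl_config(), name = "fam") {
  loops <- lapply(idx, function(k) {
    extract_loop_features(fam$structures[[k]], "A", fam$offsets[k],
                          fam$spec$length)
  })
  assemble_descriptor(loops, config, name = name)
}

# Write a family as on-disk pipeline inputs (PDB dir, seed/db FASTA).
write_family_inputs <- function(fam, dir) {
  pdb_dir <- file.path(dir, "pdbs")
  dir.create(pdb_dir, showWarnings = FALSE, recursive = TRUE)
  for (s in fam$structures) {
    writeLines(write_structure(s), file.path(pdb_dir,
                                             paste0(s$id, ".pdb")))
  }
  motifs <- vapply(seq_along(fam$structures), function(k) {
    substr(chain_sequence(fam$structures[[k]], "A"), fam$offsets[k],
           fam$offsets[k] + fam$spec$length - 1)
  }, "")
  seeds <- file.path(dir, "seeds.fasta")
  writeLines(paste0(">seed_", seq_along(motifs), "\n", motifs), seeds)
  db <- file.path(dir, "db.fasta")
  writeLines(paste0(">db_", seq_along(motifs), "\n",
                    vapply(seq_along(motifs), function(k) {
                      chain_sequence(fam$structures[[k]], "A")
                    }, "")), db)
  list(pdb_dir = pdb_dir, seeds = seeds, db = db)
}

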
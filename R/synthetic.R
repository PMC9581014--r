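# Synthetic-fixture generators: ideal-geometry peptides built from backbone
# torsions, planted-motif structure families with controlled sequence
# conservation and torsion jitter, and profile-sampled sequence databases.
# Everything the test-suite and the worked examples consume is generated
# here, deterministically per seed.

# Ideal backbone geometry (lengths in Angstrom, angles in degrees);
# omega fixed trans so torsion extraction inverts construction exactly.
.GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.5, a_n_ca_cb = 110.5
)

#' Build an ideal-geometry peptide from backbone torsions
#'
#' Constructs backbone coordinates (N, CA, C, O, plus CB for non-glycine)
#' realizing the requested phi/psi torsions with ideal bond lengths and
#' angles and trans peptide bonds (omega = 180 deg). `phi[1]` and
#' `psi[n]` are undefined at the termini and ignored.
#'
#' @param phi,psi Numeric vectors of backbone torsions in degrees, one per
#'   residue.
#' @param sequence One-letter amino-acid string (or character vector) of the
#'   same length.
#' @param id Structure identifier.
#' @param chain Chain identifier.
#' @return An `efl_structure`. `compute_dihedrals()` on the result recovers
#'   the requested torsions to well below 1e-4 degrees.
#' @examples
#' s <- build_peptide(rep(-57, 8), rep(-47, 8), "ADKLGSTW")
#' compute_dihedrals(s)
#' @export
build_peptide <- function(phi, psi, sequence, id = "peptide", chain = "A") {
  seq1 <- if (length(sequence) == 1L) {
    strsplit(sequence, "")[[1]]
  } else {
    as.character(sequence)
  }
  n <- length(seq1)
  stopifnot(n >= 1L, length(phi) == n, length(psi) == n)
  g <- .GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(cos(pi - th), sin(pi - th), 0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      N[i + 1, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_n,
                                g$a_ca_c_n, psi[i])
      CA[i + 1, ] <- .place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                 g$a_c_n_ca, 180)
      C[i + 1, ] <- .place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                                g$a_n_ca_c, phi[i + 1])
    }
  }
  for (i in seq_len(n)) {
    ps <- if (i < n) psi[i] else 180
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], g$b_c_o, g$a_ca_c_o,
                          wrap_angle(ps + 180))
  }
  rows <- list()
  for (i in seq_len(n)) {
    resid <- unname(names(AA3TO1)[match(seq1[i], AA3TO1)])
    if (is.na(resid)) resid <- "UNK"
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    el <- c("N", "C", "C", "O")
    if (seq1[i] != "G") {
      cb <- .place_atom(C[i, ], N[i, ], CA[i, ], g$b_ca_cb, g$a_n_ca_cb,
                        -122.6)
      nm <- c(nm, "CB")
      xyz <- rbind(xyz, cb)
      el <- c(el, "C")
    }
    aa1 <- if (resid %in% names(AA3TO1)) seq1[i] else "X"
    rows[[i]] <- data.frame(chain = chain, resno = i, ins = "",
                            resid = resid, aa1 = aa1,
                            elety = nm, element = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            o = 1, h = FALSE, stringsAsFactors = FALSE)
  }
  .finalize_structure(id, do.call(rbind, rows), .empty_atom_df())
}

#' Specification of a planted loop-motif family
#'
#' Bundles the conditions under which a synthetic structure family is
#' generated: motif length, per-position sequence constraints (a fixed
#' letter, or `"x"` for unconstrained positions drawn uniformly), a backbone
#' torsion template with per-position Gaussian jitter, family size, flank
#' length and RNG seed.
#'
#' The default emulates a beta-loop-alpha phosphate-binding loop: a strand
#' lead-in, a glycine-rich turn with a `GxGxxGKT`-style signature, and an
#' exit helix.
#'
#' @param length Motif length in residues.
#' @param signature Character vector of length `length`; fixed letters or
#'   `"x"`.
#' @param template Numeric `length` x 2 matrix of (phi, psi) in degrees.
#' @param jitter Torsion jitter standard deviation, degrees.
#' @param n_members Number of structures in the family.
#' @param flank Number of randomized residues on each side of the motif.
#' @param seed RNG seed.
#' @return A list of class `efl_motif_spec`.
#' @export
motif_spec <- function(length = 30L,
                       signature = NULL,
                       template = NULL,
                       jitter = 5,
                       n_members = 30L,
                       flank = 25L,
                       seed = 1L) {
  if (is.null(signature)) {
    signature <- rep("x", length)
    if (length >= 18L) {
      signature[11:18] <- c("G", "x", "G", "x", "x", "G", "K", "T")
    }
  }
  if (is.null(template)) {
    template <- matrix(NA_real_, length, 2)
    nb <- min(10L, length)
    template[seq_len(nb), ] <- rep(c(-120, 130), each = nb)
    if (length > 10L) {
      nl <- min(16L, length)
      template[11:nl, ] <- rep(c(-70, 150), each = nl - 10L)
    }
    if (length > 16L) {
      template[17:length, ] <- rep(c(-57, -47), each = length - 16L)
    }
  }
  stopifnot(length(signature) == length, nrow(template) == length,
            jitter >= 0, n_members >= 1L, flank >= 0L)
  structure(list(length = as.integer(length), signature = signature,
                 template = template, jitter = jitter,
                 n_members = as.integer(n_members),
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "efl_motif_spec")
}

# Random coil-like torsions for flanking regions: draws from three broad
# Ramachandran basins.
.coil_torsions <- function(n) {
  basins <- rbind(c(-63, -42), c(-120, 130), c(-75, 145))
  k <- sample.int(3, n, replace = TRUE, prob = c(0.35, 0.35, 0.3))
  cbind(wrap_angle(basins[k, 1] + rnorm(n, 0, 15)),
        wrap_angle(basins[k, 2] + rnorm(n, 0, 15)))
}

#' Generate a planted-motif structure family
#'
#' Each family member embeds one motif window (signature letters fixed,
#' unconstrained positions drawn uniformly over the 20 standard residues;
#' torsions = template + Gaussian jitter) between randomized coil flanks.
#' The true motif offsets (1-based residue rank of the motif start) are
#' returned for recovery experiments. Deterministic per `spec$seed`.
#'
#' @param spec An [motif_spec()] object.
#' @return List with `structures` (list of `efl_structure`), `offsets`
#'   (integer vector of true motif starts) and `spec`.
#' @export
generate_motif_family <- function(spec = motif_spec()) {
  stopifnot(inherits(spec, "efl_motif_spec"))
  set.seed(spec$seed)
  structures <- vector("list", spec$n_members)
  offsets <- integer(spec$n_members)
  for (m in seq_len(spec$n_members)) {
    motif_seq <- vapply(spec$signature, function(a) {
      if (a == "x") sample(AA20, 1) else a
    }, "")
    motif_tor <- cbind(
      wrap_angle(spec$template[, 1] + rnorm(spec$length, 0, spec$jitter)),
      wrap_angle(spec$template[, 2] + rnorm(spec$length, 0, spec$jitter)))
    fl1 <- .coil_torsions(spec$flank)
    fl2 <- .coil_torsions(spec$flank)
    seq1 <- c(sample(AA20, spec$flank, replace = TRUE), motif_seq,
              sample(AA20, spec$flank, replace = TRUE))
    tor <- rbind(fl1, motif_tor, fl2)
    structures[[m]] <- build_peptide(tor[, 1], tor[, 2], seq1,
                                     id = sprintf("fam_%03d", m))
    offsets[m] <- spec$flank + 1L
  }
  list(structures = structures, offsets = offsets, spec = spec)
}

#' Sample sequences from a profile
#'
#' Draws `n` sequences, each containing one window sampled position-wise
#' from the profile's frequencies, embedded between uniform-random flanks.
#'
#' @param p An `efl_profile` (see [build_pssm()]).
#' @param n Number of sequences.
#' @param flank_len Flank length on each side.
#' @param seed RNG seed.
#' @return Named character vector of sequences.
#' @export
sample_sequences <- function(p, n, flank_len = 20L, seed = 1L) {
  stopifnot(inherits(p, "efl_profile"), n >= 1L)
  set.seed(seed)
  out <- character(n)
  for (i in seq_len(n)) {
    win <- vapply(seq_len(p$length), function(j) {
      sample(AA20, 1, prob = p$freqs[j, ])
    }, "")
    out[i] <- paste(c(sample(AA20, flank_len, replace = TRUE), win,
                      sample(AA20, flank_len, replace = TRUE)),
                    collapse = "")
  }
  names(out) <- sprintf("syn_%04d", seq_len(n))
  out
}
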
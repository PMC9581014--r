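# Finding and placing the best realization of a descriptor in a target
# scaffold: per-position per-source score matrix, 7-residue seed segment,
# greedy extension with source switching (recombinant loops), and
# anchor-based Kabsch replacement of the target window's coordinates.

.source_id <- function(src) {
  sprintf("%s:%s:%d", src$id, src$chain, src$start)
}

#' Per-position, per-source score matrix for grafting
#'
#' For every provenance source loop of the descriptor and every descriptor
#' position, the position's weighted objective contribution
#' `W_i^P sum_j W_ij^F S_ij` of placing that source's residue and features
#' at the target position. Where the target window is defined, its native
#' features are the reference and sources are scored pairwise against
#' them; undefined (disordered) target positions are marked invalid, drop
#' back to descriptor-referenced scores and are excluded from the seed
#' search.
#'
#' @param target Target `efl_structure`.
#' @param chain Target chain.
#' @param start 1-based window start in the target chain.
#' @param d An `efl_descriptor`.
#' @return Object of class `efl_position_scores`: list with `scores`
#'   (sources x positions matrix, rownames `id:chain:start`), `valid`
#'   (logical per position), `target_loop` and `sources`.
#' @export
score_position_matrix <- function(target, chain, start, d) {
  stopifnot(inherits(d, "efl_descriptor"))
  target_loop <- extract_loop_features(target, chain, start, d$length)
  ids <- vapply(d$instances, function(x) .source_id(x$source), "")
  mat <- matrix(NA_real_, length(ids), d$length,
                dimnames = list(ids, NULL))
  for (k in seq_along(d$instances)) {
    br <- score_loop(d$instances[[k]], d, reference = target_loop)
    mat[k, ] <- br$position_scores
  }
  structure(list(scores = mat, valid = target_loop$features$defined,
                 target_loop = target_loop,
                 target = list(chain = chain, start = start),
                 sources = lapply(d$instances, function(x) x$source)),
            class = "efl_position_scores")
}

#' Find the best seed segment
#'
#' The (source, start) pair maximizing the cumulative score over
#' `seed_length` consecutive valid positions. Ties prefer the smaller
#' start, then the lexicographically smaller source id.
#'
#' @param psm An [score_position_matrix()] result.
#' @param seed_length Segment length (default 7, half a typical functional
#'   signature).
#' @return List with `source` (row name), `source_index`, `start`, `score`.
#' @export
find_seed_segment <- function(psm, seed_length = 7L) {
  stopifnot(inherits(psm, "efl_position_scores"))
  mat <- psm$scores
  N <- ncol(mat)
  if (N < seed_length) stop("no valid seed: window shorter than seed")
  ok_run <- vapply(seq_len(N - seed_length + 1L), function(st) {
    all(psm$valid[st:(st + seed_length - 1L)])
  }, TRUE)
  if (!any(ok_run)) stop("no valid seed: no run of valid positions")
  ids <- rownames(mat)
  best <- NULL
  for (st in which(ok_run)) {
    span <- st:(st + seed_length - 1L)
    sums <- rowSums(mat[, span, drop = FALSE])
    ord <- order(-sums, ids)
    cand <- list(source = ids[ord[1]], source_index = ord[1],
                 start = st, score = unname(sums[ord[1]]),
                 length = as.integer(seed_length))
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  best
}

#' Greedily extend a seed into a full graft plan
#'
#' Starting from the seed segment, the plan grows one position at a time
#' from either end, always taking the higher-scoring next position. At
#' each step the current end's source is kept unless another source scores
#' strictly higher (by more than `switch_margin`), in which case a new
#' segment opens -- this is how recombinant loops merged from several
#' structures arise. Invalid target positions are filled by the
#' best-scoring source, yielding a best-effort plan that always covers all
#' N positions.
#'
#' @param psm An [score_position_matrix()] result.
#' @param seed A [find_seed_segment()] result (computed if `NULL`).
#' @param seed_length Seed length used when `seed` is `NULL`.
#' @param switch_margin Hysteresis margin for source switching.
#' @return Object of class `efl_graft_plan`: list with `segments` (data
#'   frame `source`, `from`, `to`, `score`), per-position `assign`,
#'   `total` score and the target window.
#' @export
extend_and_merge <- function(psm, seed = NULL, seed_length = 7L,
                             switch_margin = 0) {
  stopifnot(inherits(psm, "efl_position_scores"))
  if (is.null(seed)) seed <- find_seed_segment(psm, seed_length)
  mat <- psm$scores
  ids <- rownames(mat)
  N <- ncol(mat)
  assign <- integer(N)
  l <- seed$start
  r <- seed$start + seed$length - 1L
  assign[l:r] <- seed$source_index
  pick <- function(pos, cur) {
    sc <- mat[, pos]
    ord <- order(-sc, ids)
    top <- ord[1]
    if (sc[top] > sc[cur] + switch_margin && top != cur) top else cur
  }
  while (l > 1L || r < N) {
    lv <- if (l > 1L) {
      ksrc <- pick(l - 1L, assign[l])
      c(ksrc, mat[ksrc, l - 1L])
    }
    rv <- if (r < N) {
      ksrc <- pick(r + 1L, assign[r])
      c(ksrc, mat[ksrc, r + 1L])
    }
    go_left <- !is.null(lv) && (is.null(rv) || lv[2] > rv[2])
    if (go_left) {
      l <- l - 1L
      assign[l] <- lv[1]
    } else {
      r <- r + 1L
      assign[r] <- rv[1]
    }
  }
  runs <- rle(assign)
  to <- cumsum(runs$lengths)
  from <- to - runs$lengths + 1L
  segments <- data.frame(
    source = ids[runs$values], from = from, to = to,
    score = vapply(seq_along(from), function(k) {
      sum(mat[runs$values[k], from[k]:to[k]])
    }, 0), stringsAsFactors = FALSE)
  structure(list(target = psm$target, segments = segments,
                 assign = ids[assign],
                 sources = psm$sources,
                 total = sum(mat[cbind(assign, seq_len(N))]),
                 valid = psm$valid, length = N),
            class = "efl_graft_plan")
}

#' @export
print.efl_graft_plan <- function(x, ...) {
  cat(sprintf("<efl_graft_plan> chain %s start %d, %d positions, F = %.4f\n",
              x$target$chain, x$target$start, x$length, x$total))
  for (k in seq_len(nrow(x$segments))) {
    seg <- x$segments[k, ]
    cat(sprintf("  %2d..%2d  %s  (%.4f)\n", seg$from, seg$to, seg$source,
                seg$score))
  }
  invisible(x)
}

# Backbone anchor coordinates (N, CA, C of the given residue ranks) as a
# matrix; errors if any anchor atom is missing.
.anchor_coords <- function(s, chain, ranks, what) {
  rows <- list()
  for (r in ranks) {
    for (el in c("N", "CA", "C")) {
      a <- s$atom[s$atom$chain == chain & s$atom$res_rank == r &
                    s$atom$elety == el, , drop = FALSE]
      if (nrow(a) == 0L) {
        stop(sprintf("missing anchors: %s residue rank %d atom %s (%s)",
                     s$id, r, el, what))
      }
      rows[[length(rows) + 1L]] <- c(a$x[1], a$y[1], a$z[1])
    }
  }
  do.call(rbind, rows)
}

#' Graft a planned loop into the target scaffold
#'
#' Each segment of the plan is taken from its provenance structure,
#' rigid-body superposed onto the target by least squares (Kabsch) on
#' backbone anchors -- three flanking residues on window-edge sides, the
#' target's native junction residue at internal segment boundaries -- and
#' the target window's residues are replaced (side chains carried from the
#' source unchanged). The report lists every junction's CA-CA and C-N
#' distance and the count of heavy-atom clashes (< 2 A) between grafted
#' atoms and the retained scaffold.
#'
#' @param target Target `efl_structure`.
#' @param plan An [extend_and_merge()] plan.
#' @param library Named list of provenance `efl_structure` objects, keyed
#'   by structure id.
#' @return Object of class `efl_graft`: list with `structure` (the
#'   re-engineered `efl_structure`), `junctions` (data frame), `clashes`
#'   and the `plan`.
#' @export
graft_loop <- function(target, plan, library) {
  stopifnot(inherits(plan, "efl_graft_plan"),
            inherits(target, "efl_structure"))
  chain <- plan$target$chain
  start <- plan$target$start
  N <- plan$length
  res <- chain_residues(target, chain)
  if (start - 3L < 1L || start + N + 2L > nrow(res)) {
    stop("missing anchors: target window must be flanked by >= 3 resolved ",
         "residues on each side")
  }
  src_by_id <- setNames(plan$sources,
                        vapply(plan$sources, .source_id, ""))
  new_atoms <- list()
  for (k in seq_len(nrow(plan$segments))) {
    seg <- plan$segments[k, ]
    src <- src_by_id[[seg$source]]
    if (is.null(src)) stop("unknown segment source: ", seg$source)
    src_s <- library[[src$id]]
    if (is.null(src_s)) {
      stop("missing provenance structure in library: ", src$id)
    }
    src_res <- chain_residues(src_s, src$chain)
    src_from <- src$start + seg$from - 1L
    src_to <- src$start + seg$to - 1L
    # anchors: the three backbone atoms (N, CA, C) of the residue
    # immediately flanking the segment on each side -- the scaffold flank
    # at window edges, the native junction residue at internal boundaries
    t_left <- if (seg$from == 1L) start - 1L else start + seg$from - 2L
    t_right <- if (seg$to == N) start + N else start + seg$to
    s_left <- src_from - 1L
    s_right <- src_to + 1L
    if (min(s_left) < 1L || max(s_right) > nrow(src_res)) {
      stop(sprintf("missing anchors: source %s lacks flanking residues",
                   seg$source))
    }
    P <- rbind(.anchor_coords(src_s, src$chain, c(s_left, s_right), "source"),
               NULL)
    Q <- rbind(.anchor_coords(target, chain, c(t_left, t_right), "target"),
               NULL)
    fit <- .kabsch(P, Q)
    seg_atoms <- src_s$atom[src_s$atom$chain == src$chain &
                              src_s$atom$res_rank >= src_from &
                              src_s$atom$res_rank <= src_to, , drop = FALSE]
    xyz <- .kabsch_apply(fit, as.matrix(seg_atoms[, c("x", "y", "z")]))
    seg_atoms$x <- xyz[, 1]
    seg_atoms$y <- xyz[, 2]
    seg_atoms$z <- xyz[, 3]
    # renumber into the target chain, keeping author numbering
    tgt_rank <- start + (seg$from:seg$to) - 1L
    map <- match(seg_atoms$res_rank, src_from:src_to)
    seg_atoms$chain <- chain
    seg_atoms$resno <- res$resno[match(tgt_rank, res$res_rank)][map]
    seg_atoms$ins <- res$ins[match(tgt_rank, res$res_rank)][map]
    seg_atoms$res_rank <- tgt_rank[map]
    new_atoms[[k]] <- seg_atoms
  }
  graft_df <- do.call(rbind, new_atoms)
  graft_df <- graft_df[order(graft_df$res_rank), , drop = FALSE]

  win_ranks <- start:(start + N - 1L)
  keep <- !(target$atom$chain == chain & target$atom$res_rank %in% win_ranks)
  pre <- target$atom[keep & target$atom$chain == chain &
                       target$atom$res_rank < start, , drop = FALSE]
  post <- target$atom[keep & target$atom$chain == chain &
                        target$atom$res_rank > max(win_ranks), , drop = FALSE]
  other <- target$atom[target$atom$chain != chain, , drop = FALSE]
  atom <- rbind(pre, graft_df, post, other)
  out <- .finalize_structure(paste0(target$id, "_graft"),
                             atom[, setdiff(colnames(atom),
                                            c("res_key", "res_rank"))],
                             target$ligand)

  # junction geometry: window edges plus internal segment boundaries
  bounds <- c(start - 1L,
              start + plan$segments$to[-nrow(plan$segments)] - 1L,
              start + N - 1L)
  res_out <- chain_residues(out, chain)
  jx <- lapply(bounds, function(b) {
    ca1 <- .atom_xyz(out, chain, b, "CA")
    ca2 <- .atom_xyz(out, chain, b + 1L, "CA")
    c1 <- .atom_xyz(out, chain, b, "C")
    n2 <- .atom_xyz(out, chain, b + 1L, "N")
    data.frame(left_rank = b, right_rank = b + 1L,
               ca_ca = sqrt(sum((ca1 - ca2)^2)),
               c_n = sqrt(sum((c1 - n2)^2)))
  })
  junctions <- do.call(rbind, jx)

  clashes <- .count_clashes(out, chain, win_ranks, bounds)
  structure(list(structure = out, junctions = junctions, clashes = clashes,
                 plan = plan),
            class = "efl_graft")
}

.atom_xyz <- function(s, chain, rank, elety) {
  a <- s$atom[s$atom$chain == chain & s$atom$res_rank == rank &
                s$atom$elety == elety, , drop = FALSE]
  if (nrow(a) == 0L) return(c(NA_real_, NA_real_, NA_real_))
  c(a$x[1], a$y[1], a$z[1])
}

# Heavy-atom pairs < 2 A between the grafted window and the retained
# scaffold, excluding the junction peptide C-N bonds.
.count_clashes <- function(s, chain, win_ranks, bounds) {
  a <- s$atom[!s$atom$h, , drop = FALSE]
  in_win <- a$chain == chain & a$res_rank %in% win_ranks
  A <- as.matrix(a[in_win, c("x", "y", "z"), drop = FALSE])
  B <- as.matrix(a[!in_win, c("x", "y", "z"), drop = FALSE])
  if (nrow(A) == 0L || nrow(B) == 0L) return(0L)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  hit <- which(d2 < 4, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(0L)
  ai <- a[in_win, , drop = FALSE][hit[, 1], ]
  bi <- a[!in_win, , drop = FALSE][hit[, 2], ]
  # junction peptide bonds are chemistry, not clashes
  bond <- (ai$elety == "N" & bi$elety == "C" &
             bi$res_rank == ai$res_rank - 1L) |
    (ai$elety == "C" & bi$elety == "N" & bi$res_rank == ai$res_rank + 1L)
  bond <- bond & bi$chain == chain
  sum(!bond)
}

#' Write the graft report as TSV
#'
#' Segments with their sources and scores, junction geometry and the clash
#' count.
#'
#' @param g An `efl_graft`.
#' @param path Output TSV path.
#' @export
write_graft_tsv <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# segments", con)
  utils::write.table(g$plan$segments, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("# junctions", con)
  utils::write.table(g$junctions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# clashes\t%d", g$clashes), con)
  writeLines(sprintf("# total_score\t%.6f", g$plan$total), con)
  invisible(path)
}
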
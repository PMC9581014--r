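# Sequence-profile machinery: seed PSSM construction, log-odds window
# scanning of a sequence database, the iterative expansion loop that pools
# matched segments back into the profile until it stops changing, and
# profile matching against structure-derived sequences.

#' Read (aligned) FASTA sequences
#'
#' @param path FASTA file. Seed alignments must be gapless; gaps are
#'   rejected by [build_pssm()].
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Build a position-specific scoring matrix from a gapless alignment
#'
#' Per-position amino-acid frequencies with additive pseudocounts:
#' `freqs = (counts + pseudocount * background) / (n + pseudocount)`,
#' where `n` is the number of standard-letter observations in the column.
#'
#' @param alignment Character vector of equal-length, gapless sequences
#'   (or an `AAStringSet`).
#' @param pseudocount Non-negative pseudocount mass.
#' @param background Vector of 20 background frequencies (named by
#'   one-letter code) or `NULL` for uniform 1/20.
#' @return An object of class `efl_profile`: list with `length`, `freqs`
#'   (N x 20 matrix), `background`, `pseudocount`, `n_sequences`.
#' @examples
#' p <- build_pssm(c("AG", "AG", "GG"), pseudocount = 0)
#' p$freqs
#' @export
build_pssm <- function(alignment, pseudocount = 1, background = NULL) {
  seqs <- as.character(alignment)
  if (length(seqs) == 0L) stop("empty alignment")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged alignment: sequences differ in length")
  if (any(grepl("[-.]", seqs))) stop("gapped alignment not allowed")
  if (is.null(background)) {
    background <- setNames(rep(1 / 20, 20), AA20)
  } else {
    stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-6)
    background <- setNames(as.numeric(background[AA20]), AA20)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  freqs <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    cnt <- table(factor(mat[, i], levels = AA20))
    n <- sum(cnt)
    freqs[i, ] <- (as.numeric(cnt) + pseudocount * background) /
      (n + pseudocount)
    if (n + pseudocount == 0) {
      stop(sprintf("column %d has no standard residues and no pseudocount", i))
    }
    freqs[i, ] <- freqs[i, ] / sum(freqs[i, ])
  }
  structure(list(length = L, freqs = freqs, background = background,
                 pseudocount = pseudocount, n_sequences = length(seqs)),
            class = "efl_profile")
}

#' @export
print.efl_profile <- function(x, ...) {
  cons <- paste(AA20[apply(x$freqs, 1, which.max)], collapse = "")
  cat(sprintf("<efl_profile> %d positions, %d sequences\n  consensus %s\n",
              x$length, x$n_sequences, cons))
  invisible(x)
}

.profile_lod <- function(p) {
  log2(sweep(p$freqs, 2, p$background, "/"))
}

# Score all length-N windows of one sequence; unknown letters contribute 0
# bits. Returns numeric vector over window starts (1-based), or NULL if the
# sequence is shorter than the profile.
.window_scores <- function(lod, seq1, N) {
  idx <- match(strsplit(seq1, "")[[1]], AA20)
  L <- length(idx)
  if (L < N) return(NULL)
  sc <- numeric(L - N + 1L)
  for (i in seq_len(N)) {
    col <- idx[i:(i + L - N)]
    v <- lod[i, col]
    v[is.na(col)] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan a sequence database with a profile
#'
#' Every length-N window of every database sequence is scored as the sum of
#' per-position log-odds (bits). Windows at or above `threshold` are
#' returned, made non-overlapping within each sequence by greedy
#' best-score-first selection; equal scores favour the smaller offset.
#'
#' @param p An `efl_profile`.
#' @param db Named character vector of sequences.
#' @param threshold Bit-score threshold (finite).
#' @return Data frame with `id`, `offset` (1-based window start), `score`
#'   and `segment` (the matched subsequence).
#' @export
scan_database <- function(p, db, threshold) {
  stopifnot(inherits(p, "efl_profile"), is.finite(threshold) ||
              threshold == -Inf || threshold == Inf)
  lod <- .profile_lod(p)
  N <- p$length
  ids <- names(db)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(db))
  out <- list()
  for (k in seq_along(db)) {
    sc <- .window_scores(lod, db[[k]], N)
    if (is.null(sc)) next
    ord <- order(-sc, seq_along(sc))
    taken <- logical(length(sc) + N)
    for (w in ord) {
      if (sc[w] < threshold) break
      span <- w:(w + N - 1L)
      if (any(taken[span])) next
      taken[span] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        id = ids[k], offset = w, score = sc[w],
        segment = substr(db[[k]], w, w + N - 1L), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(id = character(), offset = integer(),
                      score = numeric(), segment = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Iteratively expand a seed profile against a database
#'
#' Hard-assignment expansion loop: scan the database, pool the seed
#' alignment with all matched segments, rebuild the PSSM, and repeat until
#' the matched-segment set stops changing, the max-norm frequency change
#' drops below `tol`, or `max_iter` is reached. If the first scan yields no
#' matches the seed profile is returned flagged `"unconverged-empty"`.
#'
#' @inheritParams scan_database
#' @param seeds Gapless seed alignment (character vector).
#' @param max_iter Maximum number of scan/rebuild iterations.
#' @param tol Convergence tolerance on max absolute frequency change.
#' @param pseudocount,background Passed to [build_pssm()].
#' @return Converged `efl_profile` with attributes `segments` (the matched
#'   windows of the final scan), `iterations`, and `flag`
#'   (`"converged"`, `"max-iter"` or `"unconverged-empty"`).
#' @export
iterate_profile <- function(seeds, db, threshold, max_iter = 10L,
                            tol = 1e-6, pseudocount = 1, background = NULL) {
  p <- build_pssm(seeds, pseudocount, background)
  prev_key <- NULL
  matches <- NULL
  for (it in seq_len(max_iter)) {
    m <- scan_database(p, db, threshold)
    if (nrow(m) == 0L && it == 1L) {
      attr(p, "segments") <- m
      attr(p, "iterations") <- 1L
      attr(p, "flag") <- "unconverged-empty"
      return(p)
    }
    key <- paste(sort(paste(m$id, m$offset)), collapse = ";")
    p_new <- build_pssm(c(as.character(seeds), m$segment),
                        pseudocount, background)
    delta <- max(abs(p_new$freqs - p$freqs))
    p <- p_new
    matches <- m
    if (identical(key, prev_key) || delta < tol) {
      attr(p, "segments") <- matches
      attr(p, "iterations") <- it
      attr(p, "flag") <- "converged"
      return(p)
    }
    prev_key <- key
  }
  attr(p, "segments") <- matches
  attr(p, "iterations") <- max_iter
  attr(p, "flag") <- "max-iter"
  p
}

#' Collect loop instances by matching a profile against structures
#'
#' Chain sequences of each structure are scanned exactly as in
#' [scan_database()]; every qualifying window is converted to a feature
#' bundle via [extract_loop_features()].
#'
#' @inheritParams scan_database
#' @param structures List of `efl_structure` objects.
#' @param vdw_radius,hbond_radius Contact radii passed to feature
#'   extraction.
#' @return List of `efl_loop` objects (possibly empty).
#' @export
match_structures <- function(p, structures, threshold, vdw_radius = 5.0,
                             hbond_radius = 3.5) {
  stopifnot(inherits(p, "efl_profile"))
  out <- list()
  for (s in structures) {
    cache <- NULL
    for (ch in .chain_ids(s)) {
      seqs <- setNames(chain_sequence(s, ch), ch)
      m <- scan_database(p, seqs, threshold)
      if (nrow(m) == 0L) next
      if (is.null(cache)) {
        cache <- structure_feature_cache(s, vdw_radius, hbond_radius)
      }
      for (r in seq_len(nrow(m))) {
        out[[length(out) + 1L]] <- extract_loop_features(
          s, ch, m$offset[r], p$length, cache = cache)
      }
    }
  }
  out
}
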
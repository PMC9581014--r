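# The objective function: F = sum_i sum_j W_i^P * W_ij^F * S_ij over the
# loop's N positions and the five features (sequence, dihedrals, VdW
# contacts, H-bond acceptors, H-bond donors). All per-feature scores are
# similarities in [0, 1] so F is maximized by the best-fitting loop;
# undefined features score a neutral 0.5 so missing data dominates neither
# way.

.blosum_env <- new.env(parent = emptyenv())

# BLOSUM62 over the 20 standard letters, raw log-odds and a copy rescaled
# to [0, 1] by the matrix's global min/max.
.blosum62 <- function() {
  if (is.null(.blosum_env$raw)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    raw <- e$BLOSUM62[AA20, AA20]
    .blosum_env$raw <- raw
    .blosum_env$lo <- min(raw)
    .blosum_env$hi <- max(raw)
    .blosum_env$scaled <- (raw - min(raw)) / (max(raw) - min(raw))
  }
  .blosum_env
}

#' Sequence score of a residue against a descriptor position
#'
#' Frequency-weighted expected BLOSUM62 log-odds of the query residue
#' against the position's profile, `sum_k w_k B62(aa, k)`, rescaled to
#' `[0, 1]` by the matrix's global minimum and maximum so all features
#' share a scale. With `mode = "consensus"` the query is compared to the
#' most frequent residue instead. Unknown residues (`X`) score a neutral
#' 0.5.
#'
#' @param aa One-letter residue code.
#' @param pos A descriptor position (element of `d$positions`).
#' @param mode `"profile"` (default) or `"consensus"`.
#' @return Score in `[0, 1]`.
#' @export
score_sequence <- function(aa, pos, mode = c("profile", "consensus")) {
  mode <- match.arg(mode)
  if (!aa %in% AA20) return(0.5)
  b <- .blosum62()
  raw <- if (mode == "profile") {
    sum(pos$aa_freqs * b$raw[aa, AA20])
  } else {
    b$raw[aa, AA20[which.max(pos$aa_freqs)]]
  }
  (raw - b$lo) / (b$hi - b$lo)
}

# Pairwise sequence similarity used when a reference loop is supplied.
.score_sequence_pair <- function(aa, ref_aa) {
  if (!aa %in% AA20 || !ref_aa %in% AA20) return(NA_real_)
  b <- .blosum62()
  b$scaled[aa, ref_aa]
}

# Responsibilities of a (centred) displacement set under the mixture.
.responsibilities <- function(model, delta) {
  K <- model$K
  ll <- vapply(seq_len(K), function(k) {
    log(model$weights[k]) +
      sum(stats::dnorm(delta[k, ], 0, sqrt(model$sigma2[k, ]), log = TRUE))
  }, 0)
  ll <- ll - max(ll)
  w <- exp(ll)
  w / sum(w)
}

.erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Dihedral score of a (phi, psi) point against a cluster model
#'
#' The displacement `D` to each component mean is computed wrap-aware,
#' divided per-dimension by the model's stored median normalizer, and
#' entered into the quadratic form `D' C D` with `C = Lambda * r_k` (the
#' component precision scaled by the point's posterior responsibility),
#' summed over components; the score is `1 - erf(sum)`. A point at a
#' single-component model's mean scores exactly 1; the score decreases
#' monotonically with wrap-aware distance from the mean and tends to 0 far
#' away. Undefined points and `"no-data"` models score a neutral 0.5.
#'
#' @param point Numeric (phi, psi) in degrees.
#' @param model An `efl_dihedral_model`.
#' @param reference Optional (phi, psi) reference point; when given, the
#'   displacement is taken between `point` and `reference` and component
#'   mixture weights replace posterior responsibilities.
#' @return Score in `[0, 1]`.
#' @export
score_dihedral <- function(point, model, reference = NULL) {
  if (!identical(model$flag, "ok")) return(0.5)
  if (anyNA(point)) return(0.5)
  K <- model$K
  if (!is.null(reference)) {
    if (anyNA(reference)) return(0.5)
    dd <- c(angle_diff(point[1], reference[1]),
            angle_diff(point[2], reference[2]))
    delta <- matrix(dd, K, 2, byrow = TRUE)
    r <- model$weights
  } else {
    delta <- cbind(angle_diff(point[1], model$means[, 1]),
                   angle_diff(point[2], model$means[, 2]))
    r <- .responsibilities(model, delta)
  }
  dn <- sweep(delta, 2, model$median, "/")
  q <- sum(r * rowSums(dn^2 / model$sigma2))
  1 - .erf(q)
}

#' Count-feature score
#'
#' The mismatch between an observed and a reference count is
#' `|x - y| / max(x, y)` (0 when both are zero); the returned score is the
#' similarity `1 - mismatch`, so identical counts score 1. Used identically
#' for VdW contacts and H-bond donor/acceptor counts.
#'
#' @param x,y Non-negative counts.
#' @return Score in `[0, 1]`.
#' @export
score_counts <- function(x, y) {
  if (is.na(x) || is.na(y)) return(0.5)
  if (x < 0 || y < 0) stop("counts must be non-negative")
  if (x == 0 && y == 0) return(1)
  1 - abs(x - y) / max(x, y)
}

#' Score a loop against a descriptor
#'
#' Fills the N x 5 score matrix `S_ij` for the features sequence (`a`),
#' dihedrals (`d`), VdW contacts (`v`), H-bond acceptors (`hA`) and donors
#' (`hD`), and accumulates the objective
#' `F = sum_i sum_j W_i^P W_ij^F S_ij`. Positions flagged undefined score
#' a neutral 0.5 on every feature.
#'
#' When a `reference` loop is supplied (the grafting case, where the query
#' scaffold's native window is the reference), positions at which the
#' reference is defined are scored pairwise against it -- BLOSUM62
#' similarity of the two residues, displacement between the two dihedral
#' points under the descriptor's normalizer and precisions, and the count
#' ratio between the two structures; positions with an undefined reference
#' fall back to the descriptor's distributions.
#'
#' @param loop An `efl_loop` of the descriptor's length.
#' @param d An `efl_descriptor`.
#' @param reference Optional `efl_loop` reference (same length).
#' @param seq_mode Passed to [score_sequence()].
#' @return Object of class `efl_score`: list with the score matrix `S`,
#'   weight matrix `W`, position weights `Wp`, per-position contributions,
#'   and the total `F`.
#' @export
score_loop <- function(loop, d, reference = NULL,
                       seq_mode = c("profile", "consensus")) {
  stopifnot(inherits(loop, "efl_loop"), inherits(d, "efl_descriptor"))
  seq_mode <- match.arg(seq_mode)
  N <- d$length
  if (loop$length != N) {
    stop(sprintf("loop length %d does not match descriptor length %d",
                 loop$length, N))
  }
  if (!is.null(reference) && reference$length != N) {
    stop("reference loop length does not match descriptor length")
  }
  aa <- strsplit(loop$sequence, "")[[1]]
  ref_aa <- if (!is.null(reference)) {
    strsplit(reference$sequence, "")[[1]]
  }
  S <- matrix(0.5, N, 5, dimnames = list(NULL, FEATURES))
  ft <- loop$features
  for (i in seq_len(N)) {
    p <- d$positions[[i]]
    ref_ok <- !is.null(reference) && reference$features$defined[i]
    if (!ft$defined[i]) {
      S[i, ] <- 0.5
      next
    }
    # sequence
    if (ref_ok) {
      sp <- .score_sequence_pair(aa[i], ref_aa[i])
      S[i, "a"] <- if (is.na(sp)) score_sequence(aa[i], p, seq_mode) else sp
    } else {
      S[i, "a"] <- score_sequence(aa[i], p, seq_mode)
    }
    # dihedrals
    pt <- c(ft$phi[i], ft$psi[i])
    if (ref_ok) {
      rf <- c(reference$features$phi[i], reference$features$psi[i])
      S[i, "d"] <- if (anyNA(rf)) {
        score_dihedral(pt, p$dihedral_model)
      } else {
        score_dihedral(pt, p$dihedral_model, reference = rf)
      }
    } else {
      S[i, "d"] <- score_dihedral(pt, p$dihedral_model)
    }
    # counts (pooled intra + external totals)
    x <- c(v = ft$vdw_intra[i] + ft$vdw_external[i],
           hA = ft$ha_intra[i] + ft$ha_external[i],
           hD = ft$hd_intra[i] + ft$hd_external[i])
    if (ref_ok) {
      rft <- reference$features
      y <- c(v = rft$vdw_intra[i] + rft$vdw_external[i],
             hA = rft$ha_intra[i] + rft$ha_external[i],
             hD = rft$hd_intra[i] + rft$hd_external[i])
    } else {
      y <- c(v = p$counts$vdw$ref, hA = p$counts$ha$ref,
             hD = p$counts$hd$ref)
    }
    for (f in c("v", "hA", "hD")) S[i, f] <- score_counts(x[[f]], y[[f]])
  }
  W <- .feature_weights(d)
  Wp <- .position_weights(d)
  contrib <- S * W * Wp
  structure(list(S = S, W = W, Wp = Wp, contrib = contrib,
                 position_scores = rowSums(contrib),
                 total = sum(contrib),
                 loop_source = loop$source),
            class = "efl_score")
}

#' @export
print.efl_score <- function(x, ...) {
  cat(sprintf("<efl_score> F = %.6f over %d positions\n",
              x$total, nrow(x$S)))
  cat("  mean feature scores:",
      paste(sprintf("%s=%.3f", FEATURES, colMeans(x$S)), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write a per-position, per-feature score report
#'
#' One TSV row per (position, feature) with the score, the weights and the
#' contribution to F, followed by a `total` row.
#'
#' @param br An `efl_score` from [score_loop()].
#' @param path Output TSV path.
#' @export
write_score_tsv <- function(br, path) {
  N <- nrow(br$S)
  df <- data.frame(
    position = rep(seq_len(N), each = 5),
    feature = rep(FEATURES, N),
    S = as.vector(t(br$S)),
    W_F = as.vector(t(br$W)),
    W_P = rep(br$Wp, each = 5),
    contribution = as.vector(t(br$contrib)))
  df <- rbind(df, data.frame(position = NA, feature = "total", S = NA,
                             W_F = NA, W_P = NA, contribution = br$total))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score every window of a structure against a descriptor
#'
#' Slides the descriptor along each chain (or one chain) of the structure
#' and records the objective F of every window.
#'
#' @param d An `efl_descriptor`.
#' @param s An `efl_structure`.
#' @param chain Optional chain restriction.
#' @param vdw_radius,hbond_radius Contact radii for feature extraction.
#' @return Data frame with `chain`, `start` and `F`, one row per window.
#' @export
scan_windows <- function(d, s, chain = NULL, vdw_radius = 5.0,
                         hbond_radius = 3.5) {
  stopifnot(inherits(d, "efl_descriptor"), inherits(s, "efl_structure"))
  chains <- if (is.null(chain)) .chain_ids(s) else chain
  cache <- structure_feature_cache(s, vdw_radius, hbond_radius)
  out <- list()
  for (ch in chains) {
    nres <- nrow(chain_residues(s, ch))
    if (nres < d$length) next
    starts <- seq_len(nres - d$length + 1L)
    Fv <- vapply(starts, function(st) {
      loop <- extract_loop_features(s, ch, st, d$length, cache = cache)
      score_loop(loop, d)$total
    }, 0)
    out[[ch]] <- data.frame(chain = ch, start = starts, F = Fv,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chain = character(), start = integer(),
                      F = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Predict method for descriptors
#'
#' With `start` given, scores that single window and returns the full
#' [score_loop()] breakdown; otherwise scans all windows of the structure
#' and returns the per-window objective values.
#'
#' @param object An `efl_descriptor`.
#' @param structure An `efl_structure`.
#' @param chain Chain identifier (required with `start`).
#' @param start Optional 1-based window start.
#' @param ... Unused.
#' @export
predict.efl_descriptor <- function(object, structure, chain = NULL,
                                   start = NULL, ...) {
  if (is.null(start)) {
    return(scan_windows(object, structure, chain))
  }
  stopifnot(!is.null(chain))
  loop <- extract_loop_features(structure, chain, start, object$length)
  score_loop(loop, object)
}
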
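# The descriptor: a per-position statistical bundle over a family of loop
# instances -- amino-acid frequencies, a wrap-aware Gaussian-mixture model
# of (phi, psi), half-normal count-spread fits for VdW and H-bond features,
# per-feature weights W^F and normalized position weights W^P. Assembled by
# `assemble_descriptor()`, which is the package's model-fitting entry point.

VAR_FLOOR <- 1      # deg^2, precision cap for perfectly conserved positions
MEDIAN_FLOOR <- 1   # deg, displacement normalizer floor

#' Cluster backbone dihedrals with a Gaussian-mixture EM
#'
#' Fits a diagonal-covariance Gaussian mixture to (phi, psi) points, with
#' the number of components chosen by BIC over `1..max_K`. Angles are
#' re-centred on their circular mean per dimension before fitting, so
#' clusters straddling the +/-180 seam are handled correctly. The model
#' stores component means, per-dimension variances (floored at 1 deg^2,
#' i.e. precision `Lambda = 1/sigma^2`), mixture weights, the training
#' posterior matrix, and the per-dimension median absolute displacement
#' used to normalize displacements at scoring time.
#'
#' @param points Numeric n x 2 matrix of (phi, psi) in degrees; rows with
#'   `NA` are dropped.
#' @param max_K Largest number of mixture components considered.
#' @param seed RNG seed (the fit itself is deterministic; the seed guards
#'   any stochastic initialisation).
#' @return An object of class `efl_dihedral_model`; flagged `"no-data"`
#'   when no defined point is available (scores then fall back to neutral).
#' @export
cluster_dihedrals <- function(points, max_K = 3L, seed = 1L) {
  points <- matrix(as.numeric(points), ncol = 2)
  points <- points[complete.cases(points), , drop = FALSE]
  n <- nrow(points)
  if (n == 0L) {
    return(structure(list(flag = "no-data"), class = "efl_dihedral_model"))
  }
  center <- c(.circ_mean(points[, 1]), .circ_mean(points[, 2]))
  z <- cbind(angle_diff(points[, 1], center[1]),
             angle_diff(points[, 2], center[2]))
  spread <- apply(z, 2, function(v) diff(range(v)))
  single <- function() {
    mu <- colMeans(z)
    s2 <- pmax(apply(z, 2, function(v) mean((v - mean(v))^2)), VAR_FLOOR)
    list(K = 1L, means = matrix(mu, 1), sigma2 = matrix(s2, 1),
         weights = 1, posterior = matrix(1, n, 1))
  }
  fit <- NULL
  if (n >= 5L && max(spread) > 1e-6) {
    set.seed(seed)
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(z, G = seq_len(max_K),
                                      modelNames = "VVI", verbose = FALSE)),
      error = function(e) NULL)
  }
  mod <- if (is.null(fit)) {
    single()
  } else {
    K <- fit$G
    sig <- fit$parameters$variance$sigma
    s2 <- t(vapply(seq_len(K), function(k) pmax(diag(sig[, , k]), VAR_FLOOR),
                   numeric(2)))
    list(K = K, means = t(fit$parameters$mean),
         sigma2 = s2, weights = as.numeric(fit$parameters$pro),
         posterior = matrix(fit$z, n, K))
  }
  assign_k <- max.col(mod$posterior, ties.method = "first")
  disp <- cbind(angle_diff(z[, 1], mod$means[assign_k, 1]),
                angle_diff(z[, 2], mod$means[assign_k, 2]))
  med <- pmax(apply(abs(disp), 2, median), MEDIAN_FLOOR)
  disp_norm <- sqrt((disp[, 1] / med[1])^2 + (disp[, 2] / med[2])^2)
  means <- cbind(wrap_angle(mod$means[, 1] + center[1]),
                 wrap_angle(mod$means[, 2] + center[2]))
  structure(list(flag = "ok", K = mod$K, means = means,
                 sigma2 = mod$sigma2, weights = mod$weights,
                 posterior = mod$posterior, median = med,
                 disp_sigma = fit_halfnormal_sigma(disp_norm),
                 n = n),
            class = "efl_dihedral_model")
}

#' Half-normal scale from non-negative data
#'
#' Maximum-likelihood scale of a half-normal distribution:
#' `sigma = sqrt(mean(x^2))`.
#'
#' @param values Non-negative numeric vector (at least one value).
#' @return The fitted scale `sigma >= 0`.
#' @export
fit_halfnormal_sigma <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no values to fit")
  if (any(values < 0)) stop("half-normal fit requires non-negative values")
  sqrt(mean(values^2))
}

#' Sequence-conservation weight of a profile column
#'
#' The relative frequency of the two most frequent residues:
#' the sum of the two largest of the 20 frequencies divided by their total.
#'
#' @param aa_freqs Numeric vector of 20 per-residue frequencies.
#' @return Weight in (0, 1].
#' @export
compute_seq_weight <- function(aa_freqs) {
  stopifnot(length(aa_freqs) == 20)
  s <- sort(as.numeric(aa_freqs), decreasing = TRUE)
  (s[1] + s[2]) / sum(aa_freqs)
}

# Spread-based feature weight: the half-normal scale itself, or its bounded
# conservation-direction transform 1/(1 + sigma) in (0, 1] -- the same scale
# as the sequence weight, so no single feature can dominate by units alone.
.spread_weight <- function(sigma, invert) {
  if (invert) 1 / (1 + sigma) else sigma
}

#' Assemble a descriptor from loop instances
#'
#' The model-fitting step: pools per-position amino-acid frequencies,
#' clusters dihedrals, fits half-normal spreads to the pooled
#' (intra + external) VdW and H-bond counts, computes the per-feature
#' weights `W^F` (sequence via [compute_seq_weight()]; dihedral/count
#' features via the half-normal spread, each multiplied by its feature
#' scale factor) and the normalized position weights
#' `W_i^P = sum_j W_ij^F / sum_i sum_j W_ij^F`.
#'
#' @param instances List of `efl_loop` objects of equal length (at least 2).
#' @param config An [efl_config()]; supplies pseudocount, scale factors,
#'   `invert_spread_weights`, `max_K` and the seed.
#' @param name Descriptor name/signature label.
#' @return An object of class `efl_descriptor`.
#' @seealso [score_loop()], [predict.efl_descriptor()], [save_descriptor()]
#' @export
assemble_descriptor <- function(instances, config = efl_config(),
                                name = "descriptor") {
  if (length(instances) < 2L) stop("need at least 2 loop instances")
  lens <- vapply(instances, function(x) as.integer(x$length), 0L)
  if (length(unique(lens)) != 1L) {
    stop("loop instances have mismatched lengths")
  }
  N <- lens[1]
  sf <- config$scale_factors
  inv <- config$invert_spread_weights
  seqs <- do.call(rbind, lapply(instances, function(x) {
    strsplit(x$sequence, "")[[1]]
  }))
  positions <- vector("list", N)
  for (i in seq_len(N)) {
    letters_i <- seqs[, i]
    cnt <- table(factor(letters_i, levels = AA20))
    n_std <- sum(cnt)
    freqs <- (as.numeric(cnt) + config$pseudocount / 20) /
      (n_std + config$pseudocount)
    names(freqs) <- AA20
    freqs <- freqs / sum(freqs)

    defined <- vapply(instances, function(x) x$features$defined[i], TRUE)
    pts <- do.call(rbind, lapply(instances, function(x) {
      c(x$features$phi[i], x$features$psi[i])
    }))
    dmod <- cluster_dihedrals(pts, max_K = config$max_K, seed = config$seed)

    counts <- list()
    for (f in c("vdw", "hd", "ha")) {
      intra <- vapply(instances, function(x) {
        x$features[[paste0(f, "_intra")]][i]
      }, 0)
      ext <- vapply(instances, function(x) {
        x$features[[paste0(f, "_external")]][i]
      }, 0)
      tot <- (intra + ext)[defined]
      if (length(tot) == 0L) tot <- 0
      counts[[f]] <- list(
        observed = as.numeric(tot),
        mean = mean(tot), ref = round(mean(tot)),
        sigma = fit_halfnormal_sigma(abs(tot - mean(tot))),
        intra_mean = if (any(defined)) mean(intra[defined]) else 0,
        external_mean = if (any(defined)) mean(ext[defined]) else 0)
    }

    w <- c(
      a = compute_seq_weight(freqs) * sf[["a"]],
      d = .spread_weight(if (identical(dmod$flag, "ok")) dmod$disp_sigma
                         else 0, inv) * sf[["d"]],
      v = .spread_weight(counts$vdw$sigma, inv) * sf[["v"]],
      hA = .spread_weight(counts$ha$sigma, inv) * sf[["hA"]],
      hD = .spread_weight(counts$hd$sigma, inv) * sf[["hD"]])

    positions[[i]] <- list(aa_freqs = freqs, dihedral_model = dmod,
                           counts = counts, weights = w,
                           n_defined = sum(defined))
  }
  wsum <- vapply(positions, function(p) sum(p$weights), 0)
  total <- sum(wsum)
  if (total <= 0) total <- 1
  for (i in seq_len(N)) positions[[i]]$position_weight <- wsum[i] / total

  structure(list(name = name, length = N, positions = positions,
                 scale_factors = sf,
                 invert_spread_weights = inv,
                 pseudocount = config$pseudocount,
                 instances = instances,
                 provenance = lapply(instances, function(x) x$source)),
            class = "efl_descriptor")
}

# Convenience accessors used across scoring and grafting.
.position_weights <- function(d) {
  vapply(d$positions, function(p) p$position_weight, 0)
}

.feature_weights <- function(d) {
  t(vapply(d$positions, function(p) p$weights[FEATURES], numeric(5)))
}

#' @export
print.efl_descriptor <- function(x, ...) {
  cons <- paste(vapply(x$positions, function(p) {
    AA20[which.max(p$aa_freqs)]
  }, ""), collapse = "")
  cat(sprintf(paste0("<efl_descriptor '%s'> %d positions, ",
                     "%d contributing loops\n  consensus %s\n"),
              x$name, x$length, length(x$instances), cons))
  invisible(x)
}

#' @method summary efl_descriptor
#' @export
summary.efl_descriptor <- function(object, ...) {
  W <- .feature_weights(object)
  df <- data.frame(
    position = seq_len(object$length),
    consensus = vapply(object$positions, function(p) {
      AA20[which.max(p$aa_freqs)]
    }, ""),
    top2_freq = vapply(object$positions, function(p) {
      compute_seq_weight(p$aa_freqs)
    }, 0),
    K = vapply(object$positions, function(p) {
      if (identical(p$dihedral_model$flag, "ok")) p$dihedral_model$K
      else NA_integer_
    }, 0L),
    vdw_mean = vapply(object$positions, function(p) p$counts$vdw$mean, 0),
    W_P = .position_weights(object))
  colnames(W) <- paste0("W_", FEATURES)
  out <- cbind(df, W)
  class(out) <- c("summary.efl_descriptor", class(out))
  out
}

#' Extract descriptor weights
#'
#' Returns the per-position feature weights `W_ij^F` together with the
#' normalized position weights `W_i^P` (last column).
#'
#' @param object An `efl_descriptor`.
#' @param ... Unused.
#' @method coef efl_descriptor
#' @export
coef.efl_descriptor <- function(object, ...) {
  W <- .feature_weights(object)
  colnames(W) <- FEATURES
  cbind(W, W_P = .position_weights(object))
}

#' Plot a descriptor's position weights and count profile
#'
#' Two base-graphics panels: the normalized position weights `W_i^P` and
#' the mean intra/external VdW contact counts per position.
#'
#' @param x An `efl_descriptor`.
#' @param ... Passed to [graphics::barplot()].
#' @method plot efl_descriptor
#' @export
plot.efl_descriptor <- function(x, ...) {
  old <- par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
  on.exit(par(old))
  barplot(.position_weights(x), names.arg = seq_len(x$length),
          ylab = "W_i^P", main = x$name, ...)
  vi <- vapply(x$positions, function(p) p$counts$vdw$intra_mean, 0)
  ve <- vapply(x$positions, function(p) p$counts$vdw$external_mean, 0)
  barplot(rbind(intra = vi, external = ve), beside = TRUE,
          names.arg = seq_len(x$length), ylab = "mean VdW contacts",
          legend.text = TRUE, args.legend = list(x = "topright", bty = "n"))
  invisible(x)
}

#' Export a descriptor's sequence profile as logo TSV
#'
#' One row per position with the 20 per-residue frequencies, suitable for
#' sequence-logo plotting.
#'
#' @param d An `efl_descriptor`.
#' @param path Output TSV path.
#' @export
write_logo_tsv <- function(d, path) {
  m <- t(vapply(d$positions, function(p) p$aa_freqs, numeric(20)))
  df <- cbind(data.frame(position = seq_len(d$length)), as.data.frame(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
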
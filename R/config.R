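#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Radii are in
#' Angstrom, the scan threshold in bits, angles in degrees.
#'
#' @param loop_length Descriptor/loop length in residues.
#' @param seed_length Seed-segment length for grafting (half a typical
#'   functional signature).
#' @param vdw_radius VdW contact radius.
#' @param hbond_radius H-bond donor-acceptor distance cutoff.
#' @param pseudocount Additive pseudocount mass for sequence profiles.
#' @param scan_threshold Bit-score threshold for profile matches.
#' @param max_iter Maximum profile-expansion iterations.
#' @param tol Profile convergence tolerance (max-norm frequency change).
#' @param max_K Largest dihedral mixture size considered by BIC.
#' @param scale_factors Named numeric of per-feature scalar tuning factors
#'   for the weights, in order `a`, `d`, `v`, `hA`, `hD`.
#' @param invert_spread_weights If `TRUE`, spread-based feature weights use
#'   `1/(sigma + eps)` so conserved positions weigh more; the default keeps
#'   the spread itself as the weight.
#' @param switch_margin Hysteresis margin for switching source structures
#'   during graft-plan extension.
#' @param seed RNG seed.
#' @return A list of class `efl_config`.
#' @export
efl_config <- function(loop_length = 30L,
                       seed_length = 7L,
                       vdw_radius = 5.0,
                       hbond_radius = 3.5,
                       pseudocount = 1,
                       scan_threshold = 10,
                       max_iter = 10L,
                       tol = 1e-6,
                       max_K = 3L,
                       scale_factors = c(a = 1, d = 1, v = 1, hA = 1, hD = 1),
                       invert_spread_weights = FALSE,
                       switch_margin = 0,
                       seed = 1L) {
  stopifnot(vdw_radius > 0, hbond_radius > 0, loop_length >= 1L,
            seed_length >= 1L, seed_length <= loop_length,
            pseudocount >= 0, max_iter >= 1L, tol > 0, max_K >= 1L,
            switch_margin >= 0)
  sf <- scale_factors[FEATURES]
  if (anyNA(sf)) stop("scale_factors must be named a, d, v, hA, hD")
  stopifnot(all(sf > 0))
  structure(list(loop_length = as.integer(loop_length),
                 seed_length = as.integer(seed_length),
                 vdw_radius = vdw_radius, hbond_radius = hbond_radius,
                 pseudocount = pseudocount,
                 scan_threshold = scan_threshold,
                 max_iter = as.integer(max_iter), tol = tol,
                 max_K = as.integer(max_K),
                 scale_factors = sf,
                 invert_spread_weights = isTRUE(invert_spread_weights),
                 switch_margin = switch_margin,
                 seed = as.integer(seed)),
            class = "efl_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numbers or logicals where possible; `scale_factors` takes five
#' comma-separated numbers in feature order `a,d,v,hA,hD`.
#'
#' @param path Configuration file.
#' @param base Config whose values are overridden by the file.
#' @return An [efl_config()].
#' @export
read_config <- function(path, base = efl_config()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  args <- as.list(base)
  class(args) <- NULL
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (!key %in% names(args)) stop("unknown config key: ", key)
    if (key == "scale_factors") {
      v <- as.numeric(strsplit(val, ",")[[1]])
      if (length(v) != 5L) stop("scale_factors needs 5 values (a,d,v,hA,hD)")
      args[[key]] <- setNames(v, FEATURES)
    } else if (toupper(val) %in% c("TRUE", "FALSE")) {
      args[[key]] <- as.logical(val)
    } else {
      num <- suppressWarnings(as.numeric(val))
      args[[key]] <- if (is.na(num)) val else num
    }
  }
  do.call(efl_config, args)
}
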
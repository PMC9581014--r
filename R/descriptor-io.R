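# Versioned JSON serialization of descriptors. The schema is lossless:
# reloading a descriptor reproduces every score to machine precision.

DESCRIPTOR_SCHEMA <- "efloop-descriptor/1"

.dmod_to_list <- function(m) {
  if (!identical(m$flag, "ok")) return(list(flag = "no-data"))
  list(flag = "ok", K = m$K, means = m$means, sigma2 = m$sigma2,
       weights = m$weights, posterior = m$posterior, median = m$median,
       disp_sigma = m$disp_sigma, n = m$n)
}

.dmod_from_list <- function(l) {
  if (!identical(l$flag, "ok")) {
    return(structure(list(flag = "no-data"), class = "efl_dihedral_model"))
  }
  rowbind <- function(x) do.call(rbind, lapply(x, function(r) {
    as.numeric(unlist(r))
  }))
  structure(list(flag = "ok", K = as.integer(l$K),
                 means = rowbind(l$means),
                 sigma2 = rowbind(l$sigma2),
                 weights = as.numeric(l$weights),
                 posterior = rowbind(l$posterior),
                 median = as.numeric(l$median),
                 disp_sigma = as.numeric(l$disp_sigma),
                 n = as.integer(l$n)),
            class = "efl_dihedral_model")
}

.loop_to_list <- function(x) {
  list(source = x$source, length = x$length, sequence = x$sequence,
       features = x$features)
}

.loop_from_list <- function(l) {
  f <- as.data.frame(l$features)
  f$defined <- as.logical(f$defined)
  structure(list(source = list(id = l$source$id, chain = l$source$chain,
                               start = as.integer(l$source$start)),
                 length = as.integer(l$length), sequence = l$sequence,
                 features = f),
            class = "efl_loop")
}

#' Serialize a descriptor to JSON
#'
#' @param d An `efl_descriptor`.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON text (invisibly when `path` is given). Numbers are
#'   written at full precision so the round-trip is lossless.
#' @export
save_descriptor <- function(d, path = NULL) {
  stopifnot(inherits(d, "efl_descriptor"))
  obj <- list(
    schema = DESCRIPTOR_SCHEMA,
    name = d$name, length = d$length,
    scale_factors = as.list(d$scale_factors),
    invert_spread_weights = d$invert_spread_weights,
    pseudocount = d$pseudocount,
    positions = lapply(d$positions, function(p) {
      list(aa_freqs = as.list(p$aa_freqs),
           dihedral_model = .dmod_to_list(p$dihedral_model),
           counts = p$counts,
           weights = as.list(p$weights),
           n_defined = p$n_defined,
           position_weight = p$position_weight)
    }),
    instances = lapply(d$instances, .loop_to_list))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Load a descriptor from JSON
#'
#' @param json JSON text or a file path produced by [save_descriptor()].
#' @return An `efl_descriptor`.
#' @export
load_descriptor <- function(json) {
  txt <- if (length(json) == 1L && file.exists(json)) {
    paste(readLines(json, warn = FALSE), collapse = "\n")
  } else {
    paste(json, collapse = "\n")
  }
  obj <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) {
                    stop("descriptor JSON parse error: ",
                         conditionMessage(e))
                  })
  if (!identical(obj$schema, DESCRIPTOR_SCHEMA)) {
    stop(sprintf("descriptor schema mismatch: expected '%s', got '%s'",
                 DESCRIPTOR_SCHEMA,
                 if (is.null(obj$schema)) "<none>" else obj$schema))
  }
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  positions <- lapply(obj$positions, function(p) {
    cts <- lapply(p$counts, function(ct) {
      list(observed = as.numeric(unlist(ct$observed)),
           mean = num(ct$mean), ref = num(ct$ref), sigma = num(ct$sigma),
           intra_mean = num(ct$intra_mean),
           external_mean = num(ct$external_mean))
    })
    list(aa_freqs = setNames(vapply(p$aa_freqs, as.numeric, 0)[AA20], AA20),
         dihedral_model = .dmod_from_list(p$dihedral_model),
         counts = cts,
         weights = setNames(vapply(p$weights, as.numeric, 0)[FEATURES],
                            FEATURES),
         n_defined = as.integer(p$n_defined),
         position_weight = num(p$position_weight))
  })
  instances <- lapply(obj$instances, function(l) {
    f <- do.call(rbind, lapply(l$features, function(row) {
      data.frame(phi = num(row$phi), psi = num(row$psi),
                 vdw_intra = as.integer(row$vdw_intra),
                 vdw_external = as.integer(row$vdw_external),
                 hd_intra = as.integer(row$hd_intra),
                 hd_external = as.integer(row$hd_external),
                 ha_intra = as.integer(row$ha_intra),
                 ha_external = as.integer(row$ha_external),
                 defined = as.logical(row$defined))
    }))
    structure(list(source = list(id = l$source$id, chain = l$source$chain,
                                 start = as.integer(l$source$start)),
                   length = as.integer(l$length), sequence = l$sequence,
                   features = f),
              class = "efl_loop")
  })
  structure(list(name = obj$name, length = as.integer(obj$length),
                 positions = positions,
                 scale_factors = setNames(
                   vapply(obj$scale_factors, as.numeric, 0)[FEATURES],
                   FEATURES),
                 invert_spread_weights = isTRUE(obj$invert_spread_weights),
                 pseudocount = as.numeric(obj$pseudocount),
                 instances = instances,
                 provenance = lapply(instances, function(x) x$source)),
            class = "efl_descriptor")
}
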
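# Dihedral mixture clustering, half-normal fits, weights, descriptor
# assembly and JSON round-trips.

test_that("identical dihedral points give one floored-variance component", {
  m <- cluster_dihedrals(matrix(rep(c(-57, -47), each = 100), ncol = 2))
  expect_equal(m$K, 1L)
  expect_equal(unname(m$means[1, ]), c(-57, -47), tolerance = 1e-8)
  expect_equal(unname(m$sigma2[1, ]), c(1, 1))  # variance floor
})

test_that("two well-separated blobs are recovered with K = 2", {
  set.seed(21)
  a <- cbind(rnorm(100, -60, 5), rnorm(100, -45, 5))
  b <- cbind(rnorm(100, -120, 5), rnorm(100, 130, 5))
  m <- cluster_dihedrals(rbind(a, b), max_K = 3, seed = 1)
  expect_equal(m$K, 2L)
  ord <- order(m$means[, 1])
  expect_lt(max(abs(m$means[ord[1], ] - c(-120, 130))), 5)
  expect_lt(max(abs(m$means[ord[2], ] - c(-60, -45))), 5)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("clusters straddling the 180 seam centre near 180, not 0", {
  set.seed(22)
  pts <- cbind(wrap_angle(rnorm(80, 180, 4)), wrap_angle(rnorm(80, 180, 4)))
  m <- cluster_dihedrals(pts)
  expect_equal(m$K, 1L)
  expect_gt(abs(m$means[1, 1]), 170)  # near +/-180
  expect_gt(abs(m$means[1, 2]), 170)
  # oracle: circular mean of the raw points
  cm <- atan2(mean(sin(pts[, 1] * pi / 180)),
              mean(cos(pts[, 1] * pi / 180))) * 180 / pi
  expect_lt(abs(efloop:::angle_diff(m$means[1, 1], cm)), 3)
})

test_that("BIC recovers the true component count on separated data", {
  set.seed(23)
  for (K in 1:2) {
    centers <- list(cbind(-60, -45), rbind(c(-60, -45), c(60, 60)))[[K]]
    pts <- do.call(rbind, lapply(seq_len(K), function(k) {
      cbind(rnorm(120, centers[k, 1], 5), rnorm(120, centers[k, 2], 5))
    }))
    m <- cluster_dihedrals(pts, max_K = 3, seed = 2)
    expect_equal(m$K, K)
  }
})

test_that("half-normal MLE matches its closed form", {
  expect_equal(fit_halfnormal_sigma(rep(0, 5)), 0)
  expect_equal(fit_halfnormal_sigma(3.2), 3.2)
  expect_error(fit_halfnormal_sigma(c(1, -1)), "non-negative")
  set.seed(24)
  x <- abs(rnorm(1e4, 0, 2))
  expect_equal(fit_halfnormal_sigma(x), 2, tolerance = 0.05)
})

test_that("sequence weight is the top-two frequency mass", {
  f <- setNames(rep(0.2 / 18, 20), efloop:::AA20)
  f["A"] <- 0.5
  f["G"] <- 0.3
  expect_equal(compute_seq_weight(f), 0.8)
  expect_equal(compute_seq_weight(rep(1 / 20, 20)), 0.1)
  f2 <- setNames(rep(0, 20), efloop:::AA20)
  f2["W"] <- 1
  expect_equal(compute_seq_weight(f2), 1)
})

test_that("assembly of identical instances gives uniform position weights", {
  fam <- helix_family(n = 1)
  loop <- extract_loop_features(fam$structures[[1]], "A", fam$offsets[1], 30)
  d <- assemble_descriptor(list(loop, loop, loop),
                           efl_config(pseudocount = 0))
  wp <- vapply(d$positions, function(p) p$position_weight, 0)
  expect_equal(wp, rep(1 / 30, 30), tolerance = 1e-9)
  seq_w <- vapply(d$positions, function(p) compute_seq_weight(p$aa_freqs), 0)
  expect_equal(seq_w, rep(1, 30))
})

test_that("position weights always normalize to one", {
  fam <- helix_family(n = 6)
  for (cfg in list(efl_config(), efl_config(invert_spread_weights = TRUE))) {
    d <- family_descriptor(fam, config = cfg)
    expect_equal(sum(vapply(d$positions, function(p) p$position_weight, 0)),
                 1, tolerance = 1e-9)
  }
  expect_error(assemble_descriptor(list()), "at least 2")
})

test_that("signature positions carry higher sequence weight than random ones", {
  fam <- helix_family(n = 8)
  d <- family_descriptor(fam)
  sig_pos <- which(fam$spec$signature != "x")
  rnd_pos <- which(fam$spec$signature == "x")
  w <- vapply(d$positions, function(p) compute_seq_weight(p$aa_freqs), 0)
  expect_gt(min(w[sig_pos]), max(w[rnd_pos]))
})

test_that("assembly is invariant under instance permutation", {
  fam <- helix_family(n = 5)
  loops <- lapply(seq_along(fam$structures), function(k) {
    extract_loop_features(fam$structures[[k]], "A", fam$offsets[k], 30)
  })
  d1 <- assemble_descriptor(loops, efl_config())
  d2 <- assemble_descriptor(rev(loops), efl_config())
  expect_equal(coef(d1), coef(d2), tolerance = 1e-9)
  f1 <- score_loop(loops[[1]], d1)$total
  f2 <- score_loop(loops[[1]], d2)$total
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("descriptor JSON round-trip preserves every score to 1e-12", {
  fam <- helix_family(n = 5)
  d <- family_descriptor(fam)
  txt <- save_descriptor(d)
  d2 <- load_descriptor(txt)
  for (k in 1:3) {
    loop <- extract_loop_features(fam$structures[[k]], "A",
                                  fam$offsets[k], 30)
    b1 <- score_loop(loop, d)
    b2 <- score_loop(loop, d2)
    expect_equal(b1$total, b2$total, tolerance = 1e-12)
    expect_equal(b1$S, b2$S, tolerance = 1e-12)
  }
})

test_that("JSON schema violations and truncation error out", {
  fam <- helix_family(n = 3)
  d <- family_descriptor(fam)
  txt <- save_descriptor(d)
  expect_error(load_descriptor(substr(txt, 1, nchar(txt) %/% 2)),
               "parse error")
  wrong <- sub("efloop-descriptor/1", "other-schema/9", txt)
  expect_error(load_descriptor(wrong), "schema mismatch")
})

test_that("no-data positions survive the round-trip with flags intact", {
  fam <- helix_family(n = 3)
  loops <- lapply(seq_along(fam$structures), function(k) {
    extract_loop_features(fam$structures[[k]], "A", fam$offsets[k], 30)
  })
  # blind position 4 in every instance
  for (k in seq_along(loops)) {
    loops[[k]]$features$defined[4] <- FALSE
    loops[[k]]$features$phi[4] <- NA
    loops[[k]]$features$psi[4] <- NA
  }
  d <- assemble_descriptor(loops, efl_config())
  expect_equal(d$positions[[4]]$dihedral_model$flag, "no-data")
  d2 <- load_descriptor(save_descriptor(d))
  expect_equal(d2$positions[[4]]$dihedral_model$flag, "no-data")
  expect_equal(score_dihedral(c(-57, -47),
                              d2$positions[[4]]$dihedral_model), 0.5)
})
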
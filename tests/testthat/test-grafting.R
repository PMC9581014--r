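# Grafting: score matrix semantics, seed search vs brute force, greedy
# extension/merging, and coordinate replacement.

make_psm <- function(mat, valid = rep(TRUE, ncol(mat))) {
  # wrap a raw matrix in the class the search operates on
  structure(list(scores = mat, valid = valid, target_loop = NULL,
                 target = list(chain = "A", start = 1),
                 sources = lapply(rownames(mat), function(id) {
                   parts <- strsplit(id, ":")[[1]]
                   list(id = parts[1], chain = parts[2],
                        start = as.integer(parts[3]))
                 })),
            class = "efl_position_scores")
}

rand_mat <- function(ns, N, seed) {
  set.seed(seed)
  matrix(runif(ns * N), ns, N,
         dimnames = list(sprintf("src%02d:A:1", seq_len(ns)), NULL))
}

test_that("self-match: a provenance structure's own source is best per position", {
  fam <- helix_family(n = 5)
  d <- family_descriptor(fam)
  psm <- score_position_matrix(fam$structures[[2]], "A", fam$offsets[2], d)
  own <- sprintf("%s:A:%d", fam$structures[[2]]$id, fam$offsets[2])
  for (i in seq_len(30)) {
    expect_gte(psm$scores[own, i] + 1e-12, max(psm$scores[, i]))
  }
})

test_that("score matrix entries equal score_loop position terms", {
  fam <- helix_family(n = 4)
  d <- family_descriptor(fam)
  target <- fam$structures[[3]]
  psm <- score_position_matrix(target, "A", fam$offsets[3], d)
  tl <- extract_loop_features(target, "A", fam$offsets[3], 30)
  for (k in c(1, 4)) {
    br <- score_loop(d$instances[[k]], d, reference = tl)
    expect_equal(unname(psm$scores[k, ]), unname(br$position_scores),
                 tolerance = 1e-12)
  }
})

test_that("seed search equals brute force on random matrices", {
  for (trial in 1:200) {
    ns <- sample(2:6, 1)
    N <- sample(10:30, 1)
    mat <- rand_mat(ns, N, seed = trial)
    valid <- rep(TRUE, N)
    if (trial %% 3 == 0) valid[sample(N, sample(0:3, 1))] <- FALSE
    psm <- make_psm(mat, valid)
    if (!any(vapply(seq_len(N - 6), function(st) {
      all(valid[st:(st + 6)])
    }, TRUE))) {
      expect_error(find_seed_segment(psm), "no valid seed")
      next
    }
    got <- find_seed_segment(psm)
    want <- oracle_seed(mat, valid)
    expect_equal(got$source, want$source)
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("seed search edge cases", {
  m <- matrix(c(rep(1, 7), rep(0, 5)), 1, 12,
              dimnames = list("s:A:1", NULL))
  got <- find_seed_segment(make_psm(m))
  expect_equal(got$start, 1L)
  expect_error(find_seed_segment(make_psm(m, valid = rep(FALSE, 12))),
               "no valid seed")
})

test_that("one dominant source yields a single-segment plan", {
  mat <- rand_mat(3, 30, seed = 5)
  mat["src01:A:1", ] <- 2  # dominates everywhere
  plan <- extend_and_merge(make_psm(mat))
  expect_equal(nrow(plan$segments), 1L)
  expect_equal(plan$segments$from, 1L)
  expect_equal(plan$segments$to, 30L)
  expect_equal(plan$segments$source, "src01:A:1")
})

test_that("a constructed A/B split produces a two-segment recombinant plan", {
  mat <- matrix(0.1, 2, 30, dimnames = list(c("a:A:1", "b:A:1"), NULL))
  mat["a:A:1", 1:14] <- 1
  mat["b:A:1", 15:30] <- 1
  plan <- extend_and_merge(make_psm(mat))
  expect_equal(nrow(plan$segments), 2L)
  expect_equal(plan$segments$to[1], 14L)
  expect_equal(plan$segments$from[2], 15L)
  expect_setequal(plan$segments$source, c("a:A:1", "b:A:1"))
})

test_that("plans always cover all positions without overlap", {
  for (trial in 1:50) {
    mat <- rand_mat(sample(2:5, 1), 30, seed = 100 + trial)
    plan <- extend_and_merge(make_psm(mat))
    covered <- unlist(mapply(seq, plan$segments$from, plan$segments$to,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), 1:30)
  }
})

test_that("adding a provenance source never lowers the plan score", {
  for (trial in 1:60) {
    mat <- rand_mat(4, 30, seed = 300 + trial)
    small <- extend_and_merge(make_psm(mat[1:3, , drop = FALSE]))
    full <- extend_and_merge(make_psm(mat))
    expect_gte(full$total + 1e-9, small$total)
  }
})

test_that("identity self-graft is a fixed point", {
  fam <- helix_family(n = 3)
  d <- family_descriptor(fam)
  s <- fam$structures[[1]]
  psm <- score_position_matrix(s, "A", fam$offsets[1], d)
  plan <- extend_and_merge(psm)
  expect_equal(plan$segments$source,
               sprintf("%s:A:%d", s$id, fam$offsets[1]))
  lib <- setNames(fam$structures,
                  vapply(fam$structures, function(x) x$id, ""))
  g <- graft_loop(s, plan, lib)
  orig <- s$atom[order(s$atom$res_rank, s$atom$elety), ]
  new <- g$structure$atom[order(g$structure$atom$res_rank,
                                g$structure$atom$elety), ]
  expect_equal(nrow(new), nrow(orig))
  expect_lt(max(abs(new$x - orig$x), abs(new$y - orig$y),
                abs(new$z - orig$z)), 1e-6)
})

test_that("recombinant grafts keep junction peptide geometry", {
  fam <- helix_family(n = 6)
  d <- family_descriptor(fam, idx = 1:5)
  target <- fam$structures[[6]]
  psm <- score_position_matrix(target, "A", fam$offsets[6], d)
  plan <- extend_and_merge(psm)
  lib <- setNames(fam$structures,
                  vapply(fam$structures, function(x) x$id, ""))
  g <- graft_loop(target, plan, lib)
  expect_true(all(g$junctions$c_n >= 1.1 & g$junctions$c_n <= 1.8))
  expect_true(all(is.finite(g$junctions$ca_ca)))
})

test_that("grafting fails cleanly on missing anchors or provenance", {
  fam <- helix_family(n = 3)
  d <- family_descriptor(fam)
  s <- fam$structures[[1]]
  psm <- score_position_matrix(s, "A", fam$offsets[1], d)
  plan <- extend_and_merge(psm)
  expect_error(graft_loop(s, plan, list()), "missing provenance")
  # window too close to the terminus: no 3-residue flank
  psm2 <- score_position_matrix(s, "A", 2, d)
  plan2 <- extend_and_merge(psm2)
  expect_error(graft_loop(s, plan2, setNames(fam$structures,
                                             vapply(fam$structures,
                                                    function(x) x$id, ""))),
               "missing anchors")
})
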
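test_that("MRE scores match hand counts on the worked example", {
  sc <- mre_scores(example_candidates(), example_mre(),
                   example_mre_targets())
  expect_identical(nrow(sc), 1L)
  # shared {m1, m2}; union of miRNA neighborhoods {m1, m2, m3, m4}
  expect_equal(sc$s1, 2 / 4)
  # 7 sites total over 2 * |shared|
  expect_equal(sc$s2, 7 / 4)
  # spans: A = 921 - 100 + 1 = 822 over 4 sites; B = 421 - 50 + 1 = 372
  # over 3 sites; sites per kb averaged over the two RNAs
  expect_equal(sc$s3, mean(c(4000 / 822, 3000 / 372)), tolerance = 1e-12)
  # 7 sites from 2 distinct miRNAs
  expect_equal(sc$s4, 7 / 2)
  # mean absolute energy
  expect_equal(sc$s5, (10 + 12 + 8 + 15 + 9 + 11 + 14) / 7)
})

test_that("constant energies give s5 exactly and full overlap gives s1 = 1", {
  mre <- example_mre()
  mre$energy <- -10
  tg <- example_mre_targets()
  tg <- tg[tg$mirna %in% c("m1", "m2"), ]  # shared = all miRNAs of both
  sc <- mre_scores(example_candidates(), mre, tg)
  expect_equal(sc$s5, 10)
  expect_equal(sc$s1, 1)
})

test_that("single-site span falls back to the site length", {
  mre <- data.frame(mirna = c("m1", "m1"), target = c("A", "B"),
                    start = c(100L, 200L), end = c(121L, 221L),
                    energy = c(-5, -5))
  tg <- data.frame(mirna = c("m1", "m1"), target = c("A", "B"))
  cand <- sponge_network(data.frame(rna_a = "A", rna_b = "B", n_shared = 1L,
                                    shared_mirnas = "m1", p_shared = 0.1,
                                    p_shared_adj = 0.1), "miRHomology")
  sc <- mre_scores(cand, mre, tg)
  expect_equal(sc$s3, 1000 / 22)
})

test_that("missing MRE records follow the on_missing policy", {
  mre <- example_mre()
  mre <- mre[mre$mirna != "m2", ]  # m2 has no records now
  sc <- suppressMessages(mre_scores(example_candidates(), mre,
                                    example_mre_targets()))
  expect_identical(nrow(sc), 1L)        # scored with available records
  expect_equal(sc$s4, 5 / 1)
  expect_message(
    sc2 <- mre_scores(example_candidates(), mre, example_mre_targets(),
                      on_missing = "drop"),
    "dropped")
  expect_identical(nrow(sc2), 0L)
})

test_that("DT-Hybrid closed-form cases", {
  # two targets sharing their single miRNA: 1/k(m) = 1/2
  tg <- data.frame(mirna = c("m1", "m1"), target = c("A", "B"))
  dt <- dt_hybrid(tg)
  expect_equal(dt$matrix["A", "B"], 0.5)
  expect_equal(diag(dt$matrix), c(A = 0, B = 0))
  # disjoint miRNA sets -> 0
  tg2 <- data.frame(mirna = c("m1", "m2"), target = c("A", "B"))
  expect_equal(dt_hybrid(tg2)$matrix["A", "B"], 0)
})

test_that("DT-Hybrid equals brute force on random bipartite graphs", {
  brute <- function(A, lambda, alpha) {
    kt <- rowSums(A); km <- colSums(A)
    nt <- nrow(A)
    W <- matrix(0, nt, nt, dimnames = list(rownames(A), rownames(A)))
    S <- W
    for (i in 1:nt) for (j in 1:nt) {
      acc <- 0
      for (l in seq_len(ncol(A))) {
        if (A[i, l] == 1 && A[j, l] == 1) acc <- acc + 1 / km[l]
      }
      W[i, j] <- acc / (max(kt[i], 1)^(1 - lambda) * max(kt[j], 1)^lambda)
      inter <- sum(A[i, ] & A[j, ])
      uni <- sum(A[i, ] | A[j, ])
      S[i, j] <- if (uni > 0) inter / uni else 0
    }
    Wp <- alpha * W + (1 - alpha) * W * S
    diag(Wp) <- 0
    Wp
  }
  with_seed_local(111, {
    for (rep in 1:100) {
      nt <- sample(2:4, 1)
      nm <- sample(2:4, 1)
      A <- matrix(stats::rbinom(nt * nm, 1, 0.6), nt, nm,
                  dimnames = list(paste0("t", 1:nt), paste0("m", 1:nm)))
      edges <- which(A == 1, arr.ind = TRUE)
      if (nrow(edges) == 0 || !all(rowSums(A) > 0)) next
      tg <- data.frame(mirna = colnames(A)[edges[, 2]],
                       target = rownames(A)[edges[, 1]])
      lambda <- stats::runif(1)
      alpha <- stats::runif(1)
      got <- dt_hybrid(tg, lambda, alpha)$matrix
      want <- brute(A[sort(rownames(A)), sort(colnames(A)), drop = FALSE],
                    lambda, alpha)
      expect_lt(max(abs(got - want[rownames(got), colnames(got)])), 1e-12)
    }
  })
})

test_that("DT-Hybrid matrix is symmetric at lambda = 0.5", {
  b <- default_bundle()
  dt <- dt_hybrid(b$targets, lambda = 0.5)
  expect_lt(max(abs(dt$matrix - t(dt$matrix))), 1e-12)
})

test_that("combined scores and normalization follow the min-max contract", {
  expect_equal(combine_and_normalize(data.frame(s1 = 2))$normalized, 1)
  with_seed_local(123, {
    smat <- matrix(stats::runif(40, 0.1, 5), 10, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
    cn <- combine_and_normalize(smat)
    expect_equal(cn$combined, rowSums(log(smat)), tolerance = 1e-12)
    brute <- (cn$combined - min(cn$combined)) /
      (max(cn$combined) - min(cn$combined))
    expect_equal(cn$normalized, brute, tolerance = 1e-12)
    expect_equal(cn$normalized[which.max(cn$combined)], 1)
    expect_equal(cn$normalized[which.min(cn$combined)], 0)
  })
  expect_error(combine_and_normalize(data.frame(s1 = c(1, -2))),
               "nonpositive")
  # combined score is monotone in every component
  base <- data.frame(s1 = 2, s2 = 3, s3 = 1, s4 = 5)
  for (j in 1:4) {
    up <- base
    up[1, j] <- up[1, j] * 2
    expect_gt(combine_and_normalize(up)$combined,
              combine_and_normalize(base)$combined)
  }
})

test_that("score-based retention: cutoff endpoints and top-fraction ranks", {
  b <- default_bundle()
  # unfiltered candidate list includes decoy-decoy pairs
  cand <- candidate_pairs(b$targets, p_cutoff = 1.01)
  mt <- suppressMessages(method_mutame(cand, b$mre, b$targets, cutoff = 0.5))
  expect_true(all(mt$normalized >= 0.5))
  # two candidates: normalized scores are exactly 1 and 0
  two <- candidate_pairs(b$targets)[1:2, ]
  m2 <- method_mutame(sponge_network(two, "miRHomology"), b$mre, b$targets)
  expect_identical(nrow(m2), 1L)
  expect_equal(m2$normalized, 1)
  # top-fraction mode keeps ceiling(q * n) pairs
  mtf <- suppressMessages(method_mutame(cand, b$mre, b$targets,
                                        top_fraction = 0.1))
  sc_all <- suppressMessages(method_mutame(cand, b$mre, b$targets,
                                           cutoff = 0))
  expect_identical(nrow(mtf), as.integer(ceiling(0.1 * nrow(sc_all))))
  expect_gte(min(mtf$normalized), max(sc_all$normalized[
    !pairs_key(sc_all) %in% pairs_key(mtf)]))
})

test_that("cernia ranks planted pairs above decoys", {
  b <- default_bundle()
  cand <- candidate_pairs(b$targets, p_cutoff = 1.01)
  ce <- suppressMessages(method_cernia(cand, b$mre, b$targets, b$mrna_expr,
                                       cutoff = 0))
  planted <- pairs_key(ce) %in% pairs_key(b$truth_pairs)
  expect_true(any(planted) && any(!planted))
  rk <- rank(-ce$normalized)
  expect_lt(stats::median(rk[planted]), stats::median(rk[!planted]))
  # all planted pairs survive the default 0.5 cutoff on the mixed list
  ce5 <- suppressMessages(method_cernia(cand, b$mre, b$targets, b$mrna_expr))
  expect_gte(recall_of(ce5, b$truth_pairs), 0.9)
})
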
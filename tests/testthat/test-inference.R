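test_that("candidate_pairs screens by shared-miRNA significance", {
  # both targets hit by the sole miRNA of a 1-miRNA universe: p = 1, dropped
  t1 <- data.frame(mirna = c("m1", "m1"), target = c("A", "B"))
  expect_identical(nrow(candidate_pairs(t1)), 0L)
  expect_identical(nrow(candidate_pairs(t1, p_cutoff = 1.01)), 1L)
  net <- candidate_pairs(t1, p_cutoff = 1.01)
  expect_equal(net$p_shared, 1)
  expect_identical(net$shared_mirnas, "m1")

  # disjoint target sets -> empty network
  expect_identical(nrow(candidate_pairs(tiny_targets(), p_cutoff = 1.01,
                                        min_shared = 3)), 0L)

  # 20-miRNA universe, one pair sharing 10 of 10 -> p = 1/C(20,10)
  mk <- function(tg, mirs) data.frame(mirna = mirs, target = tg)
  t2 <- rbind(mk("A", paste0("u", 1:10)), mk("B", paste0("u", 1:10)),
              mk("C", paste0("u", 11:13)), mk("D", paste0("u", 14:16)),
              mk("E", paste0("u", 17:20)))
  net2 <- candidate_pairs(t2)
  expect_identical(nrow(net2), 1L)
  expect_identical(c(net2$rna_a, net2$rna_b), c("A", "B"))
  expect_equal(net2$p_shared, 1 / choose(20, 10), tolerance = 1e-9)
  expect_identical(net2$n_shared, 10L)

  # fewer than 2 distinct targets -> empty, not an error
  expect_identical(nrow(candidate_pairs(mk("A", paste0("u", 1:3)))), 0L)

  # overlapping namespaces rejected by default
  bad <- data.frame(mirna = c("m1", "A"), target = c("A", "B"))
  expect_error(candidate_pairs(bad), "namespace")
  expect_silent(candidate_pairs(bad, allow_shared_namespace = TRUE,
                                p_cutoff = 1.01))
})

test_that("pc keeps positively correlated significant pairs only", {
  b <- default_bundle()
  truth <- b$truth_pairs
  cand <- candidate_pairs(b$targets)
  net <- method_pc(cand, b$mrna_expr)
  expect_gte(precision_of(net, truth), 0.8)
  expect_gte(recall_of(net, truth), 0.7)
  expect_true(all(net$r > 0))
  # p_cutoff 0 -> empty
  expect_identical(nrow(method_pc(cand, b$mrna_expr, p_cutoff = 0)), 0L)
  # anti-correlated pair is excluded
  expr <- rbind(A = seq_len(20), B = -seq_len(20) + 0.01 * sin(1:20))
  cand1 <- sponge_network(data.frame(rna_a = "A", rna_b = "B",
                                     n_shared = 1L, shared_mirnas = "m1",
                                     p_shared = 0.01, p_shared_adj = 0.01),
                          "miRHomology")
  expect_identical(nrow(method_pc(cand1, expr)), 0L)
  expect_error(method_pc(cand1, expr[1, , drop = FALSE]), "missing")
})

test_that("sppc sensitivity correlation isolates miRNA-mediated co-expression", {
  b <- default_bundle()
  cand <- candidate_pairs(b$targets)
  net <- method_sppc(cand, b$mirna_expr, b$mrna_expr)
  expect_gte(recall_of(net, b$truth_pairs), 0.6)
  expect_true(all(net$sc >= 0.1))
  # planted pairs: correlation is mostly miRNA-driven, so SC is large
  expect_gt(stats::median(net$sc), 0.5)
  expect_lt(stats::median(abs(net$rho_partial)), 0.25)

  # raising the cutoff can only shrink the retained set
  net3 <- method_sppc(cand, b$mirna_expr, b$mrna_expr, sc_cutoff = 0.3)
  expect_lte(nrow(net3), nrow(net))
  expect_true(all(pairs_key(net3) %in% pairs_key(net)))

  # miRNAs independent of both RNAs: SC near 0, dropped
  with_seed_local(71, {
    ex <- rbind(A = stats::rnorm(100), B = stats::rnorm(100))
    me <- rbind(m1 = stats::rnorm(100))
    cand1 <- sponge_network(data.frame(rna_a = "A", rna_b = "B",
                                       n_shared = 1L, shared_mirnas = "m1",
                                       p_shared = 0.01, p_shared_adj = 0.01),
                            "miRHomology")
    expect_identical(nrow(method_sppc(cand1, me, ex)), 0L)
    expect_error(method_sppc(cand1, me[0, , drop = FALSE], ex), "missing")
  })
})

test_that("competition methods recover planted pairs and are reproducible", {
  b <- default_bundle()
  cand <- candidate_pairs(b$targets)
  he <- method_competition(cand, b$mirna_expr, b$mrna_expr, kind = "hermes",
                           m = 100, seed = 42)
  pp <- method_competition(cand, b$mirna_expr, b$mrna_expr, kind = "ppc",
                           m = 100, seed = 42)
  expect_gte(recall_of(he, b$truth_pairs), 0.6)
  expect_gte(recall_of(pp, b$truth_pairs), 0.6)
  # determinism under a fixed seed
  he2 <- method_competition(cand, b$mirna_expr, b$mrna_expr, kind = "hermes",
                            m = 100, seed = 42)
  expect_identical(as.data.frame(he), as.data.frame(he2))
  expect_error(method_competition(cand, b$mirna_expr, b$mrna_expr, m = 0),
               "m must be")
})

test_that("competition methods retain nothing on independent expression", {
  with_seed_local(83, {
    n <- 60
    genes <- sprintf("G%02d", 1:20)
    mirs <- sprintf("m%02d", 1:10)
    ex <- matrix(stats::rnorm(20 * n), 20, n, dimnames = list(genes, NULL))
    me <- matrix(stats::rnorm(10 * n), 10, n, dimnames = list(mirs, NULL))
    cp <- t(utils::combn(genes, 2))[1:20, ]
    cand <- sponge_network(
      data.frame(rna_a = cp[, 1], rna_b = cp[, 2], n_shared = 2L,
                 shared_mirnas = paste(mirs[1], mirs[2], sep = ","),
                 p_shared = 0.01, p_shared_adj = 0.01),
      "miRHomology")
    pp <- method_competition(cand, me, ex, kind = "ppc", m = 100, seed = 5)
    expect_lte(nrow(pp), 1)
  })
})

test_that("ppc and sppc capture overlapping linear competition signal", {
  b <- default_bundle()
  cand <- candidate_pairs(b$targets)
  sp <- method_sppc(cand, b$mirna_expr, b$mrna_expr)
  pp <- method_competition(cand, b$mirna_expr, b$mrna_expr, kind = "ppc",
                           m = 100, seed = 42)
  inter <- length(intersect(pairs_key(sp), pairs_key(pp)))
  uni <- length(union(pairs_key(sp), pairs_key(pp)))
  expect_gte(inter / uni, 0.3)
})

test_that("integration implements majority voting with boundary identities", {
  mk <- function(...) {
    p <- canonical_pairs(...elt(1), ...elt(2))
    sponge_network(unique(p), "x")
  }
  n1 <- mk(c("a", "b"), c("b", "c"))
  n2 <- mk(c("a", "c"), c("b", "d"))
  n3 <- mk(c("a", "x"), c("b", "y"))
  nets <- list(A = n1, B = n2, C = n3)
  # pair a-b present in all three
  v3 <- integrate_methods(nets, k = 3)
  expect_identical(pairs_key(v3), "a|b")
  expect_identical(v3$votes, 3L)
  expect_identical(v3$methods, "A;B;C")
  # k = 1 is the union, k = |networks| the intersection
  v1 <- integrate_methods(nets, k = 1)
  expect_identical(sort(pairs_key(v1)),
                   sort(unique(c(pairs_key(n1), pairs_key(n2),
                                 pairs_key(n3)))))
  # cardinality non-increasing in k; results subset of the union
  sizes <- vapply(1:3, function(k) nrow(integrate_methods(nets, k)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(pairs_key(v3) %in% pairs_key(v1)))
  expect_warning(out <- integrate_methods(nets, k = 4), "exceeds")
  expect_identical(nrow(out), 0L)
})

test_that("vote counts match a brute-force multiset count", {
  with_seed_local(97, {
    ids <- sprintf("N%02d", 1:12)
    all_pairs <- canonical_pairs(t(utils::combn(ids, 2))[, 1],
                                 t(utils::combn(ids, 2))[, 2])
    nets <- lapply(1:7, function(i) {
      sub <- all_pairs[sample(nrow(all_pairs), 20), ]
      sponge_network(sub[order(sub$rna_a, sub$rna_b), ], paste0("m", i))
    })
    names(nets) <- paste0("m", 1:7)
    for (k in c(1, 3, 7)) {
      res <- integrate_methods(nets, k = k)
      # brute force
      keys <- unlist(lapply(nets, pairs_key))
      counts <- table(keys)
      expect_identical(sort(pairs_key(res)),
                       sort(names(counts)[counts >= k]))
      expect_identical(unname(res$votes),
                       as.integer(counts[pairs_key(res)]))
    }
  })
})

test_that("null permutation p-values are super-uniform", {
  # 500 independent-Gaussian triplets, m = 100 lower-tail permutation tests
  with_seed_local(101, {
    n <- 50
    m <- 100
    pvals <- vapply(1:500, function(i) {
      mir <- stats::rnorm(n)
      x <- stats::rnorm(n)
      z <- stats::rnorm(n)
      obs <- delta_statistic("ppc", mir, x, z)
      null <- vapply(1:m, function(j) {
        delta_statistic("ppc", mir, x, z[sample.int(n)])
      }, numeric(1))
      permutation_pvalue(obs, null, alternative = "less")
    }, numeric(1))
    expect_lte(mean(pvals < 0.05), 0.08)
  })
})
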
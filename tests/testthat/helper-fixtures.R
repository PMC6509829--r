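# Shared fixtures, built in code at test time.

# Tiny miRNA-target table: t1 and t2 share m1, m2; t3 is disjoint.
tiny_targets <- function() {
  data.frame(
    mirna = c("m1", "m2", "m1", "m2", "m3", "m4"),
    target = c("t1", "t1", "t2", "t2", "t3", "t3"),
    stringsAsFactors = FALSE
  )
}

# MRE table for the worked muTaME example: shared {m1, m2};
# m1 has 3 sites on A and 2 on B, m2 has 1 site on each.
example_mre <- function() {
  data.frame(
    mirna = c("m1", "m1", "m1", "m1", "m1", "m2", "m2"),
    target = c("A", "A", "A", "B", "B", "A", "B"),
    start = c(100L, 300L, 700L, 150L, 400L, 900L, 50L),
    end = c(121L, 321L, 721L, 171L, 421L, 921L, 71L),
    energy = c(-10, -12, -8, -15, -9, -11, -14),
    stringsAsFactors = FALSE
  )
}

example_mre_targets <- function() {
  data.frame(
    mirna = c("m1", "m2", "m3", "m1", "m2", "m4"),
    target = c("A", "A", "A", "B", "B", "B"),
    stringsAsFactors = FALSE
  )
}

# Candidate network row for the pair (A, B) with shared miRNAs m1, m2.
example_candidates <- function() {
  sponge_network(
    data.frame(rna_a = "A", rna_b = "B", n_shared = 2L,
               shared_mirnas = "m1,m2", p_shared = 0.01, p_shared_adj = 0.01,
               stringsAsFactors = FALSE),
    "miRHomology"
  )
}

# Vectors with an exact prescribed sample correlation.
vectors_with_cor <- function(r, n = 40, seed = 11) {
  with_seed_local(seed, {
    x <- stats::rnorm(n)
    y0 <- stats::rnorm(n)
    x <- as.numeric(scale(x))
    y0 <- as.numeric(scale(stats::residuals(stats::lm(y0 ~ x))))
    list(x = x, y = r * x + sqrt(1 - r^2) * y0)
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Small default-condition bundle cached per test run.
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_sponge_data(synthetic_config())
    cache
  }
})

pairs_key <- function(df) paste(df$rna_a, df$rna_b, sep = "|")

recall_of <- function(net, truth) mean(pairs_key(truth) %in% pairs_key(net))
precision_of <- function(net, truth) {
  if (nrow(net) == 0) return(NA_real_)
  mean(pairs_key(net) %in% pairs_key(truth))
}
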
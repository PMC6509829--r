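#' Hypergeometric test for shared miRNA regulation
#'
#' Significance of the number of miRNAs shared by two RNAs, given the miRNA
#' universe. With N miRNAs of interest, K targeting RNA_i, M targeting RNA_j
#' and n shared, the p-value is the upper tail P(X >= n) for X hypergeometric:
#' p = 1 - sum_{x=0}^{n-1} C(K,x) C(N-K,M-x) / C(N,M).
#' The same kernel drives candidate-pair screening and module gene-set
#' over-representation.
#'
#' @param N integer, size of the miRNA universe.
#' @param K integer, number of miRNAs targeting the first RNA.
#' @param M integer, number of miRNAs targeting the second RNA.
#' @param n integer, number of shared miRNAs.
#' @return p-value in [0, 1]; vectorized over its arguments.
#' @examples
#' hypergeom_pvalue(N = 10, K = 5, M = 4, n = 4)  # 5/210
#' @export
hypergeom_pvalue <- function(N, K, M, n) {
  args <- cbind(N = N, K = K, M = M, n = n)
  if (any(args < 0) || any(args != floor(args))) {
    stop("N, K, M, n must be nonnegative integers")
  }
  N <- args[, "N"]; K <- args[, "K"]; M <- args[, "M"]; n <- args[, "n"]
  if (any(K > N) || any(M > N)) stop("K and M must not exceed N")
  if (any(n > pmin(K, M))) stop("n must not exceed min(K, M)")
  unname(stats::phyper(n - 1, K, N - K, M, lower.tail = FALSE))
}

#' Pearson correlation with a t-based significance test
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with \code{r} (correlation) and \code{p} (two-sided p-value
#'   from the t transform with length(x) - 2 degrees of freedom).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  r <- stats::cor(x, y)
  df <- length(x) - 2
  r_c <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tval <- r_c * sqrt(df / (1 - r_c^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = min(p, 1))
}

#' Partial Pearson correlation
#'
#' Order-|Z| partial correlation of x and y given a set of control vectors,
#' computed from the inverse of the joint correlation matrix. With a single
#' control z this reduces to the familiar closed form
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#'
#' @param x,y numeric vectors.
#' @param Z controls: NULL (plain Pearson), a numeric vector, a matrix with
#'   controls in columns, or a list of vectors.
#' @return the partial correlation (scalar).
#' @export
partial_correlation <- function(x, y, Z = NULL) {
  Zm <- control_matrix(Z, length(x))
  if (length(y) != length(x)) stop("x and y must have equal length")
  if (is.null(Zm) || ncol(Zm) == 0) return(stats::cor(x, y))
  if (length(x) <= ncol(Zm) + 2) {
    stop("need more than |Z| + 2 observations")
  }
  dat <- cbind(x, y, Zm)
  sds <- apply(dat, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance input in x, y or controls")
  R <- stats::cor(dat)
  P <- tryCatch(solve(R), error = function(e) {
    stop("singular correlation matrix; collinear controls: ",
         paste(colnames(Zm), collapse = ", "))
  })
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

control_matrix <- function(Z, n) {
  if (is.null(Z)) return(NULL)
  if (is.list(Z) && !is.data.frame(Z)) {
    if (length(Z) == 0) return(NULL)
    Z <- do.call(cbind, Z)
  }
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1)
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("controls must match the length of x and y")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  Z
}

#' Gaussian-parametric mutual information
#'
#' Closed-form estimator I = -1/2 log(1 - r^2) nats, with r the Pearson
#' correlation; nonnegative by construction (r^2 is clipped into [0, 1)).
#'
#' @param x,y numeric vectors, length >= 4.
#' @return mutual information in nats.
#' @export
mi_gaussian <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("x and y must have equal length >= 4")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  mi_from_r(stats::cor(x, y))
}

mi_from_r <- function(r) {
  r2 <- min(r^2, 1 - 1e-12)
  -0.5 * log(1 - r2)
}

#' Gaussian-parametric conditional mutual information
#'
#' I(x; y | z) = -1/2 log(1 - rho^2) with rho the partial correlation of x
#' and y given z.
#'
#' @param x,y numeric vectors, length >= 4.
#' @param z conditioning vector (or matrix of conditioning columns).
#' @return conditional mutual information in nats.
#' @export
cmi_gaussian <- function(x, y, z) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("x and y must have equal length >= 4")
  }
  mi_from_r(partial_correlation(x, y, z))
}

# Equal-frequency binning plug-in estimators; bins = ceiling(sqrt(n)) by
# default. Slower but model-free; used to cross-check nonlinear coupling.
discretize_ef <- function(x, bins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) stop("zero-variance input")
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Plug-in (binning) mutual information
#' @param x,y numeric vectors.
#' @param bins number of equal-frequency bins; default ceiling(sqrt(n)).
#' @return mutual information in nats.
#' @export
mi_binned <- function(x, y, bins = ceiling(sqrt(length(x)))) {
  bx <- discretize_ef(x, bins); by <- discretize_ef(y, bins)
  tab <- table(bx, by)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

#' Plug-in (binning) conditional mutual information
#' @param x,y,z numeric vectors.
#' @param bins number of equal-frequency bins; default ceiling(sqrt(n)).
#' @return conditional mutual information in nats.
#' @export
cmi_binned <- function(x, y, z, bins = ceiling(sqrt(length(x)))) {
  bx <- discretize_ef(x, bins); by <- discretize_ef(y, bins)
  bz <- discretize_ef(z, bins)
  n <- length(x)
  cmi <- 0
  for (zz in unique(bz)) {
    idx <- bz == zz
    pz <- sum(idx) / n
    tab <- table(bx[idx], by[idx])
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    pos <- p > 0
    cmi <- cmi + pz * sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
  }
  cmi
}

#' Competition delta statistic (hermes / ppc)
#'
#' For a (miR_k, RNA_i, RNA_j) triplet, hermes uses the change in mutual
#' information when conditioning on the candidate partner,
#' Delta I = I(miR_k; RNA_i | RNA_j) - I(miR_k; RNA_i); the ppc variant uses
#' the analogous change in absolute Pearson correlation,
#' Delta C = |rho(miR_k, RNA_i | RNA_j)| - |rho(miR_k, RNA_i)| (absolute
#' values so that sign flips under conditioning still read as a change in
#' dependence strength). When two RNAs compete for miR_k, conditioning on
#' the partner absorbs part of the miRNA-RNA dependence, so the planted
#' signature is a negative delta relative to a permuted-partner null.
#'
#' @param kind "hermes" or "ppc".
#' @param mirna_vec,rnai_vec,rnaj_vec equal-length expression vectors.
#' @param estimator "gaussian" (closed form) or "binning" (plug-in);
#'   hermes only.
#' @return the delta statistic (scalar).
#' @export
delta_statistic <- function(kind = c("hermes", "ppc"),
                            mirna_vec, rnai_vec, rnaj_vec,
                            estimator = c("gaussian", "binning")) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  if (kind == "hermes") {
    if (estimator == "gaussian") {
      cmi_gaussian(mirna_vec, rnai_vec, rnaj_vec) -
        mi_gaussian(mirna_vec, rnai_vec)
    } else {
      cmi_binned(mirna_vec, rnai_vec, rnaj_vec) -
        mi_binned(mirna_vec, rnai_vec)
    }
  } else {
    abs(partial_correlation(mirna_vec, rnai_vec, rnaj_vec)) -
      abs(stats::cor(mirna_vec, rnai_vec))
  }
}

#' Permutation p-value with pseudo-count
#'
#' One-sided p-value from m null draws, p = (1 + #{null beyond observed}) /
#' (m + 1). The pseudo-count keeps p in [1/(m+1), 1], so downstream Fisher
#' combination never sees p = 0.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of m null statistics.
#' @param alternative "greater" (count null >= observed) or "less"
#'   (count null <= observed).
#' @return p-value.
#' @export
permutation_pvalue <- function(observed, null_draws,
                               alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(null_draws)
  if (m < 1) stop("null_draws must be non-empty")
  hits <- if (alternative == "greater") sum(null_draws >= observed)
          else sum(null_draws <= observed)
  (1 + hits) / (m + 1)
}

#' Fisher's combined probability test
#'
#' Combines n independent p-values into X^2 = -2 sum(log p_k), referred to a
#' chi-square distribution with 2n degrees of freedom.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return list with \code{x2}, \code{df} and combined \code{p}.
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) < 1) stop("need at least one p-value")
  if (any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  x2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(x2 = x2, df = df, p = stats::pchisq(x2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around the standard step-up FDR procedure.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values (same length and order).
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
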
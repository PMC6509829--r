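#' MRE-based pair scores (s1-s5)
#'
#' Computes, for each candidate pair, the binding-site scores used by the
#' muTaME (s1-s4) and cernia (s1-s5, plus s6/s7 added by
#' \code{\link{method_cernia}}) methods. Let S be the pair's shared miRNAs
#' and consider the MRE records of miRNAs in S on either RNA of the pair:
#' \itemize{
#'   \item s1: fraction of shared miRNAs, |S| / |miRNAs targeting either RNA|;
#'   \item s2: MRE density, total shared-miRNA MRE count on both RNAs
#'     divided by 2|S|;
#'   \item s3: MRE distribution, mean over the two RNAs of the number of
#'     shared-miRNA MREs divided by the covered span
#'     (max(end) - min(start) + 1), scaled x1000 (sites per kb); a single
#'     site's span is its own length;
#'   \item s4: MREs per contributing miRNA, total shared-miRNA MRE count
#'     divided by the number of distinct miRNAs yielding them;
#'   \item s5: energy density, mean absolute hybridization energy over the
#'     shared-miRNA MREs (kcal/mol).
#' }
#' Shared miRNAs without MRE records are by default scored with the
#' available records; pairs with no records at all are dropped (or, with
#' \code{on_missing = "drop"}, any pair with an uncovered shared miRNA is
#' dropped).
#'
#' @param net a \code{sponge_network} with a \code{shared_mirnas} column
#'   (from \code{\link{candidate_pairs}}).
#' @param mre MRE table (see \code{\link{read_mre_table}}).
#' @param targets miRNA-target table.
#' @param on_missing "score" (default) or "drop" for shared miRNAs lacking
#'   MRE records.
#' @return data.frame with columns \code{rna_a}, \code{rna_b},
#'   \code{s1}..\code{s5}; dropped pairs are absent.
#' @export
mre_scores <- function(net, mre, targets, on_missing = c("score", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(all(c("mirna", "target", "start", "end", "energy") %in% names(mre)))
  mir_by_target <- split(targets$mirna, targets$target)
  shared <- shared_mirna_list(net)
  mre_key <- paste(mre$target, mre$mirna, sep = "\r")
  rows <- lapply(seq_len(nrow(net)), function(i) {
    a <- net$rna_a[i]; b <- net$rna_b[i]
    S <- shared[[i]]
    if (length(S) == 0) return(NULL)
    union_mirnas <- union(mir_by_target[[a]], mir_by_target[[b]])
    rec_a <- mre[mre_key %in% paste(a, S, sep = "\r"), , drop = FALSE]
    rec_b <- mre[mre_key %in% paste(b, S, sep = "\r"), , drop = FALSE]
    total <- nrow(rec_a) + nrow(rec_b)
    covered <- unique(c(rec_a$mirna, rec_b$mirna))
    if (total == 0) return(NULL)
    if (on_missing == "drop" && length(setdiff(S, covered)) > 0) return(NULL)
    span_density <- function(rec) {
      if (nrow(rec) == 0) return(NA_real_)
      span <- max(rec$end) - min(rec$start) + 1
      1000 * nrow(rec) / span
    }
    s3 <- mean(c(span_density(rec_a), span_density(rec_b)), na.rm = TRUE)
    data.frame(rna_a = a, rna_b = b,
               s1 = length(S) / length(union_mirnas),
               s2 = total / (2 * length(S)),
               s3 = s3,
               s4 = total / length(covered),
               s5 = sum(abs(c(rec_a$energy, rec_b$energy))) / total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(data.frame(rna_a = character(0),
                                          rna_b = character(0), s1 = numeric(0),
                                          s2 = numeric(0), s3 = numeric(0),
                                          s4 = numeric(0), s5 = numeric(0))),
                          rows))
  n_dropped <- nrow(net) - nrow(out)
  if (n_dropped > 0) {
    message(n_dropped, " pair(s) without usable MRE records dropped")
  }
  rownames(out) <- NULL
  out
}

#' DT-Hybrid recommendation scores
#'
#' Two-pass resource-allocation projection of the bipartite miRNA-target
#' graph onto targets:
#' w_ij = (k_i^{-(1-lambda)} k_j^{-lambda}) * sum_l a_il a_jl / k(m_l),
#' with k() the degrees, followed by the domain-tuning blend
#' W' = alpha W + (1 - alpha) W o S where S is the Jaccard similarity of the
#' two targets' miRNA neighborhoods (Hadamard product). The matrix is
#' symmetric when lambda = 0.5; the diagonal is set to zero.
#'
#' @param targets miRNA-target table.
#' @param lambda degree-weighting asymmetry in [0, 1] (default 0.5).
#' @param alpha blend weight in [0, 1] (default 0.5).
#' @return list with \code{matrix} (target x target), \code{lambda},
#'   \code{alpha}.
#' @export
dt_hybrid <- function(targets, lambda = 0.5, alpha = 0.5) {
  stopifnot(nrow(targets) > 0, lambda >= 0, lambda <= 1,
            alpha >= 0, alpha <= 1)
  targets <- unique(targets[, c("mirna", "target")])
  tg <- sort(unique(targets$target))
  mirnas <- sort(unique(targets$mirna))
  A <- matrix(0, length(tg), length(mirnas), dimnames = list(tg, mirnas))
  A[cbind(match(targets$target, tg), match(targets$mirna, mirnas))] <- 1
  kt <- rowSums(A)
  km <- colSums(A)
  if (any(kt == 0)) warning("isolated target(s) produce zero rows")
  inter <- A %*% t(A)                       # shared-miRNA counts
  C <- A %*% (t(A) / km)                    # sum_l a_il a_jl / k(m_l)
  sk <- ifelse(kt > 0, kt, 1)
  W <- outer(sk^-(1 - lambda), sk^-lambda) * C
  uni <- outer(kt, kt, "+") - inter
  S <- ifelse(uni > 0, inter / uni, 0)
  Wp <- alpha * W + (1 - alpha) * W * S
  diag(Wp) <- 0
  list(matrix = Wp, lambda = lambda, alpha = alpha)
}

#' Combine and normalize log-scores
#'
#' Combined score = sum of the natural logs of the component scores; the
#' combined scores are min-max normalized over the candidate list into
#' [0, 1]. If all combined scores are equal the normalized score is 1 for
#' every pair (a single candidate is trivially top-ranked).
#'
#' @param scores data.frame or matrix of strictly positive component scores
#'   (one row per pair).
#' @return data.frame with columns \code{combined} and \code{normalized}.
#' @export
combine_and_normalize <- function(scores) {
  smat <- as.matrix(scores)
  if (nrow(smat) == 0) {
    return(data.frame(combined = numeric(0), normalized = numeric(0)))
  }
  bad <- which(smat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive score at pair %d, component %s",
                 bad[1, 1], colnames(smat)[bad[1, 2]]))
  }
  combined <- rowSums(log(smat))
  rng <- range(combined)
  normalized <- if (rng[1] == rng[2]) rep(1, length(combined))
                else (combined - rng[1]) / (rng[2] - rng[1])
  data.frame(combined = combined, normalized = normalized)
}

retain_by_score <- function(df, cutoff, top_fraction) {
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) {
      stop("top_fraction must lie in (0, 1]")
    }
    ord <- order(-df$normalized, df$rna_a, df$rna_b)
    n_keep <- ceiling(top_fraction * nrow(df))
    df[sort(ord[seq_len(n_keep)]), , drop = FALSE]
  } else {
    df[df$normalized >= cutoff, , drop = FALSE]
  }
}

#' muTaME method
#'
#' Scores candidate pairs from their shared-miRNA MRE structure (scores
#' s1-s4 of \code{\link{mre_scores}}), combines the log-scores, min-max
#' normalizes over the candidate list and retains pairs with normalized
#' score at or above \code{cutoff} (default 0.5), or the top
#' \code{top_fraction} by rank if given (ties at the cutoff are all
#' retained; rank ties break by canonical pair order).
#'
#' @param candidates a \code{sponge_network} from \code{\link{candidate_pairs}}.
#' @param mre MRE table.
#' @param targets miRNA-target table.
#' @param cutoff normalized-score cutoff (default 0.5).
#' @param top_fraction optional fraction in (0, 1]; mutually exclusive with
#'   \code{cutoff}-based retention.
#' @param on_missing see \code{\link{mre_scores}}.
#' @return a \code{sponge_network} with columns \code{s1}..\code{s4},
#'   \code{combined}, \code{normalized}.
#' @export
method_mutame <- function(candidates, mre, targets, cutoff = 0.5,
                          top_fraction = NULL, on_missing = "score") {
  sc <- mre_scores(candidates, mre, targets, on_missing = on_missing)
  cand <- as.data.frame(candidates)
  cand <- cand[match(pair_key(sc$rna_a, sc$rna_b),
                     pair_key(cand$rna_a, cand$rna_b)), , drop = FALSE]
  df <- cbind(cand, sc[, c("s1", "s2", "s3", "s4")],
              combine_and_normalize(sc[, c("s1", "s2", "s3", "s4")]))
  sponge_network(retain_by_score(df, cutoff, top_fraction), "muTaME")
}

#' cernia method
#'
#' Extends muTaME with three further scores: s5 (hybridization-energy
#' density), s6 (DT-Hybrid recommendation score of the pair) and s7 (the
#' pair's expression Pearson correlation shifted to r + 1, floored at 1e-6,
#' so anticorrelated pairs stay in the log domain). Retention is as in
#' \code{\link{method_mutame}}.
#'
#' @param candidates a \code{sponge_network} from \code{\link{candidate_pairs}}.
#' @param mre MRE table.
#' @param targets miRNA-target table.
#' @param mrna_expr expression matrix covering the candidate RNAs.
#' @param cutoff normalized-score cutoff (default 0.5).
#' @param top_fraction optional fraction in (0, 1].
#' @param lambda,alpha DT-Hybrid parameters.
#' @param on_missing see \code{\link{mre_scores}}.
#' @return a \code{sponge_network} with columns \code{s1}..\code{s7},
#'   \code{combined}, \code{normalized}.
#' @export
method_cernia <- function(candidates, mre, targets, mrna_expr, cutoff = 0.5,
                          top_fraction = NULL, lambda = 0.5, alpha = 0.5,
                          on_missing = "score") {
  sc <- mre_scores(candidates, mre, targets, on_missing = on_missing)
  if (nrow(sc) > 0) {
    check_genes_present(unique(c(sc$rna_a, sc$rna_b)), mrna_expr, "mRNA")
  }
  dt <- dt_hybrid(targets, lambda = lambda, alpha = alpha)
  s6 <- vapply(seq_len(nrow(sc)), function(i) {
    dt$matrix[sc$rna_a[i], sc$rna_b[i]]
  }, numeric(1))
  s7 <- vapply(seq_len(nrow(sc)), function(i) {
    max(stats::cor(mrna_expr[sc$rna_a[i], ], mrna_expr[sc$rna_b[i], ]) + 1,
        1e-6)
  }, numeric(1))
  keep <- s6 > 0
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with zero DT-Hybrid score dropped")
  }
  sc <- sc[keep, , drop = FALSE]
  sc$s6 <- s6[keep]
  sc$s7 <- s7[keep]
  cand <- as.data.frame(candidates)
  cand <- cand[match(pair_key(sc$rna_a, sc$rna_b),
                     pair_key(cand$rna_a, cand$rna_b)), , drop = FALSE]
  scols <- paste0("s", 1:7)
  df <- cbind(cand, sc[, scols], combine_and_normalize(sc[, scols]))
  sponge_network(retain_by_score(df, cutoff, top_fraction), "cernia")
}
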
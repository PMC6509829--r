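#' Candidate sponge pairs by shared-miRNA significance (miRHomology)
#'
#' Generates all unordered target pairs sharing at least \code{min_shared}
#' miRNAs and scores each with the hypergeometric test on the shared count
#' (see \code{\link{hypergeom_pvalue}}); pairs with BH-adjusted p below
#' \code{p_cutoff} are retained. This is the miRHomology method and the
#' candidate screen feeding all the expression- and MRE-based methods.
#'
#' @param targets data.frame with columns \code{mirna}, \code{target}
#'   (see \code{\link{read_targets}}).
#' @param min_shared minimum number of shared miRNAs for a pair to be tested
#'   (default 1).
#' @param p_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param allow_shared_namespace allow identifiers on both sides of the
#'   miRNA-target table.
#' @return a \code{sponge_network} with columns \code{rna_a}, \code{rna_b},
#'   \code{n_shared}, \code{shared_mirnas} (comma-joined), \code{p_shared},
#'   \code{p_shared_adj}.
#' @export
candidate_pairs <- function(targets, min_shared = 1, p_cutoff = 0.05,
                            allow_shared_namespace = FALSE) {
  stopifnot(is.data.frame(targets), all(c("mirna", "target") %in% names(targets)))
  if (nrow(targets) == 0) stop("miRNA-target table is empty")
  if (min_shared < 1) stop("min_shared must be >= 1")
  targets <- unique(targets[, c("mirna", "target")])
  overlap <- intersect(unique(targets$mirna), unique(targets$target))
  if (!allow_shared_namespace && length(overlap) > 0) {
    stop("identifier(s) in both miRNA and target namespaces: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }
  mirnas <- sort(unique(targets$mirna))
  tg <- sort(unique(targets$target))
  empty <- sponge_network(data.frame(rna_a = character(0), rna_b = character(0),
                                     n_shared = integer(0),
                                     shared_mirnas = character(0),
                                     p_shared = numeric(0),
                                     p_shared_adj = numeric(0),
                                     stringsAsFactors = FALSE), "miRHomology")
  if (length(tg) < 2) return(empty)
  A <- Matrix::sparseMatrix(i = match(targets$target, tg),
                            j = match(targets$mirna, mirnas),
                            x = 1,
                            dims = c(length(tg), length(mirnas)))
  shared <- Matrix::tcrossprod(A)
  deg <- Matrix::rowSums(A)
  sh <- as.matrix(shared)
  idx <- which(upper.tri(sh) & sh >= min_shared, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  n_shared <- sh[idx]
  K <- deg[idx[, 1]]
  M <- deg[idx[, 2]]
  p <- hypergeom_pvalue(length(mirnas), K, M, n_shared)
  p_adj <- adjust_bh(p)
  keep <- p_adj < p_cutoff
  if (!any(keep)) return(empty)
  mir_by_target <- split(targets$mirna, targets$target)
  a_raw <- tg[idx[keep, 1]]
  b_raw <- tg[idx[keep, 2]]
  shared_str <- vapply(seq_along(a_raw), function(i) {
    paste(sort(intersect(mir_by_target[[a_raw[i]]], mir_by_target[[b_raw[i]]])),
          collapse = ",")
  }, character(1))
  cp <- canonical_pairs(a_raw, b_raw)
  out <- data.frame(rna_a = cp$rna_a, rna_b = cp$rna_b,
                    n_shared = as.integer(n_shared[keep]),
                    shared_mirnas = shared_str,
                    p_shared = p[keep], p_shared_adj = p_adj[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$rna_a, out$rna_b), , drop = FALSE]
  sponge_network(out, "miRHomology")
}

shared_mirna_list <- function(net) {
  strsplit(ifelse(is.na(net$shared_mirnas), "", net$shared_mirnas), ",",
           fixed = TRUE)
}

check_genes_present <- function(ids, expr, what) {
  missing <- setdiff(ids, rownames(expr))
  if (length(missing) > 0) {
    stop("missing from ", what, " expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
}

#' Positive-correlation method (pc)
#'
#' Annotates each candidate pair with the Pearson correlation of the two
#' RNAs' expression; pairs with positive correlation and BH-adjusted
#' two-sided p below \code{p_cutoff} are retained as sponge interactions.
#'
#' @param candidates a \code{sponge_network} from \code{\link{candidate_pairs}}.
#' @param mrna_expr expression matrix (genes x samples) covering all
#'   candidate RNAs.
#' @param p_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @return a \code{sponge_network} with added columns \code{r}, \code{p_cor},
#'   \code{p_cor_adj}.
#' @export
method_pc <- function(candidates, mrna_expr, p_cutoff = 0.05) {
  if (nrow(candidates) == 0) return(sponge_network(as.data.frame(candidates), "pc"))
  check_genes_present(unique(c(candidates$rna_a, candidates$rna_b)),
                      mrna_expr, "mRNA")
  if (ncol(mrna_expr) < 3) stop("at least 3 samples required")
  res <- t(vapply(seq_len(nrow(candidates)), function(i) {
    pt <- pearson_test(mrna_expr[candidates$rna_a[i], ],
                       mrna_expr[candidates$rna_b[i], ])
    c(pt$r, pt$p)
  }, numeric(2)))
  out <- as.data.frame(candidates)
  out$r <- res[, 1]
  out$p_cor <- res[, 2]
  out$p_cor_adj <- adjust_bh(out$p_cor)
  out <- out[out$r > 0 & out$p_cor_adj < p_cutoff, , drop = FALSE]
  sponge_network(out, "pc")
}

#' Sensitivity partial Pearson correlation method (sppc)
#'
#' For each candidate pair the sensitivity correlation is
#' SC = rho_ij - rho_ij|shared, the drop in the pair's Pearson correlation
#' after partialling out the expression of their shared miRNAs. Pairs with
#' SC at or above \code{sc_cutoff} are retained. Both rho_ij and the partial
#' correlation are reported so users can filter further.
#'
#' @param candidates a \code{sponge_network} from \code{\link{candidate_pairs}}.
#' @param mirna_expr miRNA expression matrix covering all shared miRNAs.
#' @param mrna_expr expression matrix covering all candidate RNAs.
#' @param sc_cutoff retention cutoff on SC (default 0.1).
#' @return a \code{sponge_network} with added columns \code{rho},
#'   \code{rho_partial}, \code{sc}.
#' @export
method_sppc <- function(candidates, mirna_expr, mrna_expr, sc_cutoff = 0.1) {
  if (nrow(candidates) == 0) return(sponge_network(as.data.frame(candidates), "sppc"))
  check_genes_present(unique(c(candidates$rna_a, candidates$rna_b)),
                      mrna_expr, "mRNA")
  shared <- shared_mirna_list(candidates)
  check_genes_present(unique(unlist(shared)), mirna_expr, "miRNA")
  res <- t(vapply(seq_len(nrow(candidates)), function(i) {
    x <- mrna_expr[candidates$rna_a[i], ]
    y <- mrna_expr[candidates$rna_b[i], ]
    Z <- t(mirna_expr[shared[[i]], , drop = FALSE])
    rho <- stats::cor(x, y)
    rho_p <- partial_correlation(x, y, Z)
    c(rho, rho_p)
  }, numeric(2)))
  out <- as.data.frame(candidates)
  out$rho <- res[, 1]
  out$rho_partial <- res[, 2]
  out$sc <- out$rho - out$rho_partial
  out <- out[out$sc >= sc_cutoff, , drop = FALSE]
  sponge_network(out, "sppc")
}

#' Competition methods with permutation null (hermes, ppc)
#'
#' For each candidate pair and each shared miRNA, computes the delta
#' statistic (\code{\link{delta_statistic}}; change in (conditional) mutual
#' information for hermes, in absolute (partial) correlation for ppc) and a
#' per-miRNA permutation p-value obtained by permuting the conditioning
#' partner's expression \code{m} times. Since competition shows up as the
#' partner's expression absorbing miRNA-RNA dependence, the per-miRNA test is
#' lower-tailed (observed delta below the permuted null). Per-miRNA p-values
#' are combined with Fisher's method; both conditioning directions are
#' computed and the pair p-value is the maximum of the two (conservative
#' AND-rule, so the result is symmetric in the pair). Pair p-values are
#' BH-adjusted and thresholded at \code{p_cutoff}.
#'
#' @param candidates a \code{sponge_network} from \code{\link{candidate_pairs}}.
#' @param mirna_expr miRNA expression matrix covering all shared miRNAs.
#' @param mrna_expr expression matrix covering all candidate RNAs.
#' @param kind "hermes" (mutual information) or "ppc" (correlation).
#' @param m number of permutations (default 100).
#' @param p_cutoff BH-adjusted p-value cutoff (default 0.05).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param estimator "gaussian" or "binning" (hermes only).
#' @return a \code{sponge_network} with added columns \code{p_comb},
#'   \code{p_comb_adj}.
#' @export
method_competition <- function(candidates, mirna_expr, mrna_expr,
                               kind = c("hermes", "ppc"), m = 100,
                               p_cutoff = 0.05, seed = NULL,
                               estimator = c("gaussian", "binning")) {
  kind <- match.arg(kind)
  estimator <- match.arg(estimator)
  if (m < 1) stop("number of permutations m must be >= 1")
  if (nrow(candidates) == 0) return(sponge_network(as.data.frame(candidates), kind))
  check_genes_present(unique(c(candidates$rna_a, candidates$rna_b)),
                      mrna_expr, "mRNA")
  shared <- shared_mirna_list(candidates)
  check_genes_present(unique(unlist(shared)), mirna_expr, "miRNA")
  ns <- ncol(mrna_expr)
  if (ns < 4) stop("at least 4 samples required")
  p_pair <- with_seed(seed, {
    vapply(seq_len(nrow(candidates)), function(i) {
      mir <- shared[[i]]
      Zm <- mirna_expr[mir, , drop = FALSE]
      xa <- mrna_expr[candidates$rna_a[i], ]
      xb <- mrna_expr[candidates$rna_b[i], ]
      p_dir <- vapply(1:2, function(d) {
        target <- if (d == 1) xa else xb  # RNA_i under test
        partner <- if (d == 1) xb else xa # RNA_j conditioned on & permuted
        perms <- replicate(m, sample.int(ns))
        pk <- competition_pk(Zm, target, partner, perms, kind, estimator)
        fisher_combine(pk)$p
      }, numeric(1))
      max(p_dir)
    }, numeric(1))
  })
  out <- as.data.frame(candidates)
  out$p_comb <- p_pair
  out$p_comb_adj <- adjust_bh(p_pair)
  out <- out[out$p_comb_adj < p_cutoff, , drop = FALSE]
  sponge_network(out, kind)
}

# Per-miRNA permutation p-values for one conditioning direction.
# Zm: shared-miRNA expression (miRNAs x samples); perms: ns x m index matrix.
competition_pk <- function(Zm, target, partner, perms, kind, estimator) {
  m <- ncol(perms)
  q <- nrow(Zm)
  if (estimator == "binning" && kind == "hermes") {
    pk <- vapply(seq_len(q), function(k) {
      obs <- delta_statistic("hermes", Zm[k, ], target, partner, "binning")
      null <- vapply(seq_len(m), function(j) {
        delta_statistic("hermes", Zm[k, ], target, partner[perms[, j]],
                        "binning")
      }, numeric(1))
      permutation_pvalue(obs, null, alternative = "less")
    }, numeric(1))
    return(pk)
  }
  # Gaussian path: each delta depends only on three pairwise correlations,
  # so compute correlations of the (permuted) partner against (target, miRNAs)
  # in one call per permutation.
  Mx <- cbind(target, t(Zm))
  r_mt <- stats::cor(target, t(Zm))[1, ]            # miR vs target, fixed
  delta_from_cors <- function(r_pt, r_pm) {
    # r_pt: partner vs target; r_pm: partner vs each miR
    rp <- (r_mt - r_pm * r_pt) / sqrt((1 - r_pm^2) * (1 - r_pt^2))
    rp[!is.finite(rp)] <- 0
    if (kind == "hermes") {
      r2p <- pmin(rp^2, 1 - 1e-12)
      r2m <- pmin(r_mt^2, 1 - 1e-12)
      -0.5 * log(1 - r2p) + 0.5 * log(1 - r2m)
    } else {
      abs(rp) - abs(r_mt)
    }
  }
  cors_obs <- stats::cor(partner, Mx)[1, ]
  d_obs <- delta_from_cors(cors_obs[1], cors_obs[-1])
  d_null <- matrix(0, nrow = q, ncol = m)
  for (j in seq_len(m)) {
    cj <- stats::cor(partner[perms[, j]], Mx)[1, ]
    d_null[, j] <- delta_from_cors(cj[1], cj[-1])
  }
  vapply(seq_len(q), function(k) {
    permutation_pvalue(d_obs[k], d_null[k, ], alternative = "less")
  }, numeric(1))
}

#' Majority-vote integration of sponge networks
#'
#' Retains the unordered pairs predicted by at least \code{k} of the input
#' networks. Vote counts and the contributing method labels are recorded.
#'
#' @param networks list of \code{sponge_network} objects (named list names,
#'   else their method attributes, are used as method labels).
#' @param k minimum number of supporting methods (default 3).
#' @return a \code{sponge_network} with columns \code{rna_a}, \code{rna_b},
#'   \code{votes}, \code{methods}.
#' @export
integrate_methods <- function(networks, k = 3) {
  if (length(networks) < 1) stop("need at least one network")
  if (k < 1) stop("k must be >= 1")
  labels <- names(networks)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_along(networks), function(i) {
      m <- attr(networks[[i]], "method")
      if (is.null(m)) paste0("method", i) else m
    }, character(1))
  }
  empty <- sponge_network(data.frame(rna_a = character(0),
                                     rna_b = character(0),
                                     votes = integer(0),
                                     methods = character(0),
                                     stringsAsFactors = FALSE), "integrate")
  if (k > length(networks)) {
    warning("k exceeds the number of networks; returning an empty network")
    return(empty)
  }
  rows <- do.call(rbind, lapply(seq_along(networks), function(i) {
    nt <- networks[[i]]
    if (nrow(nt) == 0) return(NULL)
    data.frame(key = pair_key(nt$rna_a, nt$rna_b), rna_a = nt$rna_a,
               rna_b = nt$rna_b, method = labels[i], stringsAsFactors = FALSE)
  }))
  if (is.null(rows) || nrow(rows) == 0) return(empty)
  agg <- split(rows$method, rows$key)
  votes <- vapply(agg, length, integer(1))
  keep <- names(agg)[votes >= k]
  if (length(keep) == 0) return(empty)
  first <- rows[!duplicated(rows$key), ]
  rownames(first) <- first$key
  out <- data.frame(rna_a = first[keep, "rna_a"], rna_b = first[keep, "rna_b"],
                    votes = as.integer(votes[keep]),
                    methods = vapply(agg[keep], paste, character(1),
                                     collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rna_a, out$rna_b), , drop = FALSE]
  sponge_network(out, "integrate")
}
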
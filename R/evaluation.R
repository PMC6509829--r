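#' Validate a predicted sponge network against ground truth
#'
#' Matches predicted and curated pairs under the canonical unordered pair
#' representation, so orientation never matters.
#'
#' @param net a \code{sponge_network}.
#' @param truth data.frame of curated pairs with columns \code{rna_a},
#'   \code{rna_b} (see \code{\link{read_pair_table}}); orientation is
#'   irrelevant.
#' @return list with \code{n_predicted}, \code{n_validated},
#'   \code{percent_validated} (100 * validated / predicted; 0 with a flag if
#'   nothing was predicted) and \code{validated_pairs}.
#' @export
validate_network <- function(net, truth) {
  pred_keys <- pair_key(net$rna_a, net$rna_b)
  truth_keys <- if (nrow(truth) > 0) pair_key(truth[[1]], truth[[2]]) else character(0)
  hit <- pred_keys %in% truth_keys
  n_pred <- nrow(net)
  n_val <- sum(hit)
  list(n_predicted = n_pred,
       n_validated = n_val,
       percent_validated = if (n_pred > 0) 100 * n_val / n_pred else 0,
       empty_prediction = n_pred == 0,
       validated_pairs = as.data.frame(net)[hit, c("rna_a", "rna_b"),
                                            drop = FALSE])
}

#' Cross-method overlap of sponge networks
#'
#' For every non-empty subset of methods, counts the pairs predicted by
#' exactly that subset (UpSet-style exclusive intersections), plus the
#' pairwise intersection matrix (Venn-style counts).
#'
#' @param nets named list of at least two \code{sponge_network} objects.
#' @return list with \code{exclusive} (data.frame: \code{methods}
#'   (semicolon-joined subset), \code{count}) and \code{pairwise}
#'   (method x method matrix; diagonal = network sizes).
#' @export
method_overlap <- function(nets) {
  if (length(nets) < 2) stop("need at least two networks")
  labels <- names(nets)
  if (is.null(labels) || any(!nzchar(labels))) {
    labels <- vapply(seq_along(nets), function(i) {
      m <- attr(nets[[i]], "method")
      if (is.null(m)) paste0("method", i) else m
    }, character(1))
  }
  keysets <- lapply(nets, function(nt) pair_key(nt$rna_a, nt$rna_b))
  names(keysets) <- labels
  all_keys <- unique(unlist(keysets))
  sig <- vapply(all_keys, function(k) {
    paste(labels[vapply(keysets, function(ks) k %in% ks, logical(1))],
          collapse = ";")
  }, character(1))
  tab <- table(sig)
  exclusive <- data.frame(methods = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE)
  exclusive <- exclusive[order(-exclusive$count, exclusive$methods), ]
  rownames(exclusive) <- NULL
  pairwise <- matrix(0L, length(labels), length(labels),
                     dimnames = list(labels, labels))
  for (i in seq_along(labels)) {
    for (j in seq_along(labels)) {
      pairwise[i, j] <- length(intersect(keysets[[i]], keysets[[j]]))
    }
  }
  list(exclusive = exclusive, pairwise = pairwise)
}

#' Gene-set over-representation of modules
#'
#' One-sided hypergeometric over-representation of each gene set in each
#' module against a gene universe, with BH adjustment across sets within
#' each module (the same hypergeometric kernel used for shared-miRNA
#' screening). Module members and set members are first intersected with
#' the universe.
#'
#' @param ms a \code{module_set}.
#' @param gsc a \code{gene_set_collection} (see \code{\link{read_gmt}}) or a
#'   named list of character vectors.
#' @param universe character vector of background gene identifiers
#'   (typically all genes in the expression matrix).
#' @param p_adj_cutoff significance cutoff on the BH-adjusted p-value
#'   (default 0.05).
#' @return data.frame with one row per (module, set): \code{module_id},
#'   \code{set_name}, \code{overlap}, \code{module_size}, \code{set_size},
#'   \code{universe}, \code{p}, \code{p_adj}, \code{significant}; the total
#'   number of significant rows is stored in the \code{"n_significant"}
#'   attribute.
#' @export
enrich_modules <- function(ms, gsc, universe, p_adj_cutoff = 0.05) {
  sets <- if (inherits(gsc, "gene_set_collection")) gsc$sets else gsc
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  N <- length(universe)
  rows <- list()
  for (mi in seq_along(ms$modules)) {
    mod <- intersect(ms$modules[[mi]], universe)
    if (length(mod) == 0) next
    p <- numeric(length(sets))
    ov <- integer(length(sets))
    ssz <- integer(length(sets))
    for (si in seq_along(sets)) {
      st <- intersect(sets[[si]], universe)
      o <- length(intersect(mod, st))
      p[si] <- hypergeom_pvalue(N, length(st), length(mod), o)
      ov[si] <- o
      ssz[si] <- length(st)
    }
    rows[[length(rows) + 1]] <- data.frame(
      module_id = mi, set_name = names(sets), overlap = ov,
      module_size = length(mod), set_size = ssz, universe = N,
      p = p, p_adj = adjust_bh(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(list(data.frame(module_id = integer(0),
                                          set_name = character(0),
                                          overlap = integer(0),
                                          module_size = integer(0),
                                          set_size = integer(0),
                                          universe = integer(0),
                                          p = numeric(0), p_adj = numeric(0))),
                          rows))
  out$significant <- out$p_adj < p_adj_cutoff
  rownames(out) <- NULL
  attr(out, "n_significant") <- sum(out$significant)
  out
}

#' Module survival analysis (Cox risk score, log-rank, hazard ratio)
#'
#' For each module, fits a multivariate Cox proportional-hazards model on
#' the standardized expression of the module members, computes each
#' sample's risk score as the linear predictor, splits the samples into
#' high- and low-risk groups at the \code{split_quantile} of the score
#' (default the median), tests the group difference with the log-rank test
#' and reports the hazard ratio (with 95\% CI) of the high- versus low-risk
#' group from a univariate Cox fit on the group indicator, so HR > 1 always
#' means the high-risk group fares worse. By default the risk scores are
#' cross-validated (each sample's score comes from a Cox model fitted
#' without it, over \code{cv_folds} deterministic folds): scoring and
#' testing the same samples with a multi-gene model is anti-conservative,
#' and the cross-validated score keeps the log-rank test calibrated under
#' the null while barely affecting power. \code{risk_method = "full"} gives
#' the naive full-data score. Modules with more members than fitting
#' samples are fitted with a small fixed ridge penalty (with a message).
#' Modules meeting the significance rule (log-rank p < \code{p_cutoff} and
#' HR > \code{hr_cutoff}) are flagged.
#'
#' @param ms a \code{module_set}.
#' @param expr expression matrix (genes x samples).
#' @param surv survival table (see \code{\link{read_survival}}).
#' @param p_cutoff log-rank p-value cutoff (default 0.05).
#' @param hr_cutoff hazard-ratio cutoff (default 1.5).
#' @param split_quantile risk-score split quantile (default 0.5).
#' @param ridge_lambda ridge penalty used for over-parameterized fits
#'   (default 0.1).
#' @param risk_method "cv" (cross-validated risk scores, default) or
#'   "full" (scores from the full-data fit).
#' @param cv_folds number of cross-validation folds (default 5); fold
#'   assignment is deterministic (round-robin over sample order).
#' @return data.frame with columns \code{module_id}, \code{chi_square},
#'   \code{p_value}, \code{hr}, \code{hr_low95}, \code{hr_up95},
#'   \code{significant}.
#' @export
module_survival <- function(ms, expr, surv, p_cutoff = 0.05, hr_cutoff = 1.5,
                            split_quantile = 0.5, ridge_lambda = 0.1,
                            risk_method = c("cv", "full"), cv_folds = 5) {
  risk_method <- match.arg(risk_method)
  samples <- intersect(colnames(expr), surv$sample)
  if (length(samples) < 10) stop("fewer than 10 matched samples")
  surv <- surv[match(samples, surv$sample), ]
  if (sum(surv$event) == 0) stop("all samples are censored")
  cox_coef <- function(X, y, mi) {
    ridge <- ncol(X) >= nrow(X)
    fit <- if (ridge) {
      message(sprintf("module %d: %d covariates >= %d samples, ridge penalty applied",
                      mi, ncol(X), nrow(X)))
      survival::coxph(y ~ survival::ridge(X, theta = ridge_lambda,
                                          scale = FALSE))
    } else {
      survival::coxph(y ~ X)
    }
    co <- stats::coef(fit)
    co[!is.finite(co)] <- 0
    co
  }
  rows <- lapply(seq_along(ms$modules), function(mi) {
    genes <- intersect(ms$modules[[mi]], rownames(expr))
    if (length(genes) == 0) return(NULL)
    X <- t(expr[genes, samples, drop = FALSE])
    keep <- apply(X, 2, stats::sd) > 0
    X <- X[, keep, drop = FALSE]
    if (ncol(X) == 0) return(NULL)
    X <- scale(X)
    y <- survival::Surv(surv$time, surv$event)
    if (risk_method == "full") {
      lp <- as.numeric(X %*% cox_coef(X, y, mi))
    } else {
      folds <- rep_len(seq_len(cv_folds), nrow(X))
      lp <- numeric(nrow(X))
      for (f in seq_len(cv_folds)) {
        test <- folds == f
        co <- cox_coef(X[!test, , drop = FALSE],
                       survival::Surv(surv$time[!test], surv$event[!test]),
                       mi)
        held <- as.numeric(X[test, , drop = FALSE] %*% co)
        lp[test] <- held - stats::median(held)
      }
    }
    thr <- stats::quantile(lp, split_quantile)
    grp <- factor(ifelse(lp > thr, "high", "low"), levels = c("low", "high"))
    if (length(unique(grp)) < 2) return(NULL)
    sd_fit <- survival::survdiff(y ~ grp)
    chisq <- sd_fit$chisq
    p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    gfit <- survival::coxph(y ~ grp)
    hr <- exp(stats::coef(gfit)[[1]])
    ci <- exp(stats::confint(gfit)[1, ])
    data.frame(module_id = mi, chi_square = chisq, p_value = p,
               hr = hr, hr_low95 = ci[[1]], hr_up95 = ci[[2]],
               significant = p < p_cutoff & hr > hr_cutoff)
  })
  out <- do.call(rbind, c(list(data.frame(module_id = integer(0),
                                          chi_square = numeric(0),
                                          p_value = numeric(0), hr = numeric(0),
                                          hr_low95 = numeric(0),
                                          hr_up95 = numeric(0),
                                          significant = logical(0))),
                          rows))
  rownames(out) <- NULL
  out
}
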
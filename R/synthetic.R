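#' Configuration for the synthetic sponge-data generator
#'
#' Defaults describe a small but realistic ceRNA study on the log2 expression
#' scale: 60 miRNAs, 60 RNAs of which 10 disjoint pairs and one 6-RNA module
#' carry planted sponge structure, 200 matched samples, each planted group
#' repressed by 4 dedicated shared miRNAs with linear coupling strength 0.8
#' against residual noise sd 0.3 (pair correlation around 0.88),
#' miRanda-like MRE sites (22 nt, positions within a 3 kb transcript,
#' energies uniform in [-30, -5] kcal/mol, 2-5 sites per planted interaction
#' and 1 per decoy interaction), and exponential survival with a planted
#' high/low-risk hazard ratio of 2.5 at 30% censoring. All RNAs of the
#' planted module share one miRNA set, so every within-module pair is a true
#' sponge pair and the module appears as a clique in the inferred network;
#' its mean expression drives the survival hazard.
#'
#' @param n_mirnas number of miRNAs.
#' @param n_rnas number of RNAs (must be at least 2 * n_planted_pairs +
#'   module_size; the remainder are decoys).
#' @param n_samples number of matched samples.
#' @param n_planted_pairs number of disjoint planted sponge pairs.
#' @param module_size number of RNAs in the planted sponge module (0 to
#'   disable; sizes 1-2 are not a module and are rejected).
#' @param shared_mirnas_per_pair dedicated shared miRNAs per planted pair
#'   (and for the planted module).
#' @param extra_mirnas_per_rna extra sequence-level (non-repressing) miRNAs
#'   per planted RNA.
#' @param decoy_mirnas_per_rna sequence-level miRNAs per decoy RNA.
#' @param repression_strength linear coupling strength of the shared miRNAs
#'   on planted RNAs (log2-scale signal sd).
#' @param noise_sd residual expression noise sd (log2 scale).
#' @param mre_per_interaction integer range (lo, hi) of MRE sites per
#'   planted miRNA-target interaction; decoy interactions get one site.
#' @param energy_range hybridization energy range (lo, hi), hi <= 0, kcal/mol.
#' @param survival_hr planted hazard ratio between high- and low-risk groups
#'   (driven by the planted module's mean expression).
#' @param censoring_rate expected fraction of censored samples, in [0, 1).
#' @param baseline_hazard exponential baseline hazard (events per time unit).
#' @param seed integer RNG seed; the whole bundle is deterministic given it.
#' @return a list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_mirnas = 60, n_rnas = 60, n_samples = 200,
                             n_planted_pairs = 10, module_size = 6,
                             shared_mirnas_per_pair = 4,
                             extra_mirnas_per_rna = 1,
                             decoy_mirnas_per_rna = 2,
                             repression_strength = 0.8, noise_sd = 0.3,
                             mre_per_interaction = c(2, 5),
                             energy_range = c(-30, -5), survival_hr = 2.5,
                             censoring_rate = 0.3,
                             baseline_hazard = 0.1, seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_rnas = n_rnas, n_samples = n_samples,
              n_planted_pairs = n_planted_pairs, module_size = module_size,
              shared_mirnas_per_pair = shared_mirnas_per_pair,
              extra_mirnas_per_rna = extra_mirnas_per_rna,
              decoy_mirnas_per_rna = decoy_mirnas_per_rna,
              repression_strength = repression_strength, noise_sd = noise_sd,
              mre_per_interaction = mre_per_interaction,
              energy_range = energy_range, survival_hr = survival_hr,
              censoring_rate = censoring_rate,
              baseline_hazard = baseline_hazard, seed = seed)
  counts <- c(n_mirnas, n_rnas, n_samples, n_planted_pairs,
              shared_mirnas_per_pair)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (module_size %in% c(1, 2) || module_size < 0) {
    stop("module_size must be 0 or >= 3")
  }
  n_groups <- n_planted_pairs + (module_size > 0)
  if (n_groups * shared_mirnas_per_pair > n_mirnas) {
    stop("not enough miRNAs for the requested planted structure")
  }
  if (n_rnas < 2 * n_planted_pairs + module_size) {
    stop("n_rnas must be at least 2 * n_planted_pairs + module_size")
  }
  if (energy_range[2] > 0) stop("hybridization energies must be <= 0")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must lie in [0, 1)")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic sponge-study bundle
#'
#' Emulates the inputs of a ceRNA study with known structure. Each planted
#' pair of RNAs is repressed by the same dedicated set of shared miRNAs
#' (linear negative coupling plus Gaussian noise), which induces a positive
#' expression correlation between the pair members that vanishes when the
#' shared miRNAs are conditioned on -- exactly the sponge signature the
#' inference methods test for. Decoy RNAs carry a few sequence-level
#' miRNA-target edges but no expression coupling. MRE records are drawn per
#' miRNA-target interaction with 22-nt sites placed uniformly in [1, 3000]
#' and energies uniform in the configured range; planted interactions get
#' more sites than decoys so MRE-density scores rank them higher. Survival
#' times are exponential with the hazard scaled by the planted module's
#' standardized mean expression so that a median split of that score has the
#' configured hazard ratio.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with \code{mirna_expr}, \code{mrna_expr} (matrices),
#'   \code{targets}, \code{mre}, \code{truth_pairs}, \code{survival}
#'   (data.frames), \code{modules_truth} (list) and \code{config}.
#' @export
generate_sponge_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    nm <- config$n_mirnas
    nr <- config$n_rnas
    ns <- config$n_samples
    np <- config$n_planted_pairs
    q <- config$shared_mirnas_per_pair
    mirna_ids <- sprintf("miR-%03d", seq_len(nm))
    rna_ids <- sprintf("RNA%03d", seq_len(nr))
    sample_ids <- sprintf("S%03d", seq_len(ns))
    # log2-scale miRNA expression
    Z <- matrix(stats::rnorm(nm * ns, mean = 5, sd = 1), nm, ns,
                dimnames = list(mirna_ids, sample_ids))
    msize <- config$module_size
    # planted groups: np disjoint pairs, then (optionally) one module whose
    # RNAs all share the same miRNA set
    group_rnas <- c(lapply(seq_len(np), function(p) {
      rna_ids[c(2 * p - 1, 2 * p)]
    }), if (msize > 0) list(rna_ids[2 * np + seq_len(msize)]))
    planted_rnas <- unlist(group_rnas)
    decoys <- setdiff(rna_ids, planted_rnas)
    X <- matrix(NA_real_, nr, ns, dimnames = list(rna_ids, sample_ids))
    targets <- list()
    truth <- list()
    shared_sets <- list()
    for (p in seq_along(group_rnas)) {
      members <- group_rnas[[p]]
      S <- mirna_ids[((p - 1) * q + 1):(p * q)]
      shared_sets[[p]] <- S
      signal <- colSums(Z[S, , drop = FALSE] - 5) / sqrt(q)
      for (r in members) {
        X[r, ] <- 8 - config$repression_strength * signal +
          stats::rnorm(ns, sd = config$noise_sd)
        extra <- sample(setdiff(mirna_ids, S), config$extra_mirnas_per_rna)
        targets[[length(targets) + 1]] <- data.frame(
          mirna = c(S, extra), target = r, stringsAsFactors = FALSE)
      }
      truth[[p]] <- canonical_pairs(utils::combn(members, 2)[1, ],
                                    utils::combn(members, 2)[2, ])
    }
    for (r in decoys) {
      X[r, ] <- stats::rnorm(ns, mean = 7, sd = 1)
      targets[[length(targets) + 1]] <- data.frame(
        mirna = sample(mirna_ids, config$decoy_mirnas_per_rna), target = r,
        stringsAsFactors = FALSE)
    }
    targets <- unique(do.call(rbind, targets))
    rownames(targets) <- NULL
    truth_pairs <- do.call(rbind, truth)
    # MRE records: one block of sites per miRNA-target interaction
    planted_set <- planted_rnas
    site_len <- 21L
    mre_rows <- lapply(seq_len(nrow(targets)), function(i) {
      n_sites <- if (targets$target[i] %in% planted_set) {
        sample(config$mre_per_interaction[1]:config$mre_per_interaction[2], 1)
      } else 1L
      start <- sample.int(3000L - site_len, n_sites, replace = TRUE)
      data.frame(mirna = targets$mirna[i], target = targets$target[i],
                 start = start, end = start + site_len,
                 energy = stats::runif(n_sites, config$energy_range[1],
                                       config$energy_range[2]),
                 stringsAsFactors = FALSE)
    })
    mre <- do.call(rbind, mre_rows)
    rownames(mre) <- NULL
    # survival hazard driven by the planted module's mean expression
    module_genes <- if (msize > 0) group_rnas[[np + 1]] else character(0)
    z <- if (msize > 0) {
      as.numeric(scale(colMeans(X[module_genes, , drop = FALSE])))
    } else {
      rep(0, ns)
    }
    # beta chosen so a median split of the (standard normal) risk score has
    # the configured group hazard ratio: E[z | top half] - E[z | bottom half]
    # = 2 * sqrt(2/pi) = 1.5958
    beta <- log(config$survival_hr) / 1.5958
    rate <- config$baseline_hazard * exp(beta * z)
    t_event <- stats::rexp(ns, rate = rate)
    if (config$censoring_rate > 0) {
      cens_rate <- config$baseline_hazard *
        config$censoring_rate / (1 - config$censoring_rate)
      t_cens <- stats::rexp(ns, rate = cens_rate)
    } else {
      t_cens <- rep(Inf, ns)
    }
    survival_tab <- data.frame(sample = sample_ids,
                               time = pmin(t_event, t_cens),
                               event = as.integer(t_event <= t_cens),
                               stringsAsFactors = FALSE)
    list(mirna_expr = Z, mrna_expr = X, targets = targets, mre = mre,
         truth_pairs = truth_pairs, survival = survival_tab,
         modules_truth = if (msize > 0) list(planted = module_genes)
                         else list(),
         shared_sets = shared_sets, config = config)
  })
}

#' Write a synthetic bundle to a directory in the package's standard formats
#'
#' @param bundle output of \code{\link{generate_sponge_data}}.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$mirna_expr, file.path(dir, "mirna_expr.tsv"))
  write_expression(bundle$mrna_expr, file.path(dir, "mrna_expr.tsv"))
  utils::write.table(bundle$targets, file.path(dir, "targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(bundle$mre, file.path(dir, "mre.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(bundle$truth_pairs, file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_survival(bundle$survival, file.path(dir, "survival.tsv"))
  write_modules(module_set(bundle$modules_truth, "planted"),
                file.path(dir, "modules_truth.tsv"))
  jsonlite::write_json(unclass(bundle$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Small fixed graphs for exercising the module-detection algorithms
#'
#' \itemize{
#'   \item \code{barbell_cliques}: two 4-cliques joined by a single edge
#'     (8 nodes, 13 edges);
#'   \item \code{two_triangles_shared_node}: two triangles sharing one node
#'     (5 nodes, 6 edges);
#'   \item \code{clique_plus_path}: a 5-clique with a pendant path of 3
#'     nodes (8 nodes, 13 edges);
#'   \item \code{planted_partition}: a fixed random graph with two blocks of
#'     12 nodes, within-block edge probability 0.9 and between-block 0.05
#'     (internal fixed seed, identical across calls).
#' }
#'
#' @param name graph name.
#' @return an igraph graph with named vertices; planted-partition vertices
#'   carry a \code{block} attribute.
#' @export
toy_graph <- function(name = c("barbell_cliques", "two_triangles_shared_node",
                               "clique_plus_path", "planted_partition")) {
  name <- match.arg(name)
  if (name == "barbell_cliques") {
    v1 <- paste0("a", 1:4)
    v2 <- paste0("b", 1:4)
    e <- rbind(t(utils::combn(v1, 2)), t(utils::combn(v2, 2)),
               c("a1", "b1"))
    return(igraph::graph_from_edgelist(e, directed = FALSE))
  }
  if (name == "two_triangles_shared_node") {
    e <- rbind(c("a", "b"), c("b", "x"), c("a", "x"),
               c("c", "d"), c("d", "x"), c("c", "x"))
    return(igraph::graph_from_edgelist(e, directed = FALSE))
  }
  if (name == "clique_plus_path") {
    cl <- paste0("c", 1:5)
    e <- rbind(t(utils::combn(cl, 2)),
               c("c1", "p1"), c("p1", "p2"), c("p2", "p3"))
    return(igraph::graph_from_edgelist(e, directed = FALSE))
  }
  # planted_partition
  with_seed(20190510, {
    blocks <- list(sprintf("u%02d", 1:12), sprintf("v%02d", 1:12))
    nodes <- unlist(blocks)
    pairs <- t(utils::combn(nodes, 2))
    same <- (pairs[, 1] %in% blocks[[1]]) == (pairs[, 2] %in% blocks[[1]])
    p_edge <- ifelse(same, 0.9, 0.05)
    keep <- stats::runif(nrow(pairs)) < p_edge
    g <- igraph::graph_from_edgelist(pairs[keep, , drop = FALSE],
                                     directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(nodes, igraph::V(g)$name)),
                              name = setdiff(nodes, igraph::V(g)$name))
    igraph::V(g)$block <- ifelse(igraph::V(g)$name %in% blocks[[1]], 1L, 2L)
    g
  })
}
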
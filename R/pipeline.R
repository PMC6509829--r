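default_run_config <- function() {
  list(
    seed = 1,
    out_dir = "spongenet_out",
    simulate = TRUE,
    simulate_config = list(),
    inputs = list(),            # targets, mirna_expr, mrna_expr, mre, truth,
                                # survival, gmt (file paths)
    log_transform = FALSE,
    methods = c("miRHomology", "pc", "sppc", "ppc", "hermes",
                "muTaME", "cernia"),
    p_cutoff = 0.05,
    sc_cutoff = 0.1,
    permutations = 100,
    score_cutoff = 0.5,
    min_shared = 1,
    min_vote = 3,
    module_algorithms = c("fn", "mcl", "linkcomm", "mcode"),
    module_min_size = 3,
    inflation = 2,
    vwp = 0.2,
    survival_p_cutoff = 0.05,
    survival_hr_cutoff = 1.5
  )
}

#' Read a pipeline run configuration
#'
#' YAML file with any subset of the run-configuration keys; unset keys take
#' the package defaults (p-value cutoffs 0.05, sensitivity-correlation
#' cutoff 0.1, 100 permutations, normalized-score cutoff 0.5, vote threshold
#' 3, module size cutoff 3).
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list applied on top of the file (flags win over
#'   the file).
#' @return a complete run-configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  overrides <- overrides[!vapply(overrides, is.null, logical(1))]
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full sponge-network pipeline
#'
#' Chains simulate (or load) -> candidate screening -> the selected
#' inference methods -> majority-vote integration -> module detection ->
#' validation / overlap / enrichment / survival, writing every stage's
#' output to \code{config$out_dir} along with a run-metadata JSON (seed,
#' resolved parameters, package version). All randomness flows from the
#' single seed, so a rerun with the same configuration produces identical
#' artifacts. A method whose required input is absent (e.g. cernia without
#' an MRE table) aborts with a stage-named error.
#'
#' @param config run configuration (see \code{\link{read_run_config}}).
#' @return invisibly, a list with the in-memory stage results and the
#'   artifact directory.
#' @export
run_pipeline <- function(config = read_run_config()) {
  cfg <- default_run_config()
  cfg[names(config)] <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  expr_methods <- c("pc", "sppc", "ppc", "hermes", "cernia")
  mre_methods <- c("muTaME", "cernia")

  if (isTRUE(cfg$simulate)) {
    sim_cfg <- do.call(synthetic_config,
                       c(cfg$simulate_config,
                         if (is.null(cfg$simulate_config$seed))
                           list(seed = cfg$seed)))
    bundle <- generate_sponge_data(sim_cfg)
    write_bundle(bundle, file.path(cfg$out_dir, "bundle"))
    targets <- bundle$targets
    mirna_expr <- bundle$mirna_expr
    mrna_expr <- bundle$mrna_expr
    mre <- bundle$mre
    truth <- bundle$truth_pairs
    surv <- bundle$survival
    gmt <- NULL
  } else {
    inp <- cfg$inputs
    if (is.null(inp$targets)) stop("stage load: a miRNA-target table is required")
    targets <- read_targets(inp$targets)
    mirna_expr <- if (!is.null(inp$mirna_expr))
      read_expression(inp$mirna_expr, cfg$log_transform) else NULL
    mrna_expr <- if (!is.null(inp$mrna_expr))
      read_expression(inp$mrna_expr, cfg$log_transform) else NULL
    mre <- if (!is.null(inp$mre)) read_mre_table(inp$mre) else NULL
    truth <- if (!is.null(inp$truth)) read_pair_table(inp$truth) else NULL
    surv <- if (!is.null(inp$survival)) read_survival(inp$survival) else NULL
    gmt <- if (!is.null(inp$gmt)) read_gmt(inp$gmt) else NULL
  }

  for (m in intersect(cfg$methods, expr_methods)) {
    if (is.null(mrna_expr)) {
      stop("stage infer/", m, ": gene expression data is required")
    }
  }
  for (m in intersect(cfg$methods, c("sppc", "ppc", "hermes"))) {
    if (is.null(mirna_expr)) {
      stop("stage infer/", m, ": miRNA expression data is required")
    }
  }
  for (m in intersect(cfg$methods, mre_methods)) {
    if (is.null(mre)) stop("stage infer/", m, ": an MRE table is required")
  }

  candidates <- candidate_pairs(targets, min_shared = cfg$min_shared,
                                p_cutoff = cfg$p_cutoff)
  networks <- list()
  for (m in cfg$methods) {
    net <- switch(m,
      miRHomology = candidates,
      pc = method_pc(candidates, mrna_expr, p_cutoff = cfg$p_cutoff),
      sppc = method_sppc(candidates, mirna_expr, mrna_expr,
                         sc_cutoff = cfg$sc_cutoff),
      ppc = method_competition(candidates, mirna_expr, mrna_expr, kind = "ppc",
                               m = cfg$permutations, p_cutoff = cfg$p_cutoff,
                               seed = cfg$seed),
      hermes = method_competition(candidates, mirna_expr, mrna_expr,
                                  kind = "hermes", m = cfg$permutations,
                                  p_cutoff = cfg$p_cutoff, seed = cfg$seed),
      muTaME = method_mutame(candidates, mre, targets,
                             cutoff = cfg$score_cutoff),
      cernia = method_cernia(candidates, mre, targets, mrna_expr,
                             cutoff = cfg$score_cutoff),
      stop("stage infer: unknown method '", m, "'"))
    networks[[m]] <- net
    write_network(net, file.path(cfg$out_dir,
                                 paste0("network_", m, ".tsv")))
  }

  integrated <- integrate_methods(networks, k = cfg$min_vote)
  write_network(integrated, file.path(cfg$out_dir, "network_integrate.tsv"))

  module_sets <- list()
  if (nrow(integrated) > 0) {
    g <- as_sponge_graph(integrated)
    for (alg in cfg$module_algorithms) {
      ms <- switch(alg,
        fn = fn_modules(g),
        mcl = mcl_modules(g, inflation = cfg$inflation),
        linkcomm = linkcomm_modules(g),
        mcode = mcode_modules(g, vwp = cfg$vwp),
        stop("stage modules: unknown algorithm '", alg, "'"))
      ms <- filter_modules(ms, min_size = cfg$module_min_size)
      module_sets[[alg]] <- ms
      write_modules(ms, file.path(cfg$out_dir,
                                  paste0("modules_", alg, ".tsv")))
    }
  }

  validation <- NULL
  if (!is.null(truth)) {
    validation <- lapply(c(networks, list(integrate = integrated)),
                         validate_network, truth = truth)
    vdf <- data.frame(method = names(validation),
                      n_predicted = vapply(validation, `[[`, numeric(1),
                                           "n_predicted"),
                      n_validated = vapply(validation, `[[`, numeric(1),
                                           "n_validated"),
                      percent_validated = vapply(validation, `[[`, numeric(1),
                                                 "percent_validated"))
    utils::write.table(vdf, file.path(cfg$out_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (length(networks) >= 2) {
    ov <- method_overlap(networks)
    utils::write.table(ov$exclusive, file.path(cfg$out_dir, "overlap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  enrichment <- NULL
  if (!is.null(gmt) && length(module_sets) > 0 && !is.null(mrna_expr)) {
    enrichment <- do.call(rbind, lapply(names(module_sets), function(alg) {
      e <- enrich_modules(module_sets[[alg]], gmt,
                          universe = rownames(mrna_expr))
      if (nrow(e) > 0) cbind(algorithm = alg, e) else NULL
    }))
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  surv_res <- NULL
  if (!is.null(surv) && length(module_sets) > 0 && !is.null(mrna_expr)) {
    surv_res <- do.call(rbind, lapply(names(module_sets), function(alg) {
      ms <- module_sets[[alg]]
      if (length(ms$modules) == 0) return(NULL)
      r <- module_survival(ms, mrna_expr, surv,
                           p_cutoff = cfg$survival_p_cutoff,
                           hr_cutoff = cfg$survival_hr_cutoff)
      if (nrow(r) > 0) cbind(algorithm = alg, r) else NULL
    }))
    if (!is.null(surv_res)) {
      utils::write.table(surv_res, file.path(cfg$out_dir, "survival.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  meta <- list(package = "spongenet",
               version = as.character(utils::packageVersion("spongenet")),
               seed = cfg$seed,
               config = cfg[setdiff(names(cfg), c("inputs", "out_dir"))])
  jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, candidates = candidates,
                 networks = networks, integrated = integrated,
                 modules = module_sets, validation = validation,
                 enrichment = enrichment, survival = surv_res))
}
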
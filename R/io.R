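#' Canonicalize unordered RNA pairs
#'
#' Every unordered RNA-RNA pair in the package is stored with its endpoints
#' sorted lexicographically (\code{rna_a < rna_b}), so that (A,B) and (B,A)
#' denote the same competing pair everywhere (inference, voting, validation).
#'
#' @param a,b character vectors of RNA identifiers (recycled to a common
#'   length). Identifiers are opaque, case-sensitive strings.
#' @return a data.frame with columns \code{rna_a}, \code{rna_b} in canonical
#'   order.
#' @examples
#' canonical_pairs(c("ZEB1", "PTEN"), c("PTEN", "ZEB1"))
#' @export
canonical_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (any(a == b)) {
    stop("self-pairs are not allowed: ", paste(unique(a[a == b]), collapse = ", "))
  }
  swap <- a > b
  data.frame(rna_a = ifelse(swap, b, a), rna_b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct a sponge network
#'
#' A sponge network is a data.frame of canonical, duplicate-free unordered
#' RNA pairs with per-method statistic columns and a \code{method} attribute.
#'
#' @param pairs data.frame with at least columns \code{rna_a}, \code{rna_b}
#'   (already canonical) plus statistic columns.
#' @param method character label of the method that produced the network.
#' @return an object of class \code{sponge_network} (a data.frame).
#' @export
sponge_network <- function(pairs, method) {
  stopifnot(is.data.frame(pairs), all(c("rna_a", "rna_b") %in% names(pairs)))
  if (nrow(pairs) > 0) {
    if (any(pairs$rna_a >= pairs$rna_b)) {
      stop("pairs must be canonical (rna_a < rna_b) and free of self-pairs")
    }
    if (anyDuplicated(pair_key(pairs$rna_a, pairs$rna_b))) {
      stop("duplicate pairs in network")
    }
  }
  rownames(pairs) <- NULL
  structure(pairs, method = method, class = c("sponge_network", "data.frame"))
}

#' @export
print.sponge_network <- function(x, ...) {
  cat(sprintf("sponge network [%s]: %d interactions\n",
              attr(x, "method"), nrow(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Construct a module set
#'
#' @param modules named list of character vectors (module members); names are
#'   ignored and modules are renumbered from 1.
#' @param method character label of the clustering method.
#' @return an object of class \code{module_set}.
#' @export
module_set <- function(modules, method) {
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  names(modules) <- if (length(modules)) as.character(seq_along(modules)) else character(0)
  structure(list(method = method, modules = modules), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, length, integer(1))
  cat(sprintf("module set [%s]: %d modules (sizes: %s)\n", x$method,
              length(x$modules), paste(sizes, collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix
#'
#' Expects a TSV with a header row of sample identifiers and gene identifiers
#' in the first column. Values are arbitrary expression units (e.g. FPKM or
#' log2 FPKM). Readers reject rather than coerce: duplicated identifiers,
#' non-numeric cells and missing values are hard errors (imputation is
#' upstream preprocessing, out of scope here).
#'
#' @param path file path.
#' @param log_transform if TRUE, apply log2(x + 1) after reading. Whether
#'   correlation analysis runs on the raw or log scale is a user choice; the
#'   pipeline default is to log-transform raw FPKM-like input.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression <- function(path, log_transform = FALSE) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expression table needs a gene column plus >= 1 sample")
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  if (anyDuplicated(genes)) {
    stop("duplicated gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(samples)) {
    stop("duplicated sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, samples)
  if (log_transform) num <- log2(num + 1)
  num
}

#' Write an expression matrix
#' @param mat numeric matrix (genes x samples).
#' @param path output file path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' TSV with two columns (miRNA, target); an optional header line is detected
#' by common column names. Duplicate edges are collapsed. By default the
#' miRNA and target namespaces must be disjoint.
#'
#' @param path file path.
#' @param allow_shared_namespace allow identifiers to appear on both sides.
#' @return data.frame with columns \code{mirna}, \code{target}.
#' @export
read_targets <- function(path, allow_shared_namespace = FALSE) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", blank.lines.skip = TRUE)
  if (ncol(df) < 2) stop("miRNA-target table needs at least 2 columns")
  if (nrow(df) > 0 &&
      tolower(df[1, 1]) %in% c("mirna", "mir", "mirna_id") ) {
    df <- df[-1, , drop = FALSE]
  }
  out <- unique(data.frame(mirna = df[[1]], target = df[[2]],
                           stringsAsFactors = FALSE))
  shared <- intersect(unique(out$mirna), unique(out$target))
  if (!allow_shared_namespace && length(shared) > 0) {
    stop("identifier(s) in both miRNA and target namespaces: ",
         paste(utils::head(shared, 5), collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Read an unordered RNA pair table (e.g. curated ground-truth sponge pairs)
#'
#' TSV with two identifier columns and an optional header. Pairs are
#' canonicalized (endpoints sorted) and deduplicated, so (A,B) and (B,A)
#' collapse to one entry. Self-pairs are rejected.
#'
#' @param path file path.
#' @return data.frame with canonical columns \code{rna_a}, \code{rna_b}.
#' @export
read_pair_table <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      colClasses = "character", quote = "",
                      comment.char = "", blank.lines.skip = TRUE),
    error = function(e) data.frame())
  if (nrow(df) == 0) {
    return(data.frame(rna_a = character(0), rna_b = character(0),
                      stringsAsFactors = FALSE))
  }
  if (ncol(df) < 2) stop("pair table needs at least 2 columns")
  if (tolower(df[1, 1]) %in% c("rna_a", "rna1", "rnaa", "gene1", "from")) {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    return(data.frame(rna_a = character(0), rna_b = character(0),
                      stringsAsFactors = FALSE))
  }
  cp <- canonical_pairs(df[[1]], df[[2]])
  cp <- unique(cp)
  rownames(cp) <- NULL
  cp
}

#' Read an MRE (miRNA response element) table
#'
#' TSV with columns miRNA, target, start, end, energy. Coordinates are
#' 1-based inclusive (miRanda-style). Sites with hybridization energy > 0
#' kcal/mol are dropped (only energies <= 0 are retained), and malformed rows
#' (non-numeric coordinates, start > end) are dropped; both counts are
#' reported via \code{message()} and stored in the \code{"n_dropped"}
#' attribute.
#'
#' @param path file path.
#' @return data.frame with columns \code{mirna}, \code{target}, \code{start},
#'   \code{end}, \code{energy}; multiple sites per (miRNA, target) pair are
#'   allowed.
#' @export
read_mre_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          comment.char = "", blank.lines.skip = TRUE)
  if (ncol(df) < 5) stop("MRE table needs 5 columns (miRNA, target, start, end, energy)")
  if (nrow(df) > 0 && is.na(suppressWarnings(as.numeric(df[1, 3])))) {
    df <- df[-1, , drop = FALSE]  # header line
  }
  start <- suppressWarnings(as.numeric(df[[3]]))
  end <- suppressWarnings(as.numeric(df[[4]]))
  energy <- suppressWarnings(as.numeric(df[[5]]))
  malformed <- is.na(start) | is.na(end) | is.na(energy) | start > end | start < 1
  positive <- !malformed & energy > 0
  keep <- !malformed & !positive
  n_malformed <- sum(malformed)
  n_positive <- sum(positive)
  if (n_malformed > 0) message(n_malformed, " malformed MRE row(s) dropped")
  if (n_positive > 0) message(n_positive, " MRE row(s) with energy > 0 dropped")
  out <- data.frame(mirna = df[[1]][keep], target = df[[2]][keep],
                    start = as.integer(start[keep]), end = as.integer(end[keep]),
                    energy = energy[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- c(malformed = n_malformed, positive_energy = n_positive)
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' name, description, member1, member2, ... Lines with fewer than 3 fields
#' are a hard error (reported with the line number).
#'
#' @param path file path.
#' @return object of class \code{gene_set_collection}: a list with
#'   \code{sets} (named list of character vectors) and \code{description}
#'   (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("malformed GMT line (fewer than 3 fields) at line ", short[1])
  }
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    stop("duplicated gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[[`, character(1), 2)
  names(desc) <- nm
  structure(list(sets = sets, description = desc),
            class = "gene_set_collection")
}

#' Write a GMT gene-set collection
#' @param gsc a \code{gene_set_collection} or named list of character vectors.
#' @param path output file path.
#' @export
write_gmt <- function(gsc, path) {
  if (inherits(gsc, "gene_set_collection")) {
    sets <- gsc$sets
    desc <- gsc$description
  } else {
    sets <- gsc
    desc <- stats::setNames(rep("na", length(sets)), names(sets))
  }
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns sample, time, event (0 = censored, 1 = event). Times
#' must be nonnegative and sample identifiers unique.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample}, \code{time}, \code{event}.
#' @export
read_survival <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric", "numeric"),
                          quote = "", comment.char = "")
  if (ncol(df) < 3) stop("survival table needs columns sample, time, event")
  names(df)[1:3] <- c("sample", "time", "event")
  if (anyDuplicated(df$sample)) {
    stop("duplicated sample identifier(s): ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  }
  if (any(is.na(df$time)) || any(df$time < 0)) stop("survival times must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (event)")
  df$event <- as.integer(df$event)
  df[, 1:3]
}

#' Write a survival table
#' @param surv data.frame with columns sample, time, event.
#' @param path output file path.
#' @export
write_survival <- function(surv, path) {
  utils::write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sponge network to TSV
#'
#' Emits a TSV with \code{method}, \code{rna_a}, \code{rna_b} and all
#' statistic columns; re-readable with \code{\link{read_network}}.
#'
#' @param net a \code{sponge_network}.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  df <- as.data.frame(net)
  df <- cbind(method = rep(attr(net, "method"), nrow(df)),
              df, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(method = character(0), rna_a = character(0),
                     rna_b = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sponge network written by \code{\link{write_network}}
#' @param path file path.
#' @return a \code{sponge_network}.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "",
                          colClasses = NA)
  method <- if (nrow(df) > 0) unique(df$method)[1] else "unknown"
  df$method <- NULL
  df$rna_a <- as.character(df$rna_a)
  df$rna_b <- as.character(df$rna_b)
  if ("shared_mirnas" %in% names(df)) {
    df$shared_mirnas <- as.character(df$shared_mirnas)
  }
  sponge_network(df, method)
}

#' Write a module set to TSV (module_id, method, member)
#' @param ms a \code{module_set}.
#' @param path output file path.
#' @export
write_modules <- function(ms, path) {
  rows <- do.call(rbind, c(list(data.frame(module_id = integer(0),
                                           method = character(0),
                                           member = character(0))),
                           lapply(seq_along(ms$modules), function(i) {
    data.frame(module_id = i, method = ms$method, member = ms$modules[[i]],
               stringsAsFactors = FALSE)
  })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module set written by \code{\link{write_modules}}
#' @param path file path.
#' @return a \code{module_set}.
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  method <- if (nrow(df) > 0) unique(df$method)[1] else "unknown"
  mods <- split(as.character(df$member), df$module_id)
  module_set(mods[order(as.integer(names(mods)))], method)
}
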
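#' Read GWAS summary statistics
#'
#' Reads a tab-separated GWAS summary file into the standard in-memory
#' layout (one row per SNP: id, effect allele, non-effect allele, z-score).
#' If the file carries effect sizes and standard errors instead of
#' z-scores, \code{z = beta / se} is computed. Rows with non-finite
#' statistics are dropped with a logged count.
#'
#' @param path path to a tab-separated file with a header row.
#' @param columnMap named character vector mapping the canonical column
#'   names \code{snp_id}, \code{effect_allele}, \code{non_effect_allele},
#'   and either \code{z} or both \code{beta} and \code{se} to the column
#'   names used in the file. Unmapped canonical names default to
#'   themselves.
#' @return data.frame with columns \code{snp_id}, \code{effect_allele},
#'   \code{non_effect_allele}, \code{z}.
#' @export
readGwasSummary <- function(path, columnMap = character()) {
  df <- .read_tsv(path)
  canon <- c("snp_id", "effect_allele", "non_effect_allele",
             "z", "beta", "se")
  map <- stats::setNames(canon, canon)
  if (length(columnMap) > 0) map[names(columnMap)] <- columnMap

  pick <- function(key) df[[map[[key]]]]
  for (key in c("snp_id", "effect_allele", "non_effect_allele")) {
    if (!map[[key]] %in% names(df))
      .stop_format("GWAS summary: missing mandatory column '%s'", map[[key]])
  }

  has_z <- map[["z"]] %in% names(df)
  if (!has_z) {
    for (key in c("beta", "se")) {
      if (!map[[key]] %in% names(df))
        .stop_format(
          "GWAS summary: no z column and missing mandatory column '%s'",
          map[[key]])
    }
  }

  out <- data.frame(
    snp_id = as.character(pick("snp_id")),
    effect_allele = toupper(as.character(pick("effect_allele"))),
    non_effect_allele = toupper(as.character(pick("non_effect_allele"))),
    stringsAsFactors = FALSE
  )
  if (has_z) {
    out$z <- as.numeric(pick("z"))
  } else {
    beta <- as.numeric(pick("beta"))
    se <- as.numeric(pick("se"))
    if (any(is.finite(se) & se <= 0))
      .stop_format("GWAS summary: non-positive standard error")
    out$z <- beta / se
  }

  bad_allele <- !(out$effect_allele %in% .valid_nt) |
    !(out$non_effect_allele %in% .valid_nt)
  keep <- is.finite(out$z) & !bad_allele
  if (any(!keep))
    .msg("readGwasSummary: dropped ", sum(!keep),
         " row(s) with non-finite statistics or non-ACGT alleles")
  out <- out[keep, , drop = FALSE]
  if (anyDuplicated(out$snp_id))
    .stop_format("GWAS summary: duplicate snp_id '%s'",
                 out$snp_id[anyDuplicated(out$snp_id)])
  rownames(out) <- NULL
  out
}

#' Write GWAS summary statistics
#'
#' @param gwas data.frame as returned by [readGwasSummary()].
#' @param path output path.
#' @export
writeGwasSummary <- function(gwas, path) {
  .require_columns(gwas, c("snp_id", "effect_allele", "non_effect_allele",
                           "z"), "GWAS summary")
  out <- gwas[, c("snp_id", "effect_allele", "non_effect_allele", "z")]
  out$z <- .fmt_num(out$z)
  .write_tsv(out, path)
}

# full-precision decimal representation so numeric round trips are exact
.fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read a SNP-to-gene prediction weight table
#'
#' Expects the PrediXcan weight-table schema: tab-separated with columns
#' \code{rsid}, \code{gene}, \code{weight}, \code{ref_allele},
#' \code{eff_allele}. Entries are grouped by gene; within each gene SNPs
#' are ordered lexicographically so the in-memory layout is deterministic.
#'
#' @param path path to the weight table.
#' @return a [PredictionModel-class] object.
#' @export
readPredictionModel <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("rsid", "gene", "weight", "ref_allele",
                         "eff_allele"), "prediction model")
  e <- data.frame(
    gene_id = as.character(df$gene),
    snp_id = as.character(df$rsid),
    weight = as.numeric(df$weight),
    ref_allele = toupper(as.character(df$ref_allele)),
    eff_allele = toupper(as.character(df$eff_allele)),
    stringsAsFactors = FALSE
  )
  if (nrow(e) == 0)
    warning("prediction model file has a header but no entries")
  key <- paste(e$gene_id, e$snp_id, sep = "\r")
  if (anyDuplicated(key))
    .stop_format("prediction model: duplicate (gene, rsid) pair: %s",
                 gsub("\r", "/", key[anyDuplicated(key)]))
  e <- e[order(e$gene_id, e$snp_id), , drop = FALSE]
  rownames(e) <- NULL
  new("PredictionModel", entries = e)
}

#' Write a prediction model as a PrediXcan-style weight table
#'
#' @param model a [PredictionModel-class].
#' @param path output path.
#' @export
writePredictionModel <- function(model, path) {
  e <- modelEntries(model)
  out <- data.frame(rsid = e$snp_id, gene = e$gene_id,
                    weight = .fmt_num(e$weight),
                    ref_allele = e$ref_allele, eff_allele = e$eff_allele)
  .write_tsv(out, path)
}

#' Read an LD reference SNP covariance file
#'
#' Reads whitespace-separated records \code{GENE RSID1 RSID2 VALUE}
#' (optionally gzip-compressed, detected by the \code{.gz} suffix). Either
#' triangle may be supplied; symmetric completion is implicit. Duplicate
#' records for the same unordered SNP pair must agree within 1e-10.
#'
#' @param path path to the covariance file.
#' @return a [SnpCovariance-class] object.
#' @export
readSnpCovariance <- function(path) {
  .check_file(path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
  } else con <- path
  df <- read.table(con, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  .require_columns(df, c("GENE", "RSID1", "RSID2", "VALUE"),
                   "SNP covariance")
  r <- data.frame(
    gene_id = as.character(df$GENE),
    snp_id_1 = as.character(df$RSID1),
    snp_id_2 = as.character(df$RSID2),
    value = as.numeric(df$VALUE),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(r$value)))
    .stop_format("SNP covariance: non-finite value")
  # canonical unordered pair key, per gene
  a <- pmin(r$snp_id_1, r$snp_id_2)
  b <- pmax(r$snp_id_1, r$snp_id_2)
  key <- paste(r$gene_id, a, b, sep = "\r")
  if (anyDuplicated(key)) {
    split_vals <- split(r$value, key)
    rng <- vapply(split_vals, function(v) diff(range(v)), numeric(1))
    if (any(rng > 1e-10)) {
      off <- names(rng)[which(rng > 1e-10)[1]]
      .stop_format(
        "SNP covariance: conflicting duplicate records for %s (|v1-v2| > 1e-10)",
        gsub("\r", " ", off))
    }
    keep <- !duplicated(key)
    .msg("readSnpCovariance: deduplicated ", sum(!keep),
         " consistent duplicate record(s)")
    r <- r[keep, , drop = FALSE]
  }
  if (any(r$value[r$snp_id_1 == r$snp_id_2] < 0))
    .stop_format("SNP covariance: negative diagonal (variance) entry")
  rownames(r) <- NULL
  new("SnpCovariance", records = r)
}

#' Write an LD reference SNP covariance file
#'
#' Writes one record per stored unordered SNP pair in the
#' \code{GENE RSID1 RSID2 VALUE} format. Gzip output is selected by a
#' \code{.gz} suffix.
#'
#' @param cov a [SnpCovariance-class].
#' @param path output path.
#' @export
writeSnpCovariance <- function(cov, path) {
  r <- cov@records
  out <- data.frame(GENE = r$gene_id, RSID1 = r$snp_id_1,
                    RSID2 = r$snp_id_2, VALUE = .fmt_num(r$value))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  write.table(out, con, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Assemble the dense covariance block of one gene
#'
#' Builds the symmetric SNP-by-SNP covariance matrix over a gene's model
#' SNPs. Pairs absent from the reference default to 0 (a diagonal-only
#' reference yields a diagonal block). The assembled block must be
#' positive semidefinite within tolerance 1e-8.
#'
#' @param cov a [SnpCovariance-class].
#' @param geneId gene whose block to assemble.
#' @param snpIds optional character vector restricting/ordering the SNPs;
#'   defaults to all SNPs seen for the gene, lexicographic order.
#' @return symmetric numeric matrix with SNP ids as dimnames.
#' @export
covarianceBlock <- function(cov, geneId, snpIds = NULL) {
  r <- cov@records[cov@records$gene_id == geneId, , drop = FALSE]
  if (nrow(r) == 0)
    .stop_format("no covariance records for gene '%s'", geneId)
  seen <- sort(unique(c(r$snp_id_1, r$snp_id_2)))
  snps <- if (is.null(snpIds)) seen else as.character(snpIds)
  m <- matrix(0, length(snps), length(snps), dimnames = list(snps, snps))
  i <- match(r$snp_id_1, snps)
  j <- match(r$snp_id_2, snps)
  ok <- !is.na(i) & !is.na(j)
  m[cbind(i[ok], j[ok])] <- r$value[ok]
  m[cbind(j[ok], i[ok])] <- r$value[ok]
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(1, max(diag(m)))
  if (min(ev) < -tol)
    .stop_format(
      "covariance block of gene '%s' is not positive semidefinite (min eigenvalue %.3g)",
      geneId, min(ev))
  m
}

#' Read a directed gene network from a two-column edge list
#'
#' The file must be tab-separated with a header and two columns
#' (parent, child). Duplicate edges are removed with a warning; the loaded
#' graph must be a directed acyclic graph (self-loops count as cycles).
#'
#' @param path path to the edge list.
#' @return an \pkg{igraph} directed graph.
#' @export
readNetwork <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2)
    .stop_format("network edge list must have two columns (parent, child)")
  edges <- data.frame(parent = as.character(df[[1]]),
                      child = as.character(df[[2]]),
                      stringsAsFactors = FALSE)
  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("network: removed %d duplicate edge(s)",
                    sum(duplicated(key))))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (any(igraph::which_loop(g))) {
    e <- edges[edges$parent == edges$child, ][1, ]
    .stop_format("network contains a self-loop: %s -> %s", e$parent, e$child)
  }
  if (!igraph::is_dag(g)) {
    cyc <- igraph::feedback_arc_set(g)
    ends <- igraph::ends(g, cyc[1])
    # report one cycle through a violating edge for the error message
    pth <- igraph::shortest_paths(g, from = ends[2], to = ends[1],
                                  mode = "out")$vpath[[1]]
    .stop_format("network is not acyclic; one cycle: %s -> %s",
                 paste(names(pth), collapse = " -> "), ends[2])
  }
  g
}

#' Write a directed gene network as a two-column edge list
#'
#' @param net an \pkg{igraph} directed graph.
#' @param path output path.
#' @export
writeNetwork <- function(net, path) {
  e <- igraph::as_data_frame(net, what = "edges")
  out <- data.frame(parent = e$from, child = e$to)
  .write_tsv(out, path)
}

#' Read a gene expression matrix
#'
#' Tab-separated, genes as rows; the first column holds gene ids, the
#' remaining columns one sample each. Gene ids must be unique, at least
#' two samples are required and no missing values are allowed.
#'
#' @param path path to the matrix file.
#' @return numeric matrix (genes x samples) with dimnames.
#' @export
readExpressionMatrix <- function(path) {
  .check_file(path)
  nf <- unique(utils::count.fields(path, sep = "\t", quote = "",
                                   comment.char = ""))
  if (length(nf) != 1)
    .stop_format("expression matrix has ragged rows (field counts: %s)",
                 paste(nf, collapse = ", "))
  df <- .read_tsv(path)
  if (ncol(df) < 3)
    .stop_format("expression matrix needs >= 2 sample columns")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes))
    .stop_format("expression matrix: duplicated gene id '%s'",
                 genes[anyDuplicated(genes)])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m))
    .stop_format("expression matrix contains missing values")
  rownames(m) <- genes
  m
}

#' Write a gene expression matrix
#'
#' @param expr numeric matrix (genes x samples) with dimnames.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            !is.null(colnames(expr)))
  out <- data.frame(gene_id = rownames(expr),
                    apply(expr, 2L, .fmt_num),
                    check.names = FALSE)
  .write_tsv(out, path)
}

#' Read an eigengene model from a module weight table
#'
#' Tab-separated with columns \code{module_id}, \code{gene_id},
#' \code{weight}, \code{gene_sd} (and optionally \code{gene_mean}).
#' Weight vectors are re-normalized to unit norm on load so externally
#' produced tables with arbitrary scaling are accepted.
#'
#' @param path path to the weight table.
#' @return an [EigengeneModel-class].
#' @export
readEigengeneModel <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("module_id", "gene_id", "weight", "gene_sd"),
                   "module weight table")
  df$module_id <- as.character(df$module_id)
  df$gene_id <- as.character(df$gene_id)
  mods <- split(df, df$module_id)
  # preserve first-appearance order of modules
  mods <- mods[unique(df$module_id)]
  modules <- lapply(mods, function(d) d$gene_id)
  weights <- lapply(mods, function(d) {
    w <- as.numeric(d$weight)
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) .stop_format("module '%s' has an all-zero weight vector",
                               d$module_id[1])
    w / nrm
  })
  gsd <- stats::setNames(as.numeric(df$gene_sd), df$gene_id)
  gmu <- if ("gene_mean" %in% names(df))
    stats::setNames(as.numeric(df$gene_mean), df$gene_id)
  else stats::setNames(numeric(nrow(df)), df$gene_id)
  new("EigengeneModel", modules = modules, weights = weights,
      geneMean = gmu, geneSd = gsd, unassigned = character())
}

#' Write an eigengene model as a module weight table
#'
#' @param model an [EigengeneModel-class].
#' @param path output path.
#' @export
writeEigengeneModel <- function(model, path) {
  rows <- lapply(names(model@modules), function(l) {
    g <- model@modules[[l]]
    data.frame(module_id = l, gene_id = g,
               weight = model@weights[[l]],
               gene_sd = unname(model@geneSd[g]),
               gene_mean = unname(model@geneMean[g]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weight <- .fmt_num(out$weight)
  out$gene_sd <- .fmt_num(out$gene_sd)
  out$gene_mean <- .fmt_num(out$gene_mean)
  .write_tsv(out, path)
}
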
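#' Detect co-expression modules (weighted correlation network analysis)
#'
#' Runs the classic unsigned weighted-correlation pipeline: rows are
#' standardized, Pearson correlation is raised to a soft-thresholding
#' power to give the adjacency \eqn{a_{ij} = |cor_{ij}|^{\beta}}, the
#' topological overlap measure (TOM) is computed, and average-linkage
#' hierarchical clustering of the TOM dissimilarity is cut at a fixed
#' height. Clusters smaller than \code{minModuleSize} are marked
#' unassigned (module 0). The whole stage is deterministic.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param softPower positive soft-thresholding exponent (default 6).
#' @param minModuleSize minimum genes per retained module (default 5,
#'   chosen to allow detection of small modules; must be >= 2).
#' @param cutHeight static tree-cut height on the TOM dissimilarity
#'   dendrogram, in (0, 1] (default 0.98).
#' @return named integer vector mapping each gene to a module id;
#'   0 denotes unassigned. Modules are numbered 1..K by decreasing size
#'   (ties broken by smallest member gene id).
#' @export
detectModules <- function(expr, softPower = 6, minModuleSize = 5,
                          cutHeight = 0.98) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3)
    .stop_format("module detection needs >= 3 samples")
  if (!is.numeric(minModuleSize) || minModuleSize < 2)
    .stop_format("minModuleSize must be >= 2")
  if (nrow(expr) < minModuleSize)
    .stop_format("fewer genes (%d) than minModuleSize (%d)",
                 nrow(expr), minModuleSize)
  if (!is.numeric(softPower) || softPower <= 0)
    .stop_format("softPower must be positive")
  if (!is.numeric(cutHeight) || cutHeight <= 0 || cutHeight > 1)
    .stop_format("cutHeight must be in (0, 1]")

  xs <- .standardize_rows(expr)
  a <- abs(cor(t(xs)))^softPower
  diag(a) <- 0
  tom <- .tomSimilarity(a)
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = cutHeight)

  genes <- rownames(expr)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  # deterministic, permutation-invariant labels: size desc, then smallest
  # member gene id
  firstGene <- vapply(keep, function(k) min(genes[cl == as.integer(k)]), "")
  ord <- order(-as.integer(sizes[keep]), firstGene)
  keep <- keep[ord]
  assign <- stats::setNames(integer(length(genes)), genes)
  for (i in seq_along(keep))
    assign[cl == as.integer(keep[i])] <- i
  assign
}

# unsigned topological overlap similarity; a has zero diagonal
.tomSimilarity <- function(a) {
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Fit eigengene loading weights for a module assignment
#'
#' For each module the member-gene profiles are standardized (mean 0,
#' unit variance) and the unit-norm loading vector of the first principal
#' component is extracted; the eigengene activity
#' \eqn{L_l = \sum_g R_{lg} \tilde T_g} then explains maximal variance
#' among unit-norm gene combinations. Loadings are sign-fixed so the
#' eigengene correlates non-negatively with the module's mean
#' standardized expression (tie: first nonzero loading positive). The
#' per-gene means and standard deviations observed at fit time are
#' stored in the model.
#'
#' @param expr numeric matrix, genes x samples.
#' @param modules named vector mapping gene id to module id; module 0 (or
#'   "0") marks unassigned genes. Every assigned gene must be a row of
#'   \code{expr}.
#' @return an [EigengeneModel-class].
#' @export
fitEigengeneWeights <- function(expr, modules) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.null(names(modules)))
    .stop_format("modules must be a named vector (gene id -> module id)")
  mod <- as.character(modules)
  names(mod) <- names(modules)
  assigned <- mod[mod != "0"]
  missing <- setdiff(names(assigned), rownames(expr))
  if (length(missing) > 0)
    .stop_format("module gene(s) absent from expression matrix: %s",
                 paste(head(missing, 5), collapse = ", "))

  ids <- unique(assigned)
  moduleList <- list()
  weightList <- list()
  for (l in ids) {
    g <- names(assigned)[assigned == l]
    x <- expr[g, , drop = FALSE]
    s <- apply(x, 1L, sd)
    if (any(s == 0))
      .stop_format("degenerate module '%s': constant gene(s) %s", l,
                   paste(head(g[s == 0], 5), collapse = ", "))
    xs <- (x - rowMeans(x)) / s
    sv <- svd(xs, nu = 1, nv = 0)
    w <- as.numeric(sv$u[, 1])
    L <- as.numeric(crossprod(w, xs))
    m <- colMeans(xs)
    cc <- if (sd(m) == 0 || sd(L) == 0) 0 else cor(L, m)
    if (cc < 0) {
      w <- -w
    } else if (cc == 0) {
      nz <- which(w != 0)[1]
      if (!is.na(nz) && w[nz] < 0) w <- -w
    }
    moduleList[[l]] <- g
    weightList[[l]] <- w
  }
  allg <- unlist(moduleList, use.names = FALSE)
  mu <- rowMeans(expr)[allg]
  s <- apply(expr[allg, , drop = FALSE], 1L, sd)
  names(s) <- allg
  new("EigengeneModel",
      modules = moduleList, weights = weightList,
      geneMean = mu, geneSd = s,
      unassigned = setdiff(names(mod)[mod == "0"], character()))
}

#' Eigengene activity of each module across samples
#'
#' Applies the loading vectors of an [EigengeneModel-class] to the
#' standardized expression of the module genes (standardization uses the
#' supplied matrix's own per-gene mean and standard deviation).
#'
#' @param model an [EigengeneModel-class].
#' @param expr numeric matrix, genes x samples, containing every model
#'   gene.
#' @return numeric matrix, modules x samples; rownames are module ids.
#' @export
eigengeneActivity <- function(model, expr) {
  validObject(model)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  missing <- setdiff(unlist(model@modules, use.names = FALSE),
                     rownames(expr))
  if (length(missing) > 0)
    .stop_format("gene(s) missing from expression matrix: %s",
                 paste(head(missing, 5), collapse = ", "))
  out <- matrix(NA_real_, length(model@modules), ncol(expr),
                dimnames = list(names(model@modules), colnames(expr)))
  for (l in names(model@modules)) {
    x <- expr[model@modules[[l]], , drop = FALSE]
    xs <- .standardize_rows(x)
    out[l, ] <- as.numeric(crossprod(model@weights[[l]], xs))
  }
  out
}
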
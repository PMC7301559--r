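#' Characteristic direction of a case/control expression comparison
#'
#' The characteristic direction is the unit vector that best separates
#' two Gaussian classes with a shared covariance: the direction
#' \eqn{v \propto \hat\Sigma^{-1}(\mu_1 - \mu_0)} along which the
#' log-ratio of class posteriors grows fastest (the class priors only
#' shift the constant and drop out of the direction). Because the gene
#' dimension typically exceeds the sample count, the pooled covariance
#' is shrunk toward a scaled identity:
#' \eqn{\hat\Sigma = (1-s)\,\Sigma_{pool} + s\,(tr(\Sigma_{pool})/p)\,I}.
#'
#' @param expr numeric matrix, genes x samples.
#' @param labels vector of 0/1 class labels per sample (0 = control,
#'   1 = case), at least two samples per class.
#' @param shrinkage shrinkage intensity in [0, 1], default 0.5.
#' @return a [CharacteristicDirection-class].
#' @export
characteristicDirection <- function(expr, labels, shrinkage = 0.5) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  labels <- as.integer(labels)
  if (length(labels) != ncol(expr))
    .stop_format("labels must have one entry per sample")
  if (!all(labels %in% c(0L, 1L)))
    .stop_format("labels must be 0 (control) or 1 (case)")
  n0 <- sum(labels == 0L); n1 <- sum(labels == 1L)
  if (n0 < 2 || n1 < 2)
    .stop_format("need at least 2 samples per class (got %d controls, %d cases)",
                 n0, n1)
  if (!is.numeric(shrinkage) || shrinkage < 0 || shrinkage > 1)
    .stop_format("shrinkage must lie in [0, 1]")

  x0 <- expr[, labels == 0L, drop = FALSE]
  x1 <- expr[, labels == 1L, drop = FALSE]
  dmu <- rowMeans(x1) - rowMeans(x0)
  if (all(dmu == 0))
    .stop_format("degenerate signature: class means are identical")
  p <- nrow(expr)
  s0 <- tcrossprod(x0 - rowMeans(x0))
  s1 <- tcrossprod(x1 - rowMeans(x1))
  pooled <- (s0 + s1) / (n0 + n1 - 2)
  sigma <- (1 - shrinkage) * pooled +
    shrinkage * (sum(diag(pooled)) / p) * diag(p)
  v <- tryCatch(solve(sigma, dmu), error = function(e)
    .stop_format(
      "shared covariance is singular; increase shrinkage above 0 (%s)",
      conditionMessage(e)))
  v <- v / sqrt(sum(v^2))
  new("CharacteristicDirection", geneIds = rownames(expr),
      direction = as.numeric(v))
}

#' Cosine similarity of two characteristic directions
#'
#' \eqn{d(v_1, v_2) = \langle v_1, v_2\rangle / (||v_1||\,||v_2||)},
#' computed over the intersection of the two gene universes after
#' re-normalizing the restricted vectors.
#'
#' @param v1,v2 [CharacteristicDirection-class] objects.
#' @return numeric in [-1, 1].
#' @export
cosineDistance <- function(v1, v2) {
  common <- intersect(v1@geneIds, v2@geneIds)
  if (length(common) == 0)
    .stop_format("cosineDistance: signatures share no genes")
  a <- v1@direction[match(common, v1@geneIds)]
  b <- v2@direction[match(common, v2@geneIds)]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    .stop_format("cosineDistance: zero vector on the shared gene set")
  sum(a * b) / (na * nb)
}

#' Empirical null distribution of cosine distances to a target signature
#'
#' Samples \code{n} characteristic directions — with replacement from a
#' user-supplied signature pool when one is given, otherwise isotropic
#' random unit vectors on the target's gene universe — and records their
#' cosine distances to the target. The mean and standard deviation of
#' this empirical distribution are later used to normalize observed
#' distances.
#'
#' @param target the [CharacteristicDirection-class] being matched
#'   against.
#' @param n number of sampled directions (>= 100; default 10000).
#' @param seed integer seed for reproducibility.
#' @param pool optional list of [CharacteristicDirection-class] objects
#'   to resample from.
#' @return object of class \code{NullDistribution}: list with
#'   \code{samples}, \code{mean}, \code{sd}, \code{n}, \code{seed}.
#' @export
buildNullDistribution <- function(target, n = 10000, seed = 1,
                                  pool = NULL) {
  if (!is.numeric(n) || n < 100)
    .stop_format("null distribution needs n >= 100 samples")
  if (!is.null(pool) && length(pool) == 0)
    .stop_format("empty signature pool")
  set.seed(seed)
  if (is.null(pool)) {
    p <- length(target@geneIds)
    m <- matrix(rnorm(n * p), n, p)
    m <- m / sqrt(rowSums(m^2))
    d <- as.numeric(m %*% target@direction)
  } else {
    idx <- sample.int(length(pool), n, replace = TRUE)
    d <- vapply(idx, function(i) cosineDistance(pool[[i]], target),
                numeric(1))
  }
  s <- sd(d)
  if (s == 0)
    .stop_format("degenerate null distribution (sd = 0)")
  structure(list(samples = d, mean = mean(d), sd = s, n = as.integer(n),
                 seed = seed),
            class = "NullDistribution")
}

#' Normalize a cosine distance against an empirical null
#'
#' @param d observed cosine distance.
#' @param null a \code{NullDistribution} from [buildNullDistribution()].
#' @return \code{(d - mean(null)) / sd(null)}.
#' @export
normalizeAgainstNull <- function(d, null) {
  stopifnot(inherits(null, "NullDistribution"))
  if (null$sd <= 0)
    .stop_format("null distribution has zero standard deviation")
  (d - null$mean) / null$sd
}

#' Match perturbation signatures against disease signatures
#'
#' For every (perturbation, disease) signature pair, the cosine distance
#' is normalized against an empirical null built for that disease
#' signature; strongly correlated or anticorrelated pairs (normalized
#' distance large in absolute value) are hit candidates. With
#' \code{adjust = TRUE} (default) two-sided normal p-values of the
#' normalized scores are Holm-Sidak corrected over all pairs involving a
#' perturbation, and the perturbation is a hit when any pair survives at
#' \code{alpha}; with \code{adjust = FALSE} the bare
#' \eqn{|normalized| > 1.96} rule is applied instead.
#'
#' @param perturbationSigs named list of
#'   [CharacteristicDirection-class] (e.g. one per gene perturbation).
#' @param diseaseSigs named list of [CharacteristicDirection-class].
#' @param nNull null sample size per disease signature (default 10000).
#' @param seed integer seed.
#' @param alpha significance level for adjusted p-values (default 0.05).
#' @param adjust apply Holm-Sidak over pairs per perturbation (default
#'   TRUE).
#' @param pool optional signature pool passed to
#'   [buildNullDistribution()].
#' @return list with \code{hits} (named logical per perturbation) and
#'   \code{pairs} (data.frame of all pair-level results).
#' @export
callLincsHits <- function(perturbationSigs, diseaseSigs, nNull = 10000,
                          seed = 1, alpha = 0.05, adjust = TRUE,
                          pool = NULL) {
  if (length(perturbationSigs) == 0 || length(diseaseSigs) == 0)
    .stop_format("callLincsHits: empty signature list")
  if (is.null(names(perturbationSigs)))
    names(perturbationSigs) <- paste0("pert_", seq_along(perturbationSigs))
  if (is.null(names(diseaseSigs)))
    names(diseaseSigs) <- paste0("disease_", seq_along(diseaseSigs))

  nulls <- lapply(seq_along(diseaseSigs), function(j)
    buildNullDistribution(diseaseSigs[[j]], n = nNull,
                          seed = seed + j - 1, pool = pool))
  rows <- list()
  for (i in names(perturbationSigs)) {
    for (j in seq_along(diseaseSigs)) {
      d <- cosineDistance(perturbationSigs[[i]], diseaseSigs[[j]])
      nz <- normalizeAgainstNull(d, nulls[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        perturbation = i, disease = names(diseaseSigs)[j],
        cosine = d, normalized = nz,
        p_value = pmax(2 * pnorm(-abs(nz)), .Machine$double.xmin),
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- NA_real_
  hits <- logical(length(perturbationSigs))
  names(hits) <- names(perturbationSigs)
  for (i in names(perturbationSigs)) {
    sel <- pairs$perturbation == i
    if (adjust) {
      pairs$p_adjusted[sel] <- holmSidakAdjust(pairs$p_value[sel])
      hits[i] <- any(pairs$p_adjusted[sel] < alpha)
    } else {
      hits[i] <- any(abs(pairs$normalized[sel]) > 1.96)
    }
  }
  list(hits = hits, pairs = pairs)
}
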
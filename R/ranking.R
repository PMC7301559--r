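#' Downstream genes of a node in a directed network
#'
#' All nodes reachable from \code{g0} along directed edges, excluding
#' \code{g0} itself.
#'
#' @param net directed \pkg{igraph} graph (see [readNetwork()]).
#' @param g0 node name.
#' @param directChildrenOnly if TRUE, return only the immediate children
#'   rather than the full descendant set.
#' @return character vector of node names.
#' @export
descendantGenes <- function(net, g0, directChildrenOnly = FALSE) {
  if (!g0 %in% igraph::V(net)$name)
    .stop_format("node '%s' is not in the network", g0)
  if (directChildrenOnly) {
    nb <- igraph::neighbors(net, g0, mode = "out")
    return(setdiff(names(nb), g0))
  }
  reach <- igraph::subcomponent(net, g0, mode = "out")
  setdiff(names(reach), g0)
}

#' Hypergeometric overrepresentation test for two gene sets
#'
#' Builds the 2x2 contingency table of two sets over a common background
#' (\eqn{a = |S_1 \cap S_2|}, \eqn{b = |S_1 \setminus S_2|},
#' \eqn{c = |S_2 \setminus S_1|}, \eqn{d = |B \setminus (S_1 \cup S_2)|}),
#' reports the enrichment odds ratio \eqn{OR = (a/b)/(c/d)} and the
#' one-sided upper-tail hypergeometric p-value: the sum of point
#' probabilities
#' \deqn{p(a) = \frac{(a+b)!(c+d)!(a+c)!(b+d)!}{n!\,a!\,b!\,c!\,d!}}
#' over all tables with the observed margins and overlap >= a. The
#' one-sided tail tests the alternative OR > 1. When \eqn{b = 0} or
#' \eqn{c = 0} the odds ratio is reported as \code{Inf} and flagged; the
#' exact p-value is unaffected.
#'
#' @param s1,s2 character vectors (subsets of \code{background}).
#' @param background character vector, the gene universe (nonempty).
#' @return one-row data.frame with columns \code{a}, \code{b}, \code{c},
#'   \code{d}, \code{odds_ratio}, \code{or_infinite}, \code{p_value},
#'   \code{n_s1}, \code{n_s2}, \code{n_background}.
#' @export
overrepresentationTest <- function(s1, s2, background) {
  if (length(background) == 0)
    .stop_format("overrepresentationTest: empty background")
  background <- unique(background)
  s1 <- unique(s1)
  s2 <- unique(s2)
  if (length(setdiff(s1, background)) > 0)
    .stop_format("overrepresentationTest: s1 is not a subset of the background")
  if (length(setdiff(s2, background)) > 0)
    .stop_format("overrepresentationTest: s2 is not a subset of the background")

  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  c_ <- length(setdiff(s2, s1))
  d <- length(background) - a - b - c_

  data.frame(
    a = a, b = b, c = c_, d = d,
    odds_ratio = .oddsRatio(a, b, c_, d),
    or_infinite = (b == 0 || c_ == 0),
    p_value = .hyperUpperTail(a, b, c_, d),
    n_s1 = length(s1), n_s2 = length(s2),
    n_background = length(background)
  )
}

.oddsRatio <- function(a, b, c_, d) {
  if (b == 0 || c_ == 0) return(Inf)
  (a / b) / (c_ / d)
}

# hypergeometric point probability of a 2x2 table, by the factorial form
.hyperPointProb <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  exp(lfactorial(a + b) + lfactorial(c_ + d) + lfactorial(a + c_) +
        lfactorial(b + d) - lfactorial(n) - lfactorial(a) -
        lfactorial(b) - lfactorial(c_) - lfactorial(d))
}

# one-sided upper tail at fixed margins: P(overlap >= a)
.hyperUpperTail <- function(a, b, c_, d) {
  amax <- min(a + b, a + c_)
  ks <- a:amax
  p <- sum(vapply(ks, function(k)
    .hyperPointProb(k, a + b - k, a + c_ - k, d - a + k), numeric(1)))
  min(p, 1)
}

#' Rank putative causal (driver) genes on a directed network
#'
#' For each network node with at least one downstream gene inside the
#' background, tests whether its downstream set is overrepresented in
#' the significant-component gene set. The background is
#' \eqn{B = \{\mathrm{model\ genes}\} \cap \{\mathrm{network\ nodes}\}},
#' \eqn{S_1} the component genes within B, and \eqn{S_2} the candidate's
#' descendants within B. P-values are Holm-Sidak adjusted across all
#' candidates tested in the run; a candidate is significant when its
#' adjusted p-value is below \code{alpha} and its odds ratio exceeds 1.
#'
#' @param net directed \pkg{igraph} graph.
#' @param componentGenes genes belonging to significant components (see
#'   [gwasComponentGenes()]).
#' @param modelGenes genes with a prediction model (defines the
#'   background together with the network).
#' @param alpha significance level, default 0.05.
#' @param directChildrenOnly use immediate children instead of the full
#'   downstream set (default FALSE).
#' @return data.frame ordered by rank, one row per tested candidate:
#'   \code{candidate}, contingency cells, \code{odds_ratio},
#'   \code{or_infinite}, \code{p_value}, \code{p_adjusted},
#'   \code{significant}, \code{rank}.
#' @export
rankTargets <- function(net, componentGenes, modelGenes, alpha = 0.05,
                        directChildrenOnly = FALSE) {
  nodes <- igraph::V(net)$name
  background <- intersect(unique(modelGenes), nodes)
  if (length(background) == 0)
    .stop_format("rankTargets: empty background (model genes and network nodes do not intersect)")
  s1 <- intersect(unique(componentGenes), background)

  candidates <- sort(nodes)
  rows <- list()
  for (g0 in candidates) {
    s2 <- intersect(descendantGenes(net, g0, directChildrenOnly),
                    background)
    if (length(s2) == 0) next
    r <- overrepresentationTest(s1, s2, background)
    r <- cbind(candidate = g0, r)
    rows[[g0]] <- r
  }
  if (length(rows) == 0)
    return(data.frame(candidate = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      odds_ratio = numeric(), or_infinite = logical(),
                      p_value = numeric(), p_adjusted = numeric(),
                      significant = logical(), rank = integer()))
  out <- do.call(rbind, rows)
  out$n_s1 <- NULL; out$n_s2 <- NULL; out$n_background <- NULL
  out$p_adjusted <- holmSidakAdjust(out$p_value)
  out$significant <- out$p_adjusted < alpha & out$odds_ratio > 1
  ord <- order(out$p_value, -out$odds_ratio, out$candidate)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Phenotype overrepresentation against disease-model phenotype sets
#'
#' Tests whether the phenotypes associated with a gene candidate overlap
#' the phenotypes of each disease model more than expected by chance
#' (one hypergeometric test per model, Holm-Sidak adjusted across
#' models). The candidate is a hit when at least one model's adjusted
#' p-value is below \code{alpha} with odds ratio above 1.
#'
#' @param candidatePhenotypes phenotype set of the gene candidate.
#' @param modelPhenotypes list of phenotype sets, one per disease model.
#' @param background the phenotype universe.
#' @param alpha significance level, default 0.05.
#' @return list with elements \code{hit} (logical) and \code{results}
#'   (data.frame, one row per disease model).
#' @export
phenotypeEnrichment <- function(candidatePhenotypes, modelPhenotypes,
                                background, alpha = 0.05) {
  if (length(modelPhenotypes) == 0)
    .stop_format("phenotypeEnrichment: no disease models supplied")
  if (is.null(names(modelPhenotypes)))
    names(modelPhenotypes) <- paste0("model_", seq_along(modelPhenotypes))
  rows <- lapply(names(modelPhenotypes), function(nm) {
    r <- overrepresentationTest(candidatePhenotypes,
                                modelPhenotypes[[nm]], background)
    cbind(disease_model = nm, r)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holmSidakAdjust(out$p_value)
  out$enriched <- out$p_adjusted < alpha & out$odds_ratio > 1
  rownames(out) <- NULL
  list(hit = any(out$enriched), results = out)
}
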
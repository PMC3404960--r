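# Recovery metrics against simulation ground truth.

.truthLocusOf <- function(readIds) {
  vapply(strsplit(readIds, "|", fixed = TRUE), function(p)
    if (length(p) >= 2L) p[[2L]] else NA_character_, character(1))
}

#' Majority truth locus of a cluster
#'
#' For reads simulated with the `<line>|<locus>|<idx>` id convention,
#' the truth locus most of the cluster's members trace to.
#'
#' @param cluster a [SeqCluster-class].
#' @return locus id (character).
#' @export
clusterTruthLocus <- function(cluster) {
  loc <- .truthLocusOf(cluster@members$read)
  tab <- table(loc)
  names(tab)[which.max(tab)]
}

#' Cluster purity and completeness against truth
#'
#' Fraction of clusters whose members are exactly the clustered reads of
#' one truth locus (no foreign reads, and no clusterable read of that
#' locus missing). The universe is the union of cluster members, so a
#' read whose feature went undetected (and which therefore never entered
#' clustering) does not count against the clustering step.
#'
#' @param clusters list of [SeqCluster-class].
#' @return fraction in \[0, 1\].
#' @export
clusterExactFraction <- function(clusters) {
  allReads <- unlist(lapply(clusters, function(cl) cl@members$read))
  byLocus <- split(allReads, .truthLocusOf(allReads))
  mean(vapply(clusters, function(cl) {
    loc <- clusterTruthLocus(cl)
    setequal(cl@members$read, byLocus[[loc]])
  }, logical(1)))
}

#' Sensitivity and specificity of the SSR polymorphism call
#'
#' A truth locus counts as "called polymorphic" when any cluster whose
#' majority of members trace to it yields a polymorphic SSR candidate.
#' Sensitivity is the called fraction of truly polymorphic loci;
#' specificity the not-called fraction of truly non-polymorphic loci.
#'
#' @param candidates data.frame from [screenClusters()].
#' @param clusters the list of [SeqCluster-class] the candidates came
#'   from.
#' @param truth a [SimTruth-class].
#' @return list with `sensitivity`, `specificity` and the per-locus
#'   call table.
#' @export
evaluateSsrCalls <- function(candidates, clusters, truth) {
  names(clusters) <- vapply(clusters, function(cl) cl@id, character(1))
  cand <- candidates[candidates$marker_type == "SSR", , drop = FALSE]
  cand$truth_locus <- vapply(cand$cluster_id, function(id)
    clusterTruthLocus(clusters[[id]]), character(1))
  tt <- ssrTruth(truth)
  called <- vapply(tt$locus, function(l)
    any(cand$class[cand$truth_locus == l] == "polymorphic"), logical(1))
  list(sensitivity = mean(called[tt$polymorphic]),
       specificity = mean(!called[!tt$polymorphic]),
       calls = data.frame(locus = tt$locus, truth = tt$polymorphic,
                          called = called))
}

#' Adjacent-pair order concordance between two locus orders
#'
#' Fraction of adjacent pairs of the reference order that are also
#' adjacent (in either orientation) in the test order. Loci absent from
#' the test order break their reference pairs.
#'
#' @param reference,order character vectors of locus ids.
#' @return fraction in \[0, 1\].
#' @export
adjacentConcordance <- function(reference, order) {
  refPairs <- paste(pmin(reference[-length(reference)], reference[-1L]),
                    pmax(reference[-length(reference)], reference[-1L]))
  ordPairs <- paste(pmin(order[-length(order)], order[-1L]),
                    pmax(order[-length(order)], order[-1L]))
  mean(refPairs %in% ordPairs)
}
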
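#' Median ISI signature of one condition
#'
#' The position-wise median of the successive intra-burst ISI values along
#' the response, taken across repetition trials.  Positions are kept while
#' at least `coverage` of the trials still have a value at that position,
#' so ragged trial lengths do not truncate the signature to the shortest
#' trial.
#'
#' @param trial_isis List of per-trial ISI vectors (temporal order).
#' @param coverage Minimum fraction of trials required per position.
#' @return Numeric signature vector (ms).
#' @export
median_signature <- function(trial_isis, coverage = 0.5) {
  trial_isis <- trial_isis[lengths(trial_isis) > 0]
  if (!length(trial_isis))
    stop("no trial contributes intra-burst ISIs", call. = FALSE)
  lens <- lengths(trial_isis)
  n <- length(trial_isis)
  max_pos <- max(lens)
  keep <- vapply(seq_len(max_pos),
                 function(p) sum(lens >= p) / n >= coverage, logical(1))
  len <- if (any(keep)) max(which(keep)) else 0L
  if (len == 0L) stop("coverage rule leaves an empty signature",
                      call. = FALSE)
  vapply(seq_len(len), function(p) {
    median(vapply(trial_isis[lens >= p], `[`, numeric(1), p))
  }, numeric(1))
}

#' Spearman rank-correlation distance
#'
#' `1 - rho_spearman(u, v)`, in `[0, 2]`.  Vectors of unequal length are
#' truncated to the common length before ranking.
#'
#' @param u,v Numeric vectors (common length >= 3).
#' @return Distance in `[0, 2]`.
#' @export
spearman_distance <- function(u, v) {
  len <- min(length(u), length(v))
  if (len < 3) stop("need at least 3 common positions", call. = FALSE)
  u <- u[seq_len(len)]; v <- v[seq_len(len)]
  if (sd(rank(u)) == 0 || sd(rank(v)) == 0)
    stop("zero-variance rank vector", call. = FALSE)
  1 - cor(u, v, method = "spearman")
}

#' Build a signature matrix from per-condition ISI signatures
#'
#' @param signatures List of signature vectors (possibly ragged).
#' @param arrangement,delay Vectors of condition labels, one per row.
#' @return Object of class `signature_matrix`.
#' @export
signature_matrix <- function(signatures, arrangement, delay) {
  stopifnot(length(signatures) == length(arrangement),
            length(signatures) == length(delay))
  if (any(lengths(signatures) == 0))
    stop("empty signature row", call. = FALSE)
  labels <- paste(arrangement, delay, sep = "_")
  structure(list(signatures = signatures, arrangement = arrangement,
                 delay = delay, labels = labels),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", length(x$signatures), "conditions, lengths",
      min(lengths(x$signatures)), "-", max(lengths(x$signatures)), "\n")
  invisible(x)
}

#' Pairwise Spearman distances of a signature matrix
#' @param sm A [signature_matrix()] object.
#' @return A `dist` object.
#' @export
signature_distances <- function(sm) {
  stopifnot(inherits(sm, "signature_matrix"))
  n <- length(sm$signatures)
  d <- matrix(0, n, n, dimnames = list(sm$labels, sm$labels))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    d[i, j] <- d[j, i] <- spearman_distance(sm$signatures[[i]],
                                            sm$signatures[[j]])
  }
  as.dist(d)
}

#' Complete-linkage clustering of median ISI signatures
#'
#' Agglomerates the conditions by complete linkage on the pairwise
#' Spearman rank-correlation distances.  Deterministic; equal-height
#' merges follow the lowest-index rule of the agglomeration backend.
#'
#' @param sm A [signature_matrix()] with at least two rows.
#' @return Object of class `ca1_dendrogram` wrapping the `hclust` tree and
#'   the condition metadata.
#' @export
cluster_signatures <- function(sm) {
  stopifnot(inherits(sm, "signature_matrix"))
  if (length(sm$signatures) < 2) stop("need at least two signatures",
                                      call. = FALSE)
  d <- signature_distances(sm)
  if (any(!is.finite(d))) stop("undefined pairwise distance", call. = FALSE)
  hc <- hclust(d, method = "complete")
  structure(list(hclust = hc, labels = sm$labels,
                 arrangement = sm$arrangement, delay = sm$delay),
            class = "ca1_dendrogram")
}

#' @export
print.ca1_dendrogram <- function(x, ...) {
  cat("ca1_dendrogram:", length(x$labels),
      "leaves (complete linkage, Spearman distance)\n")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the complete-linkage merge heights.
#'
#' @param dend A [cluster_signatures()] result.
#' @param path Optional file path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "ca1_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Leaf separation of arrangements in a dendrogram
#'
#' Counts how many leaves fall in arrangement-coherent subtrees: a leaf
#' scores as separated if, at the smallest enclosing cluster containing
#' more than one leaf, all members share its arrangement.  Used to check
#' that clustered- and diffused-input responses occupy distinct
#' sub-clusters.
#'
#' @param dend A [cluster_signatures()] result.
#' @return Integer count of separated leaves (out of `length(dend$labels)`).
#' @export
arrangement_separation <- function(dend) {
  stopifnot(inherits(dend, "ca1_dendrogram"))
  hc <- dend$hclust
  n <- length(dend$labels)
  members <- vector("list", nrow(hc$merge))
  leaf_ok <- logical(n)
  leaf_seen <- logical(n)
  for (k in seq_len(nrow(hc$merge))) {
    mm <- hc$merge[k, ]
    get <- function(m) if (m < 0) -m else members[[m]]
    members[[k]] <- c(get(mm[1]), get(mm[2]))
    arr <- dend$arrangement[members[[k]]]
    pure <- length(unique(arr)) == 1L
    for (leaf in members[[k]]) {
      if (!leaf_seen[leaf]) {
        leaf_ok[leaf] <- pure
        leaf_seen[leaf] <- TRUE
      }
    }
  }
  sum(leaf_ok)
}

#' Classify a new response pattern against reference signatures
#'
#' Assigns a new median ISI signature the arrangement of its nearest
#' reference condition (Spearman distance) and the delay-range sub-cluster
#' (short vs long) that condition belongs to.  Ties resolve to the
#' lowest-index reference row.
#'
#' @param signature Numeric signature vector (length >= 3).
#' @param sm Reference [signature_matrix()].
#' @param short_cutoff Boundary (ms) between the short- and long-delay
#'   sub-clusters.
#' @return List: `arrangement`, `delay_range` (`"short"`/`"long"`),
#'   `nearest` label, `distance`, and `margin` to the runner-up.
#' @export
classify_new_pattern <- function(signature, sm, short_cutoff = 120) {
  stopifnot(inherits(sm, "signature_matrix"))
  if (length(signature) < 3)
    stop("signature needs at least 3 positions", call. = FALSE)
  d <- vapply(sm$signatures, function(ref)
    spearman_distance(signature, ref), numeric(1))
  best <- which.min(d)
  ord <- sort(d)
  list(arrangement = sm$arrangement[best],
       delay_range = if (sm$delay[best] <= short_cutoff) "short" else "long",
       nearest = sm$labels[best],
       distance = d[best],
       margin = if (length(ord) > 1) ord[2] - ord[1] else NA_real_)
}

#' Decode the SLM-SR delay from a time-to-first-spike value
#'
#' Inverse interpolation on the monotone reference curve of median
#' SLM-referenced time-to-first-spike versus delay for the called
#' arrangement.  The latency relative to the SLM input grows linearly with
#' the delay (the response is driven by the later SR input), so within the
#' reference envelope the inversion is well posed.
#'
#' @param ttfs Observed time-to-first-spike (ms, relative to SLM onset).
#' @param arrangement Arrangement call for the pattern.
#' @param reference Data frame with columns `arrangement`, `delay`,
#'   `ttfs_median` (SLM-referenced medians).
#' @return Estimated delay (ms); values outside the reference envelope
#'   return `NA` with attribute `extrapolated = TRUE`.
#' @export
ttfs_decoder <- function(ttfs, arrangement, reference) {
  ref <- reference[reference$arrangement == arrangement, , drop = FALSE]
  if (!nrow(ref)) stop("no reference curve for arrangement '",
                       arrangement, "'", call. = FALSE)
  ref <- ref[order(ref$delay), ]
  if (is.unsorted(ref$ttfs_median))
    warning("reference ttfs curve is not monotone; inversion may be ambiguous")
  if (ttfs < min(ref$ttfs_median) || ttfs > max(ref$ttfs_median))
    return(structure(NA_real_, extrapolated = TRUE))
  approx(ref$ttfs_median, ref$delay, xout = ttfs, ties = "ordered")$y
}
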
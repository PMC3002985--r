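#' Synaptic contact counts per compartment class
#'
#' Fixed composition of the model cell: numbers of NMDA, AMPA, GABA-A and
#' GABA-B contacts on the SR apical trunk, SR oblique dendrites, the SLM
#' layer and the soma.  The soma receives only inhibitory input.
#'
#' @return Integer matrix (4 compartment classes x 4 receptor types).
#' @export
ca1_synapse_counts <- function() {
  m <- matrix(c(
    48, 48, 16, 16,
    62, 62,  2,  2,
    27, 27,  5,  5,
     0,  0,  5,  5), nrow = 4, byrow = TRUE,
    dimnames = list(c("SR_trunk", "SR_oblique", "SLM", "soma"),
                    c("NMDA", "AMPA", "GABA_A", "GABA_B")))
  storage.mode(m) <- "integer"
  m
}

#' The four spatial arrangements
#' @export
ca1_arrangements <- function() {
  c("fully_diffused", "fully_clustered", "SR_clustered", "SLM_clustered")
}

#' Generate a synapse layout
#'
#' Assigns the fixed synaptic contacts ([ca1_synapse_counts()]) to dendritic
#' subunits (branches) of the two receiving layers under one of four spatial
#' arrangements.  Diffused layers scatter contacts uniformly over all
#' branches of the layer; clustered layers divide the contacts into equal
#' groups placed on 8 uniformly chosen SR branches or 4 SLM branches (a
#' non-divisible remainder is dealt one contact at a time to the first
#' chosen branches).  Somatic inhibitory contacts are unaffected by the
#' arrangement.  Each branch also receives a multiplicative gain drawn from
#' a log-normal distribution, representing branch-to-branch heterogeneity.
#'
#' @param arrangement One of [ca1_arrangements()].
#' @param seed Integer seed; the same seed always yields the same layout.
#' @param n_sr_branches,n_slm_branches Number of dendritic subunits per
#'   layer (SR pools the trunk and oblique compartments).
#' @param n_sr_cluster,n_slm_cluster Branches used by the clustered
#'   arrangements.
#' @param branch_sd Log-scale s.d. of the per-branch gain.
#' @return An object of class `ca1_layout` with per-branch contact counts,
#'   branch gains, the full count matrix and the assignment metadata.
#' @export
generate_layout <- function(arrangement = ca1_arrangements(), seed,
                            n_sr_branches = 20L, n_slm_branches = 10L,
                            n_sr_cluster = 8L, n_slm_cluster = 4L,
                            branch_sd = 0.15) {
  arrangement <- match.arg(arrangement)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (n_sr_cluster > n_sr_branches || n_slm_cluster > n_slm_branches)
    stop("cluster count exceeds the branch pool", call. = FALSE)

  counts <- ca1_synapse_counts()
  sr_exc <- sum(counts[c("SR_trunk", "SR_oblique"), "AMPA"])
  sr_gabaa <- sum(counts[c("SR_trunk", "SR_oblique"), "GABA_A"])
  sr_gabab <- sum(counts[c("SR_trunk", "SR_oblique"), "GABA_B"])
  slm_exc <- counts["SLM", "AMPA"]
  slm_gabaa <- counts["SLM", "GABA_A"]
  slm_gabab <- counts["SLM", "GABA_B"]

  sr_clustered <- arrangement %in% c("fully_clustered", "SR_clustered")
  slm_clustered <- arrangement %in% c("fully_clustered", "SLM_clustered")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))

  assign_layer <- function(n_contacts, n_branches, clustered, n_cluster) {
    if (clustered) {
      branches <- sample.int(n_branches, n_cluster)
      per <- rep(n_contacts %/% n_cluster, n_cluster)
      rem <- n_contacts %% n_cluster
      if (rem > 0) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
      cnt <- integer(n_branches)
      cnt[branches] <- per
      cnt
    } else {
      tabulate(sample.int(n_branches, n_contacts, replace = TRUE),
               nbins = n_branches)
    }
  }

  sr_exc_cnt <- assign_layer(sr_exc, n_sr_branches, sr_clustered, n_sr_cluster)
  sr_gabaa_cnt <- assign_layer(sr_gabaa, n_sr_branches, sr_clustered,
                               n_sr_cluster)
  sr_gabab_cnt <- assign_layer(sr_gabab, n_sr_branches, sr_clustered,
                               n_sr_cluster)
  slm_exc_cnt <- assign_layer(slm_exc, n_slm_branches, slm_clustered,
                              n_slm_cluster)
  slm_gabaa_cnt <- assign_layer(slm_gabaa, n_slm_branches, slm_clustered,
                                n_slm_cluster)
  slm_gabab_cnt <- assign_layer(slm_gabab, n_slm_branches, slm_clustered,
                                n_slm_cluster)
  gain_sr <- exp(rnorm(n_sr_branches, 0, branch_sd))
  gain_slm <- exp(rnorm(n_slm_branches, 0, branch_sd))

  structure(list(
    arrangement = arrangement, seed = as.integer(seed),
    counts = counts,
    sr_exc = sr_exc_cnt, sr_gabaa = sr_gabaa_cnt, sr_gabab = sr_gabab_cnt,
    slm_exc = slm_exc_cnt, slm_gabaa = slm_gabaa_cnt,
    slm_gabab = slm_gabab_cnt,
    soma_gabaa = counts["soma", "GABA_A"], soma_gabab = counts["soma", "GABA_B"],
    gain_sr = gain_sr, gain_slm = gain_slm,
    n_sr_branches = as.integer(n_sr_branches),
    n_slm_branches = as.integer(n_slm_branches),
    branch_sd = branch_sd
  ), class = "ca1_layout")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Total contact counts of a layout, by compartment class
#'
#' Reconstructs the per-class totals from the branch assignment, for
#' checking conservation of the fixed composition.
#'
#' @param layout A `ca1_layout` object.
#' @return Named list with per-layer totals.
#' @export
layout_totals <- function(layout) {
  stopifnot(inherits(layout, "ca1_layout"))
  list(sr_exc = sum(layout$sr_exc),
       sr_gabaa = sum(layout$sr_gabaa), sr_gabab = sum(layout$sr_gabab),
       slm_exc = sum(layout$slm_exc),
       slm_gabaa = sum(layout$slm_gabaa), slm_gabab = sum(layout$slm_gabab),
       soma_gabaa = layout$soma_gabaa, soma_gabab = layout$soma_gabab)
}

#' @export
print.ca1_layout <- function(x, ...) {
  cat("Synapse layout:", x$arrangement, "(seed", x$seed, ")\n")
  cat("  SR:", sum(x$sr_exc), "excitatory contacts on",
      sum(x$sr_exc > 0), "of", x$n_sr_branches, "branches\n")
  cat("  SLM:", sum(x$slm_exc), "excitatory contacts on",
      sum(x$slm_exc > 0), "of", x$n_slm_branches, "branches\n")
  invisible(x)
}
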
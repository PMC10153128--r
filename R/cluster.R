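#' Cluster-mass permutation test on depth x frequency difference maps
#'
#' Nonparametric test of within-subject condition differences. The null
#' distribution is generated by randomly flipping the sign of each subject's
#' difference map (equivalent to shuffling the condition labels within
#' subject). The observed mean map is z-scored pointwise against the
#' permutation distribution, thresholded at `|z| > z_crit`, and contiguous
#' supra-threshold bins (4-neighbourhood by default, separately per sign)
#' are summed into cluster masses. Each permutation's map is z-scored and
#' clustered identically, and its maximum absolute cluster mass -- pooled
#' over both signs -- forms the null. A cluster with
#' `p = (1 + #\{null >= |mass|\}) / (n_perm + 1)` below `2 * alpha` (0.025
#' per tail) is significant; this is the max-statistic correction over the
#' whole depth x frequency plane.
#'
#' @param diff_maps subjects x depth x frequency array of within-subject
#'   condition differences (e.g. deviant minus control seed maps). NA cells
#'   (such as seed-to-seed diagonals) are treated as zero signal.
#' @param n_perm number of permutations (>= 100).
#' @param z_crit cluster-forming threshold.
#' @param alpha per-tail significance level.
#' @param adjacency 4 or 8 neighbourhood.
#' @param seed RNG seed for the sign flips.
#' @return list of class `"cluster_test"`: `clusters` (list with members,
#'   mass, sign, p, significant), `z_obs`, `null_max`, and the parameters.
#' @export
cluster_permutation <- function(diff_maps, n_perm = 2500, z_crit = 1.96,
                                alpha = 0.025, adjacency = 4, seed = 1) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  d <- dim(diff_maps)
  if (length(d) != 3) stop("diff_maps must be subjects x depth x frequency")
  ns <- d[1]
  if (ns < 5) stop("need at least 5 subjects")
  M <- matrix(diff_maps, ns, d[2] * d[3])
  M[is.na(M)] <- 0
  if (all(M == 0))
    return(structure(list(clusters = list(), z_obs = matrix(0, d[2], d[3]),
                          null_max = numeric(0), n_perm = n_perm,
                          z_crit = z_crit, alpha = alpha),
                     class = "cluster_test"))
  obs <- colMeans(M)
  S <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * ns, replace = TRUE),
                              n_perm, ns))
  P <- (S %*% M) / ns                     # permutation mean maps
  mu <- colMeans(P)
  sg <- sqrt(pmax(colMeans(P^2) - mu^2, 0))
  sg[sg == 0] <- Inf                      # constant cells carry no evidence
  z_obs <- matrix((obs - mu) / sg, d[2], d[3])
  null_max <- vapply(seq_len(n_perm), function(i) {
    z <- matrix((P[i, ] - mu) / sg, d[2], d[3])
    .max_cluster_mass(z, z_crit, as.integer(adjacency))
  }, numeric(1))
  lab <- .label_clusters(z_obs, z_crit, as.integer(adjacency))
  clusters <- list()
  for (k in seq_along(lab$mass)) {
    members <- which(lab$labels == k, arr.ind = TRUE)
    colnames(members) <- c("depth", "frequency")
    p <- (1 + sum(null_max >= abs(lab$mass[k]))) / (n_perm + 1)
    clusters[[k]] <- list(members = members, mass = lab$mass[k],
                          sign = if (lab$sign[k] > 0) "positive" else "negative",
                          p = p, significant = p < 2 * alpha)
  }
  ord <- order(vapply(clusters, function(cl) cl$p, numeric(1)))
  structure(list(clusters = clusters[ord], z_obs = z_obs, null_max = null_max,
                 n_perm = n_perm, z_crit = z_crit, alpha = alpha),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations\n",
              length(x$clusters), x$n_perm))
  for (cl in head(x$clusters, 5))
    cat(sprintf("  %s mass %.1f, %d bins, p = %.4f%s\n", cl$sign, cl$mass,
                nrow(cl$members), cl$p, if (cl$significant) " *" else ""))
  invisible(x)
}
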
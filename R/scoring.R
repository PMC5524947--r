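# Per-particle alignment quality statistics: angular clusterability (alpha),
# accuracy (chi), Monte-Carlo noise references, linear quality mappings and
# the global Q value.

#' Angular clusterability of a particle's best matches
#'
#' Weighted mean pairwise geodesic distance among the directions of the
#' top-xi most similar map projections:
#' alpha = sum_{k != n} w_n w_k d(p_n, p_k) / sum_{k != n} w_n w_k,
#' with d the symmetry-aware great-circle angle. Small alpha means the
#' matches cluster tightly: the particle aligns with precision.
#'
#' @param ms A \code{MatchSet} (see [global_search()]), or any list with
#'   \code{directions} (xi x 3) and \code{weights}.
#' @param sym A [symmetry_group()].
#' @return Clusterability in radians.
#' @export
clusterability_alpha <- function(ms, sym = symmetry_group("C1")) {
  w <- ms$weights
  xi <- length(w)
  if (xi < 2) stop("invalid input: clusterability needs at least 2 matches")
  W <- tcrossprod(w)
  diag(W) <- 0
  if (all(W == 0)) stop("degenerate input: all match weights are zero")
  D <- geodesic_cross(ms$directions, ms$directions, sym)
  sum(W * D) / sum(W)
}

#' Accuracy statistic: distance from the refined orientation to the matches
#'
#' Weighted mean symmetry-aware geodesic distance between the particle's
#' previously refined projection direction and the directions of its top-xi
#' matches: chi = sum_k w_k d(p_hat, p_k) / sum_k w_k. Small chi means the
#' global search agrees with the refined orientation: the particle aligns
#' with accuracy.
#'
#' @param p_hat Unit 3-vector, the refined projection direction.
#' @param ms A \code{MatchSet}.
#' @param sym A [symmetry_group()].
#' @return Accuracy statistic in radians, in [0, pi].
#' @export
accuracy_chi <- function(p_hat, ms, sym = symmetry_group("C1")) {
  w <- ms$weights
  if (length(w) < 1 || sum(w) == 0)
    stop("degenerate input: zero match weight sum")
  d <- geodesic_distance(rbind(p_hat)[rep(1, length(w)), ], ms$directions, sym)
  sum(w * d) / sum(w)
}

#' Monte-Carlo noise reference for the clusterability statistic
#'
#' Models the worst case in which every orientation in the asymmetric unit
#' is equally likely: draws xi uniform random directions with unit weights,
#' evaluates [clusterability_alpha()], and averages over M repeats.
#'
#' @param xi Number of directions per draw (>= 2).
#' @param M Number of Monte-Carlo repeats (~500).
#' @param sym A [symmetry_group()].
#' @param seed Integer seed; deterministic given (xi, M, sym, seed).
#' @return Mean clusterability in radians, with attributes \code{se}
#'   (Monte-Carlo standard error) and \code{draws} (the M values).
#' @export
noise_alpha_reference <- function(xi = 7, M = 500, sym = symmetry_group("C1"),
                                  seed = 1L) {
  stopifnot(xi >= 2, M >= 1)
  dirs <- random_directions_in_au(xi * M, sym, seed)
  vals <- vapply(seq_len(M), function(i) {
    idx <- ((i - 1) * xi + 1):(i * xi)
    clusterability_alpha(list(directions = dirs[idx, , drop = FALSE],
                              weights = rep(1, xi)), sym)
  }, numeric(1))
  structure(mean(vals), se = stats::sd(vals) / sqrt(M), draws = vals)
}

#' Monte-Carlo noise reference for the accuracy statistic
#'
#' Compares a fixed refined direction with xi uniform random directions in
#' the asymmetric unit (unit weights), averaged over M repeats. Computed at
#' the particle's own direction because, for non-trivial symmetry, the
#' distance-to-uniform distribution depends on where in the asymmetric unit
#' the direction sits; for C1 it is position independent.
#'
#' @param p_hat Unit 3-vector, the refined projection direction.
#' @inheritParams noise_alpha_reference
#' @return Mean accuracy statistic in radians, with attributes \code{se} and
#'   \code{draws}.
#' @export
noise_chi_reference <- function(p_hat, xi = 7, M = 500,
                                sym = symmetry_group("C1"), seed = 1L) {
  stopifnot(xi >= 1, M >= 1)
  dirs <- random_directions_in_au(xi * M, sym, seed)
  d <- geodesic_distance(rbind(p_hat)[rep(1, nrow(dirs)), ], dirs, sym)
  per_rep <- rowMeans(matrix(d, M, xi, byrow = TRUE))
  structure(mean(per_rep), se = stats::sd(per_rep) / sqrt(M), draws = per_rep)
}

## Two-point linear mapping sending ref0 -> 0 and ref1 -> 1, NOT clamped.
linear_quality <- function(x, ref1, ref0) {
  if (abs(ref1 - ref0) < 1e-9) return(NA_real_)   # degenerate reference
  (x - ref0) / (ref1 - ref0)
}

#' Precision quality score
#'
#' The unique straight line through (alpha_noise, 0) and (alpha_good, 1)
#' evaluated at the particle's clusterability. Values are deliberately not
#' clamped to [0, 1]: scores beyond 1 (tighter clustering than the perfect
#' reference) are reported as-is.
#'
#' @param alpha_m Particle clusterability, radians.
#' @param alpha_good Perfect-reference clusterability, radians.
#' @param alpha_noise Noise-reference clusterability, radians.
#' @return Dimensionless score; \code{NA} when the two references coincide
#'   within 1e-9 (degenerate reference).
#' @export
precision_score <- function(alpha_m, alpha_good, alpha_noise) {
  linear_quality(alpha_m, alpha_good, alpha_noise)
}

#' Accuracy quality score
#'
#' The straight line through (chi_noise, 0) and (chi_good, 1) evaluated at
#' the particle's accuracy statistic; not clamped.
#'
#' @param chi_m Particle accuracy statistic, radians.
#' @param chi_good Perfect-reference accuracy statistic, radians.
#' @param chi_noise Noise-reference accuracy statistic, radians.
#' @return Dimensionless score; \code{NA} on degenerate references.
#' @export
accuracy_score <- function(chi_m, chi_good, chi_noise) {
  linear_quality(chi_m, chi_good, chi_noise)
}

#' Global Q value: percentage of reliable particles
#'
#' Percentage of particles whose precision and accuracy scores are both at
#' least \code{tau}. Particles with degenerate (NA) scores count as failing.
#'
#' @param scores Data frame with columns \code{q_p} and \code{q_a} (a
#'   \code{ValidationReport}'s \code{scores} element works directly).
#' @param tau Score threshold, default 0.5.
#' @return Q in [0, 100].
#' @export
q_value <- function(scores, tau = 0.5) {
  if (inherits(scores, "ValidationReport")) scores <- scores$scores
  if (NROW(scores) == 0) stop("invalid input: empty score table")
  pass <- !is.na(scores$q_p) & !is.na(scores$q_a) &
    scores$q_p >= tau & scores$q_a >= tau
  100 * sum(pass) / NROW(scores)
}

#' Select particles passing the score threshold
#'
#' @param report A \code{ValidationReport} (see [validate_particles()]) or
#'   its \code{scores} data frame.
#' @param tau Score threshold, default 0.5.
#' @return Integer indices of particles with both scores >= tau.
#' @export
prune <- function(report, tau = 0.5) {
  scores <- if (inherits(report, "ValidationReport")) report$scores else report
  which(!is.na(scores$q_p) & !is.na(scores$q_a) &
          scores$q_p >= tau & scores$q_a >= tau)
}
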
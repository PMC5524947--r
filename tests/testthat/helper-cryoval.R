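# Shared test utilities: independent brute-force oracles for the scoring
# statistics, a rank-based ROC area, and random MatchSet generators.

## Brute-force double-loop clusterability (independent of the implementation)
brute_alpha <- function(dirs, w, sym = symmetry_group("C1")) {
  xi <- length(w)
  num <- 0; den <- 0
  for (k in seq_len(xi)) {
    for (n in seq_len(xi)) {
      if (n == k) next
      d <- min(vapply(sym$ops, function(R)
        acos(min(1, max(-1, sum(dirs[n, ] * (R %*% dirs[k, ]))))), numeric(1)))
      num <- num + w[n] * w[k] * d
      den <- den + w[n] * w[k]
    }
  }
  num / den
}

## Brute-force accuracy statistic
brute_chi <- function(p_hat, dirs, w, sym = symmetry_group("C1")) {
  num <- 0
  for (k in seq_along(w)) {
    d <- min(vapply(sym$ops, function(R)
      acos(min(1, max(-1, sum(p_hat * (R %*% dirs[k, ]))))), numeric(1)))
    num <- num + w[k] * d
  }
  num / sum(w)
}

## Uniform random unit vectors (full sphere)
random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  a <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(a), s * sin(a), z)
}

random_matchset <- function(xi = 7) {
  list(directions = random_unit_vectors(xi),
       weights = sort(stats::runif(xi, 0.05, 1), decreasing = TRUE))
}

## Rank-based area under the ROC curve (Mann-Whitney form)
rank_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">")) + 0.5 * mean(outer(pos, neg, "=="))
}

## Small cubic test volume: one centred isotropic Gaussian blob
gaussian_blob_volume <- function(n = 32, sigma = 4, voxel = 1) {
  ax <- (0:(n - 1)) - n / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  map_volume(g %o% g %o% g, voxel)
}
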
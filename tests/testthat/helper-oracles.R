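# Independent brute-force oracles. These deliberately re-derive each
# quantity by the most literal route (all-pairs loops, direct summation)
# so they share no code with the implementations they check.

oracle_prefix_min <- function(w) {
  vapply(seq_along(w), function(k) min(w[seq_len(k)]), numeric(1))
}

# direct summation of the non-centered, lag-count-normalized estimator
oracle_autocorr <- function(eta, tau_max = length(eta) - 1L) {
  n <- length(eta)
  denom <- sum(eta^2) / n
  if (denom == 0) {
    return(rep(0, tau_max + 1L))
  }
  vapply(0:tau_max, function(tau) {
    acc <- 0
    for (t in seq_len(n - tau)) acc <- acc + eta[t] * eta[t + tau]
    (acc / (n - tau)) / denom
  }, numeric(1))
}

# all-pairs count of water oxygens within cutoff of any residue atom
oracle_count <- function(residue_coords, water_oxygens, cutoff) {
  rc <- as.matrix(residue_coords)
  wo <- as.matrix(water_oxygens)
  if (nrow(wo) == 0L) {
    return(0L)
  }
  hit <- logical(nrow(wo))
  for (j in seq_len(nrow(wo))) {
    for (i in seq_len(nrow(rc))) {
      if (sqrt(sum((rc[i, ] - wo[j, ])^2)) <= cutoff) {
        hit[j] <- TRUE
        break
      }
    }
  }
  sum(hit)
}

oracle_max_radius <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  max(apply(coords, 1L, function(p) sqrt(sum((p - ctr)^2))))
}

# all-pairs distance histogram for the RDF cross-check (no normalization)
oracle_pair_histogram <- function(a, b, box, breaks) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  box <- rep_len(box, 3L)
  dists <- c()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- a[i, ] - b[j, ]
      d <- d - round(d / box) * box
      dd <- sqrt(sum(d^2))
      if (dd > 1e-9 && dd < max(breaks)) dists <- c(dists, dd)
    }
  }
  graphics::hist(dists, breaks = breaks, plot = FALSE)$counts
}
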
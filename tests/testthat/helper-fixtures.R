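# Shared fixtures, all built in code at test time.

# Adjusted Rand index via mclust (independent of the package under test).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two Gaussian blobs separated by `shift` SDs on every feature.
make_two_blobs <- function(n = 100, p = 16, shift = 10, seed = 1) {
  set.seed(seed)
  truth <- rep(1:2, length.out = n)
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  x[, truth == 2] <- x[, truth == 2] + shift
  list(x = x, truth = truth)
}

# Three equidistant blobs: centers are `d` times three orthonormal
# directions, so all pairwise center distances equal d * sqrt(2).
make_three_blobs <- function(n = 90, p = 16, d = 6, seed = 1) {
  set.seed(seed)
  truth <- rep(1:3, length.out = n)
  v <- qr.Q(qr(matrix(rnorm(p * 3), p, 3)))
  x <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("f%02d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  list(x = x + (d * v)[, truth], truth = truth)
}

# Small labelled expression matrix with a given number of shifted genes.
make_de_matrix <- function(n_genes = 200, n_per_group = 20, n_true = 20,
                           shift = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  labels <- rep(c("A", "B"), each = n_per_group)
  if (n_true > 0) x[seq_len(n_true), labels == "A"] <-
      x[seq_len(n_true), labels == "A"] + shift
  list(x = x, labels = labels, true_genes = rownames(x)[seq_len(n_true)])
}

# Exponential survival with a binary group effect and exponential censoring.
make_survival <- function(n = 100, hr = 2, base = 0.1, censor_rate = 0.3,
                          seed = 1) {
  set.seed(seed)
  group <- rbinom(n, 1, 0.5)
  haz <- base * hr^group
  t_ev <- rexp(n, haz)
  t_c <- rexp(n, censor_rate / (1 - censor_rate) * mean(haz))
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c),
       group = group)
}

# Two batches whose per-gene batch effects are exactly homogeneous:
# within-batch noise is empirically standardized per gene, and batch 2 is
# batch 1 plus a constant. Under this construction the EB posterior
# coincides with the exact location adjustment.
make_homogeneous_batches <- function(G = 300, n = 50, shift = 2, seed = 1) {
  set.seed(seed)
  noise <- matrix(rnorm(G * n), G, n)
  noise <- t(scale(t(noise)))
  b1 <- noise + rnorm(G, 8, 0.5)
  x <- cbind(b1, b1 + shift)
  dimnames(x) <- list(sprintf("g%03d", seq_len(G)),
                      sprintf("s%03d", seq_len(2 * n)))
  list(x = x, batch = rep(c("a", "b"), each = n))
}
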
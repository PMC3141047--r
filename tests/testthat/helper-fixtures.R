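# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# small random table: n compounds, p independent standard-normal
# descriptors, activity = linear signal on the first `k` + noise
random_table <- function(n, p, k = min(3L, p), noise_sd = 0.2,
                         seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  beta <- c(seq(2, 1, length.out = k), rep(0, p - k))
  y <- 7 + drop(X %*% beta) + rnorm(n, sd = noise_sd)
  descriptor_table(X, y)
}

write_fixture_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  path
}

# path graph on n atoms, single element
path_graph <- function(n, element = "C") {
  bonds <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
           else NULL
  molecular_graph(rep(element, n), bonds)
}

# star K_{1, n-1}: atom 1 is the hub
star_graph <- function(n, element = "C") {
  molecular_graph(rep(element, n), cbind(1L, seq.int(2L, n)))
}

# Erdos-Renyi-ish random connected-enough graph for eigenvalue checks
random_graph <- function(n_atoms, p_edge = 0.35, seed = 1L) {
  set.seed(seed)
  pairs <- t(combn(n_atoms, 2L))
  keep <- runif(nrow(pairs)) < p_edge
  bonds <- pairs[keep, , drop = FALSE]
  molecular_graph(rep("C", n_atoms),
                  if (nrow(bonds)) bonds else NULL)
}

# independent leading-eigenvalue oracle: shifted power iteration on the
# adjacency matrix built directly from the bond list (the +nI shift makes
# the leading eigenvalue strictly dominant, so bipartite +-lambda pairs
# cannot stall the iteration)
power_iteration_lambda <- function(g, iters = 5000L) {
  n <- length(g$elements)
  A <- matrix(0, n, n)
  if (nrow(g$bonds)) {
    A[g$bonds] <- 1
    A[g$bonds[, 2:1, drop = FALSE]] <- 1
  }
  B <- A + diag(n, n)
  v <- rep(1, n) + seq_len(n) * 1e-3
  lam <- n
  for (i in seq_len(iters)) {
    w <- B %*% v
    v <- w / sqrt(sum(w^2))
    lam_new <- drop(crossprod(v, B %*% v))
    if (abs(lam_new - lam) < 1e-13) { lam <- lam_new; break }
    lam <- lam_new
  }
  lam - n
}
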
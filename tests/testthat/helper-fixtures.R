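# shared fixtures built in code

zscore <- function(v) (v - mean(v)) / stats::sd(v)

# small two-network partition for hand-checkable cases
tiny_partition <- function() {
  tibble::tibble(node_id = 1:4,
                 node_label = paste0("n", 1:4),
                 network = c("A", "A", "B", "B"))
}

# random symmetric nonnegative z-matrix with zero diagonal
random_fc <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n * n, 0, 0.8), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random partition of n nodes into k networks, >= 2 nodes each
random_partition <- function(n, k, seed) {
  set.seed(seed)
  repeat {
    net <- sample(paste0("net", seq_len(k)), n, replace = TRUE)
    if (all(table(net) >= 2) && length(unique(net)) == k) break
  }
  tibble::tibble(node_id = seq_len(n), network = net)
}

# brute-force segregation oracle: explicit double loop over node pairs
segregation_oracle <- function(fc, partition) {
  membership <- as.character(partition$network)
  purrr::map_dfr(unique(membership), function(net) {
    w_sum <- 0; w_n <- 0; b_sum <- 0; b_n <- 0
    n <- nrow(fc)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (membership[i] == net && membership[j] == net) {
          w_sum <- w_sum + fc[i, j]; w_n <- w_n + 1
        } else if (xor(membership[i] == net, membership[j] == net)) {
          b_sum <- b_sum + fc[i, j]; b_n <- b_n + 1
        }
      }
    }
    w <- w_sum / w_n; b <- b_sum / b_n
    tibble::tibble(network = net, w_net = w, b_net = b, sys = (w - b) / w)
  })
}

# simulate directly from a moderation model (standard-normal predictors)
simulate_moderation_data <- function(n, b1, b2, b3, noise_sd = 1, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n); w <- stats::rnorm(n)
  tibble::tibble(x = x, w = w,
                 y = b1 * x + b2 * w + b3 * x * w +
                   stats::rnorm(n, 0, noise_sd))
}
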
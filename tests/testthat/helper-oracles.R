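# Independent oracles used by the unit and acceptance tests.

# Tip partial-likelihood rows (indicator for observed, ones for missing).
oracle_tip_partials <- function(tr, tip_states, states) {
  n_tip <- length(tr$tip.label)
  L <- matrix(1, n_tip, length(states))
  for (i in seq_len(n_tip)) {
    s <- tip_states[tr$tip.label[i]]
    if (!is.na(s)) {
      L[i, ] <- 0
      L[i, match(s, states)] <- 1
    }
  }
  L
}

# Brute-force likelihood and marginal posteriors by explicit summation over
# all internal-node state assignments (vectorized over assignments).
# Independent of the pruning implementation: only f81_matrix is shared, and
# that is checked separately against its closed form.
brute_force_asr <- function(tree, tip_states, params) {
  tr <- stats::reorder(tree, "postorder")
  states <- params$states
  K <- length(states)
  n_tip <- length(tr$tip.label)
  internals <- (n_tip + 1):(n_tip + tr$Nnode)
  tipL <- oracle_tip_partials(tr, tip_states, states)

  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internals))))
  colnames(grid) <- as.character(internals)
  p <- params$pi[grid[, as.character(n_tip + 1L)]]
  tip_parent <- integer(n_tip)   # parent-state column per tip edge
  tip_P <- vector("list", n_tip)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]
    ch <- tr$edge[e, 2L]
    P <- f81_matrix(tr$edge.length[e], params)
    par_state <- grid[, as.character(par)]
    if (ch <= n_tip) {
      w <- as.vector(P %*% tipL[ch, ])  # depends only on parent state
      p <- p * w[par_state]
      tip_parent[ch] <- par
      tip_P[[ch]] <- P
    } else {
      p <- p * P[cbind(par_state, grid[, as.character(ch)])]
    }
  }
  total <- sum(p)

  post <- matrix(NA_real_, n_tip + tr$Nnode, K)
  for (v in internals) {
    post[v, ] <- vapply(seq_len(K), function(s) {
      sum(p[grid[, as.character(v)] == s])
    }, numeric(1)) / total
  }
  for (i in seq_len(n_tip)) {
    s <- tip_states[tr$tip.label[i]]
    if (!is.na(s)) {
      post[i, ] <- 0
      post[i, match(s, states)] <- 1
    } else {
      # joint over the missing tip's state: its unit partial was already
      # summed out of p, so reweight by the edge transition row
      par_state <- grid[, as.character(tip_parent[i])]
      post[i, ] <- colSums(p * tip_P[[i]][par_state, , drop = FALSE]) /
        total
    }
  }
  list(log_likelihood = log(total), posteriors = post, tree = tr)
}

# Random rooted tree with branch lengths plus random (possibly partially
# missing) tip states over a random alphabet.
random_asr_case <- function(n_tips, K, missing_frac = 0) {
  tree <- ape::rtree(n_tips)
  states <- paste0("s", seq_len(K))
  pi <- as.vector(stats::runif(K, 0.5, 2))
  pi <- pi / sum(pi)
  params <- f81_params(pi, rate = stats::runif(1, 0.2, 2), states = states)
  ts <- sample(states, n_tips, replace = TRUE)
  if (missing_frac > 0) {
    ts[stats::runif(n_tips) < missing_frac] <- NA
  }
  names(ts) <- tree$tip.label
  list(tree = tree, params = params, tip_states = ts)
}

petunia_universe <- c("S3", "S3L")

fixture_path <- function(name) {
  system.file("extdata", name, package = "slocusevo")
}
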
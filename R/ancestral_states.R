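# Marginal posterior ancestral-state reconstruction of discrete SI traits
# under an F81-type model on a rooted dated tree.
#
# The model: a K-state continuous-time Markov chain whose transition kernel
# relaxes toward stationary frequencies pi,
#   P_ij(t) = exp(-mu*rho*t) * [i == j] + (1 - exp(-mu*rho*t)) * pi_j,
# with mu = 1/(1 - sum(pi^2)) normalizing to one expected substitution per
# unit of rho*t at stationarity. Likelihood by Felsenstein pruning;
# per-node marginal posteriors by the standard up/down (outside) algorithm.

#' The eight SI trait states
#'
#' Genomic/phenotypic trait coding used for family-level reconstruction of
#' S-locus evolution: Class I/II T2 RNases unlinked or linked to FBA/FBK
#' F-box genes; Class III (S-/S-like) RNases linked to SLFs (type-1
#' S-locus), additionally carrying a type-3 S-locus; type-2 S-locus;
#' type-4 S-locus; S-like RNases with no linked SLFs; absence of both
#' components.
#'
#' @return Character vector of 8 state labels.
#' @export
si_trait_alphabet <- function() {
  c("CLASSI_II_UNLINKED", "CLASSI_II_LINKED", "TYPE1_LINKED",
    "TYPE1_PLUS_TYPE3", "TYPE2_SLOCUS", "TYPE4_SLOCUS",
    "SLIKE_RNASE_ONLY", "ABSENT")
}

#' F81-type model parameters
#'
#' @param pi Stationary state frequencies (named or in alphabet order);
#'   strictly positive, summing to 1 (renormalized).
#' @param rate Positive rate scaling rho per unit branch length (Myr for a
#'   dated tree).
#' @param states Optional state labels; defaults to `names(pi)` or
#'   `state1..K`.
#' @return Object of class `f81_params` with derived normalizer
#'   `mu = 1/(1 - sum(pi^2))`.
#' @export
f81_params <- function(pi, rate = 1, states = NULL) {
  if (any(pi <= 0)) stop_input("all pi entries must be > 0")
  if (rate <= 0) stop_input("rate must be > 0")
  pi <- pi / sum(pi)
  states <- states %||% names(pi) %||% paste0("state", seq_along(pi))
  if (length(states) != length(pi) || anyDuplicated(states)) {
    stop_input("states must be unique labels matching pi")
  }
  names(pi) <- states
  structure(list(pi = pi, rate = as.numeric(rate),
                 mu = 1 / (1 - sum(pi^2)), states = states),
            class = "f81_params")
}

#' @export
print.f81_params <- function(x, ...) {
  cat("<f81_params> K =", length(x$pi), "states, rate =",
      format(x$rate, digits = 4), ", mu =", format(x$mu, digits = 4), "\n")
  print(round(x$pi, 4))
  invisible(x)
}

#' F81 transition probability
#'
#' `P(j at time t | i at time 0) = exp(-mu*rho*t)*[i==j] +
#' (1 - exp(-mu*rho*t))*pi_j`.
#'
#' @param i,j State labels or indices.
#' @param t Branch length, `t >= 0`.
#' @param params [f81_params()].
#' @return Probability.
#' @export
f81_transition <- function(i, j, t, params) {
  if (t < 0) stop_input("branch length must be >= 0")
  if (is.character(i)) i <- match(i, params$states)
  if (is.character(j)) j <- match(j, params$states)
  if (anyNA(c(i, j))) stop_input("unknown state label")
  e <- exp(-params$mu * params$rate * t)
  e * (i == j) + (1 - e) * params$pi[[j]]
}

#' Full F81 transition matrix for one branch
#'
#' @inheritParams f81_transition
#' @return K x K row-stochastic matrix (rows: ancestral state).
#' @export
f81_matrix <- function(t, params) {
  if (t < 0) stop_input("branch length must be >= 0")
  K <- length(params$pi)
  e <- exp(-params$mu * params$rate * t)
  m <- matrix(rep((1 - e) * params$pi, each = K), nrow = K)
  diag(m) <- diag(m) + e
  dimnames(m) <- list(params$states, params$states)
  m
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_input("tree must be an ape phylo")
  if (is.null(tree$edge.length)) stop_input("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop_input("negative branch length")
  tree
}

# Tip partial likelihoods: indicator rows for observed states, all-ones for
# missing (NA or absent from tip_states).
tip_partial_matrix <- function(tree, tip_states, states) {
  n <- length(tree$tip.label)
  L <- matrix(1, nrow = n, ncol = length(states))
  obs <- tip_states[tree$tip.label]
  known <- !is.na(obs)
  bad <- setdiff(obs[known], states)
  if (length(bad)) {
    stop_input("tip state(s) outside the alphabet: ",
               paste(unique(bad), collapse = ", "))
  }
  L[known, ] <- 0
  L[cbind(which(known), match(obs[known], states))] <- 1
  L
}

# Up-pass (pruning). Returns scaled partials for every node, per-node log
# scale factors, and the per-edge messages needed by the down-pass.
pruning_pass <- function(tree, tip_states, params) {
  tree <- check_tree(tree)
  tr <- stats::reorder(tree, "postorder")
  K <- length(params$states)
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  L <- matrix(1, nrow = n_node, ncol = K)
  L[seq_len(n_tip), ] <- tip_partial_matrix(tr, tip_states, params$states)
  logscale <- numeric(n_node)  # rescaling applied at this node
  sub_log <- numeric(n_node)   # accumulated log scale of descendants
  n_edge <- nrow(tr$edge)
  msg <- matrix(NA_real_, nrow = n_edge, ncol = K)  # message child -> parent

  for (e in seq_len(n_edge)) {  # postorder: children complete first
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    P <- f81_matrix(tr$edge.length[e], params)
    m <- as.vector(P %*% L[child, ])
    msg[e, ] <- m
    L[parent, ] <- L[parent, ] * m
    sub_log[parent] <- sub_log[parent] + sub_log[child] + logscale[child]
    s <- max(L[parent, ])
    if (s > 0) {
      L[parent, ] <- L[parent, ] / s
      logscale[parent] <- logscale[parent] + log(s)
    }
  }
  root <- n_tip + 1L
  list(tree = tr, partials = L, logscale = logscale, sub_log = sub_log,
       msg = msg, root = root, n_tip = n_tip, K = K)
}

total_logscale <- function(up, node) {
  up$logscale[node] + up$sub_log[node]
}

#' Log-likelihood of tip states under the F81 model
#'
#' Felsenstein pruning up the (possibly multifurcating) rooted tree; the
#' root partial is combined with the stationary prior pi. Missing tips
#' contribute all-ones partials.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param tip_states Named character vector (by tip label); NA or absent
#'   tips are treated as missing data.
#' @param params [f81_params()].
#' @return Log-probability.
#' @export
tree_log_likelihood <- function(tree, tip_states, params) {
  up <- pruning_pass(tree, tip_states, params)
  lik <- sum(params$pi * up$partials[up$root, ])
  log(lik) + total_logscale(up, up$root)
}

#' Per-node marginal posterior state probabilities
#'
#' Up-pass (pruning) followed by the outside/down-pass, yielding for every
#' node the posterior distribution over states given all tip data. Tips
#' with observed states get point masses; missing tips get genuine
#' posteriors.
#'
#' @inheritParams tree_log_likelihood
#' @return Matrix (tips then internal nodes, in ape node order) x states;
#'   rows sum to 1. Row names are tip labels and `node<N>` for internals.
#' @export
marginal_posteriors <- function(tree, tip_states, params) {
  up <- pruning_pass(tree, tip_states, params)
  tr <- up$tree
  K <- up$K
  n_node <- nrow(up$partials)
  D <- matrix(NA_real_, nrow = n_node, ncol = K)  # outside vectors
  D[up$root, ] <- params$pi

  edges_by_parent <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  # reverse postorder = parents before children
  for (e in rev(seq_len(nrow(tr$edge)))) {
    parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    sibs <- setdiff(edges_by_parent[[as.character(parent)]], e)
    sib_prod <- rep(1, K)
    for (s in sibs) sib_prod <- sib_prod * up$msg[s, ]
    P <- f81_matrix(tr$edge.length[e], params)
    D[child, ] <- as.vector(crossprod(P, D[parent, ] * sib_prod))
    s <- max(D[child, ])
    if (s > 0) D[child, ] <- D[child, ] / s  # normalization cancels below
  }

  post <- D * up$partials
  post <- post / rowSums(post)
  rownames(post) <- c(tr$tip.label,
                      paste0("node", (up$n_tip + 1L):n_node))
  colnames(post) <- params$states
  post
}

#' Estimate F81 parameters and reconstruct ancestral states
#'
#' Stationary frequencies come from observed tip-state frequencies with a
#' pseudocount of 1 per state (`pi_mode = "observed"`, default) or from
#' maximum likelihood on the simplex (`"ml"`). The rate is estimated by
#' bounded 1-D maximum likelihood (golden-section via [stats::optimize()])
#' on `[1e-6/h, 1e3/h]`, `h` = tree height. MAP states break ties by
#' alphabet order.
#'
#' @inheritParams tree_log_likelihood
#' @param states Alphabet; defaults to the sorted distinct observed states.
#' @param pi_mode `"observed"` or `"ml"`.
#' @return List of class `asr_fit`: `params`, `log_likelihood`,
#'   `posteriors`, `map_states`, `selected` (MPPA-style subsets from
#'   [select_states_mppa()]).
#' @export
fit_and_reconstruct <- function(tree, tip_states, states = NULL,
                                pi_mode = c("observed", "ml")) {
  pi_mode <- match.arg(pi_mode)
  tree <- check_tree(tree)
  obs <- tip_states[!is.na(tip_states)]
  states <- states %||% sort(unique(obs))
  if (length(states) < 2) stop_input("alphabet must have at least 2 states")

  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop_input("tree has zero height")
  lo <- 1e-6 / h; hi <- 1e3 / h

  counts <- table(factor(obs, levels = states))
  pi_obs <- (as.numeric(counts) + 1) / (length(obs) + length(states))
  names(pi_obs) <- states

  if (length(unique(obs)) < 2) {
    warning("all observed tips identical: rate unidentifiable, ",
            "returning lower bound")
    params <- f81_params(pi_obs, rate = lo, states = states)
  } else if (pi_mode == "observed") {
    # search on log scale: the likelihood plateaus at saturation and a
    # linear-scale search can park there, missing interior optima
    fit <- stats::optimize(function(lr) {
      tree_log_likelihood(tree, tip_states,
                          f81_params(pi_obs, rate = exp(lr),
                                     states = states))
    }, lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-9)
    params <- f81_params(pi_obs, rate = exp(fit$maximum), states = states)
  } else {
    K <- length(states)
    # joint bounded search over logit-pi and log-rate
    obj <- function(par) {
      w <- exp(c(par[seq_len(K - 1)], 0))
      pi <- w / sum(w)
      r <- exp(par[K])
      -tree_log_likelihood(tree, tip_states,
                           f81_params(pi, rate = r, states = states))
    }
    init <- c(log(pi_obs[-length(pi_obs)] / pi_obs[length(pi_obs)]),
              log(sqrt(lo * hi)))
    opt <- stats::optim(init, obj, method = "L-BFGS-B",
                        lower = c(rep(-10, K - 1), log(lo)),
                        upper = c(rep(10, K - 1), log(hi)))
    w <- exp(c(opt$par[seq_len(K - 1)], 0))
    params <- f81_params(w / sum(w), rate = exp(opt$par[K]),
                         states = states)
  }

  post <- marginal_posteriors(tree, tip_states, params)
  map <- states[apply(post, 1L, which.max)]  # first max = alphabet order
  names(map) <- rownames(post)
  structure(list(params = params,
                 log_likelihood = tree_log_likelihood(tree, tip_states,
                                                      params),
                 posteriors = post,
                 map_states = map,
                 selected = select_states_mppa(post)),
            class = "asr_fit")
}

#' @export
print.asr_fit <- function(x, ...) {
  cat("<asr_fit> K =", length(x$params$states), "states; rate =",
      format(x$params$rate, digits = 4), "; logL =",
      format(x$log_likelihood, digits = 6), "\n")
  invisible(x)
}

#' Threshold-fraction state selection from marginal posteriors
#'
#' Per node, keep every state whose posterior is at least
#' `threshold_fraction` times the node's maximum posterior. The MAP state
#' is always included, so the subset is never empty; a uniform posterior
#' keeps all states.
#'
#' @param posteriors Matrix from [marginal_posteriors()].
#' @param threshold_fraction Fraction of the maximum (default 0.5).
#' @return Named list of character vectors, one per node.
#' @export
select_states_mppa <- function(posteriors, threshold_fraction = 0.5) {
  states <- colnames(posteriors)
  out <- apply(posteriors, 1L, function(p) {
    states[p >= threshold_fraction * max(p)]
  }, simplify = FALSE)
  names(out) <- rownames(posteriors)
  out
}

#' Read a tip trait table
#'
#' Expected columns: `taxon`, `state` (NA for missing data).
#'
#' @param path TSV path.
#' @return Named character vector of states keyed by taxon.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "?"))
  if (length(setdiff(c("taxon", "state"), names(tab)))) {
    stop_input("trait table must have columns taxon, state")
  }
  stats::setNames(tab$state, tab$taxon)
}

#' Write per-node posteriors as TSV and an annotated Newick
#'
#' @param fit An `asr_fit`.
#' @param tree The tree used for the fit.
#' @param posterior_path Output TSV (node, then one column per state).
#' @param newick_path Optional output Newick with MAP states as internal
#'   node labels.
#' @return `posterior_path`, invisibly.
#' @export
write_asr_results <- function(fit, tree, posterior_path,
                              newick_path = NULL) {
  df <- data.frame(node = rownames(fit$posteriors),
                   map_state = fit$map_states,
                   round(fit$posteriors, 6), check.names = FALSE)
  utils::write.table(df, posterior_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(newick_path)) {
    tr <- stats::reorder(check_tree(tree), "postorder")
    n_tip <- length(tr$tip.label)
    tr$node.label <- fit$map_states[paste0("node",
                                           (n_tip + 1L):(n_tip + tr$Nnode))]
    ape::write.tree(tr, file = newick_path)
  }
  invisible(posterior_path)
}
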
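#' Configuration for the environment-coupled birth-death simulator
#'
#' @param origin_time Stem origin of the clade in Ma (> 0).
#' @param base_speciation Baseline speciation rate lambda0 (events/lineage/Myr).
#' @param base_extinction Baseline extinction rate mu0 (events/lineage/Myr).
#' @param env_link_speciation Coefficient b on the environmental proxy in
#'   log speciation rate: lambda(t) = exp(log lambda0 + b * E(t)). Units:
#'   per proxy unit.
#' @param env_link_extinction Same, acting on log extinction rate.
#' @param env_response_lag Response delay in Myr: rates at time `t` respond
#'   to the proxy value at `t + env_response_lag` (i.e. that many Myr
#'   earlier). Default 0 (instantaneous response). A positive lag makes the
#'   driver strictly precede the response, the causal ordering that directed
#'   information measures are designed to detect.
#' @param habitat_transition_rate Total rate of habitat switches along a
#'   lineage (events/lineage/Myr) for the symmetric 3-state Markov process
#'   over marine/freshwater/terrestrial.
#' @param max_tips Hard cap on the number of tips; exceeding it aborts the
#'   simulation with an error (a supercritical run would only explode again
#'   on retry).
#' @param max_retries Retries (with incrementing seeds) when the clade dies
#'   or fails to branch before 2 tips exist.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(origin_time, base_speciation, base_extinction,
                       env_link_speciation = 0, env_link_extinction = 0,
                       env_response_lag = 0, habitat_transition_rate = 0,
                       max_tips = 5000L, max_retries = 20L, seed = NULL) {
  if (origin_time <= 0) stop("'origin_time' must be positive")
  if (base_speciation < 0 || base_extinction < 0 || habitat_transition_rate < 0)
    stop("rates must be non-negative")
  if (env_response_lag < 0) stop("'env_response_lag' must be non-negative")
  if (max_tips < 2) stop("'max_tips' must be at least 2")
  structure(list(origin_time = origin_time,
                 base_speciation = base_speciation,
                 base_extinction = base_extinction,
                 env_link_speciation = env_link_speciation,
                 env_link_extinction = env_link_extinction,
                 env_response_lag = env_response_lag,
                 habitat_transition_rate = habitat_transition_rate,
                 max_tips = as.integer(max_tips),
                 max_retries = as.integer(max_retries),
                 seed = seed),
            class = "sim_config")
}

#' Simulate a complete birth-death tree with environment-linked rates
#'
#' Simulates every lineage ever born from a single stem lineage at
#' `origin_time` down to the present. Speciation and (optionally) extinction
#' rates respond log-linearly to an environmental proxy:
#' `lambda(t) = exp(log lambda0 + b_lambda E(t))`, and analogously for mu.
#' Because the rates vary continuously in time, events are scheduled by a
#' thinning (rejection) algorithm against the global rate upper bound implied
#' by the proxy's range, which is exact for bounded intensities. Habitats
#' evolve along branches as a symmetric continuous-time Markov chain over
#' marine/freshwater/terrestrial; each tip is labelled with its terminal
#' state.
#'
#' The returned tree is "complete": extinct lineages are retained as tips
#' with age > 0, lineages surviving to the present are tips at age 0. Runs
#' that end with fewer than two tips (stem dies, or survives unbranched) are
#' retried with incrementing seeds up to `max_retries`; the retry count is
#' reported.
#'
#' @param config A [sim_config()].
#' @param env Optional [env_series()] whose span covers
#'   `[origin_time, 0]`; `NULL` means a constant environment (E = 0), and a
#'   zero link coefficient makes a supplied environment inert.
#' @return A list of class `bd_sim`: `tree` (a rooted binary `phylo` with
#'   `root.edge` carrying the stem below the crown node), `habitat` (named
#'   character vector over tips), `retries`, and `config`.
#' @examples
#' sim <- simulate_bd_tree(sim_config(10, 0.3, 0.1, seed = 1))
#' sim$tree
#' @export
simulate_bd_tree <- function(config, env = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(env)) {
    stopifnot(inherits(env, "env_series"))
    lag <- config$env_response_lag
    if (max(env$times) < config$origin_time + lag || min(env$times) > lag)
      stop("environmental series must span [origin_time + lag, lag]")
  }
  for (attempt in 0:config$max_retries) {
    if (!is.null(config$seed)) set.seed(config$seed + attempt)
    res <- bd_attempt(config, env)
    if (!is.null(res)) {
      res$retries <- attempt
      res$config <- config
      return(res)
    }
  }
  stop("simulation failed: no run produced >= 2 tips in ",
       config$max_retries + 1L, " attempts")
}

# One forward simulation; NULL signals "retry" (fewer than 2 tips).
bd_attempt <- function(config, env) {
  lag <- config$env_response_lag
  envf <- if (is.null(env)) function(t) rep(0, length(t))
          else {
            f <- approxfun(env$times, env$values, rule = 1)
            function(t) f(t + lag)
          }
  # range of E over the evaluated window: knots inside plus the endpoints
  if (is.null(env)) {
    e_rng <- c(0, 0)
  } else {
    lo <- lag; hi <- config$origin_time + lag
    inside <- env$values[env$times <= hi & env$times >= lo]
    ends <- approx(env$times, env$values, xout = c(hi, lo), rule = 1)$y
    e_rng <- range(c(inside, ends))
  }
  lam0 <- config$base_speciation; bl <- config$env_link_speciation
  mu0 <- config$base_extinction;  bm <- config$env_link_extinction
  lam_bound <- lam0 * exp(max(bl * e_rng))
  mu_bound <- mu0 * exp(max(bm * e_rng))
  rate_bound <- lam_bound + mu_bound
  if (rate_bound <= 0) return(NULL)

  nmax <- 2L * config$max_tips          # lineages, not tips
  birth <- end <- numeric(nmax)
  parent <- integer(nmax)
  fate <- character(nmax)               # "speciation" / "extinct" / "extant"
  birth[1L] <- config$origin_time; parent[1L] <- 0L
  n_lin <- 1L
  alive <- 1L
  n_dead_tips <- 0L
  t <- config$origin_time

  repeat {
    n <- length(alive)
    if (n == 0L) break
    if (n + n_dead_tips > config$max_tips)
      stop("simulation exceeded max_tips = ", config$max_tips,
           "; raise the cap or lower the rates")
    t <- t - rexp(1L, n * rate_bound)
    if (t <= 0) break
    u <- runif(1L)
    e_t <- envf(t)
    lam <- lam0 * exp(bl * e_t)
    mu <- mu0 * exp(bm * e_t)
    if (u >= (lam + mu) / rate_bound) next      # thinned (phantom) event
    k <- alive[[sample.int(n, 1L)]]
    if (runif(1L) < lam / (lam + mu)) {         # speciation: k ends, 2 born
      end[k] <- t; fate[k] <- "speciation"
      c1 <- n_lin + 1L; c2 <- n_lin + 2L
      birth[c(c1, c2)] <- t; parent[c(c1, c2)] <- k
      n_lin <- n_lin + 2L
      alive <- c(alive[alive != k], c1, c2)
    } else {                                    # extinction
      end[k] <- t; fate[k] <- "extinct"
      alive <- alive[alive != k]
      n_dead_tips <- n_dead_tips + 1L
    }
  }
  if (length(alive)) { end[alive] <- 0; fate[alive] <- "extant" }
  n_tips <- sum(fate[1:n_lin] %in% c("extinct", "extant"))
  if (n_tips < 2L) return(NULL)

  lin <- list(birth = birth[1:n_lin], end = end[1:n_lin],
              parent = parent[1:n_lin], fate = fate[1:n_lin])
  tree <- lineages_to_phylo(lin, config$origin_time)
  habitat <- evolve_habitats(lin, tree, config$habitat_transition_rate)
  structure(list(tree = tree, habitat = habitat), class = "bd_sim")
}

# Convert the lineage table to an ape phylo. Each lineage is exactly one
# edge (a lineage ends by speciating, dying, or reaching the present); each
# speciation event is an internal node. Lineage 1 ends at the crown node.
lineages_to_phylo <- function(lin, origin_time) {
  n_lin <- length(lin$birth)
  is_tip <- lin$fate %in% c("extinct", "extant")
  n_tip <- sum(is_tip)
  node_no <- integer(n_lin)
  node_no[is_tip] <- seq_len(n_tip)
  # creation order of speciating lineages is a preorder: parents first
  node_no[!is_tip] <- n_tip + seq_len(sum(!is_tip))
  kids <- which(lin$parent > 0L)
  edge <- cbind(node_no[lin$parent[kids]], node_no[kids])
  edge_len <- lin$birth[kids] - lin$end[kids]
  tree <- structure(list(edge = edge,
                         edge.length = edge_len,
                         tip.label = paste0("t", seq_len(n_tip)),
                         Nnode = n_tip - 1L),
                    class = "phylo", order = "cladewise")
  tree$root.edge <- origin_time - lin$end[1L]
  # anchor absolute ages even if every tip went extinct
  attr(tree, "root_age") <- lin$end[1L]
  tree
}

# Terminal habitat states under a symmetric 3-state CTMC with total leaving
# rate q; only end states matter, so each lineage is advanced by a Poisson
# number of uniform jumps. Children start in their parent's end state.
evolve_habitats <- function(lin, tree, q) {
  n_lin <- length(lin$birth)
  state <- character(n_lin)
  start <- sample(HABITATS, 1L)
  end_state <- character(n_lin)
  for (i in seq_len(n_lin)) {
    s <- if (lin$parent[i] == 0L) start else end_state[lin$parent[i]]
    dur <- lin$birth[i] - lin$end[i]
    n_jump <- if (q > 0) stats::rpois(1L, q * dur) else 0L
    for (j in seq_len(n_jump)) s <- sample(setdiff(HABITATS, s), 1L)
    end_state[i] <- s
  }
  is_tip <- lin$fate %in% c("extinct", "extant")
  structure(end_state[is_tip], names = tree$tip.label)
}
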
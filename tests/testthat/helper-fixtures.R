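# shared fixtures, built in code

# logistic-map series (r = 3.8, chaotic) for embedding/simplex tests
logistic_series <- function(n, r = 3.8, x0 = 0.41, burn = 20L) {
  x <- numeric(n + burn)
  x[1L] <- x0
  for (t in seq_len(n + burn - 1L)) x[t + 1L] <- r * x[t] * (1 - x[t])
  x[-seq_len(burn)]
}

# independent brute-force simplex forecast: coded separately from the
# package path (plain loops, no shared helpers)
brute_simplex <- function(lib, targets, time_labels, query, exclude = integer(0)) {
  E <- ncol(lib)
  k <- E + 1L
  n <- nrow(lib)
  d <- rep(Inf, n)
  for (i in seq_len(n)) {
    if (i %in% exclude) next
    d[i] <- sqrt(sum((lib[i, ] - query)^2))
  }
  ord <- order(d, time_labels)
  ids <- ord[seq_len(k)]
  dd <- d[ids]
  if (dd[1L] == 0) {
    w <- ifelse(dd == 0, 1, 0)
  } else {
    w <- exp(-dd / dd[1L])
  }
  w <- w / sum(w)
  sum(w * targets[ids])
}

# small driven-population run set: three conditions x two replicates under a
# common temperature sequence (zero observation noise)
make_run_set <- function(n_input = 256L, temp_seed = 21L) {
  set.seed(temp_seed)
  temps <- stats::runif(n_input, 15, 35)
  runs <- list()
  for (cond in c("low", "med", "high")) {
    for (rep in 1:2) {
      pr <- nutrient_preset(cond, seed = if (rep == 1L) 100L else 200L)
      runs[[paste0(cond, rep)]] <- simulate_driven_population(
        temps, pr, init_p = c(0.2, 0.6)[rep] * pr$K_peak,
        condition = cond, replicate = rep)
    }
  }
  list(temps = temps, runs = runs)
}
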
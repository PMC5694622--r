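# Shared oracles and fixture builders.  Everything here is independent of
# the package's computational paths: the brute-force VUS evaluates the
# defining triple sum directly, and the Bayes posterior comes from the
# generating mixture in closed form.

# Tie-handling concordance weight for one ordered triple.
w3 <- function(a, b, c) {
  if (a < b && b < c) return(1)
  if ((a == b && b < c) || (a < b && b == c)) return(0.5)
  if (a == b && b == c) return(1 / 6)
  0
}

# Brute-force tie-weighted VUS: the O(n^3) triple sum over ALL index
# triples.  The weight of triple (i, j, l) is evaluated term by term as
# [t_i < t_j][t_j < t_l] + 1/2 [t_i = t_j][t_j < t_l]
# + 1/2 [t_i < t_j][t_j = t_l] + 1/6 [t_i = t_j][t_j = t_l],
# which reproduces w3() case by case; only the innermost index is
# vectorized.
brute_vus <- function(t, d) {
  n <- length(t)
  lt <- outer(t, t, "<")
  eq <- outer(t, t, "==")
  num <- 0
  for (j in seq_len(n)) {
    for (l in seq_len(n)) {
      w <- lt[, j] * lt[j, l] + 0.5 * eq[, j] * lt[j, l] +
        0.5 * lt[, j] * eq[j, l] + (1 / 6) * eq[, j] * eq[j, l]
      num <- num + sum(w * d[, 1]) * d[j, 2] * d[l, 3]
    }
  }
  num / (sum(d[, 1]) * sum(d[, 2]) * sum(d[, 3]))
}

# Closed-form class posterior of the default generating mixture.
bayes_rho <- function(tt, aa, config = sim_config()) {
  Si <- solve(config$sigma)
  num <- sapply(1:3, function(k) {
    mu <- k * config$mean_base
    d <- cbind(tt - mu[1], aa - mu[2])
    config$theta[k] * exp(-0.5 * rowSums((d %*% Si) * d))
  })
  num / rowSums(num)
}

# Fully verified dataset with given test values and classes.
full_data <- function(t, cls) {
  prepare_roc3(data.frame(T = t, D = cls, V = 1L), "T", "D", "V",
               class_order = 1:3)
}

# Paper-design dataset, prepared.
sim_prepared <- function(n, seed, config = sim_config()) {
  prepare_roc3(simulate_roc3(n, config, seed = seed), "T", "D", "V", "A")
}

# Hand-built model-fit stand-ins for unit tests of the D-hat formulas.
fake_verif <- function(pi) structure(list(pi = pi, link = "logit"),
                                     class = "verif_fit")
fake_rho <- function(rho, method = "mlogit")
  structure(list(rho = rho, method = method), class = "rho_fit")
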
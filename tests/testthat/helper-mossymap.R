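# Shared fixtures and independent oracles, all built in code.

mm_cube <- function(side = 1000) cuboid(c(0, side), c(0, side), c(0, side))

# Brute-force double-loop K estimator: the independent oracle for ripley_k.
brute_force_k <- function(xyz, region, t_grid,
                          correction = c("none", "translation")) {
  correction <- match.arg(correction)
  L <- region$hi - region$lo
  V <- prod(L)
  n <- nrow(xyz)
  vapply(t_grid, function(t) {
    acc <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij <= t) {
        w <- if (correction == "translation")
          V / prod(L - abs(xyz[i, ] - xyz[j, ])) else 1
        acc <- acc + w
      }
    }
    V / (n * (n - 1)) * acc
  }, numeric(1))
}

# Tiny terminal table: n points per (animal, origin, side, lobule) row spec.
make_points <- function(spec) {
  do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    n <- spec$n[i]
    if (n == 0) return(NULL)
    data.frame(animal = spec$animal[i], origin = spec$origin[i],
               x = rep(0, n), y = 0, z = 0,
               side = spec$side[i], lobule = spec$lobule[i],
               stripe = "unassigned", stringsAsFactors = FALSE)
  }))
}

# A small, fast study configuration used across tests.
small_config <- function(...) {
  simulation_config(
    n_terminals = c(M1 = 1200, S1 = 1200, PPC = 600, V1 = 400,
                    A1 = 400, AuD = 300),
    ...)
}

# Planted-mixing configuration with labels forced analytically:
# Sim far below the 4% floor; Cop dominated 96% by S1 with two minor
# origins (moderate); the five big lobules strongly multimodal (high).
planted_config <- function(n = 10000) {
  mix <- matrix(0, 3, 16,
                dimnames = list(c("M1", "S1", "PPC"),
                                c("I", "II", "III", "IV/V", "VI", "VII",
                                  "VIII", "IX", "X", "Sim", "CrusI",
                                  "CrusII", "PM", "Cop", "PFl", "Fl")))
  mix["M1", c("IV/V", "VI", "CrusI", "CrusII", "PM", "Cop", "Sim")] <-
    c(0.30, 0.25, 0.20, 0.15, 0.09, 0.005, 0.005)
  mix["S1", c("IV/V", "VI", "CrusI", "CrusII", "PM", "Cop", "Sim")] <-
    c(0.10, 0.28, 0.25, 0.05, 0.075, 0.24, 0.005)
  mix["PPC", c("IV/V", "VI", "CrusI", "CrusII", "PM", "Cop", "Sim")] <-
    c(0.20, 0.05, 0.14, 0.40, 0.20, 0.005, 0.005)
  simulation_config(origins = c("M1", "S1", "PPC"),
                    n_terminals = c(M1 = n, S1 = n, PPC = n),
                    contra_fraction = c(M1 = 0.7, S1 = 0.7, PPC = 0.7),
                    mixing = mix, concentration = Inf)
}

# Independent application of the two-threshold rule to planted simplex
# proportions (the classifier oracle: pure arithmetic on expectations).
analytic_labels <- function(mix, n_per_origin, input_floor = 4,
                            multimodal_threshold = 15, min_origins = 2) {
  expected <- sweep(mix, 1, n_per_origin, "*")      # origin x lobule
  lob_tot <- colSums(expected)
  side_share <- 100 * lob_tot / sum(lob_tot)        # same on both sides
  labs <- character(0)
  for (lb in colnames(mix)[lob_tot > 0]) {
    shares <- 100 * expected[, lb] / lob_tot[lb]
    dom <- which.max(shares)
    s_comb <- sum(shares[-dom][shares[-dom] > 0])
    n_nd <- sum(shares[-dom] > 0)
    labs[lb] <- if (side_share[lb] <= input_floor) "excluded"
      else if (n_nd < min_origins) "excluded"
      else if (s_comb > multimodal_threshold) "high" else "moderate"
  }
  labs
}
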
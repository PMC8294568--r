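# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms and distribution calls so that implementation and
# check stay on separate routes.

# Fixed-step RK4 integration of dC/dt = phi(t) - k*C with the absorbed
# integral A(t) = int k*C dt accumulated alongside; steps are halved until
# two successive refinements agree to rtol.
integrate_absorption_ode <- function(phi_fun, k, tau, c0 = 0, rtol = 1e-10) {
  run <- function(n_steps) {
    h <- tau / n_steps
    state <- c(C = c0, A = 0)
    deriv <- function(t, s) c(phi_fun(t) - k * s[1L], k * s[1L])
    t <- 0
    for (i in seq_len(n_steps)) {
      k1 <- deriv(t, state)
      k2 <- deriv(t + h / 2, state + h / 2 * k1)
      k3 <- deriv(t + h / 2, state + h / 2 * k2)
      k4 <- deriv(t + h, state + h * k3)
      state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    state
  }
  n <- 64L
  prev <- run(n)
  repeat {
    n <- n * 2L
    cur <- run(n)
    if (all(abs(cur - prev) <= rtol * (abs(cur) + 1e-12)) || n >= 65536L)
      return(cur)
    prev <- cur
  }
}

# Two-tailed Fisher p by explicit enumeration of every table with the
# observed margins, using the log-factorial form of the table probability
# (not dhyper).
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L]); n <- r1 + r2
  ptab <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (b < 0 || cc < 0 || d < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
          lfactorial(n) - lfactorial(a) - lfactorial(b) - lfactorial(cc) -
          lfactorial(d))
  }
  all_a <- 0:min(r1, c1)
  probs <- vapply(all_a, ptab, 0)
  keep <- !is.na(probs)
  p_obs <- ptab(tab[1L, 1L])
  sum(probs[keep][probs[keep] <= p_obs * (1 + 1e-7)])
}

# Plain (unadjusted) Rand index between two labelings.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# Homogeneous (single-type, no activity factor) cohort spec used for
# null-calibration checks where cells must be independent.
null_type_spec <- function(sd = 0.7) {
  cols <- c("inulin:acetate", "inulin:propionate", "inulin:butyrate",
            "pectin:acetate", "pectin:propionate", "pectin:butyrate")
  list(null = list(mean = setNames(rep(c(1.5, 1.1, 0.9), 2), cols), sd = sd))
}

# rates -> high/low matrix shortcut used in stability tests
binarized_from <- function(scfa_df) {
  binarize_high_low(zscore_columns(mmp_matrix(
    net_production_rates(production_rates(scfa_df)))))
}
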
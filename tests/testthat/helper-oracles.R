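# Independent one-line evaluators used as oracles: deliberately written as
# direct formula transcriptions, separate from the package implementation.

EPS0_ORACLE <- 8.8541878128e-12

# direct Cole-Cole evaluation from a plain list of numbers
oracle_eps <- function(eps_inf, d_eps, tau, alpha, sigma_dc, f) {
  w <- 2 * pi * f
  acc <- eps_inf + sigma_dc / (1i * w * EPS0_ORACLE)
  for (n in seq_along(d_eps))
    acc <- acc + d_eps[n] / (1 + (1i * w * tau[n])^(1 - alpha[n]))
  acc
}

oracle_sigma_eq <- function(eps_inf, d_eps, tau, alpha, sigma_dc, f) {
  2 * pi * f * EPS0_ORACLE * (-Im(oracle_eps(eps_inf, d_eps, tau, alpha,
                                             sigma_dc, f)))
}

# pure sum-of-Debye evaluator (all alpha = 0), coded without complex powers
oracle_debye <- function(eps_inf, d_eps, tau, sigma_dc, f) {
  w <- 2 * pi * f
  acc <- complex(real = eps_inf) + sigma_dc / (1i * w * EPS0_ORACLE)
  for (n in seq_along(d_eps)) {
    den <- 1 + (w * tau[n])^2
    acc <- acc + d_eps[n] * (1 - 1i * w * tau[n]) / den
  }
  acc
}

cc_as_args <- function(p) {
  list(eps_inf = p$eps_inf,
       d_eps = vapply(p$dispersions, `[[`, numeric(1), "delta_eps"),
       tau = vapply(p$dispersions, `[[`, numeric(1), "tau"),
       alpha = vapply(p$dispersions, `[[`, numeric(1), "alpha"),
       sigma_dc = p$sigma_dc)
}

# random valid Cole-Cole parameter draw for property tests
random_cole_cole <- function() {
  nd <- sample(0:4, 1)
  cole_cole(runif(1, 1, 80),
            lapply(seq_len(nd), function(i)
              dispersion(10^runif(1, 0, 7), 10^runif(1, -11, -2),
                         runif(1, 0, 0.5))),
            10^runif(1, -4, 0))
}

reference_profile <- function(sex = "male", bmi = 23)
  subject_profile(sex, bmi, rep(2 * pi * 6.5, 3))
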